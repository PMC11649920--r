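#' Keep only quality-controlled poly(A) length estimates
#'
#' Nanopore per-read poly(A) length callers tag each estimate with a QC
#' outcome; only reads tagged `"PASS"` (by default) carry trustworthy length
#' estimates and are retained.
#'
#' @param tbl Per-read table: `read_id`, `transcript_id`, `condition`,
#'   `replicate`, `polya_length`, `qc_tag`.
#' @param pass_tag QC tag to keep (default `"PASS"`).
#' @return A list with `table` (retained rows) and `audit` (a named count per
#'   observed tag).
#' @export
qc_filter <- function(tbl, pass_tag = "PASS") {
  check_polya_table(tbl)
  audit <- table(tbl$qc_tag)
  out <- tbl[tbl$qc_tag == pass_tag, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, audit = stats::setNames(as.integer(audit), names(audit)))
}

check_polya_table <- function(tbl) {
  need <- c("read_id", "transcript_id", "condition", "replicate",
            "polya_length", "qc_tag")
  if (!all(need %in% names(tbl)))
    stop("poly(A) read table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(tbl$polya_length)) || any(tbl$polya_length < 0))
    stop("polya_length must be finite and >= 0")
  invisible(tbl)
}

#' Summarize per-read poly(A) tails at the transcript level
#'
#' Computes per-replicate median tail lengths and read counts per transcript
#' and condition. A transcript is reported only when it has at least
#' `min_reads` reads in each of at least `min_replicates` replicates. The
#' transcript-level tail statistic is the mean of the replicate medians
#' (replicates are the experimental unit); a pooled-read median is reported
#' alongside. Expression level is summarized as the replicate mean of `log2`
#' depth-normalized read counts (fraction of the replicate's reads).
#'
#' @param tbl A QC-filtered per-read table.
#' @param min_reads Minimum reads per replicate (default 20).
#' @param min_replicates Minimum number of replicates meeting `min_reads`
#'   (default 2).
#' @return A list with `table` (`transcript_id`, `condition`,
#'   `n_replicates_passing`, `median_tail` (mean of replicate medians),
#'   `pooled_median_tail`, `mean_log2_level`, `n_reads_total`) and `audit`
#'   (`n_transcripts`, `n_excluded`).
#' @export
summarize_transcripts <- function(tbl, min_reads = 20, min_replicates = 2) {
  check_polya_table(tbl)
  depth <- tapply(tbl$read_id, list(tbl$condition, tbl$replicate), length)
  excluded <- 0L
  groups <- split(tbl, list(tbl$transcript_id, tbl$condition), drop = TRUE)
  rows <- lapply(groups, function(d) {
    reps <- split(d$polya_length, d$replicate)
    n_per_rep <- vapply(reps, length, integer(1))
    passing <- n_per_rep >= min_reads
    if (sum(passing) < min_replicates) { excluded <<- excluded + 1L; return(NULL) }
    rep_medians <- vapply(reps[passing], stats::median, numeric(1))
    lv <- log2(n_per_rep[passing] /
                 depth[d$condition[1], names(reps)[passing]])
    data.frame(transcript_id = d$transcript_id[1], condition = d$condition[1],
               n_replicates_passing = sum(passing),
               median_tail = mean(rep_medians),
               pooled_median_tail = stats::median(unlist(reps[passing])),
               mean_log2_level = mean(lv),
               n_reads_total = sum(n_per_rep[passing]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), condition = character(),
                      n_replicates_passing = integer(), median_tail = numeric(),
                      pooled_median_tail = numeric(), mean_log2_level = numeric(),
                      n_reads_total = integer())
  rownames(out) <- NULL
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  list(table = out,
       audit = c(n_transcripts = length(groups), n_excluded = excluded))
}

#' Compare per-transcript median tails between two conditions
#'
#' Matches transcripts present in both summaries and applies a paired
#' Wilcoxon signed-rank test with continuity correction to the per-transcript
#' median tails. Zero differences are dropped (standard signed-rank
#' convention) and counted; if every difference is zero the test is
#' degenerate and `p = 1` is reported. Each distribution's median and
#' quartiles are returned alongside.
#'
#' @param summary_a,summary_b Tables from [summarize_transcripts()]
#'   (`$table`).
#' @param statistic Column to compare (default `"median_tail"`).
#' @return A list: `n_pairs`, `n_zero_dropped`, `V` (signed-rank statistic),
#'   `p_value`, `median_shift` (median of b - a), and `quartiles` (2 x 3
#'   matrix of Q1/median/Q3 for each condition over matched transcripts).
#' @export
polya_compare_conditions <- function(summary_a, summary_b,
                                     statistic = "median_tail") {
  common <- intersect(summary_a$transcript_id, summary_b$transcript_id)
  if (length(common) == 0) stop("no transcripts in common")
  a <- summary_a[match(common, summary_a$transcript_id), statistic]
  b <- summary_b[match(common, summary_b$transcript_id), statistic]
  d <- b - a
  nz <- d != 0
  p <- if (any(nz)) {
    stats::wilcox.test(b[nz], a[nz], paired = TRUE, correct = TRUE,
                       exact = FALSE)$p.value
  } else 1
  V <- if (any(nz))
    unname(stats::wilcox.test(b[nz], a[nz], paired = TRUE, correct = TRUE,
                              exact = FALSE)$statistic)
  else NA_real_
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(n_pairs = length(common), n_zero_dropped = sum(!nz),
       V = V, p_value = p, median_shift = stats::median(d),
       quartiles = rbind(a = qs(a), b = qs(b)))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Correlates paired per-transcript changes (e.g. change in median tail
#' length versus change in log2 expression level between a depletion and its
#' control). The confidence interval is obtained on the Fisher
#' `atanh` scale with standard error `1/sqrt(n - 3)` and back-transformed.
#' For numerically perfect correlations the interval degenerates to `r`.
#'
#' @param delta_tail,delta_level Paired numeric vectors (>= 4 pairs).
#' @param level Confidence level (default 0.95).
#' @return A list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
delta_correlation <- function(delta_tail, delta_level, level = 0.95) {
  if (length(delta_tail) != length(delta_level))
    stop("paired vectors must have equal length")
  ok <- is.finite(delta_tail) & is.finite(delta_level)
  x <- delta_tail[ok]; y <- delta_level[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1 - 1e-12)
    return(list(r = r, ci_low = r, ci_high = r, n = n))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, ci_low = tanh(z - zc * se), ci_high = tanh(z + zc * se), n = n)
}
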