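#' Compute RIP-seq log2 enrichment from a count matrix
#'
#' Implements the enrichment pipeline for purification (IP) versus input
#' libraries, in order:
#' 1. drop features with fewer than `min_reads` reads in any sample used;
#' 2. divide each sample's counts by its total (fraction of library);
#' 3. log2 transform;
#' 4. average replicates within each condition;
#' 5. subtract the input condition from each purification condition;
#' 6. center each feature by subtracting its median across purification
#'    conditions.
#'
#' Because the filter floors counts at `min_reads`, no zero counts reach the
#' log step and no pseudocounts are used.
#'
#' @param counts Integer matrix, features x samples, with feature row names
#'   and sample column names.
#' @param samples Data frame describing the columns of `counts`: `sample`,
#'   `condition`, `replicate`, `is_input` (logical). All `is_input` samples
#'   form the input condition.
#' @param min_reads Per-sample feature filter (default 10).
#' @param center If `FALSE`, skip step 6 (useful for effect-size recovery on
#'   a single purification).
#' @return A list with `table` (long data frame `feature_id`, `purification`,
#'   `log2_enrichment`, `log2_enrichment_uncentered`) and `audit`
#'   (`n_features`, `n_filtered`, `n_used`).
#' @export
compute_enrichment <- function(counts, samples, min_reads = 10, center = TRUE) {
  check_count_matrix(counts, samples)
  if (!any(samples$is_input)) stop("at least one input sample is required")
  if (all(samples$is_input)) stop("at least one purification sample is required")

  keep <- apply(counts, 1, function(x) all(x >= min_reads))
  flt <- counts[keep, , drop = FALSE]
  if (nrow(flt) == 0) stop("no feature passed the read filter")

  frac <- sweep(flt, 2, colSums(counts), "/")  # library totals from all counts
  lg <- log2(frac)

  cond <- ifelse(samples$is_input, ".input", samples$condition)
  cond_means <- sapply(unique(cond), function(cc)
    rowMeans(lg[, cond == cc, drop = FALSE]))
  if (is.null(dim(cond_means)))  # single retained feature
    cond_means <- matrix(cond_means, nrow = 1,
                         dimnames = list(rownames(lg), unique(cond)))
  purifs <- setdiff(colnames(cond_means), ".input")
  enr <- cond_means[, purifs, drop = FALSE] - cond_means[, ".input"]

  centered <- if (center) {
    enr - apply(enr, 1, stats::median)
  } else enr

  tab <- data.frame(
    feature_id = rep(rownames(enr), times = length(purifs)),
    purification = rep(purifs, each = nrow(enr)),
    log2_enrichment = as.vector(centered),
    log2_enrichment_uncentered = as.vector(enr)
  )
  list(table = tab,
       audit = c(n_features = nrow(counts), n_filtered = sum(!keep),
                 n_used = nrow(flt)))
}

check_count_matrix <- function(counts, samples) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must be a matrix with feature row names and sample column names")
  if (any(counts < 0)) stop("counts must be >= 0")
  need <- c("sample", "condition", "replicate", "is_input")
  if (!all(need %in% names(samples)))
    stop("`samples` must have columns: ", paste(need, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)) ||
      anyDuplicated(samples$sample))
    stop("`samples$sample` must match the columns of `counts` exactly")
  invisible(NULL)
}

#' Per-replicate raw enrichment (fraction-difference mode)
#'
#' For each purification replicate, `log2` of the feature's fraction of the
#' IP library minus `log2` of its fraction of the matching input replicate.
#' This is the per-replicate quantity comparable to an RT-qPCR validation;
#' feature/replicate pairs with a zero count on either side are skipped and
#' counted.
#'
#' @inheritParams compute_enrichment
#' @return A list with `table` (`feature_id`, `purification`, `replicate`,
#'   `raw_log2_enrichment`) and `audit` (`n_skipped_zero`).
#' @export
raw_enrichment <- function(counts, samples) {
  check_count_matrix(counts, samples)
  totals <- colSums(counts)
  inputs <- samples[samples$is_input, , drop = FALSE]
  ips <- samples[!samples$is_input, , drop = FALSE]
  skipped <- 0L
  rows <- lapply(seq_len(nrow(ips)), function(i) {
    ip <- ips[i, ]
    inp <- inputs[inputs$replicate == ip$replicate, , drop = FALSE]
    if (nrow(inp) == 0)
      stop("no input sample for replicate ", ip$replicate)
    ci <- counts[, ip$sample]; cn <- counts[, inp$sample[1]]
    ok <- ci > 0 & cn > 0
    skipped <<- skipped + sum(!ok)
    data.frame(feature_id = rownames(counts)[ok],
               purification = ip$condition, replicate = ip$replicate,
               raw_log2_enrichment =
                 log2(ci[ok] / totals[ip$sample]) - log2(cn[ok] / totals[inp$sample[1]]))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, audit = c(n_skipped_zero = skipped))
}

#' Welch test of enrichment between two feature categories
#'
#' For each purification, compares `log2_enrichment` between two labeled
#' groups of features (e.g. unstable "XUT/SUT"-class transcripts versus all
#' others) with a Welch two-sample t-test, and reports each group's median
#' and quartiles plus sizes. A group with fewer than 2 features yields the
#' summary only, without a test.
#'
#' @param table Enrichment table from [compute_enrichment()] (`$table`).
#' @param categories Named character vector or data frame
#'   (`feature_id`, `category`) with exactly two category levels.
#' @param value Column of `table` to compare (default the median-centered
#'   `"log2_enrichment"`; with a single purification that column is
#'   identically zero by construction, so use
#'   `"log2_enrichment_uncentered"` there).
#' @return Data frame, one row per purification x category, with
#'   `median`, `q1`, `q3`, `n`, and the shared `t_statistic`, `df`,
#'   `p_value` of the Welch test (NA when degenerate).
#' @export
category_test <- function(table, categories, value = "log2_enrichment") {
  if (!value %in% names(table)) stop("no column `", value, "` in `table`")
  table$log2_enrichment <- table[[value]]
  if (is.data.frame(categories)) {
    cats <- stats::setNames(as.character(categories$category),
                            categories$feature_id)
  } else cats <- categories
  table$category <- cats[table$feature_id]
  if (any(is.na(table$category))) stop("every feature needs a category label")
  lev <- sort(unique(table$category))
  if (length(lev) != 2) stop("exactly two categories are required")

  rows <- lapply(split(table, table$purification), function(d) {
    g1 <- d$log2_enrichment[d$category == lev[1]]
    g2 <- d$log2_enrichment[d$category == lev[2]]
    test <- if (length(g1) >= 2 && length(g2) >= 2 &&
                (stats::var(g1) + stats::var(g2)) > 0) {
      stats::t.test(g1, g2, var.equal = FALSE)
    } else NULL
    qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    q1 <- qs(g1); q2 <- qs(g2)
    data.frame(purification = d$purification[1], category = lev,
               n = c(length(g1), length(g2)),
               median = c(q1[2], q2[2]), q1 = c(q1[1], q2[1]),
               q3 = c(q1[3], q2[3]),
               t_statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
               df = if (is.null(test)) NA_real_ else unname(test$parameter),
               p_value = if (is.null(test)) NA_real_ else test$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
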