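#' Filter a SLAM-seq conversion table
#'
#' Applies the observation-level read-depth and conversion-rate gates used
#' before half-life fitting: observations with fewer than `min_reads` reads
#' are dropped, as are observations with a raw conversion rate below
#' `min_rate`. The gates act per observation (one sample x transcript row);
#' a series (transcript x condition x replicate) that loses its `t = 0`
#' observation can no longer be normalized and is excluded entirely.
#'
#' @param tbl Conversion table: `transcript_id`, `condition`, `replicate`,
#'   `time_min`, `read_count`, `conversion_rate`.
#' @param min_reads Minimum reads per observation (default 20).
#' @param min_rate Minimum raw conversion rate (default 1e-4).
#' @return A list with `table` (retained rows) and `audit` (named counts:
#'   `n_input`, `n_low_reads`, `n_low_conversion`, `n_t0_lost`, `n_retained`).
#' @export
filter_observations <- function(tbl, min_reads = 20, min_rate = 1e-4) {
  check_conversion_table(tbl)
  low_reads <- tbl$read_count < min_reads
  low_conv <- !low_reads & tbl$conversion_rate < min_rate
  keep <- !(low_reads | low_conv)
  kept <- tbl[keep, , drop = FALSE]

  grp <- function(d) paste(d$transcript_id, d$condition, d$replicate, sep = "\r")
  had_t0 <- unique(grp(tbl[tbl$time_min == 0, , drop = FALSE]))
  has_t0 <- unique(grp(kept[kept$time_min == 0, , drop = FALSE]))
  lost <- setdiff(had_t0, has_t0)
  t0_lost <- grp(kept) %in% lost
  out <- kept[!t0_lost, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("all observations were filtered out")

  list(table = out,
       audit = c(n_input = nrow(tbl),
                 n_low_reads = sum(low_reads),
                 n_low_conversion = sum(low_conv),
                 n_t0_lost = sum(t0_lost),
                 n_retained = nrow(out)))
}

check_conversion_table <- function(tbl) {
  need <- c("transcript_id", "condition", "replicate", "time_min",
            "read_count", "conversion_rate")
  if (!all(need %in% names(tbl)))
    stop("conversion table must have columns: ", paste(need, collapse = ", "))
  if (any(tbl$read_count < 0)) stop("read counts must be >= 0")
  if (any(tbl$conversion_rate < 0 | tbl$conversion_rate > 1))
    stop("conversion rates must be in [0, 1]")
  key <- paste(tbl$transcript_id, tbl$condition, tbl$replicate, tbl$time_min)
  if (anyDuplicated(key))
    stop("(transcript, condition, replicate, time) must be unique")
  invisible(tbl)
}

#' Normalize conversion rates to 1 at time zero
#'
#' Divides each series' conversion rates by its `t = 0` rate, producing the
#' normalized abundance `A_t / A_0` that the exponential model is fitted to.
#' Series without a positive `t = 0` rate, or with fewer than 3 time points,
#' are excluded and counted.
#'
#' @param tbl A (filtered) conversion table.
#' @return A list with `table` (columns `transcript_id`, `condition`,
#'   `replicate`, `time_min`, `value`) and `audit` (`n_series`,
#'   `n_zero_t0`, `n_too_short`, `n_retained_series`).
#' @export
normalize_t0 <- function(tbl) {
  check_conversion_table(tbl)
  groups <- split(tbl, list(tbl$transcript_id, tbl$condition, tbl$replicate),
                  drop = TRUE)
  zero_t0 <- 0L; too_short <- 0L
  rows <- lapply(groups, function(d) {
    r0 <- d$conversion_rate[d$time_min == 0]
    if (length(r0) == 0 || r0[1] <= 0) { zero_t0 <<- zero_t0 + 1L; return(NULL) }
    if (length(unique(d$time_min)) < 3) { too_short <<- too_short + 1L; return(NULL) }
    data.frame(transcript_id = d$transcript_id, condition = d$condition,
               replicate = d$replicate, time_min = d$time_min,
               value = d$conversion_rate / r0[1])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(transcript_id = character(), condition = character(),
                                      replicate = integer(), time_min = numeric(),
                                      value = numeric())
  rownames(out) <- NULL
  list(table = out,
       audit = c(n_series = length(groups), n_zero_t0 = zero_t0,
                 n_too_short = too_short,
                 n_retained_series = length(groups) - zero_t0 - too_short))
}

#' Estimate per-series SLAM-seq half-lives
#'
#' Fits `A0 * exp(-k t)` to each normalized series and gates on goodness of
#' fit: series with pseudo-R^2 at or below `min_r2` get status
#' `"filtered_r2"`, failed fits `"fit_failed"`. Half-life is `ln(2)/k`, with
#' no lag and no correction for growth dilution of the labeled pool.
#'
#' @param norm Normalized series table from [normalize_t0()] (`$table`).
#' @param min_r2 Pseudo-R^2 gate (strictly greater than; default 0.8).
#' @return Data frame with one row per (transcript, condition, replicate):
#'   `run` (condition.replicate label), fit fields, `n_timepoints_used`,
#'   `status` in `ok`, `filtered_r2`, `fit_failed`.
#' @export
estimate_half_lives <- function(norm, min_r2 = 0.8) {
  stopifnot(all(c("transcript_id", "condition", "replicate", "time_min", "value")
                %in% names(norm)))
  groups <- split(norm, list(norm$transcript_id, norm$condition, norm$replicate),
                  drop = TRUE)
  rows <- lapply(groups, function(d) {
    f <- tryCatch(fit_exponential(decay_series(d$time_min, d$value)),
                  error = function(e) NULL)
    if (is.null(f) || f$status != "ok") {
      status <- "fit_failed"; f <- list(k = NA_real_, half_life = NA_real_,
                                        A0 = NA_real_, pseudo_r2 = NA_real_,
                                        k_ci_low = NA_real_, k_ci_high = NA_real_)
    } else {
      status <- if (f$pseudo_r2 > min_r2) "ok" else "filtered_r2"
    }
    data.frame(transcript_id = d$transcript_id[1], condition = d$condition[1],
               replicate = d$replicate[1],
               run = paste(d$condition[1], d$replicate[1], sep = "."),
               k = f$k, half_life = f$half_life, A0 = f$A0,
               pseudo_r2 = f$pseudo_r2,
               k_ci_low = f$k_ci_low, k_ci_high = f$k_ci_high,
               n_timepoints_used = length(unique(d$time_min)), status = status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$condition, out$replicate), , drop = FALSE]
}

#' Per-transcript log2 half-life change versus a control baseline
#'
#' The baseline for each transcript is the mean of `log2(half-life)` over the
#' control runs with status `ok` (by design, four undepleted runs); the
#' reported change is the mean over treatment runs of `log2(half-life)` minus
#' that baseline. Transcripts missing an `ok` estimate in either set are
#' skipped and counted.
#'
#' @param fits Output of [estimate_half_lives()].
#' @param controls Character vector of control run labels
#'   (`condition.replicate`).
#' @param treatment Character vector of treatment run labels.
#' @return A list with `table` (`transcript_id`, `delta_log2`, `n_controls`,
#'   `n_treatment`) and `audit` (`n_transcripts`, `n_skipped`).
#' @export
slam_compare_conditions <- function(fits, controls, treatment) {
  ok <- fits[fits$status == "ok", , drop = FALSE]
  skipped <- 0L
  rows <- lapply(split(ok, ok$transcript_id), function(d) {
    ctl <- d$half_life[d$run %in% controls]
    trt <- d$half_life[d$run %in% treatment]
    if (length(ctl) == 0 || length(trt) == 0) { skipped <<- skipped + 1L; return(NULL) }
    data.frame(transcript_id = d$transcript_id[1],
               delta_log2 = mean(log2(trt)) - mean(log2(ctl)),
               n_controls = length(ctl), n_treatment = length(trt))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(transcript_id = character(),
                                      delta_log2 = numeric(),
                                      n_controls = integer(), n_treatment = integer())
  rownames(out) <- NULL
  list(table = out,
       audit = c(n_transcripts = length(unique(ok$transcript_id)),
                 n_skipped = skipped))
}

#' Run the full SLAM-seq half-life pipeline
#'
#' Convenience wrapper: [filter_observations()], [normalize_t0()],
#' [estimate_half_lives()].
#'
#' @inheritParams filter_observations
#' @inheritParams estimate_half_lives
#' @return A list with `fits`, `filter_audit`, `normalize_audit`.
#' @export
slam_pipeline <- function(tbl, min_reads = 20, min_rate = 1e-4, min_r2 = 0.8) {
  flt <- filter_observations(tbl, min_reads = min_reads, min_rate = min_rate)
  nrm <- normalize_t0(flt$table)
  list(fits = estimate_half_lives(nrm$table, min_r2 = min_r2),
       filter_audit = flt$audit, normalize_audit = nrm$audit)
}
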