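# Seeded generators producing the exact table dialects the pipeline stages
# read, with ground truth attached as attributes. All randomness is local:
# generators set the seed themselves and restore the caller's RNG state.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# lognormal multiplicative noise with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a noisy chase decay series
#'
#' Evaluates a noiseless decay curve and multiplies it by lognormal noise with
#' mean 1 and coefficient of variation `cv`, then renormalizes to 1 at time
#' zero. The ground truth is either a kinetic [model_spec()] (the normalized
#' total of its analytic chase from steady state) or a reporter-style
#' lag-exponential truth given as `list(k = , lag = )`.
#'
#' @param truth A `padk_model`, or a list with elements `k` (per minute) and
#'   optionally `lag` (minutes, default 0).
#' @param times Sampling grid (minutes), including 0.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @return A [decay_series()] with attributes `truth` and `noiseless`.
#' @export
gen_chase <- function(truth, times, cv = 0.1, seed = 1) {
  if (cv < 0) stop("`cv` must be >= 0")
  if (!any(times == 0)) stop("`times` must include 0")
  clean <- if (inherits(truth, "padk_model")) {
    cc <- analytic_chase(truth, times = times)
    cc$total / cc$total[cc$time_min == 0]
  } else if (is.list(truth) && !is.null(truth$k)) {
    l <- if (is.null(truth$lag)) 0 else truth$lag
    lag_model_values(times, truth$k, l, 1)
  } else stop("`truth` must be a padk_model or list(k=, lag=)")
  noisy <- with_seed(seed, clean * rlnorm_cv(length(times), cv))
  out <- decay_series(times, noisy)
  attr(out, "truth") <- truth
  attr(out, "noiseless") <- clean
  out
}

#' Generate a SLAM-seq style conversion table
#'
#' Per transcript, the true conversion rate decays as
#' `r0 * 2^(-t / half_life)`. Observed read counts are Poisson around
#' `depth`; the observed conversion rate is a binomial draw over
#' `read_count * t_per_read` convertible positions. Optionally plants
#' sub-threshold rows (low read count, low conversion rate) at `t > 0` to
#' exercise the observation filters; planted row keys are recorded in the
#' `planted` attribute.
#'
#' @param true_half_lives Named numeric vector of half-lives (minutes); names
#'   are transcript ids.
#' @param times Chase sampling times (minutes), including 0.
#' @param depth Expected reads per observation (default 100).
#' @param seed Integer seed.
#' @param condition,replicate Labels stamped on every row.
#' @param r0 Conversion rate at time zero (default 0.05).
#' @param t_per_read Convertible T positions per read (default 25).
#' @param n_low_reads,n_low_conv Numbers of planted sub-threshold rows.
#' @return A conversion table data frame with attributes `truth` (the input
#'   half-lives) and `planted` (data frame of planted row keys and kinds).
#' @export
gen_slam <- function(true_half_lives, times, depth = 100, seed = 1,
                     condition = "ctrl", replicate = 1L,
                     r0 = 0.05, t_per_read = 25,
                     n_low_reads = 0, n_low_conv = 0) {
  if (depth < 1) stop("`depth` must be >= 1")
  if (is.null(names(true_half_lives)))
    names(true_half_lives) <- sprintf("tx%04d", seq_along(true_half_lives))
  if (!any(times == 0)) stop("`times` must include 0")
  grid <- expand.grid(transcript_id = names(true_half_lives),
                      time_min = as.numeric(times),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rate_true <- r0 * 2^(-grid$time_min / true_half_lives[grid$transcript_id])
  with_seed(seed, {
    reads <- pmax(stats::rpois(nrow(grid), depth), 1L)
    sites <- reads * t_per_read
    rate_obs <- stats::rbinom(nrow(grid), sites, rate_true) / sites
    tbl <- data.frame(transcript_id = grid$transcript_id,
                      condition = condition, replicate = replicate,
                      time_min = grid$time_min,
                      read_count = reads, conversion_rate = rate_obs)
    planted <- NULL
    cand <- which(tbl$time_min > 0)
    if (n_low_reads + n_low_conv > nrow(tbl[cand, ]))
      stop("too many planted rows requested")
    pick <- sample(cand, n_low_reads + n_low_conv)
    if (n_low_reads > 0) {
      i <- pick[seq_len(n_low_reads)]
      tbl$read_count[i] <- sample(1:19, n_low_reads, replace = TRUE)
      planted <- data.frame(row = i, kind = "low_reads")
    }
    if (n_low_conv > 0) {
      i <- pick[n_low_reads + seq_len(n_low_conv)]
      tbl$conversion_rate[i] <- stats::runif(n_low_conv, 1e-6, 9e-5)
      planted <- rbind(planted, data.frame(row = i, kind = "low_conversion"))
    }
    attr(tbl, "truth") <- true_half_lives
    attr(tbl, "planted") <- planted
    tbl
  })
}

#' Generate per-read poly(A) length tables from kinetic steady states
#'
#' For each transcript, reads are assigned to the long/medium/short species
#' multinomially with the steady-state proportions of its kinetic model, and
#' each read's tail length is drawn from a normal centered on the species
#' tail length (truncated at 0). QC tags are `"PASS"` with probability
#' `pass_rate`, `"SUFFCLIP"` otherwise. Per-transcript models allow stable
#' and unstable classes in one dataset.
#'
#' @param specs A single [model_spec()] or a named list of them (one per
#'   transcript).
#' @param tails A [tail_profile()].
#' @param n_reads Expected reads per transcript per replicate (Poisson);
#'   recycled over transcripts.
#' @param tail_sd Per-species tail standard deviations (long, mid, short), nt.
#' @param pass_rate Probability a read is QC-tagged `"PASS"`.
#' @param seed Integer seed.
#' @param condition Condition label.
#' @param replicates Number of replicates.
#' @return A per-read poly(A) table with attribute `truth` (list of specs).
#' @export
gen_polya_reads <- function(specs, tails = tail_profile(), n_reads = 1000,
                            tail_sd = c(5, 5, 3), pass_rate = 0.8, seed = 1,
                            condition = "wt", replicates = 2L) {
  if (inherits(specs, "padk_model")) specs <- list(tx0001 = specs)
  if (is.null(names(specs))) names(specs) <- sprintf("tx%04d", seq_along(specs))
  if (pass_rate <= 0 || pass_rate > 1) stop("`pass_rate` must be in (0, 1]")
  tail_sd <- rep(tail_sd, length.out = 3)
  n_reads <- rep(n_reads, length.out = length(specs))
  L <- unclass(tails)
  with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(replicates)) {
      for (j in seq_along(specs)) {
        ss <- steady_state(specs[[j]])
        n <- stats::rpois(1, n_reads[j])
        if (n == 0) next
        species <- sample.int(3, n, replace = TRUE, prob = ss / sum(ss))
        len <- pmax(stats::rnorm(n, L[species], tail_sd[species]), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_r%d_%06d", names(specs)[j], rep_i, seq_len(n)),
          transcript_id = names(specs)[j], condition = condition,
          replicate = rep_i, polya_length = len,
          qc_tag = ifelse(stats::runif(n) < pass_rate, "PASS", "SUFFCLIP"))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- specs
    out
  })
}

#' Generate a RIP-seq style count matrix
#'
#' Feature abundances are lognormal across features; purification (IP)
#' abundances equal input abundances times `2^effect_log2` for the enriched
#' feature set. Counts are negative binomial around
#' `library_size * feature_fraction` with `n_reps` input and `n_reps` IP
#' replicates and unequal library sizes.
#'
#' @param n_features Number of features.
#' @param enriched Indices or names of enriched features.
#' @param effect_log2 Planted log2 enrichment effect.
#' @param depth Nominal library size (default 1e6).
#' @param dispersion Negative binomial dispersion (0 gives Poisson).
#' @param seed Integer seed.
#' @param n_reps Replicates per side (default 3).
#' @return A list with `counts` (matrix), `samples` (metadata data frame) and
#'   `truth` (`enriched`, `effect_log2`).
#' @export
gen_ripseq <- function(n_features = 300, enriched = integer(0), effect_log2 = 1,
                       depth = 1e6, dispersion = 0.05, seed = 1, n_reps = 3L) {
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  with_seed(seed, {
    feats <- sprintf("feat%04d", seq_len(n_features))
    if (is.character(enriched)) enriched <- match(enriched, feats)
    abund_in <- stats::rlnorm(n_features, meanlog = 0, sdlog = 1)
    abund_ip <- abund_in
    abund_ip[enriched] <- abund_ip[enriched] * 2^effect_log2
    lib <- depth * stats::runif(2 * n_reps, 0.7, 1.3)
    draw <- function(abund, libsize) {
      mu <- libsize * abund / sum(abund)
      if (dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    counts <- cbind(
      sapply(seq_len(n_reps), function(r) draw(abund_in, lib[r])),
      sapply(seq_len(n_reps), function(r) draw(abund_ip, lib[n_reps + r])))
    dimnames(counts) <- list(feats,
                             c(sprintf("input_%d", seq_len(n_reps)),
                               sprintf("ip_%d", seq_len(n_reps))))
    samples <- data.frame(
      sample = colnames(counts),
      condition = rep(c("input", "ip"), each = n_reps),
      replicate = rep(seq_len(n_reps), 2),
      is_input = rep(c(TRUE, FALSE), each = n_reps))
    list(counts = counts, samples = samples,
         truth = list(enriched = feats[enriched], effect_log2 = effect_log2))
  })
}
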