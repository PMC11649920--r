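# shared helpers for the padk test suite

read_fixture <- function(name) {
  utils::read.delim(system.file("extdata", name, package = "padk"),
                    stringsAsFactors = FALSE)
}

# random model specs for property-style sweeps (rates log-uniform over
# roughly the biological range used in the rate scans)
random_spec <- function(kind) {
  kA <- 10^stats::runif(1, -2, 0)
  kD <- 10^stats::runif(1, -2, 0)
  model_spec(kind, kA = kA, kD = kD, P = 1)
}

# worst deviation between two chase totals, relative to the initial total
# (pointwise ratios are meaningless once totals underflow below solver atol)
max_rel_dev <- function(a, b) max(abs(a - b)) / abs(b[1])
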