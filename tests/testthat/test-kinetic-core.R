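test_that("steady states solve the fixed-point equations", {
  expect_equal(unname(steady_state(model_spec("serial", 0.25, 0.5, P = 1))),
               c(4, 4, 2))
  expect_equal(unname(steady_state(model_spec("parallel", 0.5, 0.5, P = 1))),
               c(1, 0.5, 0.5))
  expect_equal(unname(steady_state(model_spec("serial", 0.3, 0.7, P = 0))),
               c(0, 0, 0))
  # numeric relaxation from empty with production on reaches the fixed point
  for (kind in c("serial", "parallel")) {
    spec <- model_spec(kind, kA = 0.25, kD = 0.05, P = 1)
    t_end <- 50 / min(spec$kA, spec$kD)
    out <- numeric_chase(spec, init = c(0, 0, 0), times = c(0, t_end),
                         production = TRUE)
    ss <- steady_state(spec)
    expect_lt(max(abs(unlist(out[2, c("PAl", "PAm", "PAs")]) - ss) / ss), 1e-6)
  }
})

test_that("invalid model parameters are rejected", {
  expect_error(model_spec("serial", kA = 0, kD = 0.5), "kA")
  expect_error(model_spec("serial", kA = 0.1, kD = -1), "kD")
  expect_error(model_spec("serial", kA = 0.1, kD = 0.5, P = -1), "P")
  expect_error(tail_profile(10, 40, 70), "long > mid > short")
})

test_that("analytic chase matches hand-integrated closed forms", {
  # degenerate serial cascade, kA == kD
  t <- seq(0, 30, by = 0.5)
  cc <- analytic_chase(model_spec("serial", 0.5, 0.5), init = c(2, 2, 2),
                       times = t)
  expect_equal(cc$total, exp(-0.5 * t) * (6 + 4 * 0.5 * t + 0.25 * t^2),
               tolerance = 1e-12)
  # distinct eigenvalues, from the steady state (variation of constants)
  cc2 <- analytic_chase(model_spec("serial", 0.25, 0.5), times = t)
  expect_equal(cc2$total, (8 + 2 * t) * exp(-0.25 * t) + 2 * exp(-0.5 * t),
               tolerance = 1e-12)
  # empty start stays empty
  cc3 <- analytic_chase(model_spec("parallel", 0.3, 0.2), init = c(0, 0, 0),
                        times = t)
  expect_true(all(cc3$total == 0))
  expect_error(analytic_chase(model_spec("serial", 1, 1), times = c(-1, 0)),
               "times")
})

test_that("closed forms agree with stiff numerical integration", {
  set.seed(101)
  for (kind in c("serial", "parallel")) {
    for (i in 1:10) {
      spec <- random_spec(kind)
      times <- seq(0, 10 / min(spec$kA, spec$kD), length.out = 40)
      a <- analytic_chase(spec, times = times)
      n <- numeric_chase(spec, times = times)
      expect_lt(max_rel_dev(a$total, n$total), 1e-6)
    }
    # repeated-eigenvalue case explicitly
    spec <- model_spec(kind, kA = 0.2, kD = 0.2)
    times <- seq(0, 50, length.out = 40)
    expect_lt(max_rel_dev(analytic_chase(spec, times = times)$total,
                          numeric_chase(spec, times = times)$total), 1e-6)
  }
})

test_that("chase totals decrease monotonically and species stay non-negative", {
  set.seed(202)
  for (i in 1:6) {
    spec <- random_spec(sample(c("serial", "parallel"), 1))
    cc <- analytic_chase(spec, times = seq(0, 8 / min(spec$kA, spec$kD),
                                           length.out = 60))
    expect_true(all(diff(cc$total) < 0))
    expect_true(all(cc$PAl >= 0 & cc$PAm >= 0 & cc$PAs >= 0))
  }
})

test_that("mean tail is the abundance-weighted species average", {
  expect_equal(mean_tail(steady_state(model_spec("serial", 0.25, 0.5))), 46)
  expect_equal(mean_tail(steady_state(model_spec("serial", 0.25, 0.1))), 30)
  expect_equal(mean_tail(c(1, 0, 0)), 70)
  expect_error(mean_tail(c(0, 0, 0)), "undefined")
  # closed form for the serial steady-state mean tail
  tl <- tail_profile()
  for (kA in c(0.01, 0.05, 0.25)) for (kD in c(0.02, 0.1, 0.5)) {
    expected <- ((tl[["long"]] + tl[["mid"]]) / kA + tl[["short"]] / kD) /
      (2 / kA + 1 / kD)
    expect_equal(mean_tail(steady_state(model_spec("serial", kA, kD)), tl),
                 expected)
  }
})

test_that("serial mean tail is monotone in both rates with the correct limits", {
  tl <- tail_profile()
  kA_sweep <- 10^seq(-4, 2, length.out = 25)
  mt_kA <- sapply(kA_sweep, function(kA)
    mean_tail(steady_state(model_spec("serial", kA, 0.1)), tl))
  expect_true(all(diff(mt_kA) < 0))  # decreasing in kA
  kD_sweep <- 10^seq(-4, 2, length.out = 25)
  mt_kD <- sapply(kD_sweep, function(kD)
    mean_tail(steady_state(model_spec("serial", 0.1, kD)), tl))
  expect_true(all(diff(mt_kD) > 0))  # increasing in kD
  expect_equal(mean_tail(steady_state(model_spec("serial", 1e-9, 0.1)), tl),
               (tl[["long"]] + tl[["mid"]]) / 2, tolerance = 1e-6)
  expect_equal(mean_tail(steady_state(model_spec("serial", 0.1, 1e-9)), tl),
               tl[["short"]], tolerance = 1e-6)
})

test_that("crossing half-life matches analytic expectations", {
  # root of (8 + 2t) e^(-t/4) + 2 e^(-t/2) = 5
  expect_equal(half_life_crossing(model_spec("serial", 0.25, 0.5)),
               5.410601, tolerance = 1e-6)
  # parallel totals are exactly single-exponential in kD
  for (kD in c(0.02, 0.1, 0.7)) {
    expect_equal(half_life_crossing(model_spec("parallel", 0.3, kD)),
                 log(2) / kD, tolerance = 1e-7)
  }
  # kA limits collapse both models onto pure kD decay (within 1%)
  expect_equal(half_life_crossing(model_spec("parallel", 1e-6, 0.1)),
               log(2) / 0.1, tolerance = 0.01)
  expect_equal(half_life_crossing(model_spec("serial", 1e3, 0.1)),
               log(2) / 0.1, tolerance = 0.01)
})

test_that("exponential-fit half-life is exact on single-exponential chases", {
  spec <- model_spec("parallel", 1e-9, 0.1)
  est <- half_life_expfit(spec, seq(0, 30, by = 2))
  expect_equal(est, log(2) / 0.1, tolerance = 1e-6)
  # deterministic: same grid, same spec, same answer
  spec2 <- model_spec("serial", 0.25, 0.5)
  e1 <- half_life_expfit(spec2, seq(0, 40, by = 2))
  e2 <- half_life_expfit(spec2, seq(0, 40, by = 2))
  expect_identical(e1, e2)
  # window dependence: the two estimators differ on shouldered serial chases
  expect_false(isTRUE(all.equal(e1, half_life_crossing(spec2), tolerance = 0.01)))
})

test_that("grid scan covers the grid and is production-rate invariant", {
  g <- grid_scan("serial")
  expect_equal(nrow(g), 9)
  expect_true(all(g$mean_tail_nt >= 10 & g$mean_tail_nt <= 70))
  row <- g[g$kA_per_min == 0.01 & g$kD_per_min == 0.5, ]
  expect_equal(round(row$mean_tail_nt), 55)
  row2 <- g[g$kA_per_min == 0.25 & g$kD_per_min == 0.02, ]
  expect_equal(round(row2$mean_tail_nt), 16)
  g7 <- grid_scan("serial", P = 7)
  expect_equal(g$half_life_min, g7$half_life_min, tolerance = 1e-9)
  expect_equal(g$mean_tail_nt, g7$mean_tail_nt, tolerance = 1e-12)
  expect_error(grid_scan("serial", kA_values = numeric(0)), "non-empty")
})
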