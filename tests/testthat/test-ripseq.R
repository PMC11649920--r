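toy_matrix <- function() {
  counts <- matrix(c(
    # input_1 input_2 input_3 ip_1  ip_2  ip_3
      100,    120,    110,    400,  420,  380,   # enriched
      500,    480,    520,    510,  505,  490,
      50,     60,     55,     20,   25,   30,    # depleted
      1000,   900,    950,    980,  990,  1010,
      200,    210,    190,    205,  195,  200,
      150,    140,    160,    600,  580,  620),  # enriched
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("f", 1:6),
                    c("input_1", "input_2", "input_3", "ip_1", "ip_2", "ip_3")))
  samples <- data.frame(sample = colnames(counts),
                        condition = rep(c("input", "pab1"), each = 3),
                        replicate = rep(1:3, 2),
                        is_input = rep(c(TRUE, FALSE), each = 3))
  list(counts = counts, samples = samples)
}

test_that("enrichment pipeline matches step-by-step arithmetic on the toy matrix", {
  toy <- toy_matrix()
  res <- compute_enrichment(toy$counts, toy$samples)
  # oracle: explicit per-feature arithmetic, written independently
  totals <- colSums(toy$counts)
  for (f in rownames(toy$counts)) {
    lg <- log2(toy$counts[f, ] / totals)
    enr <- mean(lg[4:6]) - mean(lg[1:3])
    got <- res$table[res$table$feature_id == f, ]
    expect_equal(got$log2_enrichment_uncentered, enr, tolerance = 1e-12)
    # single purification: centering by the per-feature median zeroes it
    expect_equal(got$log2_enrichment, 0, tolerance = 1e-12)
  }
})

test_that("IP identical to input gives zero enrichment; filters are audited", {
  counts <- matrix(rep(c(100, 200, 300, 5), 2), ncol = 2,
                   dimnames = list(paste0("f", 1:4), c("in_1", "ip_1")))
  samples <- data.frame(sample = c("in_1", "ip_1"), condition = c("input", "x"),
                        replicate = 1L, is_input = c(TRUE, FALSE))
  res <- compute_enrichment(counts, samples)
  expect_equal(res$table$log2_enrichment_uncentered, rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(res$audit["n_filtered"]), 1L)  # the 5-read feature
})

test_that("per-feature median across purifications is centered to zero", {
  set.seed(5)
  counts <- matrix(rpois(40 * 8, 500), nrow = 40,
                   dimnames = list(sprintf("f%02d", 1:40),
                                   c("in_1", "in_2", "a_1", "a_2", "b_1", "b_2",
                                     "c_1", "c_2")))
  samples <- data.frame(
    sample = colnames(counts),
    condition = c("input", "input", "a", "a", "b", "b", "c", "c"),
    replicate = rep(1:2, 4),
    is_input = c(TRUE, TRUE, rep(FALSE, 6)))
  res <- compute_enrichment(counts, samples)
  med <- tapply(res$table$log2_enrichment, res$table$feature_id, median)
  expect_true(all(abs(med) < 1e-12))
})

test_that("enrichment is invariant to sequencing depth of a sample", {
  toy <- toy_matrix()
  res1 <- compute_enrichment(toy$counts, toy$samples)
  scaled <- toy$counts
  scaled[, "ip_2"] <- scaled[, "ip_2"] * 4L  # exact multiple
  res2 <- compute_enrichment(scaled, toy$samples)
  expect_equal(res1$table$log2_enrichment_uncentered,
               res2$table$log2_enrichment_uncentered, tolerance = 1e-12)
})

test_that("feature order permutations only permute output rows", {
  toy <- toy_matrix()
  res1 <- compute_enrichment(toy$counts, toy$samples)
  perm <- c(4, 2, 6, 1, 3, 5)
  res2 <- compute_enrichment(toy$counts[perm, ], toy$samples)
  m <- match(res1$table$feature_id, res2$table$feature_id)
  expect_equal(res1$table$log2_enrichment, res2$table$log2_enrichment[m])
})

test_that("raw per-replicate enrichment is the log2 fraction difference", {
  counts <- matrix(c(100, 1e6 - 100, 100, 2e6 - 100), ncol = 2,
                   dimnames = list(c("fx", "rest"), c("in_1", "ip_1")))
  samples <- data.frame(sample = c("in_1", "ip_1"), condition = c("input", "x"),
                        replicate = 1L, is_input = c(TRUE, FALSE))
  res <- raw_enrichment(counts, samples)
  # totals 1e6 vs 2e6 with equal counts: the fraction halves, log2 = -1
  expect_equal(res$table$raw_log2_enrichment[res$table$feature_id == "fx"],
               -1, tolerance = 1e-12)
  # doubling the IP fraction gives exactly +1
  counts2 <- matrix(c(100, 1e6 - 100, 200, 1e6 - 200), ncol = 2,
                    dimnames = dimnames(counts))
  res2 <- raw_enrichment(counts2, samples)
  expect_equal(res2$table$raw_log2_enrichment[res2$table$feature_id == "fx"],
               1, tolerance = 1e-10)
  # zero counts are skipped and audited
  counts3 <- counts
  counts3["fx", "ip_1"] <- 0
  res3 <- raw_enrichment(counts3, samples)
  expect_false("fx" %in% res3$table$feature_id)
  expect_equal(unname(res3$audit["n_skipped_zero"]), 1L)
})

test_that("category test is Welch's t-test with group summaries", {
  tab <- data.frame(feature_id = sprintf("f%03d", 1:400),
                    purification = "pab1",
                    log2_enrichment = c(rnorm(200), rnorm(200, 1)))
  set.seed(17)
  tab$log2_enrichment <- c(rnorm(200, 0, 1), rnorm(200, 1, 1))
  cats <- setNames(rep(c("other", "xut_sut"), each = 200), tab$feature_id)
  res <- category_test(tab, cats)
  expect_equal(nrow(res), 2)
  expect_lt(res$p_value[1], 1e-10)
  ref <- t.test(tab$log2_enrichment[1:200], tab$log2_enrichment[201:400])
  expect_equal(res$t_statistic[1], unname(ref$statistic))
  expect_equal(res$median[res$category == "other"], median(tab$log2_enrichment[1:200]))
  # identical groups: t = 0, p = 1
  tab2 <- tab
  tab2$log2_enrichment <- rep(tab$log2_enrichment[1:200], 2)
  res2 <- category_test(tab2, cats)
  expect_equal(res2$t_statistic[1], 0, tolerance = 1e-12)
  expect_equal(res2$p_value[1], 1, tolerance = 1e-12)
  # Welch df equals Student df when variances and sizes match exactly
  x <- c(-2, -1, 0, 1, 2)
  y <- x + 1
  w <- t.test(x, y, var.equal = FALSE)
  expect_equal(unname(w$parameter), 8, tolerance = 1e-9)
})
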