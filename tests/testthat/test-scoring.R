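test_that("default panel is the 12 expected IEGs, in order", {
  expect_identical(ieg_panel(),
                   c("Fos", "Jun", "Egr1", "Ier2", "Atf3", "Junb",
                     "Myc", "Crem", "Ets2", "Ier3", "Lepr", "Egfr"))
})

test_that("score identities hold exactly", {
  mu_a <- runif(12, 0.5, 5)
  # mu_c = mu_a + pseudo for all genes -> every log ratio 0 -> S = 1
  expect_equal(ieg_score(mu_a + 0.001, mu_a), 1)
  expect_equal(ieg_score(2 * (mu_a + 0.001), mu_a), 2)
  # 12-gene toy: geometric mean of (g / 1.001)
  mu_c <- 1:12
  expected <- 2 ^ mean(log2(mu_c / 1.001))
  expect_equal(ieg_score(mu_c, rep(1, 12)), expected)
  # scale equivariance to machine precision (pseudo on denominator only)
  kappa <- 3.7
  expect_equal(ieg_score(kappa * mu_c, mu_a), kappa * ieg_score(mu_c, mu_a))
  # zero mu_c entries floored at the pseudo-count, negatives rejected
  expect_equal(ieg_score(c(0, 1), c(1, 1)),
               2 ^ mean(log2(c(0.001, 1) / 1.001)))
  expect_error(ieg_score(c(-1, 1), c(1, 1)), "non-negative")
  expect_error(ieg_score(1:3, 1:2), "align")
})

test_that("group expected counts recover generating truth on synthetic data", {
  m <- panel_counts(2000, theta = 0.2, r = 4, p = 0.5, seed = 41)
  med <- median_normalize(m)
  mu <- group_expected_counts(med)
  mu_true <- zinb_mean(0.2, 4, 0.5)
  expect_true(all(abs(mu - mu_true) / mu_true < 0.10))
  # subset = all cells equals mu_a by definition
  expect_equal(group_expected_counts(med, cells = colnames(med)), mu)
  # all-zero gene within the subset -> mu = 0
  m2 <- m; m2[ieg_panel()[1], 1:30] <- 0L
  med2 <- median_normalize(m2)
  mu2 <- group_expected_counts(med2, cells = colnames(m2)[1:30])
  expect_equal(unname(mu2[1]), 0)
  expect_error(group_expected_counts(med[-1, , drop = FALSE]), "missing")
  expect_error(group_expected_counts(med, cells = colnames(med)[1:3]),
               "at least 5")
})

test_that("binary knn matches brute force and breaks ties by cell id", {
  # 3-cell toy: cell 1's nearest neighbour is its duplicate, cell 2
  m <- matrix(c(1, 1, 0,
                1, 1, 0,
                0, 0, 1), nrow = 3, byrow = FALSE,
              dimnames = list(paste0("g", 1:3), c("c1", "c2", "c3")))
  storage.mode(m) <- "integer"
  expect_identical(binary_knn_subgroup(m, "c1", k = 1, size = "plus_query"),
                   c("c1", "c2"))
  # duplicated profiles sit at distance 0 and are selected first
  expect_identical(binary_knn_subgroup(m, "c2", k = 2, size = "total"),
                   c("c2", "c1"))
  # 200-cell fixture vs the brute-force double loop
  big <- panel_counts(200, seed = 43)
  for (cell in c("c1", "c57", "c200")) {
    expect_identical(binary_knn_subgroup(big, cell, k = 20),
                     brute_knn(big, cell, 19))
    expect_identical(
      binary_knn_subgroup(big, cell, k = 20, size = "plus_query"),
      brute_knn(big, cell, 20))
  }
  expect_error(binary_knn_subgroup(m, "c1", k = 5), "at least")
  expect_error(binary_knn_subgroup(m, "nope", k = 1), "unknown cell")
})

test_that("jaccard metric treats shared absence as uninformative", {
  m <- matrix(c(1, 1, 0, 0,
                1, 0, 0, 0,
                0, 1, 1, 0), nrow = 4,
              dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  storage.mode(m) <- "integer"
  d <- iegflux:::.binary_distances(m > 0, 1, "jaccard")
  expect_equal(unname(d), c(0, 0.5, 2 / 3))
})

test_that("meta-cell scores concentrate near 1 under the null and track shifts", {
  m <- panel_counts(120, theta = 0.1, r = 4, p = 0.5, seed = 47)
  med <- median_normalize(m)
  mu_all <- group_expected_counts(med)
  cells <- paste0("c", seq(1, 120, by = 6))
  sc <- score_cells(med, cells = cells)
  expect_true(median(sc$score) > 0.5 && median(sc$score) < 2)
  # a uniform doubling of the panel doubles mu and pushes scores near 2
  mu_c2 <- group_expected_counts(med, cells = colnames(med)[1:40])
  s2 <- ieg_score(2 * mu_c2, mu_all)
  expect_equal(s2 / ieg_score(mu_c2, mu_all), 2)
  # permutation invariance: relabelling cells leaves the score unchanged
  perm <- sample(ncol(med))
  med_p <- med[, perm]
  sc_p <- metacell_score(med_p, "c7", mu_all = mu_all)
  sc_o <- metacell_score(med, "c7", mu_all = mu_all)
  expect_equal(sc_p$score, sc_o$score)
  expect_setequal(sc_p$subgroup, sc_o$subgroup)
})
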