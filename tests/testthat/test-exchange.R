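grp <- function(...) {
  v <- list(...)
  m <- do.call(rbind, v)
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("c", seq_len(ncol(m))))
  m
}

test_that("worked two-cell examples follow the transfer rules", {
  m <- grp(c(8, 0))
  expect_equal(unname(exchange_model1(m, 1 / 4)[1, ]), c(6, 2))
  expect_equal(unname(exchange_model2(m, 1 / 4)[1, ]), c(8, 2))
  # model 3: round 1 -> (6, 2); round 2 donor 6 gives 1.5 -> (4.5, 3.5)
  expect_equal(unname(exchange_model3(m, 1 / 4, 1 / 4)[1, ]), c(4.5, 3.5))
  expect_equal(unname(exchange_model4(grp(c(4, 8, 0)))[1, ]), c(4, 4, 4))
})

test_that("ties pick the lowest cell index and tiny X approaches identity", {
  m <- grp(c(5, 5, 5))
  out <- exchange_model1(m, 1 / 10)
  expect_equal(sum(out), sum(m))
  expect_equal(unname(out[1, ]), c(5 - 2 * 0.5, 5.5, 5.5))
  eps <- 1e-12
  expect_equal(exchange_model1(m, eps), m, tolerance = 1e-9)
  expect_equal(exchange_model2(m, eps), m, tolerance = 1e-9)
  expect_identical(exchange_model4(m), m)
})

test_that("conservation laws hold across random groups", {
  withr::with_seed(61, {
    for (i in 1:200) {
      N <- sample(c(3, 5, 7), 1)
      X <- sample(c(1 / 16, 1 / 12, 1 / 8, 1 / 6, 3 / 16, 1 / 4), 1)
      m <- matrix(rexp(12 * N, 1 / 4), nrow = 12,
                  dimnames = list(paste0("g", 1:12), paste0("c", 1:N)))
      tot <- rowSums(m)
      expect_equal(rowSums(exchange_model1(m, X)), tot, tolerance = 1e-12)
      expect_equal(rowSums(exchange_model3(m, X, X)), tot,
                   tolerance = 1e-12)
      m4 <- exchange_model4(m)
      expect_equal(rowSums(m4), tot, tolerance = 1e-12)
      expect_equal(unname(apply(m4, 1, var)), rep(0, 12))
      # model 2 adds exactly (N - 1) * X * donor per gene
      donors <- apply(m, 1, max)
      expect_equal(rowSums(exchange_model2(m, X)),
                   tot + (N - 1) * X * donors, tolerance = 1e-12)
    }
  })
})

test_that("donor clamping conserves totals when (N-1) X exceeds 1", {
  # N = 7, X = 1/4: the literal rule would remove 1.5x the donor's RNA
  m <- grp(c(10, rep(0, 6)))
  out <- exchange_model1(m, 1 / 4)
  expect_equal(unname(out[1, ]), c(0, rep(10 / 6, 6)))
  expect_equal(sum(out), 10)
})

test_that("group assignment partitions cells deterministically", {
  cells <- sprintf("c%02d", 1:10)
  g <- assign_groups(cells, 5, seed = 71)
  expect_length(g, 2)
  expect_setequal(unlist(g), cells)
  expect_identical(assign_groups(cells, 5, seed = 71), g)
  # remainder >= 2 forms a final smaller group
  g11 <- assign_groups(sprintf("c%02d", 1:12), 5, seed = 72)
  expect_equal(sort(lengths(g11)), c(2, 5, 5))
  # leftover singleton is left unexchanged
  g_s <- assign_groups(sprintf("c%02d", 1:11), 5, seed = 73)
  expect_equal(sort(lengths(g_s)), c(5, 5))
  expect_length(attr(g_s, "unexchanged"), 1)
  expect_error(assign_groups(cells, 1), "at least 2")
  expect_error(assign_groups(cells[1:3], 5), "at least N")
})

test_that("configuration validation covers the model grid", {
  cfg <- exchange_config(model = 3, N = 5, X = 1 / 12)
  expect_equal(cfg$X1, 1 / 12)
  expect_error(exchange_config(model = 5), "model")
  expect_error(exchange_config(N = 1), "at least 2")
  expect_error(exchange_config(X = 0), "fractions")
})

test_that("run_exchange touches only panel genes of target cells", {
  m <- panel_counts(60, seed = 81)
  med <- median_normalize(m)
  target <- paste0("c", 1:40)
  ex <- run_exchange(med, exchange_config(model = 3, N = 5, X = 1 / 12,
                                          seed = 5L),
                     target_cells = target)
  other <- setdiff(colnames(med), target)
  expect_equal(ex$matrix[, other], med[, other])
  non_panel <- setdiff(rownames(med), ieg_panel())
  expect_equal(ex$matrix[non_panel, ], med[non_panel, ])
  # per-gene totals over target cells conserved (models 1/3/4)
  expect_equal(rowSums(ex$matrix[ieg_panel(), target]),
               rowSums(med[ieg_panel(), target]), tolerance = 1e-9)
  # determinism under the config seed
  ex2 <- run_exchange(med, exchange_config(model = 3, N = 5, X = 1 / 12,
                                           seed = 5L),
                      target_cells = target)
  expect_identical(ex$matrix, ex2$matrix)
  expect_error(run_exchange(med, exchange_config(), target_cells = "zz"),
               "unknown target")
})

test_that("model 4 equalises within-group entropy", {
  m <- panel_counts(25, seed = 83)
  med <- median_normalize(m)
  ex <- run_exchange(med, exchange_config(model = 4, N = 5, seed = 9L),
                     target_cells = colnames(med))
  for (g in ex$groups) {
    ent <- ex$entropy_after$entropy[match(g, ex$entropy_after$cell_id)]
    expect_lt(diff(range(ent)), 1e-12)
  }
})

test_that("exchange raises mean entropy of a heterogeneous population", {
  gt <- benchmark_gene_table(n_background = 40, seed = 85L)
  sp <- population_spec("het", 200, gt, ieg_heterogeneity = 2 / 3,
                        seed = 87L)
  pop <- generate_population(sp)
  med <- median_normalize(pop$counts)
  ex <- run_exchange(med, exchange_config(model = 3, N = 5, X = 1 / 12,
                                          seed = 13L),
                     target_cells = colnames(med))
  expect_gt(mean(ex$entropy_after$entropy), mean(ex$entropy_before$entropy))
  wt <- wilcox.test(ex$entropy_after$entropy, ex$entropy_before$entropy,
                    alternative = "greater", paired = TRUE)
  q <- p.adjust(wt$p.value, method = "BH")
  expect_lt(q, 0.05)
})

test_that("sliding-window trajectory matches brute-force recomputation", {
  m <- panel_counts(100, seed = 91)
  med <- median_normalize(m)
  mu_all <- group_expected_counts(med)
  ent <- panel_entropy(med, mu = mu_all)
  e <- setNames(ent$entropy, ent$cell_id)
  tr <- entropy_trajectory(e, med, mu_all = mu_all)
  expect_identical(nrow(tr), 17L)  # starts 1, 6, ..., 81
  expect_true(all(tr$n_cells == 20))
  ord <- names(sort(e))
  for (i in c(1, 9, 17)) {
    cells <- ord[(5 * (i - 1) + 1):(5 * (i - 1) + 20)]
    expect_equal(tr$mean_entropy[i], mean(e[cells]))
    mu_c <- group_expected_counts(med, cells = cells)
    expect_equal(tr$score[i], ieg_score(mu_c, mu_all))
  }
  # 25 cells -> exactly 2 windows; constant entropies -> flat trajectory
  e25 <- e[1:25]
  tr25 <- entropy_trajectory(e25, med[, names(e25)], mu_all = mu_all)
  expect_identical(nrow(tr25), 2L)
  flat <- setNames(rep(1.5, 25), names(e25))
  trf <- entropy_trajectory(flat, med[, names(e25)], mu_all = mu_all)
  expect_true(all(trf$mean_entropy == 1.5))
  expect_error(entropy_trajectory(e[1:10], med, mu_all = mu_all),
               "at least 20")
})
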