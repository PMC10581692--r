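test_that("population generation is deterministic and respects invariants", {
  gt <- benchmark_gene_table(n_background = 50, seed = 5L)
  sp <- population_spec("P", 40, gt, ieg_heterogeneity = 0.5, seed = 17L)
  a <- generate_population(sp)
  b <- generate_population(sp)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_identical(a$metadata$cell_id, colnames(a$counts))
  expect_setequal(unique(a$truth$type),
                  c("ieg", "housekeeping", "mito", "background"))
})

test_that("spec validation rejects out-of-range parameters", {
  gt <- benchmark_gene_table(n_background = 10)
  expect_error(population_spec("P", 0, gt), "n_cells")
  expect_error(population_spec("P", 5, gt, ieg_heterogeneity = 1.5),
               "ieg_heterogeneity")
  bad <- gt; bad$theta[1] <- 2
  expect_error(population_spec("P", 5, bad), "theta")
})

test_that("generated counts match the analytic ZINB mean", {
  gt <- benchmark_gene_table(n_background = 5, seed = 2L)
  sp <- population_spec("P", 20000, gt[gt$type == "housekeeping", ],
                        ieg_heterogeneity = 0, mito_fraction_mean = 0,
                        seed = 23L)
  pop <- generate_population(sp)
  for (i in seq_len(nrow(sp$genes))) {
    g <- sp$genes[i, ]
    mu <- zinb_mean(g$theta, g$r, g$p)
    x <- pop$counts[i, ]
    expect_lt(abs(mean(x) - mu), 4 * sd(x) / sqrt(length(x)))
  }
})

test_that("ieg_heterogeneity controls per-cell IEG silencing", {
  gt <- benchmark_gene_table(n_background = 20, seed = 3L)
  panel <- ieg_panel()
  # h = 0: no extra zeros beyond ZINB sampling (same params as h > 0 run)
  sp1 <- population_spec("A", 200, gt, ieg_heterogeneity = 1, seed = 4L)
  pop1 <- generate_population(sp1)
  expressed <- colSums(pop1$counts[panel, ] > 0)
  expect_true(all(expressed <= 1))
  # mean per-cell entropy ~ 0 at h = 1
  med <- median_normalize(
    pop1$counts[, colSums(pop1$counts) > 0, drop = FALSE])
  mu <- pmax(rowMeans(med[panel, ]), 1e-6)
  ent <- panel_entropy(med, panel = panel, mu = mu)
  expect_lt(mean(ent$entropy), 0.01)
})

test_that("mitochondrial fraction tracks its target", {
  gt <- benchmark_gene_table(n_background = 100, seed = 6L)
  sp <- population_spec("P", 500, gt, mito_fraction_mean = 0.08, seed = 8L)
  pop <- generate_population(sp)
  mito <- is_mito(rownames(pop$counts))
  frac <- colSums(pop$counts[mito, ]) / colSums(pop$counts)
  expect_equal(mean(frac), 0.08, tolerance = 0.01)
})

test_that("benchmark dataset satisfies its structural contract", {
  ds <- small_benchmark()
  expect_s3_class(ds, "synthetic_dataset")
  expect_true(all(ds$counts >= 0))
  expect_identical(sort(ds$metadata$cell_id), sort(colnames(ds$counts)))
  expect_true(all(ieg_panel() %in% rownames(ds$counts)))
  expect_gte(sum(is_mito(rownames(ds$counts))), 1)
  expect_gte(sum(rownames(ds$counts) %in%
                   c("Gapdh", "Actb", "Ppia", "B2m", "Hprt")), 5)
  expect_setequal(unique(ds$metadata$group),
                  c("WT", "SKO-CD133neg", "SKO-CD133pos", "QC-FAIL"))
})

test_that("CD133pos/neg total IEG output is matched within 10%", {
  # checked at a size where Monte-Carlo error is well inside the band
  ds <- build_benchmark_dataset(seed = 303L, n_cells_per_group = 400)
  f <- function(g) {
    cells <- ds$metadata$cell_id[ds$metadata$group == g]
    mean(colSums(ds$counts[ieg_panel(), cells]))
  }
  expect_lt(abs(f("SKO-CD133pos") / f("SKO-CD133neg") - 1), 0.10)
})

test_that("benchmark reproduces the designed diversity contrast", {
  ds <- small_benchmark()
  md <- ds$metadata
  keep <- md$group != "QC-FAIL"
  med <- median_normalize(ds$counts[, md$cell_id[keep]])
  ent_by <- lapply(c(pos = "SKO-CD133pos", neg = "SKO-CD133neg"),
                   function(g) {
    cells <- md$cell_id[md$group == g]
    panel_entropy(med, cells = cells)$entropy
  })
  expect_gt(mean(ent_by$pos), mean(ent_by$neg))
})

test_that("dataset write/read round-trips through the 10x layout", {
  ds <- small_benchmark()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  m <- read_counts(dir)
  expect_identical(m, ds$counts)
  md <- read_metadata(dir)
  expect_identical(md$cell_id, ds$metadata$cell_id)
})
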