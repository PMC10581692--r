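# Shared fixtures, all built in code.

# Small count matrix with named genes/cells; deterministic.
toy_counts <- function(n_genes = 6, n_cells = 4, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, 3), nrow = n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("c", seq_len(n_cells))))
    storage.mode(m) <- "integer"
    m
  })
}

# A matrix holding every panel gene plus a few extras, iid ZINB cells.
panel_counts <- function(n_cells, theta = 0.1, r = 3, p = 0.6, seed = 1L,
                         extra_genes = 3) {
  genes <- c(iegflux::ieg_panel(), paste0("x", seq_len(extra_genes)))
  withr::with_seed(seed, {
    m <- t(vapply(genes, function(g)
      iegflux::rzinb(n_cells, theta, r, p), numeric(n_cells)))
    colnames(m) <- paste0("c", seq_len(n_cells))
    storage.mode(m) <- "integer"
    m
  })
}

# Brute-force Hamming knn, the independent oracle for binary_knn_subgroup.
brute_knn <- function(m, cell, n_nb) {
  B <- m > 0
  ids <- colnames(m)
  q <- match(cell, ids)
  d <- vapply(seq_along(ids), function(j) sum(B[, j] != B[, q]), numeric(1))
  others <- setdiff(seq_along(ids), q)
  ord <- others[order(d[others], ids[others])]
  c(cell, ids[ord[seq_len(n_nb)]])
}

# Cached small benchmark for tests that need the full dataset but not the
# 300-cell study size.
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- iegflux::build_benchmark_dataset(seed = 301L,
                                                 n_cells_per_group = 60)
    cache
  }
})
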