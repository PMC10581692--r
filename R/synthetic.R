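# ZINB-based synthetic single-cell UMI data emulating the populations the
# IEG analysis contrasts: WT-like hepatocytes, signal-deficient
# CD133-negative cells with stochastic per-cell IEG silencing,
# CD133-positive cells with evenly spread IEG expression at a matched
# total level, and deliberate QC-failing spike-in cells.

#' Sample a gene's counts under a ZINB model
#'
#' Thin, validated wrapper around [rzinb()] with the generator's argument
#' order.
#'
#' @param theta Zero-inflation proportion in `[0, 1]`.
#' @param r NB size (`> 0`).
#' @param p NB success probability in `(0, 1)`.
#' @param n Number of cells to draw.
#' @param seed Optional integer seed.
#' @return Integer vector of `n` counts; mean
#'   `(1 - theta) * p * r / (1 - p)`.
#' @export
sample_zinb <- function(theta, r, p, n, seed = NULL) {
  rzinb(n, theta = theta, r = r, p = p, seed = seed)
}

#' Specification of one synthetic cell population
#'
#' @param name Population label (becomes the metadata `group`).
#' @param n_cells Number of cells (>= 1).
#' @param genes Per-gene generating parameters: `data.frame` with columns
#'   `gene`, `type` (`"ieg"`, `"background"`, `"housekeeping"`, `"mito"`),
#'   `theta`, `r`, `p`.
#' @param ieg_heterogeneity Proportion in `[0, 1]`: each cell silences
#'   `round(h * (N_g - 1))` randomly chosen IEG species, so 0 means no
#'   extra silencing and 1 means at most one IEG retained per cell.
#' @param mito_fraction_mean Expected mitochondrial UMI fraction.
#' @param cd133_status,ccnd1_status,cluster Metadata labels for the
#'   population's cells.
#' @param seed Integer seed; the spec plus seed fully determines the
#'   generated matrix.
#' @return Validated list of class `population_spec`.
#' @export
population_spec <- function(name, n_cells, genes, ieg_heterogeneity = 0,
                            mito_fraction_mean = 0.05,
                            cd133_status = NA_character_,
                            ccnd1_status = "pos",
                            cluster = "periportal",
                            seed = 1L) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  req <- c("gene", "type", "theta", "r", "p")
  if (!is.data.frame(genes) || !all(req %in% names(genes)))
    stop("`genes` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes$gene))
    stop("duplicate gene names in `genes`", call. = FALSE)
  .check_zinb_params(genes$theta, genes$r, genes$p)
  if (ieg_heterogeneity < 0 || ieg_heterogeneity > 1)
    stop("`ieg_heterogeneity` must lie in [0, 1]", call. = FALSE)
  if (mito_fraction_mean < 0 || mito_fraction_mean >= 1)
    stop("`mito_fraction_mean` must lie in [0, 1)", call. = FALSE)
  structure(list(name = name, n_cells = as.integer(n_cells), genes = genes,
                 ieg_heterogeneity = ieg_heterogeneity,
                 mito_fraction_mean = mito_fraction_mean,
                 cd133_status = cd133_status, ccnd1_status = ccnd1_status,
                 cluster = cluster, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate one population's count matrix and metadata
#'
#' Every gene is drawn from its ZINB parameters; IEG genes are then
#' subjected to per-cell random silencing (a Bernoulli-mask stand-in for
#' stochastic, cell-to-cell-heterogeneous IEG expression): each cell
#' zeroes `round(h * (N_g - 1))` randomly chosen IEG species, where `h` is
#' `ieg_heterogeneity`. Mitochondrial counts are drawn so the expected
#' mitochondrial fraction equals `mito_fraction_mean`. Deterministic under
#' the spec's seed.
#'
#' @param spec A [population_spec()].
#' @return List: `counts` (integer matrix, genes x cells), `metadata`
#'   (one row per cell), `truth` (the generating parameter table).
#' @export
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec"))
    stop("`spec` must be a population_spec()", call. = FALSE)
  g <- spec$genes
  n <- spec$n_cells
  withr::with_seed(spec$seed, {
    counts <- matrix(0L, nrow = nrow(g), ncol = n,
                     dimnames = list(g$gene,
                                     sprintf("%s_c%04d", spec$name, seq_len(n))))
    non_mito <- g$type != "mito"
    for (i in which(non_mito))
      counts[i, ] <- rzinb(n, g$theta[i], g$r[i], g$p[i])

    ieg_rows <- which(g$type == "ieg")
    n_g <- length(ieg_rows)
    if (n_g > 0 && spec$ieg_heterogeneity > 0) {
      n_sil <- round(spec$ieg_heterogeneity * (n_g - 1))
      if (n_sil > 0)
        for (j in seq_len(n)) {
          sil <- sample(ieg_rows, n_sil)
          counts[sil, j] <- 0L
        }
    }

    mito_rows <- which(g$type == "mito")
    if (length(mito_rows) > 0 && spec$mito_fraction_mean > 0) {
      tot <- colSums(counts[non_mito, , drop = FALSE])
      frac <- spec$mito_fraction_mean
      lambda <- tot * frac / (1 - frac) / length(mito_rows)
      for (i in mito_rows)
        counts[i, ] <- stats::rpois(n, lambda)
    }
    counts
  }) -> counts
  metadata <- data.frame(
    cell_id = colnames(counts), group = spec$name,
    cd133_status = spec$cd133_status, ccnd1_status = spec$ccnd1_status,
    cluster = spec$cluster, stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = g)
}

# Default per-gene parameter tables -----------------------------------------

#' Default generating parameters for the benchmark gene universe
#'
#' 12 IEG panel genes with moderate expression and light dropout, 5
#' housekeeping genes, 5 mitochondrial genes (placeholder parameters; the
#' generator draws them from the target mitochondrial fraction) and
#' `n_background` background genes with log-uniform mean and size.
#'
#' @param n_background Number of background genes (default 500).
#' @param seed Integer seed for the background parameter draws.
#' @return `data.frame` with columns `gene`, `type`, `theta`, `r`, `p`.
#' @export
benchmark_gene_table <- function(n_background = 500, seed = 99L) {
  panel <- ieg_panel()
  ieg_mu <- seq(2, 8, length.out = length(panel))
  ieg_r <- rep(6, length(panel))
  ieg <- data.frame(gene = panel, type = "ieg", theta = 0.05, r = ieg_r,
                    p = ieg_mu / (ieg_mu + ieg_r))
  hk_mu <- c(30, 25, 20, 12, 10)
  hk_r <- rep(10, 5)
  hk <- data.frame(
    gene = c("Gapdh", "Actb", "Ppia", "B2m", "Hprt"),
    type = "housekeeping", theta = 0, r = hk_r, p = hk_mu / (hk_mu + hk_r))
  mito <- data.frame(
    gene = c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Cytb", "mt-Atp6"),
    type = "mito", theta = 0, r = 5, p = 0.5)
  bg <- withr::with_seed(seed, {
    mu <- exp(stats::runif(n_background, log(0.5), log(20)))
    r <- exp(stats::runif(n_background, log(0.5), log(5)))
    data.frame(gene = sprintf("Bg%04d", seq_len(n_background)),
               type = "background",
               theta = stats::runif(n_background, 0, 0.3),
               r = r, p = mu / (mu + r))
  })
  rbind(ieg, hk, mito, bg)
}

# Expected fraction of total IEG output retained under per-cell silencing
.ieg_retained_fraction <- function(h, n_g) {
  1 - round(h * (n_g - 1)) / n_g
}

.rescale_ieg_mean <- function(genes, factor) {
  # scale the NB mean mu = p*r/(1-p) by `factor` via r, keeping p and theta
  i <- genes$type == "ieg"
  genes$r[i] <- genes$r[i] * factor
  genes
}

.qc_spikein_counts <- function(gene_table) {
  genes <- gene_table$gene
  n_genes <- length(genes)
  mito <- is_mito(genes)
  m <- matrix(0L, nrow = n_genes, ncol = 3L,
              dimnames = list(genes, c("QCFAIL_lowgenes", "QCFAIL_mito",
                                       "QCFAIL_highumi")))
  non_mito_idx <- which(!mito)
  # 150 detected genes (fails "over 200"), modest total
  m[non_mito_idx[1:150], 1L] <- 1L
  # 25% mitochondrial UMIs: 3000 non-mito + 1000 mito of 4000 total
  m[non_mito_idx[1:300], 2L] <- 10L
  m[which(mito), 2L] <- as.integer(1000 / sum(mito))
  # 25,000 total UMIs (fails "< 20,000"): 400 genes x 62 + 200 mito
  m[non_mito_idx[1:400], 3L] <- 62L
  m[which(mito)[1L], 3L] <- 200L
  m
}

#' Build the four-population synthetic benchmark dataset
#'
#' Populations (sharing one gene universe):
#' \describe{
#'   \item{WT-like}{moderate IEG silencing (`h = 1/4`), full IEG output.}
#'   \item{SKO-CD133neg-like}{high per-cell IEG silencing (`h = 2/3`;
#'     each cell retains about 5 of the 12 IEG species).}
#'   \item{SKO-CD133pos-like}{no extra silencing (`h = 0`), with the IEG
#'     means rescaled so its expected total IEG output matches the
#'     CD133-negative population (within 10% by construction).}
#'   \item{QC-FAIL}{three spike-in cells, one violating each cell filter:
#'     150 detected genes, 25% mitochondrial UMIs, 25,000 total UMIs.}
#' }
#'
#' @param seed Integer master seed; population seeds are derived from it.
#' @param n_cells_per_group Cells per biological population (default 300).
#' @param n_background Background genes (default 500).
#' @return List of class `synthetic_dataset`: `counts`, `metadata`,
#'   `truth` (per-population generating tables).
#' @export
build_benchmark_dataset <- function(seed = 1L, n_cells_per_group = 300,
                                    n_background = 500) {
  seed <- as.integer(seed)
  gt <- benchmark_gene_table(n_background = n_background,
                             seed = (seed %% 1000000L) + 7L)
  n_g <- length(ieg_panel())
  h_wt <- 1 / 4; h_neg <- 2 / 3; h_pos <- 0
  # match expected total IEG output of the CD133pos population to CD133neg
  match_factor <- .ieg_retained_fraction(h_neg, n_g) /
    .ieg_retained_fraction(h_pos, n_g)
  specs <- list(
    population_spec("WT", n_cells_per_group, gt,
                    ieg_heterogeneity = h_wt, seed = seed + 1L),
    population_spec("SKO-CD133neg", n_cells_per_group, gt,
                    ieg_heterogeneity = h_neg, cd133_status = "neg",
                    seed = seed + 2L),
    population_spec("SKO-CD133pos", n_cells_per_group,
                    .rescale_ieg_mean(gt, match_factor),
                    ieg_heterogeneity = h_pos, cd133_status = "pos",
                    seed = seed + 3L))
  pops <- lapply(specs, generate_population)
  counts <- do.call(cbind, lapply(pops, `[[`, "counts"))
  metadata <- do.call(rbind, lapply(pops, `[[`, "metadata"))

  spike <- .qc_spikein_counts(gt)
  counts <- cbind(counts, spike)
  metadata <- rbind(metadata, data.frame(
    cell_id = colnames(spike), group = "QC-FAIL",
    cd133_status = NA_character_, ccnd1_status = NA_character_,
    cluster = NA_character_, stringsAsFactors = FALSE))

  # mark ~10% of biological cells cyclin-D1-negative, to exercise the
  # ccnd1 stratification filter downstream
  metadata$ccnd1_status <- withr::with_seed(seed + 4L, {
    st <- metadata$ccnd1_status
    bio <- metadata$group != "QC-FAIL"
    st[bio] <- ifelse(stats::runif(sum(bio)) < 0.1, "neg", "pos")
    st
  })

  out <- list(counts = counts, metadata = metadata,
              truth = stats::setNames(lapply(specs, `[[`, "genes"),
                                      vapply(specs, `[[`, "", "name")))
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic benchmark: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$metadata$group))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Matrix-Market triplet with gene/barcode tables plus `metadata.csv`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  write_counts(dataset$counts, dir, metadata = dataset$metadata)
}
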