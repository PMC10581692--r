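# Gene/cell quality-control filters and normalisations for UMI count
# matrices. Filter order follows the preprocessing convention: genes first
# (expressed in < min_cells cells removed), then cells.

#' Remove genes expressed in too few cells
#'
#' A gene is retained when it has a non-zero count in at least `min_cells`
#' cells. The cell set is unchanged.
#'
#' @param m Genes-by-cells count matrix.
#' @param min_cells Minimum number of expressing cells (default 3).
#' @return Filtered count matrix.
#' @export
filter_genes <- function(m, min_cells = 3) {
  validate_counts(m)
  keep <- rowSums(m > 0) >= min_cells
  m[keep, , drop = FALSE]
}

#' Remove low-quality cells
#'
#' Retains cells satisfying all of, with strict inequalities:
#' detected genes `> min_genes` and `< max_genes`; mitochondrial UMI
#' fraction `< max_mito`; total UMI `< max_umi`. Mitochondrial genes are
#' flagged by name (see [is_mito()]) unless `mito` is supplied.
#'
#' @param m Genes-by-cells count matrix.
#' @param min_genes,max_genes Detected-gene bounds (defaults 200, 5000).
#' @param max_mito Mitochondrial UMI fraction ceiling (default 0.20).
#' @param max_umi Total UMI ceiling (default 20000).
#' @param mito Optional logical per-gene mitochondrial flag.
#' @return Filtered count matrix; the gene set is unchanged. Warns (and
#'   passes the mitochondrial criterion vacuously) when no gene is
#'   flagged mitochondrial.
#' @export
filter_cells <- function(m, min_genes = 200, max_genes = 5000,
                         max_mito = 0.20, max_umi = 20000, mito = NULL) {
  validate_counts(m)
  if (is.null(mito)) mito <- is_mito(rownames(m))
  if (length(mito) != nrow(m))
    stop("`mito` must have one flag per gene", call. = FALSE)
  detected <- colSums(m > 0)
  total <- colSums(m)
  if (!any(mito)) {
    warning("no mitochondrial genes flagged; the mitochondrial-fraction ",
            "criterion passes vacuously")
    mito_frac <- rep(0, ncol(m))
  } else {
    mito_frac <- colSums(m[mito, , drop = FALSE]) / pmax(total, 1)
  }
  keep <- detected > min_genes & detected < max_genes &
    mito_frac < max_mito & total < max_umi
  m[, keep, drop = FALSE]
}

.check_positive_totals <- function(total) {
  if (any(total <= 0))
    stop("some cells have zero total counts; run filter_cells() first",
         call. = FALSE)
}

#' Log-normalise to 10,000 counts per cell
#'
#' `value(g, c) = log(1 + 10000 * count(g, c) / total(c))`, natural log.
#'
#' @param m Count matrix with positive per-cell totals.
#' @param scale_factor Per-cell target sum before the log (default 10000).
#' @return Numeric matrix with attribute `normalization = "lognorm_10k"`.
#' @export
normalize_log10k <- function(m, scale_factor = 1e4) {
  validate_counts(m)
  total <- colSums(m)
  .check_positive_totals(total)
  out <- log1p(sweep(m, 2L, total / scale_factor, "/"))
  attr(out, "normalization") <- "lognorm_10k"
  out
}

#' Median normalisation by total-count size factors
#'
#' Size factor `s(c) = total(c) / median(totals)`; values are counts
#' divided by the cell's size factor, so the median size factor is 1 and a
#' median-depth cell keeps its raw counts.
#'
#' @param m Count matrix with positive per-cell totals.
#' @return Numeric matrix with attributes `normalization = "median_norm"`
#'   and `size_factors`.
#' @export
median_normalize <- function(m) {
  validate_counts(m)
  total <- colSums(m)
  .check_positive_totals(total)
  sf <- total / stats::median(total)
  out <- sweep(m, 2L, sf, "/")
  attr(out, "normalization") <- "median_norm"
  attr(out, "size_factors") <- stats::setNames(sf, colnames(m))
  out
}

#' Z-scale genes across cells
#'
#' Centres and scales each gene (row) to mean 0, sd 1 across cells.
#' Zero-variance genes map to all-zero rows.
#'
#' @param m Normalised (typically log-normalised) matrix.
#' @return Scaled matrix with attribute `normalization = "zscaled"`.
#' @export
zscale_genes <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("`m` must be a numeric matrix", call. = FALSE)
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, stats::sd)
  out <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  out[sdev == 0, ] <- 0
  attr(out, "normalization") <- "zscaled"
  out
}
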