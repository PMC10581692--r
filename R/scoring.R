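# Composite IEG expression score S_C over ZINB-expected counts, and the
# 20-nearest-neighbour binary-distance meta-cell machinery.

#' The default immediate-early gene panel
#'
#' Twelve IEGs induced during liver regeneration, used as the feature set
#' for scoring, entropy and exchange simulation.
#'
#' @return Character vector of 12 gene symbols.
#' @export
ieg_panel <- function() {
  c("Fos", "Jun", "Egr1", "Ier2", "Atf3", "Junb",
    "Myc", "Crem", "Ets2", "Ier3", "Lepr", "Egfr")
}

.check_panel <- function(m, panel) {
  if (anyDuplicated(panel))
    stop("panel contains duplicate genes", call. = FALSE)
  missing <- setdiff(panel, rownames(m))
  if (length(missing))
    stop("panel genes missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(panel)
}

#' Per-gene ZINB-expected counts within a cell subset
#'
#' For each panel gene, fits a ZINB model to the median-normalized counts
#' of the cells in `cells` and returns the fitted expected count
#' `mu = (1 - theta) * p * r / (1 - p)`. With `cells` equal to all cells
#' this yields the population expectations `mu_a`.
#'
#' @param m Median-normalized matrix (output of [median_normalize()]).
#' @param cells Cell ids (or column indices) of the subset, at least 5.
#' @param panel Gene panel (default [ieg_panel()]).
#' @return Named numeric vector of expected counts, one per panel gene.
#' @export
group_expected_counts <- function(m, cells = colnames(m),
                                  panel = ieg_panel()) {
  .check_panel(m, panel)
  sub <- m[panel, cells, drop = FALSE]
  if (ncol(sub) < 5L)
    stop("expected-count estimation needs at least 5 cells, got ",
         ncol(sub), call. = FALSE)
  vapply(panel, function(g) fit_zinb(sub[g, ])$mu, numeric(1L))
}

#' Composite IEG score of a cell group
#'
#' The geometric-mean fold change of group over population expectations:
#' `S_C = 2 ^ mean(log2(mu_c / (mu_a + pseudo)))` over the panel genes,
#' with `pseudo = 0.001` stabilising the denominator. Zero group
#' expectations are floored at the same pseudo-count so the log stays
#' finite; negative values are an error.
#'
#' @param mu_group Per-gene expected counts of the group (`mu_c`).
#' @param mu_all Per-gene expected counts of the whole population (`mu_a`).
#' @param pseudo Denominator pseudo-count (default 0.001).
#' @return The score `S_C`, a positive real; 1 means the group matches the
#'   population, 2 means a uniform two-fold elevation.
#' @export
ieg_score <- function(mu_group, mu_all, pseudo = 0.001) {
  if (length(mu_group) != length(mu_all))
    stop("`mu_group` and `mu_all` must align to the same panel",
         call. = FALSE)
  if (any(mu_group < 0) || any(mu_all < 0))
    stop("expected counts must be non-negative", call. = FALSE)
  mu_c <- ifelse(mu_group == 0, pseudo, mu_group)
  2 ^ mean(log2(mu_c / (mu_all + pseudo)))
}

.binarize <- function(m) m > 0

.binary_distances <- function(B, q, metric = c("hamming", "jaccard")) {
  metric <- match.arg(metric)
  b <- B[, q]
  if (metric == "hamming") {
    colSums(B != b)
  } else {
    inter <- colSums(B & b)
    uni <- colSums(B | b)
    d <- 1 - inter / uni
    d[uni == 0] <- 0  # two all-absent profiles are identical
    d
  }
}

#' Binary-distance nearest-neighbour subgroup of a cell
#'
#' Binarises the matrix (count > 0) and ranks all other cells by Hamming
#' (default) or Jaccard distance to the query cell. The subgroup is the
#' query cell plus its nearest neighbours; with `size = "total"` (default)
#' the subgroup has `k` cells including the query, with
#' `size = "plus_query"` it has `k + 1`. Ties are broken by ascending
#' cell id, so the result is deterministic.
#'
#' @param m Count (or normalised) matrix; only presence/absence is used.
#' @param cell Query cell id.
#' @param k Subgroup size parameter (default 20).
#' @param metric Binary distance, `"hamming"` or `"jaccard"`.
#' @param size `"total"`: subgroup of `k` cells including the query;
#'   `"plus_query"`: query plus `k` neighbours.
#' @return Character vector of cell ids, query first.
#' @export
binary_knn_subgroup <- function(m, cell, k = 20,
                                metric = c("hamming", "jaccard"),
                                size = c("total", "plus_query")) {
  metric <- match.arg(metric)
  size <- match.arg(size)
  ids <- colnames(m)
  q <- match(cell, ids)
  if (is.na(q)) stop("unknown cell id: ", cell, call. = FALSE)
  n_nb <- if (size == "total") k - 1L else k
  if (ncol(m) - 1L < n_nb)
    stop("need at least ", n_nb, " other cells, have ", ncol(m) - 1L,
         call. = FALSE)
  d <- .binary_distances(.binarize(m), q, metric)
  others <- setdiff(seq_along(ids), q)
  ord <- others[order(d[others], ids[others])]
  c(cell, ids[ord[seq_len(n_nb)]])
}

#' Meta-cell IEG score of a single cell
#'
#' Composes [binary_knn_subgroup()] (on presence/absence),
#' [group_expected_counts()] on the subgroup, and [ieg_score()] against
#' the population expectations.
#'
#' @param m Median-normalized matrix.
#' @param cell Query cell id.
#' @param panel Gene panel.
#' @param k Subgroup size (default 20).
#' @param counts Optional raw count matrix used for the binary distance;
#'   defaults to `m` (binarisation is identical since normalisation
#'   preserves zeros).
#' @param mu_all Optional precomputed population expectations, to avoid
#'   refitting per query cell.
#' @param ... Passed to [binary_knn_subgroup()].
#' @return Named list: `cell`, `subgroup`, `score`.
#' @export
metacell_score <- function(m, cell, panel = ieg_panel(), k = 20,
                           counts = NULL, mu_all = NULL, ...) {
  if (is.null(counts)) counts <- m
  if (is.null(mu_all)) mu_all <- group_expected_counts(m, panel = panel)
  sub <- binary_knn_subgroup(counts, cell, k = k, ...)
  mu_c <- group_expected_counts(m, cells = sub, panel = panel)
  list(cell = cell, subgroup = sub, score = ieg_score(mu_c, mu_all))
}

#' Meta-cell IEG scores for many cells
#'
#' @param m Median-normalized matrix.
#' @param cells Cell ids to score (default all).
#' @param panel Gene panel.
#' @param k Subgroup size.
#' @param ... Passed to [metacell_score()].
#' @return `data.frame` with columns `cell_id`, `score`.
#' @export
score_cells <- function(m, cells = colnames(m), panel = ieg_panel(),
                        k = 20, ...) {
  mu_all <- group_expected_counts(m, panel = panel)
  scores <- vapply(cells, function(cl)
    metacell_score(m, cl, panel = panel, k = k, mu_all = mu_all, ...)$score,
    numeric(1L))
  data.frame(cell_id = cells, score = unname(scores),
             stringsAsFactors = FALSE)
}
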