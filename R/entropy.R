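# Per-cell IEG diversity (Shannon entropy of expectation-normalised
# abundances), intercellular variation (pairwise Euclidean distances on
# scaled data), and pairwise group comparisons (Wilcoxon + BH).

#' Shannon entropy of a single cell's IEG profile
#'
#' Relative abundances `r_i = count_i / mu_i` (counts median-normalized,
#' `mu_i` the ZINB-expected count of gene `i` in the analysis population)
#' are normalised to proportions `p_i = r_i / sum(r)` and summarised as
#' `E = -sum(p_i * log2(p_i))` with `0 * log(0) == 0`. A cell with no IEG
#' expression gets `E = 0` and `flag_no_ieg = TRUE`.
#'
#' @param counts_j Per-panel-gene median-normalized counts of one cell.
#' @param mu Per-gene expected counts (same order), all `> 0`.
#' @return List: `E` (bits), `p_vec`, `r_vec`, `flag_no_ieg`.
#' @export
cell_entropy <- function(counts_j, mu) {
  if (length(counts_j) != length(mu))
    stop("counts and expected counts must align to the same panel",
         call. = FALSE)
  if (any(mu <= 0))
    stop("expected counts must be positive; drop zero-mu genes first",
         call. = FALSE)
  r <- counts_j / mu
  s <- sum(r)
  if (s == 0)
    return(list(E = 0, p_vec = r, r_vec = r, flag_no_ieg = TRUE))
  p <- r / s
  pos <- p > 0
  list(E = -sum(p[pos] * log2(p[pos])), p_vec = p, r_vec = r,
       flag_no_ieg = FALSE)
}

#' Per-cell IEG entropy for an analysis population
#'
#' Fits the per-gene expectations `mu_i` on the analysis population
#' (unless supplied) and computes [cell_entropy()] for every cell. Panel
#' genes whose fitted `mu` is 0 across the population are excluded with a
#' warning (their relative abundance is undefined).
#'
#' @param m Median-normalized matrix.
#' @param cells Cells of the analysis population (default all columns).
#' @param panel Gene panel (default [ieg_panel()]).
#' @param mu Optional named per-gene expected counts; fitted from
#'   `m[, cells]` when `NULL`.
#' @return `data.frame`: `cell_id`, `entropy` (bits), `flag_no_ieg`.
#' @export
panel_entropy <- function(m, cells = colnames(m), panel = ieg_panel(),
                          mu = NULL) {
  .check_panel(m, panel)
  if (is.null(mu)) mu <- group_expected_counts(m, cells = cells, panel = panel)
  mu <- mu[panel]
  drop <- names(mu)[mu <= 0]
  if (length(drop)) {
    warning("panel genes with zero expected count excluded from entropy: ",
            paste(drop, collapse = ", "))
    panel <- setdiff(panel, drop)
    mu <- mu[panel]
  }
  sub <- m[panel, cells, drop = FALSE]
  ent <- apply(sub, 2L, function(x) {
    ce <- cell_entropy(x, mu)
    c(ce$E, ce$flag_no_ieg)
  })
  data.frame(cell_id = cells, entropy = ent[1L, ],
             flag_no_ieg = as.logical(ent[2L, ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise intercellular variation of a cell group
#'
#' All pairwise Euclidean distances between the group's cells on z-scaled
#' data, restricted to the panel genes by default.
#'
#' @param scaled Z-scaled matrix (output of [zscale_genes()]).
#' @param cells Cell ids of the group, at least 2.
#' @param genes Genes to use (default [ieg_panel()]; `NULL` for all).
#' @return List of class `variation_result`: `distances` (a `dist`),
#'   `summary` (median, IQR, n_cells).
#' @export
group_variation <- function(scaled, cells, genes = ieg_panel()) {
  if (length(cells) < 2L)
    stop("variation needs at least 2 cells", call. = FALSE)
  if (is.null(genes)) genes <- rownames(scaled)
  .check_panel(scaled, genes)
  d <- stats::dist(t(scaled[genes, cells, drop = FALSE]))
  out <- list(
    distances = d,
    summary = c(median = stats::median(d), iqr = stats::IQR(d),
                n_cells = length(cells)))
  class(out) <- "variation_result"
  out
}

#' @export
print.variation_result <- function(x, ...) {
  cat(sprintf(
    "Intercellular variation: %d cells, median distance %.4f (IQR %.4f)\n",
    x$summary["n_cells"], x$summary["median"], x$summary["iqr"]))
  invisible(x)
}

#' Pairwise Wilcoxon rank-sum comparisons with BH adjustment
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups, with
#' Benjamini-Hochberg adjustment across the pairs.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups,
#'   each with >= 3 values).
#' @return `data.frame`: `group_a`, `group_b`, `statistic`, `p`, `q`.
#' @export
compare_groups <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L)
    stop("need a named list of at least 2 groups", call. = FALSE)
  if (is.null(names(values_by_group)) || any(names(values_by_group) == ""))
    stop("all groups must be named", call. = FALSE)
  n <- vapply(values_by_group, length, integer(1L))
  if (any(n < 3L))
    stop("each group needs at least 3 values; too small: ",
         paste(names(values_by_group)[n < 3L], collapse = ", "),
         call. = FALSE)
  pairs <- utils::combn(names(values_by_group), 2L)
  res <- apply(pairs, 2L, function(gg) {
    wt <- suppressWarnings(
      stats::wilcox.test(values_by_group[[gg[1L]]],
                         values_by_group[[gg[2L]]], exact = NULL))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                    statistic = res["statistic", ], p = res["p", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
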