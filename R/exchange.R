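# Intercellular mRNA exchange simulation: random grouping, the four
# exchange models, end-to-end application to a normalised matrix, and the
# entropy-ordered sliding-window trajectory.
#
# Group matrices are genes x cells (one small group of N cells). Donor
# selection is per gene: for each IEG the cell with the highest level
# donates, ties broken by the lowest cell index.

#' Exchange simulation configuration
#'
#' @param model Exchange model id, 1-4.
#' @param N Group size (>= 2; the study grid is 3, 5, 7).
#' @param X Exchange fraction in (0, 1) (grid 1/16, 1/12, 1/8, 1/6, 3/16,
#'   1/4); used by models 1 and 2.
#' @param X1,X2 First- and second-round fractions for model 3 (default
#'   `X`).
#' @param seed Integer seed controlling the random grouping.
#' @return Validated list of class `exchange_config`.
#' @export
exchange_config <- function(model = 3, N = 5, X = 1 / 12,
                            X1 = X, X2 = X, seed = 1L) {
  if (!model %in% 1:4) stop("`model` must be 1, 2, 3 or 4", call. = FALSE)
  if (N < 2) stop("group size `N` must be at least 2", call. = FALSE)
  frs <- c(X = X, X1 = X1, X2 = X2)
  if (any(frs <= 0 | frs >= 1))
    stop("exchange fractions must lie in (0, 1)", call. = FALSE)
  structure(list(model = model, N = N, X = X, X1 = X1, X2 = X2,
                 seed = as.integer(seed)), class = "exchange_config")
}

#' Randomly partition cells into exchange groups
#'
#' Uniformly random groups of size `N`; leftover cells form one final
#' smaller group when at least 2 remain, otherwise a leftover singleton is
#' left unexchanged. Deterministic under `seed`.
#'
#' @param cells Cell ids.
#' @param N Group size (>= 2).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return List of character vectors; attribute `unexchanged` holds any
#'   leftover singleton.
#' @export
assign_groups <- function(cells, N, seed = NULL) {
  if (N < 2) stop("group size `N` must be at least 2", call. = FALSE)
  if (length(cells) < N)
    stop("need at least N = ", N, " cells, have ", length(cells),
         call. = FALSE)
  perm <- if (is.null(seed)) sample(cells) else
    withr::with_seed(seed, sample(cells))
  n_full <- length(cells) %/% N
  rem <- length(cells) %% N
  groups <- split(perm[seq_len(n_full * N)],
                  rep(seq_len(n_full), each = N))
  names(groups) <- NULL
  unexchanged <- character(0)
  if (rem >= 2) {
    groups[[n_full + 1L]] <- perm[(n_full * N + 1L):length(perm)]
  } else if (rem == 1L) {
    unexchanged <- perm[length(perm)]
  }
  attr(groups, "unexchanged") <- unexchanged
  groups
}

.donor_transfer <- function(mat, X, reduce_donor = TRUE) {
  N <- ncol(mat)
  donor <- max.col(mat, ties.method = "first")
  idx <- cbind(seq_len(nrow(mat)), donor)
  d <- mat[idx]
  # Per-recipient transfer; capped at d / (N - 1) so the donor cannot go
  # negative when (N - 1) * X > 1 (e.g. N = 7, X = 1/4) and the group
  # total is conserved.
  t_amt <- if (reduce_donor) pmin(X * d, d / (N - 1)) else X * d
  out <- mat + t_amt
  # pmax guards against -1e-16-scale float residue when (N-1)*X == 1
  out[idx] <- if (reduce_donor) pmax(d - (N - 1) * t_amt, 0) else d
  out
}

#' Exchange model 1: donor gives, donor is depleted
#'
#' Per gene, the highest-expressing cell gives a fraction `X` of its RNA
#' to each of the other `N - 1` cells and loses `(N - 1) * X` of it. The
#' per-gene group total is conserved (the transfer is capped so the donor
#' never goes negative).
#'
#' @param mat Genes-by-cells matrix of one group.
#' @param X Exchange fraction.
#' @return Matrix of the same shape.
#' @export
exchange_model1 <- function(mat, X) {
  .check_group_matrix(mat, X)
  .donor_transfer(mat, X, reduce_donor = TRUE)
}

#' Exchange model 2: donor gives, donor level maintained
#'
#' As model 1, but the donor's level is maintained (continuous
#' transcription), so the per-gene group total increases by
#' `(N - 1) * X * donor`.
#'
#' @inheritParams exchange_model1
#' @export
exchange_model2 <- function(mat, X) {
  .check_group_matrix(mat, X)
  .donor_transfer(mat, X, reduce_donor = FALSE)
}

#' Exchange model 3: two rounds of depleting exchange
#'
#' Model 1 with fraction `X1`, then, after re-selecting the
#' highest-expressing cell per gene, model 1 again with fraction `X2`.
#' Conserves the per-gene group total.
#'
#' @inheritParams exchange_model1
#' @param X1,X2 First- and second-round fractions.
#' @export
exchange_model3 <- function(mat, X1, X2) {
  exchange_model1(exchange_model1(mat, X1), X2)
}

#' Exchange model 4: complete mixing
#'
#' Every cell's level of each gene becomes the pre-exchange group mean.
#'
#' @param mat Genes-by-cells matrix of one group.
#' @export
exchange_model4 <- function(mat) {
  .check_group_matrix(mat, 0.5)
  matrix(rowMeans(mat), nrow = nrow(mat), ncol = ncol(mat),
         dimnames = dimnames(mat))
}

.check_group_matrix <- function(mat, X) {
  if (!is.matrix(mat) || !is.numeric(mat) || any(mat < 0))
    stop("group matrix must be numeric and non-negative", call. = FALSE)
  if (ncol(mat) < 2L)
    stop("a group needs at least 2 cells", call. = FALSE)
  if (X <= 0 || X >= 1)
    stop("exchange fraction must lie in (0, 1)", call. = FALSE)
  invisible(mat)
}

.apply_exchange <- function(mat, config) {
  switch(as.character(config$model),
         "1" = exchange_model1(mat, config$X),
         "2" = exchange_model2(mat, config$X),
         "3" = exchange_model3(mat, config$X1, config$X2),
         "4" = exchange_model4(mat),
         stop("unknown exchange model: ", config$model, call. = FALSE))
}

#' Run the exchange simulation on a normalised matrix
#'
#' Randomly partitions the target cells into groups of `config$N`,
#' applies the configured exchange model to the panel genes of each group,
#' and recomputes per-cell entropy. The per-gene expectations `mu` used
#' for entropy are fitted on the target population before exchange and
#' held fixed afterwards, so the entropy shift isolates the exchange
#' effect. Non-target cells and non-panel genes are untouched.
#'
#' @param m Median-normalized matrix.
#' @param config An [exchange_config()].
#' @param target_cells Cell ids to exchange among (e.g. the CD133-negative
#'   population).
#' @param panel Gene panel (default [ieg_panel()]).
#' @param mu Optional pre-fitted per-gene expectations for entropy.
#' @return List: `matrix` (post-exchange), `groups`, `mu`,
#'   `entropy_before`, `entropy_after` (data frames from
#'   [panel_entropy()]), `config`.
#' @export
run_exchange <- function(m, config, target_cells, panel = ieg_panel(),
                         mu = NULL) {
  if (!inherits(config, "exchange_config"))
    stop("`config` must be an exchange_config()", call. = FALSE)
  .check_panel(m, panel)
  missing_cells <- setdiff(target_cells, colnames(m))
  if (length(missing_cells))
    stop("unknown target cells: ",
         paste(utils::head(missing_cells, 5L), collapse = ", "),
         call. = FALSE)
  if (is.null(mu))
    mu <- group_expected_counts(m, cells = target_cells, panel = panel)
  before <- panel_entropy(m, cells = target_cells, panel = panel, mu = mu)
  groups <- assign_groups(target_cells, config$N, seed = config$seed)
  out <- m
  for (g in groups)
    out[panel, g] <- .apply_exchange(out[panel, g, drop = FALSE], config)
  after <- panel_entropy(out, cells = target_cells, panel = panel, mu = mu)
  list(matrix = out, groups = groups, mu = mu,
       entropy_before = before, entropy_after = after, config = config)
}

#' Entropy-ordered sliding-window trajectory
#'
#' Orders cells by entropy (low to high) and slides a window of
#' `window` cells with step `step`; each window is treated as a meta-cell
#' whose mean entropy and composite IEG score are reported. Trailing
#' partial windows are dropped.
#'
#' @param entropies Named per-cell entropies (bits); names are cell ids.
#' @param m Median-normalized matrix used for the window scores.
#' @param panel Gene panel.
#' @param mu_all Population expectations for the score denominator;
#'   fitted from all columns of `m` when `NULL`.
#' @param window Window size in cells (default 20).
#' @param step Step between window starts (default 5).
#' @return `data.frame`: `window_index`, `mean_entropy`, `score`,
#'   `n_cells`.
#' @export
entropy_trajectory <- function(entropies, m, panel = ieg_panel(),
                               mu_all = NULL, window = 20, step = 5) {
  if (is.null(names(entropies)))
    stop("`entropies` must be named by cell id", call. = FALSE)
  n <- length(entropies)
  if (n < window)
    stop("trajectory needs at least ", window, " cells, got ", n,
         call. = FALSE)
  if (is.null(mu_all)) mu_all <- group_expected_counts(m, panel = panel)
  ord <- names(sort(entropies))
  starts <- seq(1L, n - window + 1L, by = step)
  rows <- lapply(seq_along(starts), function(i) {
    cells <- ord[starts[i]:(starts[i] + window - 1L)]
    mu_c <- group_expected_counts(m, cells = cells, panel = panel)
    data.frame(window_index = i,
               mean_entropy = mean(entropies[cells]),
               score = ieg_score(mu_c, mu_all),
               n_cells = window)
  })
  do.call(rbind, rows)
}
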