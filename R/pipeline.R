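# End-to-end orchestration: simulate -> QC -> normalise -> score ->
# entropy/variation -> exchange -> compare, with a persisted config,
# per-stage logging and plot-ready CSV outputs.

#' Build a pipeline run configuration
#'
#' All analysis constants are defaults here, never hard-coded in stages.
#'
#' @param seed Master seed for the run.
#' @param n_cells_per_group Benchmark population size.
#' @param n_background Background genes in the benchmark.
#' @param min_cells Gene filter: minimum expressing cells.
#' @param min_genes,max_genes,max_mito,max_umi Cell filter thresholds.
#' @param k Meta-cell subgroup size for scoring.
#' @param window,step Sliding-window size and step for the trajectory.
#' @param pseudo Score pseudo-count.
#' @param scale_factor Log-normalisation scale factor.
#' @param stratify_ccnd1 Restrict entropy/variation analyses to
#'   cyclin-D1-positive cells?
#' @param exchange An [exchange_config()].
#' @param stages Named logical toggles: `score`, `exchange`.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_cells_per_group = 300,
                       n_background = 500, min_cells = 3,
                       min_genes = 200, max_genes = 5000,
                       max_mito = 0.20, max_umi = 20000,
                       k = 20, window = 20, step = 5, pseudo = 0.001,
                       scale_factor = 1e4, stratify_ccnd1 = TRUE,
                       exchange = exchange_config(seed = seed + 10L),
                       stages = list(score = TRUE, exchange = TRUE)) {
  cfg <- list(seed = as.integer(seed),
              n_cells_per_group = n_cells_per_group,
              n_background = n_background, min_cells = min_cells,
              min_genes = min_genes, max_genes = max_genes,
              max_mito = max_mito, max_umi = max_umi, k = k,
              window = window, step = step, pseudo = pseudo,
              scale_factor = scale_factor, stratify_ccnd1 = stratify_ccnd1,
              exchange = unclass(exchange), stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$exchange <- do.call(exchange_config, cfg$exchange)
  do.call(run_config, cfg)
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic benchmark, applies gene and cell filters,
#' normalises, computes per-cell meta-cell scores and entropies,
#' intercellular variation, pairwise group tests, runs the exchange
#' simulation on the CD133-negative population and writes the
#' entropy-ordered trajectories.
#'
#' Outputs written to `out_dir`: `config.yaml`, `entropy.csv`,
#' `scores.csv` (when the score stage is on), `variation.csv`,
#' `tests.csv`, `trajectory.csv`, `manifest.yaml`, `log.txt`.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- character(0)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)

  # -- simulate
  ds <- build_benchmark_dataset(seed = config$seed,
                                n_cells_per_group = config$n_cells_per_group,
                                n_background = config$n_background)
  log <- .log_stage(log, "simulate", sprintf("%d genes x %d cells",
                                             nrow(ds$counts), ncol(ds$counts)))

  # -- qc (genes, then cells)
  m <- filter_genes(ds$counts, min_cells = config$min_cells)
  log <- .log_stage(log, "qc", sprintf("gene filter: %d -> %d genes",
                                       nrow(ds$counts), nrow(m)))
  m2 <- filter_cells(m, min_genes = config$min_genes,
                     max_genes = config$max_genes,
                     max_mito = config$max_mito, max_umi = config$max_umi)
  log <- .log_stage(log, "qc", sprintf("cell filter: %d -> %d cells",
                                       ncol(m), ncol(m2)))
  meta <- ds$metadata[match(colnames(m2), ds$metadata$cell_id), ]

  # -- normalise
  med <- median_normalize(m2)
  scaled <- zscale_genes(normalize_log10k(m2, config$scale_factor))
  log <- .log_stage(log, "normalize", "median_norm + lognorm_10k/zscale")

  groups <- split(meta$cell_id, meta$group)
  analysis_cells <- function(g) {
    cells <- groups[[g]]
    if (config$stratify_ccnd1) {
      keep <- meta$ccnd1_status[match(cells, meta$cell_id)] == "pos"
      cells <- cells[keep %in% TRUE]
    }
    cells
  }

  # -- entropy per population (mu fitted within each analysis population)
  ent <- do.call(rbind, lapply(names(groups), function(g) {
    cells <- analysis_cells(g)
    if (length(cells) < 5L) return(NULL)
    e <- panel_entropy(med, cells = cells)
    e$group <- g
    e
  }))
  utils::write.csv(ent, file.path(out_dir, "entropy.csv"),
                   row.names = FALSE)
  log <- .log_stage(log, "entropy", sprintf("%d cells scored", nrow(ent)))

  # -- meta-cell scores per population
  if (isTRUE(config$stages$score)) {
    sc <- do.call(rbind, lapply(names(groups), function(g) {
      cells <- analysis_cells(g)
      if (length(cells) < config$k + 5L) return(NULL)
      s <- score_cells(med[, cells, drop = FALSE], k = config$k)
      s$group <- g
      s
    }))
    utils::write.csv(sc, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    log <- .log_stage(log, "score", sprintf("%d cells scored", nrow(sc)))
  }

  # -- intercellular variation per population
  vr <- do.call(rbind, lapply(names(groups), function(g) {
    cells <- analysis_cells(g)
    if (length(cells) < 2L) return(NULL)
    v <- group_variation(scaled, cells)
    data.frame(group = g, median_distance = v$summary[["median"]],
               iqr_distance = v$summary[["iqr"]],
               n_cells = v$summary[["n_cells"]])
  }))
  utils::write.csv(vr, file.path(out_dir, "variation.csv"),
                   row.names = FALSE)
  log <- .log_stage(log, "variation", sprintf("%d groups", nrow(vr)))

  # -- pairwise entropy comparisons
  by_group <- split(ent$entropy, ent$group)
  by_group <- by_group[vapply(by_group, length, 1L) >= 3L]
  tests <- compare_groups(by_group)
  utils::write.csv(tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  log <- .log_stage(log, "compare", sprintf("%d pairs", nrow(tests)))

  # -- exchange simulation on the CD133-negative population + trajectories
  if (isTRUE(config$stages$exchange)) {
    target <- meta$cell_id[meta$cd133_status %in% "neg"]
    ex_cfg <- do.call(exchange_config, config$exchange)
    ex <- run_exchange(med, ex_cfg, target_cells = target)
    traj <- .exchange_trajectories(med, ex, meta, config)
    utils::write.csv(traj, file.path(out_dir, "trajectory.csv"),
                     row.names = FALSE)
    log <- .log_stage(log, "exchange",
                      sprintf("model %d on %d cells; mean entropy %.3f -> %.3f",
                              ex_cfg$model, length(target),
                              mean(ex$entropy_before$entropy),
                              mean(ex$entropy_after$entropy)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("iegflux")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_genes_raw = nrow(ds$counts), n_cells_raw = ncol(ds$counts),
    n_genes_qc = nrow(m2), n_cells_qc = ncol(m2))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

.exchange_trajectories <- function(med, ex, meta, config) {
  target <- ex$entropy_before$cell_id
  pos <- meta$cell_id[meta$cd133_status %in% "pos"]
  rows <- list()
  add <- function(group, phase, ent_df, mat, mu) {
    if (nrow(ent_df) < config$window) return(NULL)
    tr <- entropy_trajectory(
      stats::setNames(ent_df$entropy, ent_df$cell_id),
      mat[, ent_df$cell_id, drop = FALSE],
      mu_all = mu, window = config$window, step = config$step)
    tr$group <- group
    tr$phase <- phase
    tr
  }
  rows$pre <- add("SKO-CD133neg", "pre", ex$entropy_before, med, ex$mu)
  rows$post <- add("SKO-CD133neg", "post", ex$entropy_after, ex$matrix,
                   ex$mu)
  if (length(pos) >= config$window) {
    mu_pos <- group_expected_counts(med, cells = pos)
    ep <- panel_entropy(med, cells = pos, mu = mu_pos)
    rows$pos <- add("SKO-CD133pos", "reference", ep, med, mu_pos)
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Summarise a completed pipeline run
#'
#' Recomputes tabular summaries from the run directory's CSV outputs:
#' entropy medians/IQRs per group, the pairwise test table, variation
#' summaries and the trajectory table. Idempotent; errors name any
#' missing stage output.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Named list of data frames: `entropy_summary`, `tests`,
#'   `variation`, `trajectory` (when present).
#' @export
report <- function(run_dir) {
  need <- function(f, stage) {
    path <- file.path(run_dir, f)
    if (!file.exists(path))
      stop("missing output `", f, "` for stage `", stage,
           "`; run run_pipeline() first", call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ent <- need("entropy.csv", "entropy")
  entropy_summary <- do.call(rbind, lapply(split(ent, ent$group),
    function(d) data.frame(
      group = d$group[1L], n_cells = nrow(d),
      median_entropy = stats::median(d$entropy),
      iqr_entropy = stats::IQR(d$entropy))))
  rownames(entropy_summary) <- NULL
  out <- list(entropy_summary = entropy_summary,
              tests = need("tests.csv", "compare"),
              variation = need("variation.csv", "variation"))
  traj_path <- file.path(run_dir, "trajectory.csv")
  if (file.exists(traj_path))
    out$trajectory <- utils::read.csv(traj_path, stringsAsFactors = FALSE)
  out
}
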