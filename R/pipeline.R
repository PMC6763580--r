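#' Build a pipeline run configuration
#'
#' Collects every stage parameter (defaults follow the package-wide
#' defaults), the master seed, and either a simulation request or input
#' paths. Stage seeds are derived deterministically from the master seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param simulate named list of arguments for \code{\link{cohort_spec}} /
#'   \code{\link{simulate_cohort}} (e.g. \code{n_donors}, \code{weeks},
#'   \code{conditions}, \code{cells_per_sample}, \code{planted}), or
#'   \code{NULL} to read files.
#' @param input_files character vector of cell files (when not simulating).
#' @param meta_file metadata TSV with \code{SampleMeta} columns (when not
#'   simulating).
#' @param condition which condition to cluster (\code{"unstim"} or
#'   \code{"stim"}).
#' @param qc_min_cells,cells_per_sample,n_reference,cofactor prep stage.
#' @param perplexity,theta,iterations embed stage.
#' @param target_bins hexbin stage.
#' @param k,min_cells cluster stage.
#' @param group,stratify stats stage.
#' @param screen optional named list for the screen stage:
#'   \code{markers}, \code{n_perm}, \code{theta_grid}.
#' @return A \code{run_config} list.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = list(),
                       input_files = NULL, meta_file = NULL,
                       condition = "unstim",
                       qc_min_cells = 3000, cells_per_sample = 6000,
                       n_reference = 30000, cofactor = 5,
                       perplexity = 60, theta = 0.5, iterations = 2000,
                       target_bins = 10000, k = 28, min_cells = 1500,
                       group = "location", stratify = "week",
                       screen = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, input_files = input_files,
                 meta_file = meta_file, condition = condition,
                 qc_min_cells = qc_min_cells,
                 cells_per_sample = cells_per_sample,
                 n_reference = n_reference, cofactor = cofactor,
                 perplexity = perplexity, theta = theta,
                 iterations = iterations, target_bins = target_bins,
                 k = k, min_cells = min_cells, group = group,
                 stratify = stratify, screen = screen),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a \code{run_config}.
#' @return \code{character(0)} when valid, otherwise the list of violations.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)
  chk(is.character(config$out_dir) && nzchar(config$out_dir),
      "out_dir must be a non-empty path")
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed must be a single integer")
  chk(config$perplexity > 0, "perplexity > 0")
  chk(config$theta >= 0 && config$theta <= 1, "theta in [0, 1]")
  chk(config$iterations >= 1, "iterations >= 1")
  chk(config$target_bins >= 1, "target_bins >= 1")
  chk(config$k >= 1, "k >= 1")
  chk(config$min_cells >= 1, "min_cells >= 1")
  chk(config$qc_min_cells >= 0, "qc_min_cells >= 0")
  chk(config$cells_per_sample >= 1, "cells_per_sample >= 1")
  chk(config$condition %in% c("unstim", "stim"),
      "condition must be 'unstim' or 'stim'")
  if (!is.null(config$screen)) {
    if (!is.null(config$screen$n_perm))
      chk(config$screen$n_perm >= 1, "screen n_perm >= 1")
  }
  if (is.null(config$simulate) || !length(config$simulate)) {
    chk(!is.null(config$input_files) && length(config$input_files) > 0,
        "input_files required when not simulating")
    chk(!is.null(config$meta_file), "meta_file required when not simulating")
  }
  v
}

#' Run the full staged pipeline
#'
#' Stages: prep (load or simulate, QC, transform, downsample, pool) ->
#' embed (t-SNE) -> cluster (hexbin, adjacency, constrained linkage, cut,
#' min-size, propagate) -> stats (occupancy, stratified rank-sum tests, PCA +
#' MANOVA partition when the design allows) -> screen (optional HAZ
#' permutation screen on stimulated functional features). All intermediate
#' artifacts are TSV; a YAML manifest records seeds, parameters, per-stage
#' row counts and md5 hashes of every output.
#'
#' @param config a \code{run_config}; invalid configurations abort before any
#'   compute.
#' @return Invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid config: ", paste(viol, collapse = "; "))
  if (!is.null(config$meta_file) && !file.exists(config$meta_file))
    stop("metadata file not found: ", config$meta_file)
  for (f in config$input_files)
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- list(package_version = as.character(
    utils::packageVersion("hexclust")),
    seed = config$seed, stages = list(), files = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] done")
  }

  ## prep ------------------------------------------------------------------
  simulating <- length(config$simulate) > 0
  if (simulating) {
    sim_args <- config$simulate
    spec_args <- sim_args[intersect(names(sim_args),
                                    names(formals(cohort_spec)))]
    spec <- do.call(cohort_spec, spec_args)
    cps <- sim_args$cells_per_sample %||% config$cells_per_sample
    sim <- simulate_cohort(spec, cells_per_sample = cps,
                           seed = config$seed)
    meta <- sim$meta
    tables <- sim$tables
    panel <- sim$panel
  } else {
    meta <- utils::read.table(config$meta_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    tables <- lapply(config$input_files, read_cells)
    names(tables) <- vapply(tables, function(t) t$sample_id[1], character(1))
    tables <- lapply(tables, asinh_transform, panel = config$cofactor)
    panel <- marker_panel(colnames(tables[[1]]$values))
    sim <- NULL
  }
  keep_ids <- meta$sample_id[meta$condition == config$condition]
  tables <- tables[names(tables) %in% keep_ids]
  qc <- vapply(tables, function(t)
    qc_filter(t, config$qc_min_cells)$keep, logical(1))
  if (any(!qc))
    message("prep: discarding ", sum(!qc), " sample(s) below QC threshold")
  tables <- tables[qc]
  if (!length(tables)) stop("prep: no samples passed QC")
  tables <- lapply(seq_along(tables), function(i)
    suppressWarnings(downsample(tables[[i]], config$cells_per_sample,
                                seed = config$seed + i)))
  pooled <- pool_cells(tables, reference = NULL, seed = config$seed)
  write_cells(pooled, out("pooled.tsv"))
  log_stage("prep", n_samples = length(tables), n_cells = n_cells(pooled))

  ## embed -----------------------------------------------------------------
  emb <- run_tsne(pooled, perplexity = config$perplexity,
                  theta = config$theta, iterations = config$iterations,
                  seed = config$seed + 101L)
  write_embedding(emb, out("embedding.tsv"))
  log_stage("embed", n_cells = nrow(emb$coords))

  ## cluster ---------------------------------------------------------------
  grid <- build_hexgrid(emb, target_bins = config$target_bins)
  graph <- build_adjacency(compute_bin_graph(grid, pooled))
  fit <- hex_adjclust(graph, panel, k = config$k,
                      min_cells = config$min_cells)
  labels <- data.frame(cell_id = seq_len(n_cells(pooled)),
                       sample_id = pooled$sample_id,
                       cluster = fit$assignment$cell_cluster)
  utils::write.table(labels, out("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fit$history, out("merges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bin_graph(graph, out("bins.tsv"), out("edges.tsv"))
  log_stage("cluster", n_bins = nrow(graph$bins),
            k = fit$assignment$k)

  ## stats -----------------------------------------------------------------
  occ <- compute_occupancy(fit$assignment$cell_cluster, pooled$sample_id,
                           k = fit$assignment$k)
  utils::write.table(data.frame(sample_id = rownames(occ), occ,
                                check.names = FALSE),
                     out("occupancy.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tests <- tryCatch(
    test_occupancy(occ, meta, group = config$group,
                   stratify = if (length(unique(
                     meta[[config$stratify]][meta$sample_id %in%
                                               rownames(occ)])) > 1L)
                     config$stratify else NULL),
    error = function(e) {
      message("stats: occupancy tests skipped (", conditionMessage(e), ")")
      NULL
    })
  if (!is.null(tests))
    utils::write.table(tests, out("occupancy_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  vp <- tryCatch({
    scores <- pca_occupancy(occ)
    covs <- intersect(c("batch_set", "week", "location", "ethnicity",
                        "sex", "cmv_status"), names(meta))
    suppressWarnings(manova_partition(scores, meta, covariates = covs))
  }, error = function(e) {
    message("stats: variance partition skipped (", conditionMessage(e), ")")
    NULL
  })
  if (!is.null(vp))
    utils::write.table(vp, out("variance_partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  log_stage("stats", n_samples = nrow(occ),
            n_tests = if (is.null(tests)) 0L else nrow(tests))

  ## screen ----------------------------------------------------------------
  scr <- NULL
  if (!is.null(config$screen) && simulating &&
      "stim" %in% sim$meta$condition) {
    markers <- config$screen$markers %||%
      names(panel$roles)[panel$roles == "function"]
    feats <- functional_features(sim, markers, condition = "stim")
    stim_meta <- sim$meta[sim$meta$condition == "stim", , drop = FALSE]
    scr <- permutation_screen(
      feats, stim_meta,
      theta_grid = config$screen$theta_grid %||% seq(0, 2, 0.1),
      n_perm = config$screen$n_perm %||% 5000,
      seed = config$seed + 202L)
    utils::write.table(scr$per_theta, out("screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(scr$candidates, out("screen_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("screen", n_features = ncol(feats),
              n_candidates = nrow(scr$candidates))
  }

  ## manifest --------------------------------------------------------------
  outputs <- list.files(config$out_dir, pattern = "\\.tsv$",
                        full.names = TRUE)
  manifest$files <- lapply(stats::setNames(outputs, basename(outputs)),
                           function(f) list(md5 = unname(tools::md5sum(f)),
                                            rows = length(
                                              readLines(f)) - 1L))
  manifest$params <- unclass(config)[setdiff(names(config),
                                             c("out_dir", "input_files",
                                               "meta_file", "simulate"))]
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(list(manifest = manifest, pooled = pooled, embedding = emb,
                 graph = graph, fit = fit, occupancy = occ, tests = tests,
                 variance = vp, screen = scr, meta = meta, sim = sim))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
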