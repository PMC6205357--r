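#' Read / write a run configuration
#'
#' A run is reproducible from its YAML configuration plus seed alone. The
#' configuration holds either a synthetic `scenario` (the arguments of
#' [scenario_config()]) or `data` paths (mask directory/glob + behavior
#' CSV), plus `method` parameters (`B`, `v`, `alpha`, `grid`, `tolerance`,
#' `k_inner`, `k_outer`, `min_frequency`) and a `seed`.
#'
#' @param path YAML file path.
#' @param config a configuration list (for writing).
#' @return `read_run_config()`: the configuration list. `write_run_config()`:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config$.dir <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

config_scenario <- function(config) {
  sc <- config$scenario
  if (is.null(sc)) sc <- list()
  sc$seed <- if (is.null(config$seed)) 1L else config$seed
  args <- sc[names(sc) %in% names(formals(scenario_config))]
  if (!is.null(sc$preset)) {
    f <- switch(sc$preset, focal = scenario_focal,
                size_driven = scenario_size_driven, null = scenario_null,
                battery = scenario_battery,
                stop(sprintf("unknown scenario preset '%s'", sc$preset)))
    do.call(f, args[names(args) %in% names(formals(f))])
  } else do.call(scenario_config, args)
}

config_cohort <- function(config) {
  if (!is.null(config$data)) {
    paths <- config$data$masks
    if (length(paths) == 1 && dir.exists(file.path(config$.dir %||% ".", paths)))
      paths <- list.files(file.path(config$.dir %||% ".", paths),
                          pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    load_cohort(paths, config$data$behavior)
  } else {
    simulate_cohort(config_scenario(config))$cohort
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort to disk
#'
#' Writes per-participant NIfTI lesion masks, the behavior CSV, ground-truth
#' region masks (NIfTI) + JSON, and the resolved configuration, so the
#' pipeline can consume synthetic and real data identically.
#'
#' @param config configuration list (see [read_run_config()]) or a YAML
#'   path.
#' @param out_dir output directory (created if missing).
#' @return The simulated `list(cohort, truth)`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config_scenario(config)
  sim <- simulate_cohort(sc)
  g <- sim$cohort$geometry
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (i in seq_along(sim$cohort$masks))
    write_volume(sim$cohort$masks[[i]], g,
                 file.path(mask_dir, paste0(sim$cohort$ids[i], ".nii.gz")))
  write.csv(cbind(participant_id = sim$cohort$ids,
                  lesion_size_cc = sim$cohort$sizes_cc, sim$cohort$behavior),
            file.path(out_dir, "behavior.csv"), row.names = FALSE)
  for (nm in names(sim$truth$regions))
    write_volume(sim$truth$regions[[nm]], g,
                 file.path(out_dir, paste0("region_", nm, ".nii.gz")))
  jsonlite::write_json(
    list(seed = sc$seed, n = sc$n,
         regions = lapply(sim$truth$regions, as.integer),
         sizes_vox = sim$truth$sizes_vox,
         deficit_models = sim$truth$deficit_models),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(sim)
}

#' Full-sample lesion-symptom mapping to disk
#'
#' Runs VLSM (continuous FWER) or SCCAN (with sparseness optimization) on
#' the full sample for every behavior column, writing statistic/weight
#' volumes, binary templates, the sparseness search path (CSV) and a JSON
#' parameter sidecar.
#'
#' @param config configuration list or YAML path.
#' @param method `"vlsm"` or `"sccan"`.
#' @param out_dir output directory.
#' @return Named list of templates, invisibly.
#' @export
cmd_map <- function(config, method = c("vlsm", "sccan"), out_dir) {
  method <- match.arg(method)
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- config_cohort(config)
  mp <- config$method %||% list()
  seed <- config$seed %||% 1L
  mask <- build_analysis_mask(cohort, mp$min_frequency %||% 0.10)
  X <- dtlvc_normalize(cohort, mask)
  g <- cohort$geometry
  out <- list()
  for (d in names(cohort$behavior)) {
    y <- cohort$behavior[[d]]
    if (method == "vlsm") {
      sm <- continuous_fwer_threshold(X, y, B = mp$B %||% 1000,
                                      v = mp$v %||% 100,
                                      alpha = mp$alpha %||% 0.05,
                                      seed = derive_seed(seed, "map", d))
      stat <- numeric(n_voxels(g)); stat[mask$voxels] <- sm$statistic
      write_volume(array(stat, g$dims), g,
                   file.path(out_dir, sprintf("%s_%s_stat.nii.gz", d, method)))
      tmpl <- vlsm_template(sm)
      sidecar <- c(sm$params, list(threshold = sm$threshold,
                                   template_voxels = tmpl$size))
    } else {
      opt <- optimize_sparseness(X, y, grid = mp$grid %||%
                                   c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1),
                                 k = mp$k_inner %||% 4,
                                 tolerance = mp$tolerance %||% 0.02,
                                 seed = derive_seed(seed, "sgrid", d))
      write.csv(opt$path, file.path(out_dir, sprintf("%s_sccan_path.csv", d)),
                row.names = FALSE)
      fit <- sccan_fit(X, y, opt$s_star)
      wmap <- numeric(n_voxels(g)); wmap[mask$voxels] <- fit$weights
      write_volume(array(wmap, g$dims), g,
                   file.path(out_dir, sprintf("%s_%s_weights.nii.gz", d, method)))
      tmpl <- suppressMessages(sccan_template(fit))
      sidecar <- list(s_star = opt$s_star,
                      cv_correlation = as.numeric(opt$cv_correlation),
                      template_voxels = tmpl$size, seed = seed)
    }
    write_volume(tmpl, g,
                 file.path(out_dir, sprintf("%s_%s_template.nii.gz", d, method)))
    jsonlite::write_json(sidecar,
                         file.path(out_dir, sprintf("%s_%s_params.json", d, method)),
                         auto_unbox = TRUE, digits = NA)
    out[[d]] <- tmpl
  }
  invisible(out)
}

#' Cross-validated prediction study to disk
#'
#' Runs [run_study2()] for the requested methods and writes the per-
#' participant predictor table (CSV), the model-comparison table (CSV +
#' JSON), and a Markdown report with the R-squared table (size / load /
#' both, per deficit and method) and significance flags.
#'
#' @param config configuration list or YAML path.
#' @param out_dir output directory.
#' @param methods methods to run.
#' @return The `study2_result`, invisibly.
#' @export
cmd_predict <- function(config, out_dir, methods = c("vlsm", "sccan")) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- config_cohort(config)
  mp <- config$method %||% list()
  seed <- config$seed %||% 1L
  res <- run_study2(cohort, methods = methods,
                    config = utils::modifyList(
                      list(seed = seed),
                      mp[names(mp) %in% c("k", "B", "v", "alpha", "sccan_s",
                                          "grid", "tolerance", "k_inner",
                                          "min_frequency", "rebuild_mask")]))
  for (m in names(res$predictors)) {
    pt <- res$predictors[[m]]
    write.csv(data.frame(participant_id = cohort$ids, fold = as.integer(pt$folds),
                         lesion_size_cc = pt$lesion_size_cc, pt$loads,
                         check.names = FALSE),
              file.path(out_dir, sprintf("predictors_%s.csv", m)),
              row.names = FALSE)
  }
  write.csv(res$comparisons, file.path(out_dir, "model_comparisons.csv"),
            row.names = FALSE)
  jsonlite::write_json(res$comparisons, file.path(out_dir, "model_comparisons.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  md <- c(sprintf("# Lesion-load prediction report"),
          sprintf(""),
          sprintf("seed: %d | folds: %d | methods: %s", seed, res$config$k,
                  paste(names(res$predictors), collapse = ", ")),
          "",
          "| method | deficit | R2 size | R2 load | R2 both | dR2 | p | sig |",
          "|---|---|---|---|---|---|---|---|",
          apply(res$comparisons, 1, function(r)
            sprintf("| %s | %s | %.3f | %.3f | %.3f | %.3f | %.3g | %s |",
                    r[["method"]], r[["deficit"]], as.numeric(r[["r2_size"]]),
                    as.numeric(r[["r2_load"]]), as.numeric(r[["r2_both"]]),
                    as.numeric(r[["delta_r2"]]), as.numeric(r[["p_value"]]),
                    ifelse(as.logical(r[["significant"]]), "*", ""))))
  writeLines(md, file.path(out_dir, "report.md"))
  write_run_config(config, file.path(out_dir, "config.yaml"))
  invisible(res)
}
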