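#' Run the full comparative-physiology pipeline
#'
#' For every scenario: simulate (or accept) the growth series and the
#' three time-point chromatograms, fit the growth parameters, select the
#' fifth / half / max OD sampling points, quantify each chromatogram by
#' the internal-standard method, and classify the resulting lipid
#' trajectory. Per-sample failures are caught, reported, and do not stop
#' the remaining samples.
#'
#' @param scenarios Named list of [scenario_config()] objects (e.g. from
#'   [clade_scenarios()]).
#' @param out_dir Optional output directory; when given, writes
#'   `growth_parameters.tsv` (strain, medium, mu_max, generation_time,
#'   lag, od_max), `timepoints.tsv`, `trajectories.tsv`,
#'   `composition.tsv` and a `manifest.json` recording every setting and
#'   seed used.
#' @param window,lag_threshold Passed to [growth_fit()].
#' @param min_prominence,baseline_window,rt_tolerance Passed to the peak
#'   detection and assignment steps.
#' @param epsilon,oleaginous_threshold Passed to [build_trajectory()].
#' @param seed Optional integer; when given, re-seeds scenario `i` with
#'   `seed + 100 * i` for end-to-end reproducibility.
#' @param verbose Log per-sample progress to stderr.
#' @return (Invisibly) a `pipeline_report`: data frames `growth`,
#'   `timepoints`, `trajectories`, `composition`, plus `fits`,
#'   `trajectory_objects` and a character vector `failures`.
#' @export
#' @examples
#' sc <- clade_scenarios("oleic")[1:2]
#' rep <- run_pipeline(sc)
#' rep$trajectories
run_pipeline <- function(scenarios, out_dir = NULL, window = 5L,
                         lag_threshold = 0.10, min_prominence = 20,
                         baseline_window = 1, rt_tolerance = 0.1,
                         epsilon = 0.10, oleaginous_threshold = 20,
                         seed = NULL, verbose = FALSE) {
  if (inherits(scenarios, "scenario_config")) scenarios <- list(scenarios)
  growth_rows <- list(); tp_rows <- list(); trajs <- list(); fits <- list()
  failures <- character()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    id <- names(scenarios)[i] %||% paste0("scenario_", i)
    if (!is.null(seed))
      sc$growth$seed <- as.integer(seed + 100L * i)
    res <- tryCatch({
      bundle <- simulate_scenario(sc)
      fit <- growth_fit(bundle$growth, window = window,
                        lag_threshold = lag_threshold)
      tps <- select_timepoints(bundle$growth, fit)
      quants <- lapply(bundle$samples, function(smp)
        analyze_chromatogram(smp$chromatogram, sc$rt_library,
                             min_prominence = min_prominence,
                             baseline_window = baseline_window,
                             rt_tolerance = rt_tolerance))
      traj <- build_trajectory(quants,
                               strain_label = sc$growth$strain_label,
                               medium_label = sc$growth$medium_label,
                               epsilon = epsilon,
                               oleaginous_threshold = oleaginous_threshold)
      list(fit = fit, tps = tps, traj = traj)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", id, conditionMessage(res)))
      if (verbose) message(sprintf("[%s] FAILED: %s", id,
                                   conditionMessage(res)))
      next
    }
    if (verbose) message(sprintf("[%s] ok (mu_max %.3f, max %%CDW %.1f)",
                                 id, res$fit$mu_max, res$traj$max_pct_cdw))
    fit <- res$fit
    growth_rows[[id]] <- data.frame(
      strain = sc$growth$strain_label, medium = sc$growth$medium_label,
      mu_max = fit$mu_max, generation_time = fit$generation_time,
      lag = fit$lag, od_max = fit$od_max, r2 = fit$r2,
      stringsAsFactors = FALSE)
    tp_rows[[id]] <- cbind(strain = sc$growth$strain_label,
                           medium = sc$growth$medium_label,
                           as.data.frame(res$tps))
    trajs[[id]] <- res$traj
    fits[[id]] <- fit
  }
  report <- structure(list(
    growth = if (length(growth_rows)) do.call(rbind, growth_rows) else
      data.frame(),
    timepoints = if (length(tp_rows)) do.call(rbind, tp_rows) else
      data.frame(),
    trajectories = if (length(trajs)) trajectory_report(trajs) else
      data.frame(),
    composition = composition_report(trajs),
    fits = fits, trajectory_objects = trajs, failures = failures,
    settings = list(window = window, lag_threshold = lag_threshold,
                    min_prominence = min_prominence,
                    baseline_window = baseline_window,
                    rt_tolerance = rt_tolerance, epsilon = epsilon,
                    oleaginous_threshold = oleaginous_threshold,
                    seed = seed)), class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d sample(s), %d failure(s)\n",
              nrow(x$growth), length(x$failures)))
  if (nrow(x$trajectories)) {
    print(x$trajectories[, c("strain", "medium", "max_pct_cdw", "pattern",
                             "oleaginous", "major_compound")],
          row.names = FALSE)
  }
  if (length(x$failures)) cat("failures:\n ", paste(x$failures,
                                                    collapse = "\n  "), "\n")
  invisible(x)
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$growth, "growth_parameters.tsv")
  wt(report$timepoints, "timepoints.tsv")
  wt(report$trajectories, "trajectories.tsv")
  wt(report$composition, "composition.tsv")
  manifest <- c(report$settings,
                list(package = "oleagin",
                     version = as.character(utils::packageVersion("oleagin")),
                     r_version = R.version.string,
                     n_samples = nrow(report$growth),
                     failures = report$failures))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' Load a pipeline run configuration from YAML or JSON
#'
#' The file holds an optional `settings` block (any [run_pipeline()]
#' argument) and a `scenarios` list; each scenario gives the
#' [growth_sim_config()] fields plus `pct_cdw` (length 3) and optionally
#' a named `composition` map, `cdw_per_od` and `aliquot_od_units`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with elements `scenarios` (named list of
#'   [scenario_config()]) and `settings`.
#' @export
load_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  scenarios <- list()
  for (s in cfg$scenarios %||% list()) {
    g_args <- s[intersect(names(s), names(formals(growth_sim_config)))]
    g <- do.call(growth_sim_config, g_args)
    sc_args <- list(growth = g, pct_cdw = unlist(s$pct_cdw))
    if (!is.null(s$composition)) sc_args$composition <- unlist(s$composition)
    for (f in c("cdw_per_od", "aliquot_od_units", "chrom_noise_sd"))
      if (!is.null(s[[f]])) sc_args[[f]] <- s[[f]]
    scenarios[[paste(g$strain_label, g$medium_label, sep = "_")]] <-
      do.call(scenario_config, sc_args)
  }
  list(scenarios = scenarios, settings = cfg$settings %||% list())
}
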