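#' Configure a synthetic GC-FID chromatogram
#'
#' Each fatty acid with mass `m` micrograms contributes a Gaussian peak
#' centred at its library retention time with area `k * RF * m`, where `k`
#' is a single global detector response constant (pA min per microgram) and
#' `RF` the per-compound response factor. The internal standard (C17:0 in
#' the default library) is always added at `is_mass_ug` micrograms, the
#' amount spiked into each sample before derivatisation. A linear baseline
#' drift and white detector noise can be superimposed.
#'
#' @param fa_masses_ug Named numeric vector, micrograms of each fatty acid;
#'   names must exist in `rt_library` (the internal standard is excluded —
#'   it is always present at `is_mass_ug`).
#' @param is_mass_ug Internal-standard mass, micrograms (default 75, the
#'   routine spike).
#' @param rt_library An [default_rt_library()]-style library; supplies
#'   retention times and response factors.
#' @param k Detector response constant, pA min per microgram.
#' @param peak_width_sd Gaussian peak width (sd), minutes.
#' @param baseline_level,baseline_drift Baseline offset (pA) and slope
#'   (pA per minute).
#' @param noise_sd White detector noise sd, pA (0 = noiseless).
#' @param sampling_rate Points per minute.
#' @param rt_range Chromatogram time window, minutes.
#' @param seed Integer seed for the noise draw.
#' @return A `chrom_sim_config` list.
#' @export
#' @examples
#' cfg <- chrom_sim_config(c("C18:1(n-9)" = 75), noise_sd = 0)
#' chrom <- simulate_chromatogram(cfg)
chrom_sim_config <- function(fa_masses_ug = numeric(), is_mass_ug = 75,
                             rt_library = default_rt_library(), k = 1000,
                             peak_width_sd = 0.04, baseline_level = 10,
                             baseline_drift = 0.5, noise_sd = 2,
                             sampling_rate = 100, rt_range = NULL,
                             seed = 1L) {
  fa_masses_ug <- unlist(fa_masses_ug)
  if (length(fa_masses_ug) && is.null(names(fa_masses_ug)))
    stop_config("fa_masses_ug must be a named vector")
  unknown <- setdiff(names(fa_masses_ug), rt_library$fa_name)
  if (length(unknown))
    stop_config("fatty acid(s) not in RT library: %s",
                paste(unknown, collapse = ", "))
  is_name <- rt_library$fa_name[rt_library$is_internal_standard]
  if (is_name %in% names(fa_masses_ug))
    stop_config("the internal standard (%s) is added via is_mass_ug", is_name)
  if (any(!is.finite(fa_masses_ug)) || any(fa_masses_ug < 0))
    stop_config("fatty-acid masses must be finite and non-negative")
  if (is_mass_ug <= 0) stop_config("is_mass_ug must be > 0")
  if (peak_width_sd <= 0 || sampling_rate <= 0 || k <= 0)
    stop_config("peak_width_sd, sampling_rate and k must be > 0")
  if (is.null(rt_range))
    rt_range <- c(0, max(rt_library$rt_min) + 2)
  structure(list(fa_masses_ug = fa_masses_ug, is_mass_ug = is_mass_ug,
                 rt_library = rt_library, k = k,
                 peak_width_sd = peak_width_sd,
                 baseline_level = baseline_level,
                 baseline_drift = baseline_drift, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, rt_range = rt_range,
                 seed = as.integer(seed)),
            class = "chrom_sim_config")
}

#' Simulate a GC-FID chromatogram
#'
#' @param config A [chrom_sim_config()].
#' @param sample_id Sample identifier stored in the metadata.
#' @param aliquot_od_units,aliquot_cdw_mg Aliquot metadata carried through
#'   to quantification (OD units harvested; cell dry weight in mg).
#' @return A `chromatogram` object. If any two simulated peaks sit closer
#'   than three peak widths, an `overlap_warning` entry is recorded in the
#'   metadata.
#' @export
simulate_chromatogram <- function(config, sample_id = "sample",
                                  aliquot_od_units = 10,
                                  aliquot_cdw_mg = NA_real_) {
  stopifnot(inherits(config, "chrom_sim_config"))
  lib <- config$rt_library
  is_row <- lib[lib$is_internal_standard, ]
  fa <- config$fa_masses_ug
  fa <- fa[fa > 0]
  rows <- lib[match(names(fa), lib$fa_name), ]
  rts <- c(rows$rt_min, is_row$rt_min)
  areas <- c(config$k * rows$response_factor * unname(fa),
             config$k * is_row$response_factor * config$is_mass_ug)

  rt <- seq(config$rt_range[1L], config$rt_range[2L],
            by = 1 / config$sampling_rate)
  y <- config$baseline_level + config$baseline_drift * rt
  for (i in seq_along(rts))
    y <- y + areas[i] * stats::dnorm(rt, rts[i], config$peak_width_sd)
  if (config$noise_sd > 0)
    y <- y + with_seed(config$seed,
                       stats::rnorm(length(rt), 0, config$noise_sd))

  meta <- list(sample_id = sample_id, aliquot_od_units = aliquot_od_units,
               aliquot_cdw_mg = aliquot_cdw_mg,
               is_mass_ug = config$is_mass_ug)
  if (length(rts) > 1L) {
    gaps <- diff(sort(rts))
    if (any(gaps < 3 * config$peak_width_sd))
      meta$overlap_warning <- sprintf(
        "peaks closer than 3 peak widths (min gap %.3f min)", min(gaps))
  }
  chromatogram(rt, y, metadata = meta)
}

#' Construct a chromatogram object
#'
#' @param rt_min Strictly increasing retention times, minutes, on a grid
#'   uniform to within 1 percent; at least 100 points.
#' @param intensity_pA Detector signal, picoamperes.
#' @param metadata List with at least `sample_id` and `is_mass_ug`
#'   (internal-standard mass, default 75), plus `aliquot_cdw_mg` when
#'   quantification per cell dry weight is wanted.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(rt_min, intensity_pA, metadata = list()) {
  if (length(rt_min) < 100L)
    stop_config("a chromatogram needs at least 100 points")
  d <- diff(rt_min)
  if (any(d <= 0)) stop_config("retention times must be strictly increasing")
  if ((max(d) - min(d)) / mean(d) > 0.01)
    stop_config("retention-time grid must be uniform to within 1%%")
  if (any(!is.finite(intensity_pA)))
    stop_config("intensities must be finite")
  if (is.null(metadata$is_mass_ug)) metadata$is_mass_ug <- 75
  structure(list(rt_min = rt_min, intensity_pA = intensity_pA,
                 metadata = metadata),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("GC-FID chromatogram '%s': %d points, %.2f-%.2f min\n",
              x$metadata$sample_id %||% "?", length(x$rt_min),
              min(x$rt_min), max(x$rt_min)))
  if (!is.null(x$metadata$overlap_warning))
    cat("  note:", x$metadata$overlap_warning, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a chromatogram CSV with JSON metadata sidecar
#'
#' The trace is stored as a two-column CSV (`rt_min`, `intensity_pA`); the
#' aliquot metadata (sample id, OD units harvested, cell dry weight, IS
#' mass) travels in `<path>.meta.json`.
#'
#' @param path CSV file path.
#' @return `read_chromatogram()` returns a `chromatogram`;
#'   `write_chromatogram()` returns `path` invisibly.
#' @export
read_chromatogram <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("rt_min", "intensity_pA"), names(d))
  if (length(miss))
    stop_config("%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  chromatogram(d$rt_min, d$intensity_pA, metadata = meta)
}

#' @rdname read_chromatogram
#' @param chrom A `chromatogram`.
#' @export
write_chromatogram <- function(chrom, path) {
  utils::write.csv(data.frame(rt_min = chrom$rt_min,
                              intensity_pA = chrom$intensity_pA),
                   path, row.names = FALSE)
  jsonlite::write_json(chrom$metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
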