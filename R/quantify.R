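#' Quantify fatty acids by the internal-standard method
#'
#' Converts assigned peak areas into masses using the spiked C17:0
#' internal standard: `mass_i = area_i / area_IS * is_mass_ug / RF_i`.
#' Masses are then normalised to the aliquot cell dry weight to give
#' mg per g CDW and a total lipid content in percent of CDW
#' (`sum(mass_ug) / (cdw_mg * 1000) * 100`). Being a pure area-ratio
#' method, the result is invariant to any global rescaling of the
#' detector signal.
#'
#' @param peaks An [assign_peaks()]-ed peak table.
#' @param lib The retention-time library used for assignment (supplies
#'   response factors and identifies the internal standard).
#' @param aliquot_cdw_mg Cell dry weight of the harvested aliquot, mg;
#'   defaults to the value in the peak-table metadata.
#' @param is_mass_ug Internal-standard mass, micrograms; defaults to the
#'   metadata value (75 by convention).
#' @param include_unassigned If `TRUE`, unassigned peak areas are also
#'   converted to mass (response factor 1) and counted in the total lipid
#'   content; by default only identified FAMEs are counted.
#' @return An object of class `fa_quant`: `masses_ug`, `mg_per_g_cdw`,
#'   `fractions` (of total identified FA mass), `pct_cdw_total`,
#'   `sample_id`, `aliquot_cdw_mg`, `flags`.
#' @export
#' @examples
#' cfg <- chrom_sim_config(c("C18:1(n-9)" = 150, "C16:0" = 75), noise_sd = 0)
#' chrom <- simulate_chromatogram(cfg, aliquot_cdw_mg = 10)
#' pk <- assign_peaks(detect_peaks(chrom), default_rt_library())
#' quantify_fames(pk, default_rt_library())
quantify_fames <- function(peaks, lib, aliquot_cdw_mg = NULL,
                           is_mass_ug = NULL, include_unassigned = FALSE) {
  stopifnot(inherits(peaks, "peak_table"))
  lib <- validate_rt_library(lib)
  meta <- attr(peaks, "metadata") %||% list()
  if (is.null(aliquot_cdw_mg)) aliquot_cdw_mg <- meta$aliquot_cdw_mg
  if (is.null(is_mass_ug)) is_mass_ug <- meta$is_mass_ug %||% 75

  is_name <- lib$fa_name[lib$is_internal_standard]
  is_row <- which(peaks$assignment == is_name)
  if (length(is_row) != 1L || peaks$area[is_row] <= 0)
    stop_config("internal standard (%s) peak missing or empty: cannot quantify",
                is_name)
  area_is <- peaks$area[is_row]

  assigned <- which(!is.na(peaks$assignment) & peaks$assignment != is_name)
  fa <- peaks$assignment[assigned]
  rf <- lib$response_factor[match(fa, lib$fa_name)]
  masses <- stats::setNames(peaks$area[assigned] / area_is * is_mass_ug / rf,
                            fa)

  extra_ug <- 0
  if (include_unassigned) {
    un <- which(is.na(peaks$assignment))
    extra_ug <- sum(peaks$area[un]) / area_is * is_mass_ug
  }

  total_ug <- sum(masses) + extra_ug
  flags <- character()
  fractions <- if (sum(masses) > 0) masses / sum(masses) else {
    flags <- c(flags, "zero_total_fa")
    stats::setNames(rep(NA_real_, length(masses)), fa)
  }
  if (any(peaks$flagged[assigned])) flags <- c(flags, "saturated_peak")

  has_cdw <- is_scalar_num(aliquot_cdw_mg) && aliquot_cdw_mg > 0
  structure(list(
    masses_ug = masses,
    mg_per_g_cdw = if (has_cdw) masses / aliquot_cdw_mg else
      stats::setNames(rep(NA_real_, length(masses)), fa),
    fractions = fractions,
    pct_cdw_total = if (has_cdw) total_ug / (aliquot_cdw_mg * 1000) * 100
                    else NA_real_,
    sample_id = meta$sample_id %||% NA_character_,
    aliquot_cdw_mg = if (has_cdw) aliquot_cdw_mg else NA_real_,
    is_mass_ug = is_mass_ug, flags = flags), class = "fa_quant")
}

#' @export
print.fa_quant <- function(x, ...) {
  cat(sprintf("FAME quantification '%s': %d compound(s)\n",
              x$sample_id, length(x$masses_ug)))
  if (length(x$masses_ug)) {
    d <- data.frame(mass_ug = round(x$masses_ug, 2),
                    mg_per_g_cdw = round(x$mg_per_g_cdw, 2),
                    fraction = round(x$fractions, 4))
    print(d)
  }
  cat(sprintf("total lipid: %s%% of CDW\n",
              format(round(x$pct_cdw_total, 2))))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' One-call chromatogram quantification
#'
#' Convenience wrapper running [detect_peaks()], [assign_peaks()] and
#' [quantify_fames()] with shared settings.
#'
#' @param chrom A [chromatogram()].
#' @param lib Retention-time library.
#' @param min_prominence,baseline_window Passed to [detect_peaks()].
#' @param rt_tolerance Passed to [assign_peaks()].
#' @param ... Passed to [quantify_fames()].
#' @return An `fa_quant`.
#' @export
analyze_chromatogram <- function(chrom, lib = default_rt_library(),
                                 min_prominence = 20, baseline_window = 1,
                                 rt_tolerance = 0.1, ...) {
  pk <- detect_peaks(chrom, min_prominence = min_prominence,
                     baseline_window = baseline_window)
  pk <- assign_peaks(pk, lib, rt_tolerance = rt_tolerance)
  quantify_fames(pk, lib, ...)
}

#' Write a FAME quantification as TSV
#'
#' Writes the per-compound table (`fa_name`, `mass_ug`, `mg_per_g_cdw`,
#' `fraction`) and returns the one-row summary (`sample`,
#' `pct_cdw_total`) invisibly.
#'
#' @param quant An `fa_quant`.
#' @param path Output TSV path.
#' @export
write_fa_quant <- function(quant, path) {
  d <- data.frame(fa_name = names(quant$masses_ug),
                  mass_ug = unname(quant$masses_ug),
                  mg_per_g_cdw = unname(quant$mg_per_g_cdw),
                  fraction = unname(quant$fractions),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(data.frame(sample = quant$sample_id,
                       pct_cdw_total = quant$pct_cdw_total))
}
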