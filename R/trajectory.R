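#' Classify a three-point lipid accumulation pattern
#'
#' Labels the time course of total lipid content measured at the three
#' physiological states (one fifth, one half and the maximum OD600).
#' With relative steps `d12 = (c2 - c1) / max(c1, floor)` and
#' `d23 = (c3 - c2) / max(c2, floor)` and tolerance `epsilon`:
#'
#' * `accumulate_then_mobilize` — rise then fall (`d12 > epsilon`,
#'   `d23 < -epsilon`): lipid built up during exponential growth is
#'   re-consumed in the deceleration phase;
#' * `continuous_increase` — `d12 > epsilon` with no later fall and a net
#'   gain (`c3 > c1 * (1 + epsilon)`), or a flat start followed by a rise;
#' * `decline` — net loss (`c3 < c1 * (1 - epsilon)`) with no initial
#'   rise;
#' * `stable` — anything else.
#'
#' @param contents Numeric length 3, non-negative percent-CDW values in
#'   time order.
#' @param epsilon Relative tolerance for calling a change real
#'   (default 0.10).
#' @param floor Denominator floor guarding against zero contents.
#' @return One of `"accumulate_then_mobilize"`, `"continuous_increase"`,
#'   `"decline"`, `"stable"`.
#' @export
#' @examples
#' classify_pattern(c(34.4, 24, 15.2))  # "decline"
#' classify_pattern(c(10, 20, 10))      # "accumulate_then_mobilize"
classify_pattern <- function(contents, epsilon = 0.10, floor = 1e-6) {
  if (length(contents) != 3L)
    stop_config("contents must have exactly 3 values")
  if (any(!is.finite(contents)) || any(contents < 0))
    stop_config("lipid contents must be finite and non-negative")
  c1 <- contents[1L]; c2 <- contents[2L]; c3 <- contents[3L]
  d12 <- (c2 - c1) / max(c1, floor)
  d23 <- (c3 - c2) / max(c2, floor)
  if (d12 > epsilon && d23 < -epsilon) return("accumulate_then_mobilize")
  if ((d12 > epsilon && d23 >= -epsilon && c3 > c1 * (1 + epsilon)) ||
      (abs(d12) <= epsilon && d23 > epsilon)) return("continuous_increase")
  if (c3 < c1 * (1 - epsilon) && d12 <= epsilon) return("decline")
  "stable"
}

#' Call a strain oleaginous
#'
#' A yeast is oleaginous when its stored lipid exceeds roughly a fifth to
#' a quarter of its biomass; the default threshold takes the lower bound.
#' The comparison is strict, so a content exactly at the threshold is not
#' called oleaginous.
#'
#' @param max_pct_cdw Maximum observed lipid content, percent of CDW.
#' @param threshold Oleaginy threshold, percent (default 20; must lie in
#'   (0, 100)).
#' @return Logical.
#' @export
#' @examples
#' call_oleaginous(67.1)  # TRUE
#' call_oleaginous(20)    # FALSE: strict inequality
call_oleaginous <- function(max_pct_cdw, threshold = 20) {
  if (!is_scalar_num(threshold) || threshold <= 0 || threshold >= 100)
    stop_config("threshold must lie strictly between 0 and 100")
  if (any(max_pct_cdw < 0) || any(max_pct_cdw > 100))
    stop_config("max_pct_cdw must lie in [0, 100]")
  max_pct_cdw > threshold
}

#' Major accumulated compound
#'
#' Returns the fatty acid with the largest mass; compounds within 1
#' percent (relative) of the maximum are returned together as a tie set,
#' as when C16:0 and C18:1(n-9) accumulate in tandem.
#'
#' @param composition Named numeric vector, mass per compound (any
#'   consistent unit, e.g. mg per g CDW).
#' @param tie_tol Relative tie tolerance (default 0.01).
#' @return Character vector of one or more compound names, or
#'   `NA_character_` (with attribute `undefined = TRUE`) when all masses
#'   are zero.
#' @export
#' @examples
#' major_compound(c("C18:2(n-6)" = 30, "C18:1(n-9)" = 20))
major_compound <- function(composition, tie_tol = 0.01) {
  if (!length(composition)) stop_config("composition is empty")
  if (any(!is.finite(composition)) || any(composition < 0))
    stop_config("composition masses must be finite and non-negative")
  top <- max(composition)
  if (top <= 0)
    return(structure(NA_character_, undefined = TRUE))
  names(composition)[composition >= top * (1 - tie_tol)]
}

#' Assemble a lipid trajectory from three time-point quantifications
#'
#' Combines the quantifications made at the fifth / half / max OD600
#' sampling points into one record and applies the classification rules:
#' accumulation pattern over the three total contents, oleaginy of the
#' trajectory maximum, and the major compound at the OD-max point (where
#' the culture is harvested for storage assessment).
#'
#' @param quants List of three [quantify_fames()] results in time order;
#'   an element may be `NULL` (missed harvest), in which case the
#'   classifications are left unset.
#' @param strain_label,medium_label Sample identifiers.
#' @param epsilon Pattern tolerance, see [classify_pattern()].
#' @param oleaginous_threshold Percent-CDW threshold, see
#'   [call_oleaginous()].
#' @return A `lipid_trajectory` object: `points` (data frame `timepoint`,
#'   `pct_cdw`), `composition` (list of mg-per-g-CDW vectors), `pattern`,
#'   `max_pct_cdw`, `oleaginous`, `major_compound_at_max`.
#' @export
build_trajectory <- function(quants, strain_label = "strain",
                             medium_label = "medium", epsilon = 0.10,
                             oleaginous_threshold = 20) {
  if (length(quants) != 3L)
    stop_config("quants must hold exactly three time points")
  labels <- c("fifth", "half", "max")
  missing_pt <- vapply(quants, is.null, TRUE)
  pct <- vapply(seq_len(3L), function(i)
    if (missing_pt[i]) NA_real_ else quants[[i]]$pct_cdw_total, 0)
  comp <- lapply(seq_len(3L), function(i)
    if (missing_pt[i]) NULL else quants[[i]]$mg_per_g_cdw)

  complete <- !anyNA(pct)
  max_pct <- if (all(is.na(pct))) NA_real_ else max(pct, na.rm = TRUE)
  pattern <- if (complete) classify_pattern(pct, epsilon) else NA_character_
  oleaginous <- if (is.na(max_pct)) NA else
    call_oleaginous(max_pct, oleaginous_threshold)
  major <- if (!missing_pt[3L] && length(comp[[3L]]))
    major_compound(comp[[3L]]) else NA_character_

  structure(list(
    strain_label = strain_label, medium_label = medium_label,
    points = data.frame(timepoint = labels, pct_cdw = pct,
                        stringsAsFactors = FALSE),
    composition = stats::setNames(comp, labels),
    pattern = pattern, max_pct_cdw = max_pct, oleaginous = oleaginous,
    major_compound_at_max = major), class = "lipid_trajectory")
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  cat(sprintf("Lipid trajectory: %s on %s\n", x$strain_label,
              x$medium_label))
  cat(sprintf("  %% CDW at fifth/half/max: %s\n",
              paste(format(round(x$points$pct_cdw, 2)), collapse = " / ")))
  cat(sprintf("  pattern: %s | max %s%% CDW | oleaginous: %s\n",
              x$pattern, format(round(x$max_pct_cdw, 2)), x$oleaginous))
  cat(sprintf("  major compound at OD max: %s\n",
              paste(x$major_compound_at_max, collapse = " + ")))
  invisible(x)
}

#' Trajectory and composition reports
#'
#' `trajectory_report()` flattens trajectories into the per-strain report
#' table (one row per strain-by-medium); `composition_report()` returns
#' the long-format per-compound table (strain, medium, timepoint,
#' fa_name, mg_per_g_cdw).
#'
#' @param trajectories List of `lipid_trajectory` objects.
#' @return A data frame.
#' @export
trajectory_report <- function(trajectories) {
  do.call(rbind, lapply(trajectories, function(tr) {
    p <- tr$points$pct_cdw
    data.frame(strain = tr$strain_label, medium = tr$medium_label,
               pct_cdw_fifth = p[1L], pct_cdw_half = p[2L],
               pct_cdw_max = p[3L], pattern = tr$pattern,
               max_pct_cdw = tr$max_pct_cdw, oleaginous = tr$oleaginous,
               major_compound = paste(tr$major_compound_at_max,
                                      collapse = "+"),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname trajectory_report
#' @export
composition_report <- function(trajectories) {
  rows <- list()
  for (tr in trajectories) {
    for (tp in names(tr$composition)) {
      comp <- tr$composition[[tp]]
      if (is.null(comp) || !length(comp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        strain = tr$strain_label, medium = tr$medium_label, timepoint = tp,
        fa_name = names(comp), mg_per_g_cdw = unname(comp),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(strain = character(), medium = character(),
                      timepoint = character(), fa_name = character(),
                      mg_per_g_cdw = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
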