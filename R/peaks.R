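#' Detect and integrate peaks in a GC-FID chromatogram
#'
#' The baseline is estimated by a centred rolling minimum of width
#' `baseline_window` minutes followed by a rolling mean of the same width
#' (a piecewise-linear envelope under the trace), and subtracted. Peaks
#' are local maxima of the corrected signal with topographic prominence of
#' at least `min_prominence`. Each peak's bounds run outward from the apex
#' to the first baseline crossing — where the corrected signal drops below
#' `max(0.1% of the apex height, 3 x the robust noise estimate)` — but
#' never past the valley shared with an adjacent detected peak, so
#' overlapping peaks are split at the minimum between their apexes. Areas
#' are trapezoidal integrals of the corrected signal between the bounds.
#'
#' Flat-topped (saturated) apexes are kept and flagged, not dropped.
#'
#' @param chrom A [chromatogram()].
#' @param min_prominence Minimum peak prominence, pA (default 20, an
#'   order of magnitude above typical detector noise excursions).
#' @param baseline_window Width of the rolling-minimum window, minutes
#'   (default 1; must exceed the widest peak).
#' @return A `peak_table` data frame: `rt_apex`, `height`, `prominence`,
#'   `area` (pA min), `left_min`, `right_min`, `flagged`, `assignment`
#'   (`NA` until [assign_peaks()]). The chromatogram metadata travels
#'   along as an attribute.
#' @export
#' @examples
#' cfg <- chrom_sim_config(c("C18:1(n-9)" = 75), noise_sd = 0)
#' detect_peaks(simulate_chromatogram(cfg))
detect_peaks <- function(chrom, min_prominence = 20, baseline_window = 1) {
  stopifnot(inherits(chrom, "chromatogram"))
  rt <- chrom$rt_min
  y <- chrom$intensity_pA
  n <- length(y)
  dt <- (rt[n] - rt[1L]) / (n - 1L)
  k <- max(1L, round(baseline_window / dt / 2))
  base_min <- rolling_min(y, k)
  # rolling mean recentres the minimum envelope
  cs <- cumsum(c(0, base_min))
  lo <- pmax(seq_len(n) - k, 1L); hi <- pmin(seq_len(n) + k, n)
  baseline <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  z <- y - baseline

  noise <- stats::mad(diff(z)) / sqrt(2)

  # local maxima; a clipped plateau produces two edge maxima which are
  # merged into one flagged apex
  apex <- which(diff(sign(diff(z))) < 0) + 1L
  flat <- vapply(apex, function(i) z[i] == z[i + 1L] || z[i] == z[i - 1L],
                 TRUE)
  if (length(apex) > 1L) {
    tol <- 1e-9 * max(abs(z))
    keep <- rep(TRUE, length(apex))
    last <- 1L
    for (j in 2L:length(apex)) {
      between <- min(z[apex[last]:apex[j]])
      if (between >= max(z[apex[last]], z[apex[j]]) - tol) {
        keep[j] <- FALSE          # same plateau: no dip between the tops
        flat[last] <- TRUE
      } else last <- j
    }
    apex <- apex[keep]; flat <- flat[keep]
  }

  # topographic prominence
  prom <- vapply(apex, function(i) {
    h <- z[i]
    left <- if (i > 1L) {
      higher <- which(z[1:(i - 1L)] > h)
      lo_i <- if (length(higher)) max(higher) + 1L else 1L
      min(z[lo_i:(i - 1L)])
    } else h
    right <- if (i < n) {
      higher <- which(z[(i + 1L):n] > h)
      hi_i <- if (length(higher)) i + min(higher) - 1L else n
      min(z[(i + 1L):hi_i])
    } else h
    h - max(left, right)
  }, 0)

  keep <- prom >= min_prominence
  apex <- apex[keep]; prom <- prom[keep]; flat <- flat[keep]

  m <- length(apex)
  out <- data.frame(rt_apex = numeric(m), height = numeric(m),
                    prominence = prom, area = numeric(m),
                    left_min = numeric(m), right_min = numeric(m),
                    flagged = if (m) flat else logical(0),
                    assignment = rep(NA_character_, m),
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i <- apex[j]
    thresh <- max(0.001 * z[i], 3 * noise)
    # valley caps against neighbouring detected peaks
    lcap <- if (j > 1L) {
      seg <- apex[j - 1L]:i; seg[which.min(z[seg])]
    } else 1L
    rcap <- if (j < m) {
      seg <- i:apex[j + 1L]; seg[which.min(z[seg])]
    } else n
    li <- i
    while (li > lcap && z[li] > thresh) li <- li - 1L
    ri <- i
    while (ri < rcap && z[ri] > thresh) ri <- ri + 1L
    out$rt_apex[j] <- rt[i]
    out$height[j] <- z[i]
    out$left_min[j] <- rt[li]
    out$right_min[j] <- rt[ri]
    out$area[j] <- max(trapz(rt[li:ri], z[li:ri]), 0)
  }
  structure(out, metadata = chrom$metadata,
            class = c("peak_table", "data.frame"))
}

#' Assign detected peaks to a retention-time library
#'
#' Matches peaks to library compounds by retention time: candidate pairs
#' within `rt_tolerance` are assigned greedily in order of increasing
#' retention-time distance, so each library entry captures at most one
#' peak (the nearest) and each peak at most one compound. Remaining peaks
#' stay unassigned.
#'
#' @param peaks A [detect_peaks()] table.
#' @param lib An [default_rt_library()]-style library.
#' @param rt_tolerance Maximum apex-to-library distance, minutes
#'   (default 0.1).
#' @return The peak table with its `assignment` column filled in.
#' @export
assign_peaks <- function(peaks, lib, rt_tolerance = 0.1) {
  stopifnot(inherits(peaks, "peak_table"))
  lib <- validate_rt_library(lib)
  if (nrow(peaks) == 0L) return(peaks)
  d <- abs(outer(peaks$rt_apex, lib$rt_min, "-"))
  cand <- which(d <= rt_tolerance, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_peak <- logical(nrow(peaks)); used_lib <- logical(nrow(lib))
    for (r in seq_len(nrow(cand))) {
      p <- cand[r, 1L]; l <- cand[r, 2L]
      if (!used_peak[p] && !used_lib[l]) {
        peaks$assignment[p] <- lib$fa_name[l]
        used_peak[p] <- TRUE; used_lib[l] <- TRUE
      }
    }
  }
  peaks
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("Peak table: %d peak(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(format(as.data.frame(x), digits = 4))
  invisible(x)
}
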