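#' Estimate growth parameters from an OD600 time series
#'
#' Fits the classical batch-culture growth parameters without assuming a
#' parametric growth law. The maximum specific growth rate is the largest
#' least-squares slope of ln(OD) over all sliding windows of `window`
#' consecutive points (ties broken by the earliest window). The lag phase
#' is the intersection of that tangent line with the baseline, taken as
#' the mean ln(OD) of the pre-growth plateau (points collected before the
#' smoothed curve exceeds the initial OD by `lag_threshold`, relatively).
#' The maximum cell density is the maximum of the median-smoothed series
#' (window 3), and the generation time is `ln(2) / mu_max`.
#'
#' A lag is reported as absent (`NA`) when the tangent construction gives
#' a non-positive time or when the baseline plateau is shorter than one
#' sampling interval — as for cultures transferred onto a medium they are
#' already adapted to. A series that never rises `lag_threshold` above its
#' initial density is flagged `no_growth`; its `mu_max` is reported as
#' computed but `lag` and `generation_time` are unset.
#'
#' @param series An [od_series()] (or data frame with `time_h`, `od600`).
#' @param window Number of consecutive points per regression window
#'   (default 5; must be between 3 and the series length).
#' @param lag_threshold Relative OD rise over the initial density that
#'   marks the end of the baseline plateau (default 0.10).
#' @return An object of class `growth_fit` with components `mu_max`
#'   (per hour), `lag` (hours or `NA`), `od_max`, `generation_time`
#'   (hours), `window_start`, `window_end`, `r2` (of the winning window),
#'   `no_growth`, `baseline_log_od`, and the data used.
#' @seealso [select_timepoints()], [generation_time()]
#' @export
#' @examples
#' cfg <- growth_sim_config("YAYA", "glucose", mu_true = 0.71,
#'                          lag_true = 5.19, od_max_true = 20.86,
#'                          noise_sd = 0)
#' fit <- growth_fit(simulate_growth_curve(cfg))
#' coef(fit)
growth_fit <- function(series, window = 5L, lag_threshold = 0.10) {
  if (!inherits(series, "od_series"))
    series <- od_series(series$time_h, series$od600,
                        replicate = series$replicate %||% "r1")
  n <- nrow(series)
  window <- as.integer(window)
  if (window < 3L) stop_config("window must be at least 3 points")
  if (window > n) stop_config("series has fewer points than the window")

  t <- series$time_h
  logod <- log(series$od600)
  sm <- smooth_od(series$od600)
  od_max <- max(sm)
  od0_est <- sm[1L]

  # sliding-window log-linear regression; earliest window wins ties
  nw <- n - window + 1L
  slopes <- numeric(nw)
  inters <- numeric(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + window - 1L)
    f <- ls_line(t[idx], logod[idx])
    inters[i] <- f[1L]; slopes[i] <- f[2L]
  }
  top <- max(slopes)
  best <- which(slopes >= top - 1e-9 * max(abs(top), 1))[1L]
  mu_max <- slopes[best]
  bidx <- best:(best + window - 1L)
  r2 <- ls_r2(t[bidx], logod[bidx])

  no_growth <- !(od_max > od0_est * (1 + lag_threshold)) || mu_max <= 1e-8

  # baseline plateau: points before the smoothed curve leaves od0
  growth_start <- which(sm > od0_est * (1 + lag_threshold))[1L]
  plateau <- if (is.na(growth_start)) seq_len(n) else seq_len(growth_start - 1L)
  baseline <- if (length(plateau)) mean(logod[plateau]) else logod[1L]
  dt <- stats::median(diff(t))
  plateau_len <- if (length(plateau) >= 2L)
    t[plateau[length(plateau)]] - t[1L] else 0

  lag <- NA_real_
  if (!no_growth && length(plateau) >= 2L && plateau_len >= dt) {
    cand <- (baseline - inters[best]) / mu_max
    if (cand > 0) lag <- cand
  }

  structure(list(
    mu_max = if (no_growth) max(mu_max, 0) else mu_max,
    lag = if (no_growth) NA_real_ else lag,
    od_max = od_max,
    generation_time = if (no_growth || mu_max <= 0) NA_real_
                      else log(2) / mu_max,
    window_start = t[bidx[1L]], window_end = t[bidx[window]],
    r2 = r2, no_growth = no_growth, baseline_log_od = baseline,
    tangent = c(intercept = unname(inters[best]), slope = unname(mu_max)),
    window = window, lag_threshold = lag_threshold,
    series = series, smoothed = sm,
    strain_label = attr(series, "strain_label"),
    medium_label = attr(series, "medium_label"),
    call = match.call()), class = "growth_fit")
}

#' Generation (doubling) time from the maximum specific growth rate
#'
#' @param mu_max Maximum specific growth rate, per hour (> 0).
#' @return `ln(2) / mu_max`, in hours.
#' @export
#' @examples
#' generation_time(0.78)  # 0.89 h
generation_time <- function(mu_max) {
  if (any(!is.finite(mu_max)) || any(mu_max <= 0))
    stop_config("mu_max must be positive")
  log(2) / mu_max
}

#' @export
print.growth_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Growth fit%s%s\n",
              if (!is.null(x$strain_label)) paste0(": ", x$strain_label) else "",
              if (!is.null(x$medium_label)) paste0(" on ", x$medium_label) else ""))
  if (x$no_growth) {
    cat(sprintf("  no growth detected (OD max %.3g)\n", x$od_max))
    return(invisible(x))
  }
  cat(sprintf("  mu_max  %.*g h^-1   (window %g-%g h, R2 %.4f)\n",
              digits, x$mu_max, x$window_start, x$window_end, x$r2))
  cat(sprintf("  lag     %s\n",
              if (is.na(x$lag)) "absent" else sprintf("%.*g h", digits, x$lag)))
  cat(sprintf("  OD max  %.*g\n", digits, x$od_max))
  cat(sprintf("  gen. time %.*g h\n", digits, x$generation_time))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu_max = object$mu_max, lag = object$lag, od_max = object$od_max,
    generation_time = object$generation_time)
}

#' @export
summary.growth_fit <- function(object, ...) {
  structure(list(fit = object,
                 n = nrow(object$series),
                 span = range(object$series$time_h)), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d observations over %g-%g h; baseline ln(OD) %.3f\n",
              x$n, x$span[1L], x$span[2L], x$fit$baseline_log_od))
  invisible(x)
}

#' Piecewise growth envelope implied by the fitted parameters
#'
#' The fitted description of the curve is the tangent construction itself:
#' ln(OD) follows the baseline until the lag ends, rises along the maximum-
#' slope tangent, and saturates at ln(OD max).
#'
#' @param object A `growth_fit`.
#' @param newdata Optional data frame with a `time_h` column.
#' @param ... Unused.
#' @return Predicted OD600 at the requested times.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$time_h else newdata$time_h
  if (object$no_growth)
    return(rep(exp(object$baseline_log_od), length(t)))
  y <- pmax(object$baseline_log_od,
            object$tangent[["intercept"]] + object$tangent[["slope"]] * t)
  exp(pmin(y, log(object$od_max)))
}

#' @export
fitted.growth_fit <- function(object, ...) predict.growth_fit(object)

#' @export
residuals.growth_fit <- function(object, ...)
  object$series$od600 - fitted(object)

#' Resample growth curves from a fitted model
#'
#' Draws new synthetic OD series from a delayed-logistic generator
#' parameterised at the estimates, with log-normal noise of the given sd —
#' the parametric-bootstrap companion to [growth_fit()].
#'
#' @param object A `growth_fit` (with growth detected).
#' @param nsim Number of series to draw.
#' @param seed Integer seed.
#' @param noise_sd Log-scale noise sd of the simulated readings.
#' @param ... Unused.
#' @return A list of `od_series`.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = 1L,
                                noise_sd = 0.02, ...) {
  if (object$no_growth) stop_config("cannot simulate from a no-growth fit")
  s <- object$series
  lapply(seq_len(nsim), function(i) {
    cfg <- growth_sim_config(
      strain_label = object$strain_label %||% "fit",
      medium_label = object$medium_label %||% "fit",
      od0 = exp(object$baseline_log_od), od_max_true = object$od_max,
      mu_true = object$mu_max,
      lag_true = if (is.na(object$lag)) 0 else object$lag,
      sampling_interval = stats::median(diff(s$time_h)),
      duration = max(s$time_h), noise_sd = noise_sd,
      seed = as.integer(seed) + i - 1L)
    simulate_growth_curve(cfg, replicate = paste0("sim", i))
  })
}

#' @export
plot.growth_fit <- function(x, log = "y", ...) {
  s <- x$series
  graphics::plot(s$time_h, s$od600, log = log, xlab = "time (h)",
                 ylab = "OD600", pch = 16, cex = 0.6, ...)
  tt <- seq(min(s$time_h), max(s$time_h), length.out = 200)
  graphics::lines(tt, predict(x, data.frame(time_h = tt)), col = "firebrick")
  graphics::abline(h = x$od_max, lty = 3, col = "grey40")
  if (!x$no_growth && !is.na(x$lag))
    graphics::abline(v = x$lag, lty = 2, col = "steelblue")
  invisible(x)
}

#' Select the three physiological sampling time points
#'
#' Returns the earliest times at which linear interpolation of the
#' median-smoothed OD curve first reaches one fifth of the maximum OD,
#' half the maximum, and the maximum itself (the last taken as
#' `(1 - delta) * od_max` so that the plateau is detected robustly).
#'
#' @param series The [od_series()] that was fitted.
#' @param params The corresponding [growth_fit()].
#' @param delta Relative shortfall defining "at OD max" (default 0.02).
#' @return A `timepoint_selection` data frame with columns `timepoint`
#'   (`fifth`, `half`, `max`), `target_od`, `time_h`, `od_at`. Targets the
#'   curve never reaches give `NA` with a warning.
#' @export
#' @examples
#' cfg <- growth_sim_config(mu_true = 0.42, lag_true = 3.38,
#'                          od_max_true = 23.71, noise_sd = 0)
#' s <- simulate_growth_curve(cfg)
#' select_timepoints(s, growth_fit(s))
select_timepoints <- function(series, params, delta = 0.02) {
  stopifnot(inherits(params, "growth_fit"))
  if (params$no_growth)
    stop_config("cannot select time points: no growth detected")
  sm <- smooth_od(series$od600)
  t <- series$time_h
  targets <- c(fifth = params$od_max / 5, half = params$od_max / 2,
               max = (1 - delta) * params$od_max)
  times <- vapply(targets, function(tg) first_crossing(t, sm, tg), 0)
  if (anyNA(times))
    warning(sprintf("target(s) never reached: %s",
                    paste(names(times)[is.na(times)], collapse = ", ")),
            call. = FALSE)
  od_at <- ifelse(is.na(times), NA_real_,
                  stats::approx(t, sm, xout = times, rule = 2)$y)
  structure(data.frame(timepoint = names(targets), target_od = unname(targets),
                       time_h = unname(times), od_at = unname(od_at),
                       stringsAsFactors = FALSE),
            class = c("timepoint_selection", "data.frame"))
}
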