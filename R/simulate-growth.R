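#' Configure a synthetic growth-curve simulation
#'
#' Describes one strain-by-medium batch culture followed by OD600: initial
#' density, carrying capacity, maximum specific growth rate, lag phase and
#' a sampling scheme. Two lag models are available: `"delayed_logistic"`
#' holds the culture at `od0` for the duration of the lag and then grows
#' logistically, so the configured lag is exactly recoverable; `"baranyi"`
#' uses the Baranyi-Roberts adjustment function with `h0 = mu * lag` for a
#' smooth transition out of the lag.
#'
#' In both models `mu_true` is the maximum specific growth rate, i.e. the
#' maximum slope of ln(OD) versus time, attained as the culture leaves the
#' lag (the internal logistic rate is scaled by `1/(1 - od0/od_max)` so the
#' realised maximum equals `mu_true`).
#'
#' @param strain_label,medium_label Sample identifiers.
#' @param od0 Initial OD600 (> 0); cultures are inoculated at 0.5 by default.
#' @param od_max_true Carrying capacity in OD600 units (> `od0`).
#' @param mu_true Maximum specific growth rate, per hour.
#' @param lag_true Lag phase in hours; 0 means no lag.
#' @param model `"delayed_logistic"` or `"baranyi"`.
#' @param sampling_interval Hours between OD readings.
#' @param duration Total culture time, hours (must cover the lag).
#' @param noise_sd Standard deviation of multiplicative log-normal OD noise
#'   on the log scale (0 = noiseless); keeps simulated OD positive.
#' @param seed Integer seed for the noise draw.
#' @return A `growth_sim_config` list.
#' @export
#' @examples
#' cfg <- growth_sim_config("YAYA", "glucose", mu_true = 0.71,
#'                          lag_true = 5.19, od_max_true = 20.86)
#' series <- simulate_growth_curve(cfg)
#' head(series)
growth_sim_config <- function(strain_label = "strain", medium_label = "glucose",
                              od0 = 0.5, od_max_true = 20, mu_true = 0.5,
                              lag_true = 0, model = "delayed_logistic",
                              sampling_interval = 0.5, duration = 30,
                              noise_sd = 0.02, seed = 1L) {
  if (!model %in% c("delayed_logistic", "baranyi"))
    stop_config("unknown growth model '%s'", model)
  if (!is_scalar_num(od0) || od0 <= 0) stop_config("od0 must be > 0")
  if (od0 >= od_max_true) stop_config("od0 must be < od_max_true")
  if (mu_true <= 0) stop_config("mu_true must be > 0")
  if (lag_true < 0) stop_config("lag_true must be >= 0")
  if (sampling_interval <= 0) stop_config("sampling_interval must be > 0")
  if (duration < lag_true) stop_config("duration must cover the lag phase")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(strain_label = strain_label, medium_label = medium_label,
                 od0 = od0, od_max_true = od_max_true, mu_true = mu_true,
                 lag_true = lag_true, model = model,
                 sampling_interval = sampling_interval, duration = duration,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "growth_sim_config")
}

# Noiseless model OD at times t for a growth_sim_config.
od_model <- function(cfg, t) {
  K <- cfg$od_max_true; od0 <- cfg$od0
  # logistic rate giving a maximum d ln(OD)/dt of exactly mu_true
  r <- cfg$mu_true / (1 - od0 / K)
  if (cfg$model == "delayed_logistic") {
    te <- pmax(t - cfg$lag_true, 0)
    K / (1 + (K / od0 - 1) * exp(-r * te))
  } else {
    # Baranyi-Roberts in y = ln OD with h0 = r * lag
    y0 <- log(od0); ymax <- log(K)
    h0 <- r * cfg$lag_true
    A <- t + (1 / r) * log(exp(-r * t) + exp(-h0) - exp(-r * t - h0))
    y <- y0 + r * A - log(1 + (exp(r * A) - 1) / exp(ymax - y0))
    exp(y)
  }
}

#' Simulate an OD600 growth curve
#'
#' Evaluates the configured growth model on a regular time grid and, when
#' `noise_sd > 0`, applies seeded multiplicative log-normal measurement
#' noise. The simulated OD is floored at 1e-6 so logs remain defined.
#'
#' @param config A [growth_sim_config()].
#' @param replicate Replicate identifier recorded in the output.
#' @return An `od_series` data frame with columns `time_h`, `od600`,
#'   `replicate`, carrying `strain_label` and `medium_label` attributes.
#' @export
simulate_growth_curve <- function(config, replicate = "r1") {
  stopifnot(inherits(config, "growth_sim_config"))
  times <- seq(0, config$duration, by = config$sampling_interval)
  od <- od_model(config, times)
  if (config$noise_sd > 0) {
    eps <- with_seed(config$seed,
                     stats::rnorm(length(times), 0, config$noise_sd))
    od <- od * exp(eps)
  }
  od <- pmax(od, 1e-6)
  od_series(times, od, replicate = replicate,
            strain_label = config$strain_label,
            medium_label = config$medium_label)
}

#' Construct an OD time series
#'
#' @param time_h Strictly increasing sampling times, hours.
#' @param od600 Positive OD600 readings.
#' @param replicate Replicate identifier.
#' @param strain_label,medium_label Sample identifiers.
#' @return An `od_series` data frame.
#' @export
od_series <- function(time_h, od600, replicate = "r1",
                      strain_label = "strain", medium_label = "medium") {
  if (length(time_h) < 5L) stop_config("an OD series needs at least 5 points")
  if (any(diff(time_h) <= 0)) stop_config("times must be strictly increasing")
  if (any(!is.finite(od600)) || any(od600 <= 0))
    stop_config("all OD600 values must be finite and > 0")
  structure(data.frame(time_h = time_h, od600 = od600,
                       replicate = replicate, stringsAsFactors = FALSE),
            strain_label = strain_label, medium_label = medium_label,
            class = c("od_series", "data.frame"))
}

#' Read / write OD series CSV
#'
#' The on-disk format has columns `time_h`, `od600`, `replicate`.
#'
#' @param path CSV file path.
#' @param strain_label,medium_label Identifiers attached on read.
#' @return `read_od_series()` returns an `od_series`;
#'   `write_od_series()` returns `path` invisibly.
#' @export
read_od_series <- function(path, strain_label = "strain",
                           medium_label = "medium") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time_h", "od600"), names(d))
  if (length(miss))
    stop_config("%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  if (is.null(d$replicate)) d$replicate <- "r1"
  od_series(d$time_h, d$od600, d$replicate, strain_label, medium_label)
}

#' @rdname read_od_series
#' @param series An `od_series`.
#' @export
write_od_series <- function(series, path) {
  utils::write.csv(as.data.frame(series)[c("time_h", "od600", "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}
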