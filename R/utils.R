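# Internal numerical helpers shared across modules.

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Centred rolling minimum with window half-width k points; edges use the
# truncated window.
rolling_min <- function(y, k) {
  n <- length(y)
  if (k <= 0L || n == 0L) return(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    out[i] <- min(y[lo:hi])
  }
  out
}

# Centred rolling median, window 3, robust to single-point spikes.
smooth_od <- function(od) {
  if (length(od) < 3L) return(od)
  as.numeric(stats::runmed(od, 3L, endrule = "keep"))
}

# Least-squares slope and intercept of y on x (closed form).
ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - b * mx, slope = b)
}

# R^2 of the least-squares line fit.
ls_r2 <- function(x, y) {
  f <- ls_line(x, y)
  res <- y - (f[1L] + f[2L] * x)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(1)
  1 - sum(res^2) / tss
}

# Earliest x at which the piecewise-linear interpolant of (x, y) first
# reaches level `target` from below; NA if never reached.
first_crossing <- function(x, y, target) {
  if (y[1L] >= target) return(x[1L])
  idx <- which(y >= target)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  x0 <- x[i - 1L]; x1 <- x[i]; y0 <- y[i - 1L]; y1 <- y[i]
  if (y1 == y0) return(x1)
  x0 + (target - y0) / (y1 - y0) * (x1 - x0)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
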