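# Independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral (re-derived here so tests do not lean on the
# package's internal helper).
oracle_trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Closed-form area of a Gaussian peak a * dnorm(x; mu, sd) is a.
# Trapezoid of a sampled Gaussian over +-8 sd, for cross-checking traces.
oracle_gaussian_trapz <- function(total_area, mu, sd, dx = 0.005) {
  x <- seq(mu - 8 * sd, mu + 8 * sd, by = dx)
  oracle_trapz(x, total_area * dnorm(x, mu, sd))
}

# Brute-force first crossing of a model curve with a level, on a dense
# grid.
oracle_first_crossing <- function(f, level, t_max, dt = 1e-3) {
  tt <- seq(0, t_max, by = dt)
  i <- which(f(tt) >= level)[1]
  if (is.na(i)) NA_real_ else tt[i]
}

# Exhaustive nearest-assignment of peaks to library retention times:
# consider every (peak, entry) pair within tolerance, repeatedly commit
# the globally closest pair.
oracle_assign <- function(peak_rt, lib_rt, tol) {
  assign <- rep(NA_integer_, length(peak_rt))
  used <- logical(length(lib_rt))
  repeat {
    d <- abs(outer(peak_rt, lib_rt, "-"))
    d[!is.na(assign), ] <- Inf
    d[, used] <- Inf
    if (!any(d <= tol)) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    assign[ij[1]] <- ij[2]
    used[ij[2]] <- TRUE
  }
  assign
}

# Exhaustive-scan argmax with relative ties.
oracle_major <- function(comp, tol = 0.01) {
  best <- -Inf
  for (v in comp) if (v > best) best <- v
  out <- character()
  for (nm in names(comp)) if (comp[[nm]] >= best * (1 - tol)) out <- c(out, nm)
  out
}

# Brute-force per-substrate partition scan over a long-format score table.
oracle_partition <- function(df, weak_ok = TRUE) {
  res <- list(universal = character(), unused = character(),
              variable = character())
  for (s in unique(df$substrate)) {
    sc <- df$score[df$substrate == s]
    ok <- if (weak_ok) sc %in% c("growth", "weak") else sc == "growth"
    if (all(ok)) res$universal <- c(res$universal, s)
    else if (all(sc == "none")) res$unused <- c(res$unused, s)
    else res$variable <- c(res$variable, s)
  }
  res
}

# Random long-format phenotype matrix.
random_phenotype_matrix <- function(n_strains, n_substrates, seed) {
  set.seed(seed)
  g <- expand.grid(strain = paste0("S", seq_len(n_strains)),
                   substrate = paste0("sub", seq_len(n_substrates)),
                   stringsAsFactors = FALSE)
  g$substrate_class <- "sugar/other"
  g$medium <- "MMB"
  g$score <- sample(c("growth", "weak", "none"), nrow(g), replace = TRUE)
  g$halo <- NA
  phenotype_matrix(g)
}

# Noiseless standard chromatogram config used in several files.
quiet_chrom <- function(masses, ...) {
  chrom_sim_config(masses, noise_sd = 0, baseline_drift = 0, ...)
}
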