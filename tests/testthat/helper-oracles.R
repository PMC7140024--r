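# Independent oracles used across the suite. None of these call the code
# paths they are used to check.

# Numerical integration of the falling-head ODE
#   A_p dH/dt = -K A_s gamma H / dx
# written directly from the physics, not via the package's flux function.
ode_height_oracle <- function(times, k, geom = device_geometry(),
                              fluid = fluid_properties()) {
  rate <- k * (pi * (geom$sample_diameter_mm / 2)^2) /
    (pi * (geom$pipette_diameter_mm / 2)^2) *
    fluid$specific_weight_N_mm3 / geom$sample_thickness_mm
  f <- function(t, y, parms) list(-rate * y)
  out <- deSolve::ode(y = c(H = geom$initial_height_mm), times = times,
                      func = f, parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  unname(out[, "H"])
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (tie-free samples only).
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(length(pooled), n1), 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(1, p)
}

# Dense grid search over K: the argmin of the filtration objective.
grid_search_k <- function(trace, lo, hi, n = 4000) {
  ks <- exp(seq(log(lo), log(hi), length.out = n))
  obj <- vapply(ks, function(k) filtration_objective(trace, k), 1)
  ks[which.min(obj)]
}

# Dense 2-D grid search over (ic50, slope) for the 4PL with top/bottom
# profiled by closed-form least squares at each grid node (design columns
# 1-f and f), under the same bottom >= 0 constraint the fitter imposes.
grid_search_ic50 <- function(conc, v, ic50_range = c(0.05, 200),
                             slope_range = c(0.2, 5), n = 140) {
  l50s <- seq(log10(ic50_range[1]), log10(ic50_range[2]), length.out = n)
  slopes <- seq(slope_range[1], slope_range[2], length.out = n)
  best <- c(Inf, NA, NA)
  lc <- log10(conc)
  for (l50 in l50s) {
    for (s in slopes) {
      f <- 1 / (1 + 10^(s * (lc - l50)))
      x1 <- 1 - f
      a <- sum(x1^2); b <- sum(x1 * f); c2 <- sum(f^2)
      d <- sum(x1 * v); e <- sum(f * v)
      det <- a * c2 - b * b
      if (abs(det) < 1e-12) next
      bot <- (d * c2 - b * e) / det
      top <- (a * e - b * d) / det
      if (bot < 0) {            # clip to the feasible region
        bot <- 0
        top <- e / c2
      }
      if (top < bot) next
      rss <- sum((v - bot * x1 - top * f)^2)
      if (rss < best[1]) best <- c(rss, l50, s)
    }
  }
  list(ic50 = 10^best[2], slope = best[3], rss = best[1])
}
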