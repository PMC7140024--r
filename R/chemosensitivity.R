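#' Normalize plate-reader viability signals to untreated controls
#'
#' Each treated well's raw signal is divided by the mean untreated signal
#' of its own (cell line, culture setting, timepoint) stratum and expressed
#' as percent viability. Untreated wells are normalized too (their stratum
#' mean maps to 100%).
#'
#' @param plate A data.frame with columns `cell_line, setting, drug,
#'   conc_uM, timepoint_h, replicate, signal, is_untreated` (the plate
#'   schema of [read_plate()]).
#' @return The input with an added `viability_pct` column.
#' @examples
#' plate <- gen_dose_response(ic50_true = 5, seed = 1)
#' head(normalize_viability(plate))
#' @export
normalize_viability <- function(plate) {
  req <- c("cell_line", "setting", "conc_uM", "timepoint_h", "signal",
           "is_untreated")
  missing_cols <- setdiff(req, names(plate))
  if (length(missing_cols)) {
    stop("schema-mismatch: plate table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stratum <- interaction(plate$cell_line, plate$setting, plate$timepoint_h,
                         drop = TRUE)
  ctrl_mean <- tapply(plate$signal[plate$is_untreated],
                      stratum[plate$is_untreated], mean)
  missing_ctrl <- union(setdiff(levels(stratum), names(ctrl_mean)),
                        names(ctrl_mean)[is.na(ctrl_mean)])
  if (length(missing_ctrl)) {
    stop("missing-control: no untreated wells for stratum ",
         paste(missing_ctrl, collapse = "; "), call. = FALSE)
  }
  plate$viability_pct <-
    as.numeric(100 * plate$signal / ctrl_mean[as.character(stratum)])
  rownames(plate) <- NULL
  plate
}

#' Four-parameter logistic (Hill) viability model
#'
#' \deqn{V(c) = bottom + \frac{top - bottom}
#'   {1 + 10^{\,slope\,(\log_{10} c - \log_{10} IC_{50})}}}
#' The inhibitory parameterization: `slope > 0` gives viability decreasing
#' with concentration, and `V(IC50) = (top + bottom)/2`.
#'
#' @param conc_uM Concentration(s) in uM, > 0.
#' @param ic50 IC50 in uM.
#' @param slope Hill slope (> 0 for an inhibitor).
#' @param top,bottom Upper/lower viability asymptotes (%).
#' @return Viability in percent.
#' @export
hill_viability <- function(conc_uM, ic50, slope = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) /
    (1 + 10^(slope * (log10(conc_uM) - log10(ic50))))
}

#' Fit a dose-response (4PL) curve and estimate the IC50
#'
#' Least-squares fit of [hill_viability()] on log10 concentration to
#' well-level normalized viabilities at a single timepoint, via
#' bounded Gauss-Newton with box constraints (`slope > 0`,
#' `0 <= bottom <= top`), backed by a variable-projection profile search
#' over (slope, log10 IC50) in case the direct four-parameter pass fails
#' or stalls in a poor local optimum; the candidate with the lowest
#' residual sum of squares wins. `top` is initialized at 100 (the
#' untreated level) but not fixed, so incomplete kill at the top
#' concentration is tolerated; the IC50 is initialized where the observed
#' response crosses the midpoint.
#'
#' @param records A data.frame with columns `conc_uM` (> 0 rows are used)
#'   and `viability_pct`, typically one timepoint's slice of
#'   [normalize_viability()] output.
#' @param slope_init Starting Hill slope.
#' @return A `hill_fit` list: `ic50`, `hill_slope`, `top`, `bottom`,
#'   `rss`, `n_points`, `converged`.
#' @examples
#' conc <- rep(c(0.1, 1, 10, 100), each = 3)
#' rec <- data.frame(conc_uM = conc,
#'                   viability_pct = hill_viability(conc, ic50 = 5))
#' fit_dose_response(rec)$ic50
#' @export
fit_dose_response <- function(records, slope_init = 1) {
  d <- records[records$conc_uM > 0, , drop = FALSE]
  if (length(unique(d$conc_uM)) < 3L) {
    stop("insufficient-n: need >= 3 distinct positive concentrations",
         call. = FALSE)
  }
  v <- d$viability_pct
  if (stats::sd(v) < sqrt(.Machine$double.eps) * max(1, abs(mean(v)))) {
    stop("flat-response: all responses identical; no dose effect to fit",
         call. = FALSE)
  }
  lc <- log10(d$conc_uM)

  top0 <- 100
  bottom0 <- max(0, min(v))
  mid <- (top0 + bottom0) / 2
  mean_by_c <- tapply(v, lc, mean)
  lc_levels <- as.numeric(names(mean_by_c))
  below <- which(mean_by_c <= mid)
  lic50_0 <- if (length(below)) lc_levels[min(below)] else max(lc_levels)
  slope_lo <- 1e-3
  slope_hi <- 20
  lic50_lo <- min(lc) - 3
  lic50_hi <- max(lc) + 3

  bounds <- list(lower = c(top = 0, bottom = 0, slope = slope_lo,
                           lic50 = lic50_lo),
                 upper = c(top = Inf, bottom = Inf, slope = slope_hi,
                           lic50 = lic50_hi))
  candidates <- list()
  candidates$gn <- fit_4pl_port(lc, v,
                                list(top = top0, bottom = bottom0,
                                     slope = slope_init, lic50 = lic50_0),
                                bounds)
  vp <- fit_4pl_varpro(lc, v, slope_init, lic50_0,
                       c(slope_lo, slope_hi), c(lic50_lo, lic50_hi))
  candidates$vp <- vp
  if (!is.null(vp)) {
    # polish the profile solution with a bounded Gauss-Newton pass for
    # full numerical precision (the profile search alone stops near 1e-4)
    candidates$polished <- fit_4pl_port(lc, v,
                                        list(top = vp$top,
                                             bottom = max(vp$bottom, 1e-8),
                                             slope = vp$slope,
                                             lic50 = vp$lic50),
                                        bounds)
  }
  candidates <- Filter(function(x) !is.null(x) && is.finite(x$rss),
                       candidates)
  if (!length(candidates)) {
    return(structure(list(ic50 = NA_real_, hill_slope = NA_real_,
                          top = NA_real_, bottom = NA_real_, rss = NA_real_,
                          n_points = nrow(d), converged = FALSE),
                     class = "hill_fit"))
  }
  best <- candidates[[which.min(vapply(candidates, `[[`, 1, "rss"))]]
  structure(
    list(ic50 = 10^best$lic50, hill_slope = best$slope,
         top = best$top, bottom = best$bottom, rss = best$rss,
         n_points = nrow(d), converged = TRUE),
    class = "hill_fit"
  )
}

# Bounded Gauss-Newton (PORT) pass over all four 4PL parameters; returns
# NULL when the algorithm aborts or lands in the infeasible bottom > top
# corner, in which case another candidate route is used.
fit_4pl_port <- function(lc, v, start, bounds) {
  fit <- tryCatch(
    suppressWarnings(stats::nls(
      v ~ bottom + (top - bottom) / (1 + 10^(slope * (lc - lic50))),
      start = start, algorithm = "port",
      lower = bounds$lower, upper = bounds$upper,
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["bottom"]] > cf[["top"]]) return(NULL)
  list(top = cf[["top"]], bottom = cf[["bottom"]], slope = cf[["slope"]],
       lic50 = cf[["lic50"]], rss = sum(stats::resid(fit)^2))
}

# Variable-projection 4PL least squares: for fixed (slope, log10 IC50) the
# model is linear in (bottom, top) through v = bottom (1 - f) + top f with
# f = 1/(1 + 10^(slope (lc - lic50))), so the asymptotes are profiled out
# analytically (clipped to 0 <= bottom <= top) and a bounded quasi-Newton
# search runs over the two nonlinear parameters only.
fit_4pl_varpro <- function(lc, v, slope_init, lic50_init, slope_bounds,
                           lic50_bounds) {
  profile_fit <- function(par) {
    f <- 1 / (1 + 10^(par[1] * (lc - par[2])))
    co <- tryCatch(stats::lm.fit(cbind(1 - f, f), v)$coefficients,
                   error = function(e) c(NA_real_, NA_real_))
    bottom <- co[1]; top <- co[2]
    if (!all(is.finite(co)) || top < bottom) {
      bottom <- top <- mean(v)
    } else if (bottom < 0) {
      bottom <- 0
      top <- sum(v * f) / sum(f^2)
      if (!is.finite(top) || top < 0) top <- max(v)
    }
    list(bottom = bottom, top = top,
         rss = sum((v - bottom - (top - bottom) * f)^2))
  }
  starts <- list(c(slope_init, lic50_init),
                 c(1, stats::median(lc)),
                 c(2, stats::median(lc)))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, function(p) profile_fit(p)$rss, method = "L-BFGS-B",
                   lower = c(slope_bounds[1], lic50_bounds[1]),
                   upper = c(slope_bounds[2], lic50_bounds[2]),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) return(NULL)
  prof <- profile_fit(best$par)
  list(top = prof$top, bottom = prof$bottom, slope = best$par[1],
       lic50 = best$par[2], rss = prof$rss)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: IC50 = %.4g uM (slope %.3g, top %.3g%%, bottom %.3g%%)\n",
              x$ic50, x$hill_slope, x$top, x$bottom))
  cat(sprintf("  rss = %.4g over %d wells; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' IC50 fold change between two culture settings
#'
#' Ratio `ic50_a / ic50_b`; values above 1 mean setting `a` is less
#' sensitive to the drug (a higher concentration is needed for the same
#' inhibition), the typical direction for 3D scaffold cultures versus 2D
#' monolayers.
#'
#' @param fit_a,fit_b Converged [fit_dose_response()] results.
#' @param label_a,label_b Setting labels for the report.
#' @return A list `fold_change`, `label`, `ic50_a`, `ic50_b`.
#' @examples
#' a <- structure(list(ic50 = 11.58, converged = TRUE), class = "hill_fit")
#' b <- structure(list(ic50 = 1.3, converged = TRUE), class = "hill_fit")
#' compare_settings(a, b, "3DT", "2D")$fold_change
#' @export
compare_settings <- function(fit_a, fit_b, label_a = "a", label_b = "b") {
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("unusable-fit: both fits must have converged", call. = FALSE)
  }
  list(fold_change = fit_a$ic50 / fit_b$ic50,
       label = paste0(label_a, "/", label_b),
       ic50_a = fit_a$ic50, ic50_b = fit_b$ic50)
}

#' Per-concentration viability summary with cross-setting tests
#'
#' Mean +/- SEM viability per (setting, concentration, timepoint), plus
#' pairwise tests of each non-reference setting against the reference
#' setting at every positive concentration.
#'
#' @param normalized Output of [normalize_viability()].
#' @param reference Setting used as comparator (default `"2D"`).
#' @param parametric Passed to [two_group_test()].
#' @return A list with `summary` (data.frame `setting, conc_uM,
#'   timepoint_h, mean_viability_pct, sem_viability_pct, n`; SEM is `NA`
#'   for singleton cells) and `tests` (comparisons at each concentration
#'   and timepoint vs the reference, `NULL` when the reference is absent).
#' @export
viability_fold_change_table <- function(normalized, reference = "2D",
                                        parametric = TRUE) {
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg_key <- list(setting = normalized$setting, conc_uM = normalized$conc_uM,
                  timepoint_h = normalized$timepoint_h)
  summary <- do.call(rbind, lapply(
    split(normalized, agg_key, drop = TRUE),
    function(d) data.frame(setting = d$setting[1], conc_uM = d$conc_uM[1],
                           timepoint_h = d$timepoint_h[1],
                           mean_viability_pct = mean(d$viability_pct),
                           sem_viability_pct = sem(d$viability_pct),
                           n = nrow(d), stringsAsFactors = FALSE)
  ))
  summary <- summary[order(summary$timepoint_h, summary$conc_uM,
                           summary$setting), ]
  rownames(summary) <- NULL

  tests <- NULL
  settings <- setdiff(unique(normalized$setting), reference)
  if (reference %in% normalized$setting && length(settings)) {
    rows <- list()
    for (tp in unique(normalized$timepoint_h)) {
      for (cc in sort(unique(normalized$conc_uM[normalized$conc_uM > 0]))) {
        ref_v <- normalized$viability_pct[normalized$setting == reference &
                                            normalized$conc_uM == cc &
                                            normalized$timepoint_h == tp]
        for (s in settings) {
          v <- normalized$viability_pct[normalized$setting == s &
                                          normalized$conc_uM == cc &
                                          normalized$timepoint_h == tp]
          if (length(v) >= 3L && length(ref_v) >= 3L) {
            res <- two_group_test(v, ref_v, parametric = parametric,
                                  comparison = sprintf("%s vs %s @ %g uM, %g h",
                                                       s, reference, cc, tp))
            rows[[length(rows) + 1L]] <- data.frame(
              setting = s, conc_uM = cc, timepoint_h = tp,
              p = res$p_value, stars = res$stars, stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) tests <- do.call(rbind, rows)
  }
  list(summary = summary, tests = tests)
}
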