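#' Construct a filtration trace
#'
#' One sample's observed fluid-column descent: times `time_s` (strictly
#' increasing) and heights `height_mm` (strictly positive), with sample
#' identity, tissue group and repeat index.
#'
#' @param sample_id Sample identifier.
#' @param times Observation times (s), strictly increasing, length >= 3.
#' @param heights Observed column heights (mm), same length, all > 0.
#' @param group Tissue group; one of `"fresh"`, `"recellularized_3DT"`,
#'   `"decellularized"`, `"reference_material"`.
#' @param repeat_index Repeat number of the measurement on this sample.
#' @return A `filtration_trace`: a data.frame with columns `sample_id`,
#'   `group`, `repeat_index`, `time_s`, `height_mm`.
#' @export
filtration_trace <- function(sample_id, times, heights,
                             group = c("fresh", "recellularized_3DT",
                                       "decellularized", "reference_material"),
                             repeat_index = 1L) {
  group <- match.arg(group)
  times <- as.numeric(times)
  heights <- as.numeric(heights)
  if (length(times) != length(heights)) {
    stop("invalid-trace: times and heights must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("invalid-trace: a trace needs at least 3 observations", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("invalid-trace: times must be strictly increasing", call. = FALSE)
  }
  if (any(heights <= 0) || any(!is.finite(heights))) {
    stop("invalid-trace: heights must be strictly positive", call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(sample_id), group = group,
                    repeat_index = as.integer(repeat_index),
                    time_s = times, height_mm = heights,
                    stringsAsFactors = FALSE)
  class(out) <- c("filtration_trace", "data.frame")
  out
}

#' Restrict a trace to the analysis height window
#'
#' Keeps only the observations whose height lies in the closed window
#' `geom$window_mm` (boundaries included), preserving order. Heights above
#' the window (settling transients) and below it (late-time readings) are
#' both dropped before fitting.
#'
#' @param trace A [filtration_trace()].
#' @param geom A [device_geometry()] supplying the window.
#' @return The filtered trace (possibly with zero rows; downstream fitting
#'   raises on too few points).
#' @export
apply_window <- function(trace, geom = device_geometry()) {
  stopifnot(inherits(trace, "filtration_trace") || is.data.frame(trace))
  w <- geom$window_mm
  keep <- trace$height_mm >= w[1] & trace$height_mm <= w[2]
  out <- trace[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative-residual fitting objective for the filtration model
#'
#' \deqn{I(K) = \frac{1}{N} \sum_{i=1}^N \left[1 -
#'   \frac{H(t_i)}{H_{i,exp}}\right]^2}
#' the mean squared relative residual between the closed-form model height
#' and the observed height, computed over the in-window points only.
#'
#' @param trace A [filtration_trace()].
#' @param k Candidate permeability in mm^4/(N s).
#' @inheritParams decay_rate
#' @param t0 Clock origin for the model; defaults to the trace's first
#'   observation time.
#' @param windowed If `TRUE` (default), restrict to the analysis window
#'   first.
#' @return Non-negative scalar; zero iff the model reproduces every
#'   in-window observation exactly.
#' @export
filtration_objective <- function(trace, k, geom = device_geometry(),
                                 fluid = fluid_properties(),
                                 t0 = NULL, windowed = TRUE) {
  use <- if (windowed) apply_window(trace, geom) else trace
  if (nrow(use) == 0L) {
    stop("no-usable-points: no observations inside the analysis window",
         call. = FALSE)
  }
  if (is.null(t0)) t0 <- trace$time_s[1]
  h_model <- column_height(use$time_s, t0 = t0, k = k, geom = geom,
                           fluid = fluid)
  mean((1 - h_model / use$height_mm)^2)
}

#' Fit the permeability coefficient to an observed trace
#'
#' Estimates the single unknown \eqn{K} of the falling-head model by
#' minimizing [filtration_objective()] over \eqn{K \ge 0}. The initial
#' guess comes from ordinary least squares on \eqn{\ln H_i} vs \eqn{t_i}
#' (the log-slope is \eqn{-r}, and \eqn{K = r A_p \Delta x /(A_s \gamma)}),
#' then a bounded one-dimensional golden-section/parabolic search on
#' `[0, 100 * k_init]` refines it.
#'
#' A non-decaying trace (non-negative log-slope, e.g. an impermeable fresh
#' sample plus reading jitter) returns `k_hat = 0` with `converged = TRUE`
#' and a warning recorded on the estimate.
#'
#' @param trace A [filtration_trace()].
#' @inheritParams filtration_objective
#' @param rel_tol Relative convergence tolerance on K.
#' @return A `permeability_fit` list: `k_hat` (mm^4/(N s)),
#'   `objective_value`, `n_points_used`, `converged`, `window_applied`,
#'   `t0`, `warning` (character or `NA`), plus the trace identifiers.
#' @examples
#' tr <- gen_filtration_trace(k_true = 500, n_points = 40, noise_sd_rel = 0,
#'                            seed = 1)
#' fit_permeability(tr)$k_hat
#' @export
fit_permeability <- function(trace, geom = device_geometry(),
                             fluid = fluid_properties(), t0 = NULL,
                             rel_tol = 1e-10) {
  use <- apply_window(trace, geom)
  if (nrow(use) < 3L) {
    stop("no-usable-points: need at least 3 in-window observations",
         call. = FALSE)
  }
  if (is.null(t0)) t0 <- trace$time_s[1]

  slope <- stats::coef(stats::lm(log(height_mm) ~ time_s, data = use))[["time_s"]]
  warn <- NA_character_
  if (slope >= -1e-12) {  # flat within floating-point jitter, or rising
    k_hat <- 0
    warn <- "non-decaying trace: log-slope >= 0, permeability clamped to 0"
    obj <- filtration_objective(trace, 0, geom, fluid, t0 = t0)
    converged <- TRUE
  } else {
    rate_init <- -slope
    k_init <- rate_init * geom$pipette_area_mm2 * geom$sample_thickness_mm /
      (geom$sample_area_mm2 * fluid$specific_weight_N_mm3)
    opt <- stats::optimize(
      function(k) filtration_objective(trace, k, geom, fluid, t0 = t0),
      interval = c(0, 100 * k_init),
      tol = max(rel_tol * k_init, .Machine$double.eps)
    )
    k_hat <- opt$minimum
    obj <- opt$objective
    converged <- TRUE
  }
  structure(
    list(sample_id = trace$sample_id[1], group = trace$group[1],
         repeat_index = trace$repeat_index[1],
         k_hat = k_hat, objective_value = obj, n_points_used = nrow(use),
         converged = converged, window_applied = geom$window_mm, t0 = t0,
         warning = warn),
    class = "permeability_fit"
  )
}

#' @export
print.permeability_fit <- function(x, ...) {
  cat(sprintf("Permeability fit: sample %s (%s, repeat %d)\n",
              x$sample_id, x$group, x$repeat_index))
  cat(sprintf("  K = %.6g mm^4/(N s); objective I = %.3g; %d points in [%g, %g] mm\n",
              x$k_hat, x$objective_value, x$n_points_used,
              x$window_applied[1], x$window_applied[2]))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Fit permeability for every (sample, repeat) trace in a table
#'
#' @param traces A data.frame of stacked traces with columns `sample_id`,
#'   `group`, `repeat_index` (or `repeat`), `time_s`, `height_mm`, e.g. as
#'   read by [read_traces()].
#' @inheritParams fit_permeability
#' @return A data.frame with one row per (sample, repeat):
#'   `sample_id, group, repeat_index, k_mm4_per_Ns, objective, n_points,
#'   converged`.
#' @export
fit_permeability_table <- function(traces, geom = device_geometry(),
                                   fluid = fluid_properties()) {
  if ("repeat" %in% names(traces) && !"repeat_index" %in% names(traces)) {
    names(traces)[names(traces) == "repeat"] <- "repeat_index"
  }
  key <- interaction(traces$sample_id, traces$repeat_index, drop = TRUE)
  fits <- lapply(split(traces, key), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    tr <- filtration_trace(d$sample_id[1], d$time_s, d$height_mm,
                           group = d$group[1],
                           repeat_index = d$repeat_index[1])
    f <- fit_permeability(tr, geom, fluid)
    data.frame(sample_id = f$sample_id, group = f$group,
               repeat_index = f$repeat_index, k_mm4_per_Ns = f$k_hat,
               objective = f$objective_value, n_points = f$n_points_used,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out[order(out$sample_id, out$repeat_index), , drop = FALSE]
}

#' Reliability summary over repeated permeability measurements
#'
#' Summarizes repeat-level estimates per sample (mean, sd, coefficient of
#' variation of K) and across samples, mirroring a reference-material
#' protocol of repeated measurements on the same sample and measurements
#' across several samples of the same material.
#'
#' @param estimates A data.frame with columns `sample_id` and
#'   `k_mm4_per_Ns` (one row per repeat), e.g. from
#'   [fit_permeability_table()].
#' @return A list of class `reliability_summary` with `per_sample` (columns
#'   `sample_id, n_repeats, mean_k, sd_k, cv`), `n_samples`,
#'   `across_sample_mean_k`, `across_sample_sd_k`, `across_sample_cv`.
#' @export
reliability_summary <- function(estimates) {
  sp <- split(estimates$k_mm4_per_Ns, estimates$sample_id)
  if (any(vapply(sp, length, 1L) < 2L)) {
    stop("insufficient-repeats: every sample needs >= 2 repeats", call. = FALSE)
  }
  per_sample <- do.call(rbind, lapply(names(sp), function(s) {
    ks <- sp[[s]]
    data.frame(sample_id = s, n_repeats = length(ks), mean_k = mean(ks),
               sd_k = stats::sd(ks),
               cv = if (mean(ks) > 0) stats::sd(ks) / mean(ks) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  sample_means <- per_sample$mean_k
  structure(
    list(per_sample = per_sample,
         n_samples = nrow(per_sample),
         across_sample_mean_k = mean(sample_means),
         across_sample_sd_k = stats::sd(sample_means),
         across_sample_cv = if (mean(sample_means) > 0)
           stats::sd(sample_means) / mean(sample_means) else 0),
    class = "reliability_summary"
  )
}

#' @export
print.reliability_summary <- function(x, ...) {
  cat(sprintf("Reliability over %d samples (%d repeats each on average)\n",
              x$n_samples, round(mean(x$per_sample$n_repeats))))
  cat(sprintf("  per-sample CV of K: %s\n",
              paste(sprintf("%.3g", x$per_sample$cv), collapse = ", ")))
  cat(sprintf("  across-sample mean K = %.6g, sd = %.3g, CV = %.3g\n",
              x$across_sample_mean_k, x$across_sample_sd_k,
              x$across_sample_cv))
  invisible(x)
}

#' Compare permeability between tissue groups
#'
#' Pairwise group comparisons of per-sample permeability estimates (repeats
#' averaged first), by default with the Mann-Whitney test, reporting group
#' medians and significance stars.
#'
#' @param estimates A data.frame with columns `sample_id`, `group`,
#'   `k_mm4_per_Ns`.
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @return A data.frame with one row per group pair: `group_a, group_b,
#'   median_a, median_b, n_a, n_b, method, statistic, p, stars`.
#' @export
compare_permeability_groups <- function(estimates,
                                        method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  per_sample <- stats::aggregate(k_mm4_per_Ns ~ sample_id + group,
                                 data = estimates, FUN = mean)
  groups <- split(per_sample$k_mm4_per_Ns, per_sample$group)
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L) {
    stop("insufficient-n: need at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 3L)) {
    stop("insufficient-n: every group needs >= 3 estimates", call. = FALSE)
  }
  pairs <- utils::combn(names(groups), 2L)
  out <- do.call(rbind, apply(pairs, 2L, function(gp) {
    a <- groups[[gp[1]]]; b <- groups[[gp[2]]]
    res <- two_group_test(a, b, parametric = (method == "t_test"),
                          comparison = paste(gp[1], "vs", gp[2]))
    data.frame(group_a = gp[1], group_b = gp[2],
               median_a = stats::median(a), median_b = stats::median(b),
               n_a = length(a), n_b = length(b),
               method = res$method, statistic = res$statistic, p = res$p_value,
               stars = res$stars, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
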