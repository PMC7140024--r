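#' Simulate a falling-head filtration trace
#'
#' Generates observation times spanning the descent across the analysis
#' window (via [time_to_height()]) and heights on the closed-form decay
#' curve, each multiplied by `1 + eps` with
#' `eps ~ Normal(0, noise_sd_rel)` — multiplicative noise, mimicking
#' constant relative reading precision on a graduated pipette. With
#' `k_true = 0` the column never moves and a fixed 10-minute grid is used.
#'
#' All generators in the package are seed-deterministic: the same
#' arguments and seed give bit-identical output.
#'
#' @param k_true True permeability in mm^4/(N s).
#' @param geom,fluid Device and fluid (defaults as in [device_geometry()]).
#' @param n_points Number of observations.
#' @param noise_sd_rel Relative sd of the multiplicative height noise.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param sample_id,group,repeat_index Trace identity fields.
#' @return A [filtration_trace()].
#' @examples
#' tr <- gen_filtration_trace(1000, n_points = 10, noise_sd_rel = 0.01,
#'                            seed = 42)
#' @export
gen_filtration_trace <- function(k_true, geom = device_geometry(),
                                 fluid = fluid_properties(), n_points = 50,
                                 noise_sd_rel = 0.01, seed = NULL,
                                 sample_id = "synthetic",
                                 group = "reference_material",
                                 repeat_index = 1L) {
  check_permeability(k_true)
  stopifnot(noise_sd_rel >= 0, n_points >= 3)
  if (!is.null(seed)) set.seed(seed)
  t_end <- if (k_true > 0) {
    time_to_height(geom$window_mm[1], k_true, geom, fluid, t0 = 0)
  } else {
    600
  }
  times <- seq(0, t_end, length.out = n_points)
  h_model <- column_height(times, t0 = 0, k = k_true, geom = geom,
                           fluid = fluid)
  eps <- if (noise_sd_rel > 0) stats::rnorm(n_points, 0, noise_sd_rel) else
    numeric(n_points)
  filtration_trace(sample_id, times, h_model * (1 + eps), group = group,
                   repeat_index = repeat_index)
}

#' Simulate permeability traces for the tissue-group comparison
#'
#' Draws per-sample true permeabilities from log-normal distributions with
#' the given group medians (default ordering
#' fresh < recellularized_3DT < decellularized) and renders each as a
#' noisy filtration trace. The default medians are synthetic magnitudes
#' chosen so a descent completes within minutes of simulated time.
#'
#' @param median_by_group Named vector of group median K (mm^4/(N s)).
#' @param log_sd sd of log K within each group (sdlog of the log-normal).
#' @param n_per_group Samples per group (8 matches a reference-material
#'   protocol of eight samples).
#' @param n_points,noise_sd_rel Per-trace acquisition settings.
#' @param seed Integer seed.
#' @return A list with `traces` (stacked trace data.frame) and `truth`
#'   (`sample_id, group, k_true`).
#' @export
gen_group_permeabilities <- function(median_by_group = c(
                                       fresh = 50,
                                       recellularized_3DT = 500,
                                       decellularized = 2000),
                                     log_sd = 0.5, n_per_group = 8,
                                     n_points = 50, noise_sd_rel = 0.01,
                                     seed = 1L) {
  stopifnot(all(median_by_group > 0), log_sd >= 0)
  set.seed(seed)
  traces <- list(); truth <- list()
  for (g in names(median_by_group)) {
    k_true <- stats::rlnorm(n_per_group, meanlog = log(median_by_group[[g]]),
                            sdlog = log_sd)
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      tr <- gen_filtration_trace(k_true[i], n_points = n_points,
                                 noise_sd_rel = noise_sd_rel, seed = NULL,
                                 sample_id = sid, group = g)
      traces[[sid]] <- tr
      truth[[sid]] <- data.frame(sample_id = sid, group = g,
                                 k_true = k_true[i], stringsAsFactors = FALSE)
    }
  }
  out_tr <- do.call(rbind, traces)
  rownames(out_tr) <- NULL
  out_truth <- do.call(rbind, truth)
  rownames(out_truth) <- NULL
  list(traces = out_tr, truth = out_truth)
}

#' Simulate the reliability protocol: repeats x samples
#'
#' Repeated noisy measurements of the same reference material: `n_samples`
#' samples sharing one true K, each measured `n_repeats` times.
#'
#' @param k_true Reference-material permeability (mm^4/(N s)).
#' @param n_repeats Repeats per sample (the protocol uses 5).
#' @param n_samples Number of samples (the protocol uses 8).
#' @inheritParams gen_filtration_trace
#' @return A stacked trace data.frame.
#' @export
gen_reliability_traces <- function(k_true = 1000, n_repeats = 5,
                                   n_samples = 8, n_points = 50,
                                   noise_sd_rel = 0.01, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_samples)) {
    for (r in seq_len(n_repeats)) {
      out[[length(out) + 1L]] <- gen_filtration_trace(
        k_true, n_points = n_points, noise_sd_rel = noise_sd_rel,
        seed = NULL, sample_id = sprintf("ref_%02d", s),
        group = "reference_material", repeat_index = r)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a plate-reader dose-response dataset
#'
#' Well-level signals on a log-spaced concentration grid plus untreated
#' wells. Treated signals follow [hill_viability()] scaled to the control
#' level; all wells get additive Gaussian noise expressed in percentage
#' points of the control level.
#'
#' @param ic50_true True IC50 (uM).
#' @param hill,top,bottom True curve parameters (viability %).
#' @param conc_grid Positive concentrations (uM); default
#'   `c(0.1, 1, 10, 100)`.
#' @param n_reps Replicate wells per concentration (and untreated wells).
#' @param noise_sd_pp Noise sd in percentage points.
#' @param control_level Raw-signal level of untreated wells (arbitrary
#'   units), so normalization is a real operation on the output.
#' @param cell_line,setting,drug,timepoint_h Metadata for the records.
#' @param seed Integer seed.
#' @return A plate data.frame in the [read_plate()] schema.
#' @export
gen_dose_response <- function(ic50_true, hill = 1, top = 100, bottom = 0,
                              conc_grid = c(0.1, 1, 10, 100), n_reps = 3,
                              noise_sd_pp = 5, control_level = 1000,
                              cell_line = "HT29", setting = "2D",
                              drug = "5FU", timepoint_h = 72, seed = NULL) {
  stopifnot(all(conc_grid > 0), length(conc_grid) >= 2L, noise_sd_pp >= 0)
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(conc_grid, each = n_reps)
  v_true <- hill_viability(conc, ic50_true, hill, top, bottom)
  n_tr <- length(conc)
  noise <- function(n) if (noise_sd_pp > 0)
    stats::rnorm(n, 0, noise_sd_pp / 100 * control_level) else numeric(n)
  treated <- data.frame(
    cell_line = cell_line, setting = setting, drug = drug, conc_uM = conc,
    timepoint_h = timepoint_h, replicate = rep(seq_len(n_reps),
                                               times = length(conc_grid)),
    signal = v_true / 100 * control_level + noise(n_tr),
    is_untreated = FALSE, stringsAsFactors = FALSE)
  untreated <- data.frame(
    cell_line = cell_line, setting = setting, drug = drug, conc_uM = 0,
    timepoint_h = timepoint_h, replicate = seq_len(n_reps),
    signal = control_level + noise(n_reps),
    is_untreated = TRUE, stringsAsFactors = FALSE)
  rbind(untreated, treated)
}

#' Simulate a marker count table
#'
#' Binomial positives per image: each image scores `n_nuclei` nuclei, each
#' positive with its condition's probability.
#'
#' @param p_by_condition Named vector of positive-cell probabilities.
#' @param n_nuclei Nuclei per image.
#' @param n_images Images per condition.
#' @param marker Marker label.
#' @param seed Integer seed.
#' @return A counts data.frame in the [read_counts()] schema.
#' @export
gen_count_table <- function(p_by_condition = c(`3DT` = 0.75), n_nuclei = 400,
                            n_images = 10, marker = "Ki67", seed = 1L) {
  stopifnot(all(p_by_condition >= 0), all(p_by_condition <= 1))
  set.seed(seed)
  out <- do.call(rbind, lapply(names(p_by_condition), function(cond) {
    data.frame(marker = marker, condition = cond,
               image_id = sprintf("%s_img%02d", cond, seq_len(n_images)),
               positive = stats::rbinom(n_images, n_nuclei,
                                        p_by_condition[[cond]]),
               total = n_nuclei, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a zebrafish xenograft cohort
#'
#' Per-embryo records: injected cell counts `cells_2h ~ Poisson(mean_cells)`
#' (about 200 cells are implanted per embryo), a caudal fluorescence time
#' course with an arm-specific multiplicative decline per 24 h (log-normal
#' noise), and a 72 h retention flag drawn with an arm-specific
#' probability.
#'
#' @param n_per_arm Embryos per treatment arm (at least 50 per group in
#'   the emulated design).
#' @param mean_cells Mean injected cell count.
#' @param retention_by_arm Named vector: probability an embryo still
#'   carries cells at 72 h.
#' @param decline_by_arm Named vector: per-24 h multiplicative fluorescence
#'   factor (1 = stable, < 1 = signal loss).
#' @param noise_sd_log sd of the log-normal multiplicative noise per step.
#' @param f0_mean Mean baseline fluorescence (arbitrary units).
#' @param seed Integer seed.
#' @return An embryo data.frame in the [read_embryos()] schema.
#' @export
gen_embryo_cohort <- function(n_per_arm = 50, mean_cells = 200,
                              retention_by_arm = c(DMSO = 0.6, IC50_2D = 0.6,
                                                   IC50_3D = 0.5),
                              decline_by_arm = c(DMSO = 0.95, IC50_2D = 0.85,
                                                 IC50_3D = 0.6),
                              noise_sd_log = 0.1, f0_mean = 1000, seed = 1L) {
  stopifnot(identical(sort(names(retention_by_arm)),
                      sort(names(decline_by_arm))))
  set.seed(seed)
  out <- do.call(rbind, lapply(names(decline_by_arm), function(arm) {
    n <- n_per_arm
    cells <- stats::rpois(n, mean_cells)
    f0 <- stats::rlnorm(n, log(f0_mean), 0.2)
    step <- function(f) f * decline_by_arm[[arm]] *
      stats::rlnorm(n, 0, noise_sd_log)
    f24 <- step(f0); f48 <- step(f24); f72 <- step(f48)
    data.frame(embryo_id = sprintf("%s_e%03d", arm, seq_len(n)), arm = arm,
               cells_2h = cells, f0 = f0, f24 = f24, f48 = f48, f72 = f72,
               retained_at_72h = stats::runif(n) < retention_by_arm[[arm]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
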