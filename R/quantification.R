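#' Percent-positive summary of marker count tables
#'
#' Per-image percentage `100 * positive / total`, summarized per
#' (marker, condition) group as mean and sd across images. The dispersion
#' is the standard deviation across images, labeled as such in the output.
#'
#' @param counts A data.frame with columns `marker, condition, image_id,
#'   positive, total` (`positive <= total`, `total > 0`).
#' @return A data.frame `marker, condition, n_images, mean_pct, sd_pct`.
#' @examples
#' counts <- gen_count_table(p_by_condition = c(`3DT` = 0.75), seed = 1)
#' percent_positive(counts)
#' @export
percent_positive <- function(counts) {
  if (any(counts$total <= 0)) {
    stop("empty-image: total count must be positive", call. = FALSE)
  }
  if (any(counts$positive < 0) || any(counts$positive > counts$total)) {
    stop("invalid-counts: need 0 <= positive <= total", call. = FALSE)
  }
  counts$pct <- 100 * counts$positive / counts$total
  out <- do.call(rbind, lapply(
    split(counts, list(marker = counts$marker, condition = counts$condition),
          drop = TRUE),
    function(d) data.frame(marker = d$marker[1], condition = d$condition[1],
                           n_images = nrow(d), mean_pct = mean(d$pct),
                           sd_pct = if (nrow(d) > 1L) stats::sd(d$pct) else NA_real_,
                           stringsAsFactors = FALSE)
  ))
  rownames(out) <- NULL
  out[order(out$marker, out$condition), , drop = FALSE]
}

#' Co-localization percentage
#'
#' Percentage of cells co-localized with the drug signal:
#' `100 * colocalized / cells`.
#'
#' @param colocalized_count Number of co-localized events.
#' @param cell_count Total number of cells scored (> 0).
#' @return Percentage.
#' @examples
#' colocalization_percent(130, 200)  # 65
#' @export
colocalization_percent <- function(colocalized_count, cell_count) {
  if (any(cell_count <= 0)) stop("empty-image: cell count must be > 0",
                                 call. = FALSE)
  100 * colocalized_count / cell_count
}

#' Apply the xenograft cohort inclusion filters
#'
#' Two rules emulating a zebrafish xenotransplantation analysis protocol:
#' \enumerate{
#'   \item Embryos with fewer than 100 cells at 2 h post-injection are
#'     discarded (`cells_2h = 100` exactly is retained: the rule is a
#'     strict "less than").
#'   \item The 72 h timepoint is dropped from analysis when fewer than 50%
#'     of retained untreated (DMSO) embryos still carry cells at 72 h.
#' }
#'
#' @param embryos A data.frame with columns `embryo_id, arm, cells_2h, f0,
#'   f24, f48, f72, retained_at_72h` (the schema of [read_embryos()]).
#' @param control_arm Label of the untreated arm (default `"DMSO"`).
#' @return A list with `retained` (surviving rows), `exclusion_log`
#'   (`embryo_id, arm, rule, detail`; one row per removed embryo, so
#'   retained + logged rows equal input rows), `analysis_timepoints_h`
#'   (the timepoints kept), and `untreated_retention_72h` (the fraction
#'   driving rule 2, `NA` without untreated embryos).
#' @export
filter_embryo_cohort <- function(embryos, control_arm = "DMSO") {
  if (nrow(embryos) == 0L) stop("empty-cohort: no embryo records", call. = FALSE)
  low <- embryos$cells_2h < 100
  exclusion_log <- data.frame(
    embryo_id = embryos$embryo_id[low], arm = embryos$arm[low],
    rule = rep("cells_2h_lt_100", sum(low)),
    detail = sprintf("%d cells at 2 h post-injection", embryos$cells_2h[low]),
    stringsAsFactors = FALSE)
  retained <- embryos[!low, , drop = FALSE]
  rownames(retained) <- NULL

  timepoints <- c(0, 24, 48, 72)
  ctrl <- retained[retained$arm == control_arm, , drop = FALSE]
  retention <- if (nrow(ctrl)) mean(ctrl$retained_at_72h) else NA_real_
  if (!is.na(retention) && retention < 0.5) timepoints <- c(0, 24, 48)

  list(retained = retained, exclusion_log = exclusion_log,
       analysis_timepoints_h = timepoints,
       untreated_retention_72h = retention)
}

#' Fluorescence fold change of an injected embryo
#'
#' Caudal-region fluorescence at a treatment timepoint divided by the
#' pre-treatment (time 0) signal of the same embryo.
#'
#' @param record One embryo row (with columns `f0` and `f<timepoint>`).
#' @param timepoint_h Timepoint in hours (24, 48 or 72).
#' @return Dimensionless fold change.
#' @examples
#' fluorescence_fold_change(data.frame(f0 = 100, f24 = 50), 24)  # 0.5
#' @export
fluorescence_fold_change <- function(record, timepoint_h) {
  col <- paste0("f", timepoint_h)
  if (!col %in% names(record) || any(is.na(record[[col]]))) {
    stop("missing-measurement: no fluorescence value at ", timepoint_h, " h",
         call. = FALSE)
  }
  if (any(record$f0 <= 0)) {
    stop("invalid-baseline: fluorescence at time 0 must be > 0", call. = FALSE)
  }
  record[[col]] / record$f0
}

#' Per-arm fluorescence fold-change comparison
#'
#' Computes every retained embryo's fold change at a timepoint and tests
#' each treated arm against the control arm.
#'
#' @param filtered Output of [filter_embryo_cohort()].
#' @param timepoint_h Timepoint (must be in `analysis_timepoints_h`).
#' @param control_arm Control arm label.
#' @param parametric Passed to [two_group_test()].
#' @return A list with `fold_changes` (`embryo_id, arm, fold_change`) and
#'   `tests` (comparisons table rows vs control).
#' @export
embryo_fold_change_analysis <- function(filtered, timepoint_h = 48,
                                        control_arm = "DMSO",
                                        parametric = FALSE) {
  if (!timepoint_h %in% filtered$analysis_timepoints_h) {
    stop("missing-measurement: timepoint ", timepoint_h,
         " h was dropped by the cohort filters", call. = FALSE)
  }
  ret <- filtered$retained
  fc <- data.frame(embryo_id = ret$embryo_id, arm = ret$arm,
                   fold_change = fluorescence_fold_change(ret, timepoint_h),
                   stringsAsFactors = FALSE)
  arms <- setdiff(unique(fc$arm), control_arm)
  tests <- do.call(rbind, lapply(arms, function(a) {
    res <- two_group_test(fc$fold_change[fc$arm == a],
                          fc$fold_change[fc$arm == control_arm],
                          parametric = parametric,
                          comparison = sprintf("%s vs %s @ %g h", a,
                                               control_arm, timepoint_h))
    comparisons_table(res)
  }))
  list(fold_changes = fc, tests = tests)
}
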