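read_checked_csv <- function(path, required, label) {
  if (!file.exists(path)) {
    stop("empty-file: ", label, " file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0L) stop("empty-file: ", label, " table has no rows: ", path,
                          call. = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("schema-mismatch: ", label, " table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

check_numeric_col <- function(d, cols, label) {
  for (col in cols) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("unit-mismatch: non-numeric values in ", label, " column '", col,
           "' at data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  d
}

#' Read tabular pipeline inputs
#'
#' CSV readers for the four input kinds, with header and type checks.
#' Schemas (all headers required, UTF-8, "." decimal):
#' \describe{
#'   \item{traces}{`sample_id, group, repeat, time_s, height_mm`}
#'   \item{plate}{`cell_line, setting, drug, conc_uM, timepoint_h,
#'     replicate, signal, is_untreated`}
#'   \item{counts}{`marker, condition, image_id, positive, total`}
#'   \item{embryos}{`embryo_id, arm, cells_2h, f0, f24, f48, f72,
#'     retained_at_72h`}
#' }
#'
#' @param path Path to the CSV file.
#' @return A typed data.frame (traces get column `repeat_index`).
#' @export
read_traces <- function(path) {
  d <- read_checked_csv(path, c("sample_id", "group", "repeat", "time_s",
                                "height_mm"), "traces")
  d <- check_numeric_col(d, c("time_s", "height_mm"), "traces")
  names(d)[names(d) == "repeat"] <- "repeat_index"
  d$repeat_index <- as.integer(d$repeat_index)
  d
}

#' @rdname read_traces
#' @export
read_plate <- function(path) {
  d <- read_checked_csv(path, c("cell_line", "setting", "drug", "conc_uM",
                                "timepoint_h", "replicate", "signal",
                                "is_untreated"), "plate")
  d <- check_numeric_col(d, c("conc_uM", "timepoint_h", "signal"), "plate")
  d$is_untreated <- as.logical(d$is_untreated)
  d
}

#' @rdname read_traces
#' @export
read_counts <- function(path) {
  d <- read_checked_csv(path, c("marker", "condition", "image_id", "positive",
                                "total"), "counts")
  check_numeric_col(d, c("positive", "total"), "counts")
}

#' @rdname read_traces
#' @export
read_embryos <- function(path) {
  d <- read_checked_csv(path, c("embryo_id", "arm", "cells_2h", "f0", "f24",
                                "f48", "f72", "retained_at_72h"), "embryos")
  d <- check_numeric_col(d, c("cells_2h", "f0", "f24", "f48", "f72"),
                         "embryos")
  d$retained_at_72h <- as.logical(d$retained_at_72h)
  d
}

#' Write a pipeline table as CSV
#'
#' Thin wrapper fixing the conventions every table in the package uses
#' (header row, no row names, "." decimal). Traces are written with the
#' on-disk column name `repeat`.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(x, path) {
  names(x)[names(x) == "repeat_index"] <- "repeat"
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis on a set of inputs
#'
#' Orchestrates the four stages on whatever inputs the config provides —
#' permeability fitting plus group comparison, viability normalization
#' plus IC50 fitting and 3D/2D fold change, marker quantification, embryo
#' filtering plus fold-change tests — writes one CSV per stage plus a JSON
#' summary and a run manifest (input file MD5 hashes, seed, config) to the
#' output directory, and returns the summary.
#'
#' @param config A list (or path to a JSON file) with optional elements
#'   `traces_csv`, `plate_csv`, `counts_csv`, `embryos_csv`, `device`
#'   (geometry overrides), `fluid`, `timepoint_h` (IC50 analysis
#'   timepoint, default 72), `reference_setting` (default `"2D"`),
#'   `parametric_viability` (default `TRUE`), `out_dir` and `seed`.
#' @param out_dir Output directory (overrides the config's).
#' @return The summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- c("traces_csv", "plate_csv", "counts_csv", "embryos_csv", "device",
             "fluid", "timepoint_h", "reference_setting",
             "parametric_viability", "out_dir", "seed")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("schema-mismatch: unknown config keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("empty-file: no output directory configured",
                             call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  geom <- do.call(device_geometry, as.list(config$device))
  fluid <- do.call(fluid_properties, as.list(config$fluid))
  tp <- if (is.null(config$timepoint_h)) 72 else config$timepoint_h
  ref <- if (is.null(config$reference_setting)) "2D" else
    config$reference_setting
  parametric <- if (is.null(config$parametric_viability)) TRUE else
    config$parametric_viability

  summary <- list()
  inputs <- unlist(config[intersect(names(config),
                                    c("traces_csv", "plate_csv",
                                      "counts_csv", "embryos_csv"))],
                   use.names = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!is.null(config$traces_csv)) {
    summary$permeability <- stage("permeability", {
      traces <- read_traces(config$traces_csv)
      fits <- fit_permeability_table(traces, geom, fluid)
      write_pipeline_csv(fits, file.path(out_dir, "k_estimates.csv"))
      per_sample <- stats::aggregate(k_mm4_per_Ns ~ sample_id + group,
                                     data = fits, FUN = mean)
      medians <- stats::aggregate(k_mm4_per_Ns ~ group, data = per_sample,
                                  FUN = stats::median)
      groups_ok <- length(unique(fits$group)) >= 2L &&
        all(table(per_sample$group) >= 3L)
      comp <- if (groups_ok) compare_permeability_groups(fits) else NULL
      if (!is.null(comp)) {
        write_pipeline_csv(comp, file.path(out_dir, "k_group_tests.csv"))
      }
      list(median_k_by_group = stats::setNames(as.list(medians$k_mm4_per_Ns),
                                               medians$group),
           n_fits = nrow(fits), tests = comp)
    })
  }

  if (!is.null(config$plate_csv)) {
    summary$chemosensitivity <- stage("chemosensitivity", {
      plate <- read_plate(config$plate_csv)
      norm <- normalize_viability(plate)
      tab <- viability_fold_change_table(norm, reference = ref,
                                         parametric = parametric)
      write_pipeline_csv(tab$summary, file.path(out_dir,
                                                "viability_summary.csv"))
      sl <- norm[norm$timepoint_h == tp, , drop = FALSE]
      fits <- lapply(split(sl, list(sl$cell_line, sl$drug, sl$setting),
                           drop = TRUE),
                     function(d) {
                       f <- fit_dose_response(d)
                       data.frame(cell_line = d$cell_line[1],
                                  drug = d$drug[1], setting = d$setting[1],
                                  ic50_uM = f$ic50, hill_slope = f$hill_slope,
                                  top = f$top, bottom = f$bottom,
                                  converged = f$converged,
                                  stringsAsFactors = FALSE)
                     })
      ic50 <- do.call(rbind, fits)
      rownames(ic50) <- NULL
      write_pipeline_csv(ic50, file.path(out_dir, "ic50.csv"))
      folds <- NULL
      for (key in unique(paste(ic50$cell_line, ic50$drug))) {
        sub <- ic50[paste(ic50$cell_line, ic50$drug) == key, ]
        if (ref %in% sub$setting) {
          others <- setdiff(sub$setting, ref)
          for (s in others) {
            folds <- rbind(folds, data.frame(
              cell_line = sub$cell_line[1], drug = sub$drug[1],
              comparison = paste0(s, "/", ref),
              fold_change = sub$ic50_uM[sub$setting == s] /
                sub$ic50_uM[sub$setting == ref],
              stringsAsFactors = FALSE))
          }
        }
      }
      list(ic50 = ic50, fold_changes = folds, timepoint_h = tp)
    })
  }

  if (!is.null(config$counts_csv)) {
    summary$quantification <- stage("quantification", {
      counts <- read_counts(config$counts_csv)
      pct <- percent_positive(counts)
      write_pipeline_csv(pct, file.path(out_dir, "marker_percentages.csv"))
      list(marker_percentages = pct)
    })
  }

  if (!is.null(config$embryos_csv)) {
    summary$embryos <- stage("embryos", {
      emb <- read_embryos(config$embryos_csv)
      filt <- filter_embryo_cohort(emb)
      write_pipeline_csv(filt$exclusion_log,
                         file.path(out_dir, "embryo_exclusions.csv"))
      tp48 <- if (48 %in% filt$analysis_timepoints_h) {
        embryo_fold_change_analysis(filt, timepoint_h = 48)
      } else NULL
      list(n_input = nrow(emb), n_retained = nrow(filt$retained),
           n_excluded = nrow(filt$exclusion_log),
           analysis_timepoints_h = filt$analysis_timepoints_h,
           untreated_retention_72h = filt$untreated_retention_72h,
           fold_change_tests = if (!is.null(tp48)) tp48$tests else NULL)
    })
  }

  if (!length(summary)) {
    stop("empty-file: config provides no input tables", call. = FALSE)
  }

  manifest <- list(
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(f) unname(tools::md5sum(f))),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    package_version = as.character(utils::packageVersion("scaffoldperm")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(summary)
}
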