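#' Run the SPECT quantification pipeline from a config file
#'
#' Config-driven front end tying the modules together. The YAML/JSON config
#' holds:
#'
#' ```yaml
#' early_volume: early.nii.gz
#' delayed_volume: delayed.nii.gz
#' early_time_h: 0.25        # optional, else sidecar/default
#' delayed_time_h: 4.0
#' half_life_h: 13.2235
#' study_id: patient01
#' vois:
#'   heart: {shape: ellipsoid, center_mm: [165, 215, 115], semi_axes_mm: [52, 52, 47]}
#'   lumen: {shape: ellipsoid, center_mm: [165, 215, 115], semi_axes_mm: [13.4, 13.4, 13.4]}
#'   mediastinum: {shape: box, center_mm: [165, 215, 185], edge_mm: [22, 22, 22]}
#'   lung: {shape: box, center_mm: [280, 200, 120], edge_mm: [22, 22, 22]}
#'   liver: {shape: box, center_mm: [230, 230, 30], edge_mm: [22, 22, 22]}
#' ```
#'
#' Writes `report.csv` (one row, see [report_row()]), QC mask NIfTIs for every
#' VOI, and `quantify.log` collecting warnings (box-size violations, clipped
#' VOIs, undefined washout rates). Warnings never change the exit status;
#' errors abort.
#'
#' @param config Path to a YAML/JSON config, or an equivalent named list.
#' @param output_dir Output directory (created if absent).
#' @return Invisibly, the one-row report `data.frame`.
#' @export
run_quantify <- function(config, output_dir) {
  cfg <- load_config(config)
  for (key in c("early_volume", "delayed_volume"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config is missing '%s'", key), call. = FALSE)
  if (is.null(cfg$vois)) stop("config is missing 'vois'", call. = FALSE)
  vois <- if (is.character(cfg$vois)) read_voi_config(cfg$vois)
          else parse_voi_list(cfg$vois)
  for (req in c("heart", "lumen", "mediastinum"))
    if (is.null(vois[[req]]))
      stop(sprintf("required VOI missing: %s", req), call. = FALSE)

  early <- read_volume(cfg$early_volume, acquisition_time_h = cfg$early_time_h,
                       label = "early")
  delayed <- read_volume(cfg$delayed_volume,
                         acquisition_time_h = cfg$delayed_time_h,
                         label = "delayed")
  pair <- study_pair(early, delayed,
                     half_life_h = cfg$half_life_h %||% 13.2235)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  report <- withCallingHandlers(
    spect_index_report(pair, vois$heart, vois$lumen, vois$mediastinum,
                       vois$lung, vois$liver),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })

  row <- report_row(report, study_id = cfg$study_id %||% "study")
  utils::write.csv(row, file.path(output_dir, "report.csv"),
                   row.names = FALSE)
  for (nm in names(vois)) {
    if (is.null(vois[[nm]])) next
    write_mask(suppressWarnings(rasterize_voi(vois[[nm]], pair$early$geometry)),
               file.path(output_dir, sprintf("mask_%s.nii.gz", nm)))
  }
  writeLines(c(sprintf("quantify: study %s, decay factor %.6f",
                       cfg$study_id %||% "study", report$decay_factor),
               log_lines),
             file.path(output_dir, "quantify.log"))
  invisible(row)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config))
    stop(sprintf("config file not found: %s", config), call. = FALSE)
  if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
  else yaml::read_yaml(config)
}

parse_voi_list <- function(vois) {
  lapply(vois, function(v) {
    if (inherits(v, "voi")) return(v)
    switch(v$shape,
      ellipsoid = {
        rot <- if (!is.null(v$rotation))
          matrix(as.numeric(unlist(v$rotation)), 3, 3, byrow = TRUE)
        else diag(3)
        ellipsoid_voi(unlist(v$center_mm), unlist(v$semi_axes_mm), rot)
      },
      box = box_voi(unlist(v$center_mm), unlist(v$edge_mm)),
      stop(sprintf("unknown VOI shape '%s'", v$shape), call. = FALSE))
  })
}

#' Run the planar quantification pipeline from a config file
#'
#' Planar counterpart of [run_quantify()]: config keys `early_image`,
#' `delayed_image`, acquisition times, `half_life_h`, and `rois` (path to an
#' ROI config or inline list with `heart` and `mediastinum`). Writes
#' `planar_report.csv`.
#'
#' @param config Path to a YAML/JSON config, or an equivalent named list.
#' @param output_dir Output directory.
#' @return Invisibly, the one-row report `data.frame`.
#' @export
run_planar <- function(config, output_dir) {
  cfg <- load_config(config)
  for (key in c("early_image", "delayed_image", "rois"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config is missing '%s'", key), call. = FALSE)
  rois <- if (is.character(cfg$rois)) read_roi_config(cfg$rois)
          else parse_roi_list(cfg$rois)
  for (req in c("heart", "mediastinum"))
    if (is.null(rois[[req]]))
      stop(sprintf("required ROI missing: %s", req), call. = FALSE)
  early <- read_planar(cfg$early_image, acquisition_time_h = cfg$early_time_h,
                       label = "early")
  delayed <- read_planar(cfg$delayed_image,
                         acquisition_time_h = cfg$delayed_time_h,
                         label = "delayed")
  pair <- study_pair(early, delayed, half_life_h = cfg$half_life_h %||% 13.2235)
  report <- planar_index_report(pair, rois$heart, rois$mediastinum)
  row <- report_row(report, study_id = cfg$study_id %||% "study")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(row, file.path(output_dir, "planar_report.csv"),
                   row.names = FALSE)
  invisible(row)
}

parse_roi_list <- function(rois) {
  lapply(rois, function(r) {
    if (inherits(r, "planar_roi")) return(r)
    switch(r$kind,
      polygon = planar_roi_polygon(matrix(as.numeric(unlist(r$vertices_mm)),
                                          ncol = 2, byrow = TRUE)),
      rectangle = planar_roi_rectangle(unlist(r$corner_mm), unlist(r$size_mm)),
      stop(sprintf("unknown ROI kind '%s'", r$kind), call. = FALSE))
  })
}

#' Agreement analysis between two quantification reports
#'
#' Takes two report CSVs (first and second segmentation, or two raters)
#' produced by [run_quantify()] batches, matches rows by `study_id`, and
#' computes per-quantity agreement statistics shaped like a published
#' reproducibility table: grand mean, mean absolute difference, paired CV,
#' ICC with 95% CI, and the one-sample t-test p-value of the absolute
#' differences.
#'
#' @param report_a,report_b Paths to CSV files (or data.frames) with a
#'   `study_id` column and identical numeric columns.
#' @param output_csv Optional path for the agreement CSV.
#' @return data.frame with one row per quantity.
#' @export
run_agreement <- function(report_a, report_b, output_csv = NULL) {
  a <- if (is.character(report_a)) utils::read.csv(report_a) else report_a
  b <- if (is.character(report_b)) utils::read.csv(report_b) else report_b
  if (!("study_id" %in% names(a)) || !("study_id" %in% names(b)))
    stop("both reports need a study_id column", call. = FALSE)
  missing_cols <- union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
  if (length(missing_cols) > 0)
    stop(sprintf("column(s) present in only one report: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (!setequal(a$study_id, b$study_id))
    stop("study_id mismatch between the two reports", call. = FALSE)
  b <- b[match(a$study_id, b$study_id), ]
  quantities <- names(a)[vapply(a, is.numeric, logical(1))]
  quantities <- setdiff(quantities, c("replicate", "segmentation"))
  out <- lapply(quantities, function(q) {
    m1 <- a[[q]]; m2 <- b[[q]]
    if (any(!is.finite(m1)) || any(!is.finite(m2)) || length(m1) < 3)
      return(data.frame(quantity = q, n = length(m1), mean = NA_real_,
                        mean_abs_diff = NA_real_, sd_abs_diff = NA_real_,
                        cv_percent = NA_real_, icc = NA_real_,
                        icc_lo = NA_real_, icc_hi = NA_real_,
                        t_p_value = NA_real_))
    s <- agreement_summary(replicate_table(m1, m2, a$study_id))
    data.frame(quantity = q, n = s$n, mean = s$mean,
               mean_abs_diff = s$mean_abs_diff, sd_abs_diff = s$sd_abs_diff,
               cv_percent = s$cv_percent, icc = s$icc, icc_lo = s$icc_ci95[1],
               icc_hi = s$icc_ci95[2], t_p_value = s$t_p_value)
  })
  out <- do.call(rbind, out)
  if (!is.null(output_csv))
    utils::write.csv(out, output_csv, row.names = FALSE)
  out
}

#' Generate and write a phantom study from a config
#'
#' Reads an optional phantom config (any [phantom_spec()] argument may be
#' overridden; organ VOIs via the `shape`/`center_mm` syntax), generates the
#' paired study, and writes `early.nii.gz`, `delayed.nii.gz` (with JSON
#' sidecars) plus `ground_truth.json`.
#'
#' @param config Optional path to a YAML/JSON config or named list.
#' @param output_dir Output directory.
#' @param seed Optional seed overriding the config/default seed.
#' @return Invisibly, the `generate_study()` result.
#' @export
run_phantom <- function(config = NULL, output_dir, seed = NULL) {
  cfg <- if (is.null(config)) list() else load_config(config)
  args <- list()
  if (!is.null(cfg$geometry))
    args$geometry <- grid_geometry(unlist(cfg$geometry$shape),
                                   unlist(cfg$geometry$spacing_mm),
                                   unlist(cfg$geometry$origin_mm %||% c(0, 0, 0)))
  for (nm in c("heart_outer", "heart_inner", "liver", "lung"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- parse_voi_list(cfg[nm])[[1]]
  for (nm in c("densities", "washout"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- unlist(cfg[[nm]])
  for (nm in c("early_time_h", "delayed_time_h", "half_life_h", "psf_fwhm_mm",
               "poisson_noise", "seed"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(seed)) args$seed <- seed
  spec <- do.call(phantom_spec, args)
  st <- generate_study(spec)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(st$pair$early, file.path(output_dir, "early.nii.gz"))
  write_volume(st$pair$delayed, file.path(output_dir, "delayed.nii.gz"))
  jsonlite::write_json(
    list(densities = as.list(st$truth$densities),
         washout = as.list(st$truth$washout),
         decay_factor = st$truth$decay_factor,
         ratio_myocardium_background = st$truth$ratio_myocardium_background,
         ratio_myocardium_lumen = st$truth$ratio_myocardium_lumen),
    file.path(output_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(st)
}
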