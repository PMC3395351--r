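#' Physical decay factor between two acquisitions
#'
#' `f = 0.5^(delta_t_h / half_life_h)`: the fraction of activity remaining
#' after `delta_t_h` hours of physical decay. Dividing delayed counts by `f`
#' removes physical decay so that washout reflects biology only.
#'
#' @param delta_t_h Time between early and delayed acquisition, hours (>= 0).
#' @param half_life_h Isotope physical half-life, hours (> 0). Defaults to
#'   13.2235 h (I-123).
#' @return Scalar in `(0, 1]`.
#' @examples
#' decay_factor(3.75)           # ~0.8215 for I-123
#' decay_factor(13.2235)        # exactly 0.5 after one half-life
#' @export
decay_factor <- function(delta_t_h, half_life_h = 13.2235) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L || half_life_h <= 0)
    stop("half_life_h must be a positive scalar", call. = FALSE)
  if (!is.numeric(delta_t_h) || length(delta_t_h) != 1L ||
      !is.finite(delta_t_h) || delta_t_h < 0)
    stop("delta_t_h must be a nonnegative scalar", call. = FALSE)
  0.5^(delta_t_h / half_life_h)
}

#' Uptake ratio between a target and a reference density
#'
#' The heart-to-mediastinum (HM) ratio and its variants are plain quotients of
#' mean count densities: `HM_early = eH / eM`, `HM_delayed = dH / dM`.
#'
#' @param target Nonnegative target mean density (e.g. heart).
#' @param reference Positive reference mean density (e.g. mediastinum).
#' @return `target / reference`.
#' @export
uptake_ratio <- function(target, reference) {
  if (!is.finite(target) || target < 0)
    stop("target density must be finite and >= 0", call. = FALSE)
  if (!is.finite(reference) || reference <= 0)
    stop("undefined ratio: reference density must be > 0", call. = FALSE)
  target / reference
}

#' Washout rate of specific cardiac uptake
#'
#' Fractional loss of background-subtracted cardiac counts between the early
#' and delayed acquisitions, after removing physical decay from the delayed
#' counts:
#'
#' `WOR = ((eH - eM) - (dH/f - dM/f)) / (eH - eM)`,  `f = 0.5^(time/T)`.
#'
#' May legitimately fall below 0 (net accumulation) or exceed 1.
#'
#' @param eH,eM Early heart and mediastinum (reference) mean densities.
#' @param dH,dM Delayed heart and mediastinum mean densities.
#' @param factor Physical decay factor in `(0, 1]`, see [decay_factor()].
#' @return Scalar washout rate (raw fraction, not percent).
#' @examples
#' washout_rate(100, 20, 70, 15, 0.8)       # 0.140625
#' f <- decay_factor(3.75)
#' washout_rate(100, 20, 100 * f, 20 * f, f)  # pure physical decay -> 0
#' @export
washout_rate <- function(eH, eM, dH, dM, factor) {
  vals <- c(eH, eM, dH, dM)
  if (any(!is.finite(vals)))
    stop("densities must be finite", call. = FALSE)
  if (!is.finite(factor) || factor <= 0 || factor > 1)
    stop("decay factor must lie in (0, 1]", call. = FALSE)
  if (eH == eM)
    stop("undefined washout rate: early specific uptake eH - eM is zero",
         call. = FALSE)
  ((eH - eM) - (dH / factor - dM / factor)) / (eH - eM)
}

#' Organ-specific washout
#'
#' Decay-corrected fractional count loss in a single organ VOI:
#' `(eOrgan - dOrgan/f) / eOrgan`. Always <= 1; negative values indicate
#' continued accumulation between the acquisitions.
#'
#' @param eOrgan Early organ mean density (> 0).
#' @param dOrgan Delayed organ mean density (>= 0).
#' @param factor Physical decay factor in `(0, 1]`.
#' @return Scalar organ washout.
#' @export
organ_washout <- function(eOrgan, dOrgan, factor) {
  if (!is.finite(eOrgan) || eOrgan <= 0)
    stop("undefined organ washout: early organ density must be > 0",
         call. = FALSE)
  if (!is.finite(dOrgan) || dOrgan < 0)
    stop("delayed organ density must be finite and >= 0", call. = FALSE)
  if (!is.finite(factor) || factor <= 0 || factor > 1)
    stop("decay factor must lie in (0, 1]", call. = FALSE)
  (eOrgan - dOrgan / factor) / eOrgan
}

new_index_report <- function(combination, early_ratio, delayed_ratio, wor,
                             wor_flag = NA_character_) {
  structure(list(combination = combination, early_ratio = early_ratio,
                 delayed_ratio = delayed_ratio, wor = wor,
                 wor_flag = wor_flag),
            class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("%s: early %.3f, delayed %.3f, WOR %s%s\n", x$combination,
              x$early_ratio, x$delayed_ratio,
              ifelse(is.na(x$wor), "undefined", sprintf("%.3f", x$wor)),
              ifelse(is.na(x$wor_flag), "", sprintf(" [%s]", x$wor_flag))))
  invisible(x)
}

# washout_rate with batch semantics: an undefined WOR (eH == eM) becomes a
# flagged NA instead of an exception, so one degenerate study does not abort
# a batch
washout_rate_flagged <- function(eH, eM, dH, dM, factor) {
  tryCatch(list(wor = washout_rate(eH, eM, dH, dM, factor),
                flag = NA_character_),
           error = function(e) {
             warning(conditionMessage(e), call. = FALSE)
             list(wor = NA_real_, flag = "undefined")
           })
}

#' SPECT index report for the HM, MM and ML VOI combinations
#'
#' Rasterizes the five VOIs on the study geometry, extracts early/delayed
#' count statistics (the myocardial wall by heart-minus-lumen subtraction),
#' and applies the uptake-ratio and washout formulas to three combinations:
#' heart-to-mediastinum (HM), myocardial wall-to-mediastinum (MM) and wall-to-
#' lumen (ML). Organ-specific washout is computed for every VOI. All indices
#' operate on mean count densities (counts per voxel); totals are reported
#' but not used in the indices.
#'
#' @param pair A [study_pair()] of volumes.
#' @param heart,lumen [ellipsoid_voi()]s; the lumen must rasterize to a
#'   subset of the heart.
#' @param mediastinum A [box_voi()] (size checked against 10-15 cm^3).
#' @param lung,liver Optional [box_voi()]s.
#' @return An object of class `spect_report`: list with `combinations`
#'   (named `index_report`s for HM, MM, ML), `organ_washouts` (named vector),
#'   `stats` (data.frame of per-VOI early/delayed statistics) and
#'   `decay_factor`.
#' @export
spect_index_report <- function(pair, heart, lumen, mediastinum,
                               lung = NULL, liver = NULL) {
  stopifnot(inherits(pair, "study_pair"), inherits(pair$early, "volume_grid"))
  geom <- pair$early$geometry
  vox <- voxel_volume_mm3(geom)
  f <- decay_factor(pair$delta_t_h, pair$half_life_h)

  heart_mask <- rasterize_ellipsoid(heart, geom)
  lumen_mask <- rasterize_ellipsoid(lumen, geom)
  if (!is_subset_mask(lumen_mask, heart_mask))
    stop("lumen VOI is not contained in the heart VOI", call. = FALSE)

  vois <- list(heart = heart_mask, lumen = lumen_mask,
               mediastinum = rasterize_box(mediastinum, geom))
  if (!is.null(lung)) vois$lung <- rasterize_box(lung, geom)
  if (!is.null(liver)) vois$liver <- rasterize_box(liver, geom)

  early <- lapply(vois, function(m) count_stats(pair$early, m))
  delayed <- lapply(vois, function(m) count_stats(pair$delayed, m))
  for (nm in intersect(c("mediastinum", "lung", "liver"), names(early)))
    validate_box_size(early[[nm]])

  early$wall <- wall_stats(early$heart, early$lumen, TRUE, vox)
  delayed$wall <- wall_stats(delayed$heart, delayed$lumen, TRUE, vox)

  combo <- function(label, tgt, ref) {
    w <- washout_rate_flagged(early[[tgt]]$mean_density,
                              early[[ref]]$mean_density,
                              delayed[[tgt]]$mean_density,
                              delayed[[ref]]$mean_density, f)
    new_index_report(label,
                     uptake_ratio(early[[tgt]]$mean_density,
                                  early[[ref]]$mean_density),
                     uptake_ratio(delayed[[tgt]]$mean_density,
                                  delayed[[ref]]$mean_density),
                     w$wor, w$flag)
  }
  combinations <- list(HM = combo("HM", "heart", "mediastinum"),
                       MM = combo("MM", "wall", "mediastinum"),
                       ML = combo("ML", "wall", "lumen"))

  organs <- names(early)
  washouts <- vapply(organs, function(nm)
    organ_washout(early[[nm]]$mean_density, delayed[[nm]]$mean_density, f),
    numeric(1))

  stats <- data.frame(
    voi = organs,
    early_mean_density = vapply(early, `[[`, numeric(1), "mean_density"),
    delayed_mean_density = vapply(delayed, `[[`, numeric(1), "mean_density"),
    early_total = vapply(early, `[[`, numeric(1), "total_counts"),
    delayed_total = vapply(delayed, `[[`, numeric(1), "total_counts"),
    size_ml = vapply(early, `[[`, numeric(1), "size_ml"),
    row.names = NULL)

  structure(list(combinations = combinations, organ_washouts = washouts,
                 stats = stats, decay_factor = f),
            class = "spect_report")
}

#' @export
print.spect_report <- function(x, ...) {
  cat(sprintf("SPECT index report (decay factor %.5f)\n", x$decay_factor))
  for (r in x$combinations) print(r)
  cat("organ washouts:\n")
  print(round(x$organ_washouts, 4))
  invisible(x)
}

#' Flatten a SPECT or planar report to a one-row data frame
#'
#' One CSV-ready row per study: per-VOI early/delayed mean densities and
#' sizes, per-combination early/delayed ratios and WOR, per-organ washout.
#'
#' @param report A `spect_report` or `planar_report`.
#' @param study_id Identifier placed in the first column.
#' @return A one-row `data.frame`.
#' @export
report_row <- function(report, study_id = "study") {
  row <- list(study_id = study_id)
  st <- report$stats
  for (i in seq_len(nrow(st))) {
    nm <- st$voi[i]
    row[[paste0(nm, "_early_density")]] <- st$early_mean_density[i]
    row[[paste0(nm, "_delayed_density")]] <- st$delayed_mean_density[i]
    row[[paste0(nm, "_size_ml")]] <- st$size_ml[i]
  }
  for (r in report$combinations) {
    lab <- tolower(r$combination)
    row[[paste0(lab, "_early")]] <- r$early_ratio
    row[[paste0(lab, "_delayed")]] <- r$delayed_ratio
    row[[paste0(lab, "_wor")]] <- r$wor
  }
  for (nm in names(report$organ_washouts))
    row[[paste0(nm, "_washout")]] <- unname(report$organ_washouts[nm])
  as.data.frame(row, stringsAsFactors = FALSE)
}
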