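#' Digital thorax phantom specification
#'
#' Defines a synthetic thorax for end-to-end validation of the VOI pipeline:
#' organ geometry in physical mm, per-organ early count densities, per-organ
#' biological washout fractions, acquisition times and isotope half-life, an
#' isotropic Gaussian PSF, and optional Poisson noise.
#'
#' The anatomy comprises a myocardial shell between two concentric ellipsoids
#' (outer = entire heart, inner = left-ventricular lumen), box-shaped liver
#' and lung regions, and a uniform soft-tissue/mediastinum background. Voxels
#' are painted by centre membership with deterministic precedence
#' lumen > myocardial shell > liver > lung > background.
#'
#' The delayed volume is the early one scaled per organ by
#' `(1 - w_organ) * 0.5^(delta_t / half_life)`: biological washout and
#' physical decay compose multiplicatively, and decay is applied to the
#' delayed image only, so that [organ_washout()] recovers `w_organ` exactly
#' when blur and noise are off. Default densities sit in the regime of
#' published clinical mean count densities (liver 28, lung 12.8, soft tissue
#' 4.8, myocardium 9.3, lumen 5.0 counts/voxel) and the default washout
#' fractions place the delayed densities in the same regime.
#'
#' @param geometry A [grid_geometry()] (default 128 x 128 x 64 voxels at
#'   3.3 mm isotropic).
#' @param heart_outer,heart_inner [ellipsoid_voi()]s bounding the myocardial
#'   shell; `heart_inner` must lie strictly inside `heart_outer`.
#' @param liver,lung [box_voi()]s for the organ regions (not the measurement
#'   VOIs).
#' @param densities Named numeric vector of early count densities
#'   (counts/voxel) for `myocardium`, `lumen`, `liver`, `lung`, `background`.
#' @param washout Named numeric vector of biological washout fractions
#'   (w <= 1; negative = continued accumulation) for the same organs.
#' @param early_time_h,delayed_time_h Acquisition times, hours post-injection.
#' @param half_life_h Isotope half-life (default I-123, 13.2235 h).
#' @param psf_fwhm_mm Isotropic Gaussian PSF full width at half maximum in mm
#'   (0 disables blurring; default 15).
#' @param poisson_noise Logical: sample voxel counts from a Poisson law.
#' @param seed Integer seed driving the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = grid_geometry(c(128, 128, 64),
                                                  c(3.3, 3.3, 3.3)),
                         heart_outer = ellipsoid_voi(c(165, 215, 115),
                                                     c(50, 50, 45)),
                         heart_inner = ellipsoid_voi(c(165, 215, 115),
                                                     c(28, 28, 25)),
                         liver = box_voi(c(230, 230, 30), c(180, 160, 55)),
                         lung = box_voi(c(280, 200, 120), c(110, 130, 150)),
                         densities = c(myocardium = 9.3, lumen = 5.0,
                                       liver = 28.0, lung = 12.8,
                                       background = 4.8),
                         washout = c(myocardium = -0.07, lumen = -0.07,
                                     liver = -0.16, lung = 0.0,
                                     background = -0.04),
                         early_time_h = 0.25, delayed_time_h = 4.0,
                         half_life_h = 13.2235, psf_fwhm_mm = 15,
                         poisson_noise = FALSE, seed = 1L) {
  organs <- c("myocardium", "lumen", "liver", "lung", "background")
  stopifnot(inherits(geometry, "grid_geometry"),
            inherits(heart_outer, "ellipsoid_voi"),
            inherits(heart_inner, "ellipsoid_voi"),
            inherits(liver, "box_voi"), inherits(lung, "box_voi"),
            all(organs %in% names(densities)),
            all(organs %in% names(washout)))
  if (any(!is.finite(densities)) || any(densities < 0))
    stop("organ densities must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(washout)) || any(washout > 1))
    stop("biological washout fractions must be finite and <= 1", call. = FALSE)
  if (delayed_time_h <= early_time_h)
    stop("delayed_time_h must exceed early_time_h", call. = FALSE)
  if (half_life_h <= 0) stop("half_life_h must be > 0", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  # lumen strictly inside the outer ellipsoid: sampled containment check on
  # the inner surface
  if (!ellipsoid_inside(heart_inner, heart_outer))
    stop("heart_inner (lumen) must lie strictly inside heart_outer",
         call. = FALSE)
  structure(list(geometry = geometry, heart_outer = heart_outer,
                 heart_inner = heart_inner, liver = liver, lung = lung,
                 densities = densities[organs], washout = washout[organs],
                 early_time_h = early_time_h, delayed_time_h = delayed_time_h,
                 half_life_h = half_life_h, psf_fwhm_mm = psf_fwhm_mm,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# check inner ellipsoid surface points fall inside the outer ellipsoid
ellipsoid_inside <- function(inner, outer, n = 200) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(42)  # deterministic sampling of the inner surface
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- t(inner$rotation %*% (t(u) * inner$semi_axes)) +
    matrix(inner$center, n, 3, byrow = TRUE)
  d <- t(outer$rotation) %*% (t(pts) - outer$center)
  all(colSums((d / outer$semi_axes)^2) < 1)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:\n")
  print(x$geometry)
  cat(sprintf("  densities: %s\n",
              paste(sprintf("%s=%g", names(x$densities), x$densities),
                    collapse = ", ")))
  cat(sprintf("  washout:   %s\n",
              paste(sprintf("%s=%g", names(x$washout), x$washout),
                    collapse = ", ")))
  cat(sprintf("  t = %g -> %g h, T = %g h, PSF FWHM %g mm, Poisson %s, seed %d\n",
              x$early_time_h, x$delayed_time_h, x$half_life_h, x$psf_fwhm_mm,
              x$poisson_noise, x$seed))
  invisible(x)
}

# organ label array by voxel-centre membership, precedence
# lumen > myocardial shell > liver > lung > background
phantom_labels <- function(spec) {
  geom <- spec$geometry
  outer_m <- suppressWarnings(rasterize_ellipsoid(spec$heart_outer, geom))$members
  inner_m <- suppressWarnings(rasterize_ellipsoid(spec$heart_inner, geom))$members
  liver_m <- suppressWarnings(rasterize_box(spec$liver, geom))$members
  lung_m <- suppressWarnings(rasterize_box(spec$lung, geom))$members
  lab <- array("background", geom$shape)
  lab[lung_m] <- "lung"
  lab[liver_m] <- "liver"
  lab[outer_m & !inner_m] <- "myocardium"
  lab[inner_m] <- "lumen"
  lab
}

#' Separable 3D Gaussian blur
#'
#' Convolves a 3D array with an isotropic Gaussian kernel of the given FWHM
#' (mm), applied separably along each axis with zero padding at the grid
#' boundary. Counts are conserved up to losses past the boundary.
#'
#' @param values 3D numeric array.
#' @param spacing Voxel spacing mm triple.
#' @param fwhm_mm Full width at half maximum in mm (0 returns the input).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur3 <- function(values, spacing, fwhm_mm) {
  if (fwhm_mm == 0) return(values)
  stopifnot(length(dim(values)) == 3L)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- values
  for (ax in 1:3) {
    n <- dim(out)[1]           # operate on the first axis, then rotate
    sigma_vox <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(4 * sigma_vox))
    kern <- stats::dnorm(seq(-r, r), sd = sigma_vox)
    kern <- kern / sum(kern)
    K <- matrix(0, n, n)
    for (off in seq(-r, r)) {
      idx <- seq_len(n)
      keep <- idx + off >= 1 & idx + off <= n
      K[cbind(idx[keep], (idx + off)[keep])] <- kern[off + r + 1]
    }
    d <- dim(out)
    out <- K %*% matrix(out, d[1], d[2] * d[3])
    dim(out) <- d
    out <- aperm(out, c(2, 3, 1))
  }
  out
}

#' Generate a paired early/delayed phantom study
#'
#' Paints organ densities onto the voxel grid, derives the delayed volume by
#' per-organ biological washout composed with physical decay, then optionally
#' applies the Gaussian PSF to both volumes and samples independent Poisson
#' noise (seeded; early and delayed use distinct substreams of the seed).
#'
#' @param spec A [phantom_spec()].
#' @return List with `pair` (a [study_pair()]), `truth` (a `ground_truth`
#'   list: per-organ early densities, washout fractions, decay factor, and
#'   the configured myocardium:background and myocardium:lumen density
#'   ratios), and `labels` (the organ label array).
#' @examples
#' spec <- phantom_spec(geometry = grid_geometry(c(32, 32, 16), c(13, 13, 13)),
#'                      psf_fwhm_mm = 0)
#' st <- generate_study(spec)
#' st$truth$decay_factor
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_labels(spec)
  dens <- spec$densities
  w <- spec$washout
  f <- decay_factor(spec$delayed_time_h - spec$early_time_h, spec$half_life_h)

  early <- array(dens[lab], dim(lab))
  delayed <- array((dens * (1 - w) * f)[lab], dim(lab))

  if (spec$psf_fwhm_mm > 0) {
    early <- gaussian_blur3(early, spec$geometry$spacing, spec$psf_fwhm_mm)
    delayed <- gaussian_blur3(delayed, spec$geometry$spacing, spec$psf_fwhm_mm)
  }
  if (spec$poisson_noise) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    early <- array(stats::rpois(length(early), early), dim(early))
    set.seed(spec$seed + 1L)
    delayed <- array(stats::rpois(length(delayed), delayed), dim(delayed))
  }

  pair <- study_pair(
    volume_grid(early, spec$geometry, spec$early_time_h, "early"),
    volume_grid(delayed, spec$geometry, spec$delayed_time_h, "delayed"),
    half_life_h = spec$half_life_h)
  truth <- structure(list(
    densities = dens, washout = w, decay_factor = f,
    ratio_myocardium_background = unname(dens["myocardium"] / dens["background"]),
    ratio_myocardium_lumen = unname(dens["myocardium"] / dens["lumen"])),
    class = "ground_truth")
  list(pair = pair, truth = truth, labels = lab)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default measurement VOIs for a phantom study
#'
#' Two styles: `"matched"` VOIs coincide with the anatomical boundaries
#' (heart = outer shell ellipsoid, lumen = inner ellipsoid), making every
#' density and washout recoverable exactly on a noiseless unblurred phantom;
#' `"clinical"` VOIs mimic practice — a heart ellipsoid slightly larger than
#' the organ ("contain the entire heart"), a small ~10 mL lumen ellipsoid in
#' the cavity centre, and ~12.7 mL boxes in the mediastinum (superior to the
#' heart, between the lungs), right lung and liver centres.
#'
#' @param spec A [phantom_spec()].
#' @param style `"clinical"` (default) or `"matched"`.
#' @return Named list of VOIs: `heart`, `lumen`, `mediastinum`, `lung`,
#'   `liver`.
#' @export
phantom_vois <- function(spec, style = c("clinical", "matched")) {
  style <- match.arg(style)
  # 23.1 mm edges (7 voxel spacings) rasterize to a stable 7^3-voxel,
  # ~12.3 mL box at 3.3 mm spacing, inside the conventional 10-15 cm^3 band
  box_edge <- rep(23.1, 3)
  # mediastinal VOI placed from anatomical landmarks, as in the planar
  # methodology: against the lung border (apex side), superior to the heart
  med_center <- c(spec$lung$center[1] - spec$lung$edge_lengths[1] / 2 - 14,
                  spec$heart_outer$center[2],
                  spec$heart_outer$center[3] + spec$heart_outer$semi_axes[3] + 12)
  if (style == "matched") {
    list(heart = spec$heart_outer, lumen = spec$heart_inner,
         mediastinum = box_voi(med_center, box_edge),
         lung = box_voi(spec$lung$center, box_edge),
         liver = box_voi(spec$liver$center, box_edge))
  } else {
    list(heart = ellipsoid_voi(spec$heart_outer$center,
                               spec$heart_outer$semi_axes + 2),
         lumen = ellipsoid_voi(spec$heart_inner$center, rep(13.4, 3)),
         mediastinum = box_voi(med_center, box_edge),
         lung = box_voi(spec$lung$center, box_edge),
         liver = box_voi(spec$liver$center, box_edge))
  }
}

#' Jitter a VOI centre by a uniform offset
#' @param voi A VOI.
#' @param jitter_mm Max absolute per-axis offset in mm.
#' @return The VOI translated by a `runif(3, -jitter_mm, jitter_mm)` offset.
#' @keywords internal
jitter_voi <- function(voi, jitter_mm) {
  if (jitter_mm == 0) return(voi)
  off <- stats::runif(3, -jitter_mm, jitter_mm)
  if (inherits(voi, "ellipsoid_voi"))
    ellipsoid_voi(voi$center + off, voi$semi_axes, voi$rotation)
  else box_voi(voi$center + off, voi$edge_lengths)
}

#' Test-retest recovery experiment on the phantom
#'
#' Emulates the repeated-segmentation reproducibility design: for each
#' replicate a fresh phantom realization is generated (new Poisson noise when
#' enabled) and quantified twice, each time with every VOI centre
#' independently jittered by a seeded uniform offset (the stand-in for manual
#' re-segmentation). Per-quantity agreement statistics (paired CV, ICC) are
#' then computed over the replicate pairs.
#'
#' @param spec A [phantom_spec()].
#' @param n_replicates Number of replicate pairs (>= 2).
#' @param voi_jitter_mm Maximum per-axis VOI centre offset in mm.
#' @param vois Named VOI list (default `phantom_vois(spec, "clinical")`).
#' @param seed Seed for the jitter and noise stream.
#' @param resample_noise When `FALSE` (default) both segmentations of a
#'   replicate quantify the same noisy realization, as when one acquisition
#'   is segmented twice; when `TRUE` each segmentation sees an independent
#'   noise realization (repeated acquisition), so pure Poisson counting error
#'   enters the agreement statistics even without jitter.
#' @return List with `measurements` (data.frame: replicate, segmentation,
#'   one column per quantity) and `agreement` (data.frame: quantity, mean,
#'   mean_abs_diff, cv_percent, icc, icc lower/upper).
#' @export
recovery_experiment <- function(spec, n_replicates, voi_jitter_mm,
                                vois = phantom_vois(spec, "clinical"),
                                seed = spec$seed, resample_noise = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), n_replicates >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   2L * n_replicates),
                        nrow = n_replicates)
  rows <- vector("list", 2L * n_replicates)
  for (i in seq_len(n_replicates)) {
    spec_i <- spec
    spec_i$seed <- noise_seeds[i, 1]
    st <- generate_study(spec_i)
    for (s in 1:2) {
      if (resample_noise && s == 2L) {
        spec_i$seed <- noise_seeds[i, 2]
        st <- generate_study(spec_i)
      }
      jittered <- lapply(vois, jitter_voi, jitter_mm = voi_jitter_mm)
      rep_i <- suppressWarnings(
        spect_index_report(st$pair, jittered$heart, jittered$lumen,
                           jittered$mediastinum, jittered$lung,
                           jittered$liver))
      row <- report_row(rep_i, study_id = sprintf("rep%03d_seg%d", i, s))
      row$replicate <- i
      row$segmentation <- s
      rows[[2L * (i - 1L) + s]] <- row
    }
  }
  meas <- do.call(rbind, rows)
  quantities <- setdiff(names(meas), c("study_id", "replicate", "segmentation"))
  agr <- lapply(quantities, function(q) {
    m1 <- meas[[q]][meas$segmentation == 1]
    m2 <- meas[[q]][meas$segmentation == 2]
    if (any(!is.finite(m1)) || any(!is.finite(m2)))
      return(data.frame(quantity = q, mean = NA_real_, mean_abs_diff = NA_real_,
                        cv_percent = NA_real_, icc = NA_real_,
                        icc_lo = NA_real_, icc_hi = NA_real_))
    s <- agreement_summary(replicate_table(m1, m2))
    data.frame(quantity = q, mean = s$mean, mean_abs_diff = s$mean_abs_diff,
               cv_percent = s$cv_percent, icc = s$icc,
               icc_lo = s$icc_ci95[1], icc_hi = s$icc_ci95[2])
  })
  list(measurements = meas, agreement = do.call(rbind, agr))
}
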