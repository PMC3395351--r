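#' Grid geometry for a 3D count volume
#'
#' Describes the voxel lattice of a SPECT volume in physical millimetre
#' coordinates. The centre of voxel index `(i, j, k)` (0-based) lies at
#' `origin + (i, j, k) * spacing`.
#'
#' @param shape Integer triple `(nx, ny, nz)`, each component >= 1.
#' @param spacing Positive numeric triple, voxel spacing in mm.
#' @param origin Numeric triple, physical coordinate (mm) of the centre of
#'   voxel `(0, 0, 0)`. Defaults to the zero vector.
#'
#' @return An object of class `grid_geometry` with fields `shape`, `spacing`
#'   and `origin`.
#' @examples
#' g <- grid_geometry(c(128, 128, 64), spacing = c(3.3, 3.3, 3.3))
#' voxel_volume_mm3(g)
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(shape)) || any(shape < 1L))
    stop("all shape components must be >= 1", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be > 0 mm", call. = FALSE)
  if (any(!is.finite(origin)))
    stop("origin must be finite", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' Voxel volume of a grid in cubic millimetres
#' @param geometry A [grid_geometry()].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  prod(geometry$spacing)
}

#' Physical coordinates of voxel centres along one axis
#' @param geometry A [grid_geometry()].
#' @param axis Axis index 1, 2 or 3.
#' @return Numeric vector of voxel-centre coordinates in mm.
#' @keywords internal
axis_coords <- function(geometry, axis) {
  geometry$origin[axis] +
    (seq_len(geometry$shape[axis]) - 1) * geometry$spacing[axis]
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

check_counts <- function(values, what = "voxel") {
  if (any(!is.finite(values)))
    stop(sprintf("%s values must be finite (no NaN/Inf)", what), call. = FALSE)
  if (any(values < 0))
    stop(sprintf("negative %s values are not valid counts", what), call. = FALSE)
  invisible(TRUE)
}

#' 3D SPECT count volume
#'
#' A reconstructed count volume together with its voxel lattice and
#' acquisition metadata. Values are counts (or count densities) and must be
#' finite and nonnegative.
#'
#' @param values 3D numeric array of counts, all finite and >= 0.
#' @param geometry A [grid_geometry()] whose `shape` matches `dim(values)`.
#' @param acquisition_time_h Nonnegative scalar, acquisition time in hours
#'   post-injection.
#' @param label Free-text label, conventionally `"early"`, `"delayed"` or
#'   `"other"`.
#'
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, geometry, acquisition_time_h = 0,
                        label = "other") {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("expected 3D volume", call. = FALSE)
  if (!identical(as.integer(dim(values)), geometry$shape))
    stop("values shape does not match geometry shape", call. = FALSE)
  check_counts(values)
  if (!is.numeric(acquisition_time_h) || length(acquisition_time_h) != 1L ||
      !is.finite(acquisition_time_h) || acquisition_time_h < 0)
    stop("acquisition_time_h must be a nonnegative scalar (hours)", call. = FALSE)
  structure(list(values = values, geometry = geometry,
                 acquisition_time_h = as.numeric(acquisition_time_h),
                 label = as.character(label)[1]),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid '%s': %d x %d x %d voxels @ (%g, %g, %g) mm, t = %g h, total counts %g\n",
              x$label, x$geometry$shape[1], x$geometry$shape[2],
              x$geometry$shape[3], x$geometry$spacing[1],
              x$geometry$spacing[2], x$geometry$spacing[3],
              x$acquisition_time_h, sum(x$values)))
  invisible(x)
}

#' 2D anterior planar count image
#'
#' @param values 2D numeric array of pixel counts, finite and >= 0.
#' @param pixel_spacing Positive numeric pair, pixel spacing in mm.
#' @param origin Numeric pair, physical coordinate (mm) of the centre of
#'   pixel `(0, 0)`.
#' @param acquisition_time_h Nonnegative scalar, hours post-injection.
#' @param label Free-text label.
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(values, pixel_spacing, origin = c(0, 0),
                         acquisition_time_h = 0, label = "other") {
  values <- as.array(values)
  if (length(dim(values)) != 2L)
    stop("expected 2D planar image", call. = FALSE)
  pixel_spacing <- as.numeric(pixel_spacing)
  origin <- as.numeric(origin)
  stopifnot(length(pixel_spacing) == 2L, length(origin) == 2L)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be > 0 mm", call. = FALSE)
  check_counts(values, "pixel")
  if (!is.numeric(acquisition_time_h) || length(acquisition_time_h) != 1L ||
      !is.finite(acquisition_time_h) || acquisition_time_h < 0)
    stop("acquisition_time_h must be a nonnegative scalar (hours)", call. = FALSE)
  structure(list(values = values, shape = as.integer(dim(values)),
                 pixel_spacing = pixel_spacing, origin = origin,
                 acquisition_time_h = as.numeric(acquisition_time_h),
                 label = as.character(label)[1]),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("planar_image '%s': %d x %d pixels @ (%g, %g) mm, t = %g h, total counts %g\n",
              x$label, x$shape[1], x$shape[2], x$pixel_spacing[1],
              x$pixel_spacing[2], x$acquisition_time_h, sum(x$values)))
  invisible(x)
}

#' Paired early/delayed study
#'
#' Couples an early and a delayed acquisition of the same patient on identical
#' geometry, together with the isotope half-life. The interval
#' `delta_t_h = delayed - early` acquisition time drives the physical decay
#' factor `0.5^(delta_t_h / half_life_h)` used in washout computations.
#'
#' @param early,delayed Two [volume_grid()]s or two [planar_image()]s with
#'   identical geometry; `delayed` must be acquired strictly later.
#' @param half_life_h Isotope physical half-life in hours. Defaults to
#'   13.2235 h (I-123).
#' @return An object of class `study_pair` with fields `early`, `delayed`,
#'   `half_life_h` and `delta_t_h`.
#' @examples
#' g <- grid_geometry(c(8, 8, 8), c(3, 3, 3))
#' e <- volume_grid(array(10, c(8, 8, 8)), g, acquisition_time_h = 0.25, label = "early")
#' d <- volume_grid(array(8, c(8, 8, 8)), g, acquisition_time_h = 4, label = "delayed")
#' sp <- study_pair(e, d)
#' decay_factor(sp$delta_t_h, sp$half_life_h)
#' @export
study_pair <- function(early, delayed, half_life_h = 13.2235) {
  if (!(inherits(early, "volume_grid") && inherits(delayed, "volume_grid")) &&
      !(inherits(early, "planar_image") && inherits(delayed, "planar_image")))
    stop("early and delayed must both be volume_grid or both planar_image",
         call. = FALSE)
  if (inherits(early, "volume_grid")) {
    if (!same_geometry(early$geometry, delayed$geometry))
      stop("early and delayed volumes must share an identical geometry",
           call. = FALSE)
  } else {
    if (!identical(early$shape, delayed$shape) ||
        any(abs(early$pixel_spacing - delayed$pixel_spacing) > 1e-6))
      stop("early and delayed planar images must share an identical geometry",
           call. = FALSE)
  }
  if (!is.numeric(half_life_h) || half_life_h <= 0)
    stop("half_life_h must be > 0", call. = FALSE)
  dt <- delayed$acquisition_time_h - early$acquisition_time_h
  if (!is.finite(dt) || dt <= 0)
    stop("delayed acquisition must occur strictly after the early one",
         call. = FALSE)
  structure(list(early = early, delayed = delayed,
                 half_life_h = as.numeric(half_life_h), delta_t_h = dt),
            class = "study_pair")
}

#' @export
print.study_pair <- function(x, ...) {
  cat(sprintf("study_pair: delta_t = %g h, half-life = %g h, decay factor %.5f\n",
              x$delta_t_h, x$half_life_h,
              0.5^(x$delta_t_h / x$half_life_h)))
  print(x$early)
  print(x$delayed)
  invisible(x)
}
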