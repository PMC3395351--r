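#' Ellipsoidal volume of interest
#'
#' An ellipsoid in physical mm coordinates, used for the heart VOI ("contain
#' the entire heart") and the left-ventricular lumen VOI. An optional rotation
#' lets the ellipsoid be placed in a reoriented cardiac frame without
#' resampling the volume.
#'
#' @param center Numeric mm triple.
#' @param semi_axes Positive mm triple `(a, b, c)`.
#' @param rotation 3x3 orthonormal matrix (columns = ellipsoid axes in grid
#'   frame); defaults to identity.
#' @return An object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center, semi_axes, rotation = diag(3)) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("all semi_axes must be > 0 mm", call. = FALSE)
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be a 3x3 orthonormal matrix", call. = FALSE)
  structure(list(center = center, semi_axes = semi_axes, rotation = rotation),
            class = c("ellipsoid_voi", "voi"))
}

#' Box-shaped volume of interest
#'
#' An axis-aligned box in physical mm coordinates, used for the mediastinal,
#' lung and liver VOIs. The reference methodology keeps these between 10 and
#' 15 cm^3; see [validate_box_size()].
#'
#' @param center Numeric mm triple.
#' @param edge_lengths Positive mm triple of full edge lengths.
#' @return An object of class `box_voi`.
#' @export
box_voi <- function(center, edge_lengths) {
  center <- as.numeric(center); edge_lengths <- as.numeric(edge_lengths)
  stopifnot(length(center) == 3L, length(edge_lengths) == 3L)
  if (any(!is.finite(edge_lengths)) || any(edge_lengths <= 0))
    stop("all edge_lengths must be > 0 mm", call. = FALSE)
  structure(list(center = center, edge_lengths = edge_lengths),
            class = c("box_voi", "voi"))
}

#' @export
print.ellipsoid_voi <- function(x, ...) {
  cat(sprintf("ellipsoid_voi: center (%g, %g, %g) mm, semi-axes (%g, %g, %g) mm%s\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              if (max(abs(x$rotation - diag(3))) > 1e-12) ", rotated" else ""))
  invisible(x)
}

#' @export
print.box_voi <- function(x, ...) {
  cat(sprintf("box_voi: center (%g, %g, %g) mm, edges (%g, %g, %g) mm, %.1f mL\n",
              x$center[1], x$center[2], x$center[3],
              x$edge_lengths[1], x$edge_lengths[2], x$edge_lengths[3],
              prod(x$edge_lengths) / 1000))
  invisible(x)
}

new_voxel_mask <- function(members, geometry) {
  stopifnot(is.logical(members),
            identical(as.integer(dim(members)), geometry$shape))
  structure(list(members = members, geometry = geometry),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  n <- sum(x$members)
  cat(sprintf("voxel_mask: %d member voxels (%.2f mL) on %d x %d x %d grid\n",
              n, n * voxel_volume_mm3(x$geometry) / 1000,
              x$geometry$shape[1], x$geometry$shape[2], x$geometry$shape[3]))
  invisible(x)
}

# warn when the VOI extends past the voxel-centre lattice hull (it is then
# silently clipped to the grid)
warn_if_clipped <- function(lo, hi, geometry, what) {
  gmin <- geometry$origin
  gmax <- geometry$origin + (geometry$shape - 1) * geometry$spacing
  if (any(lo < gmin - 1e-9) || any(hi > gmax + 1e-9))
    warning(sprintf("%s extends beyond the grid and is clipped", what),
            call. = FALSE)
}

#' Rasterize an ellipsoid VOI to a voxel mask
#'
#' A voxel belongs to the mask iff its centre `c` satisfies
#' `|| diag(1/a) R^T (c - center) ||^2 <= 1` (closed boundary; no
#' partial-volume weighting). Parts of the ellipsoid outside the grid are
#' clipped with a warning.
#'
#' @param voi An [ellipsoid_voi()].
#' @param geometry A [grid_geometry()].
#' @return A `voxel_mask`.
#' @examples
#' g <- grid_geometry(c(25, 25, 25), c(1, 1, 1))
#' m <- rasterize_ellipsoid(ellipsoid_voi(c(12, 12, 12), c(10, 10, 10)), g)
#' sum(m$members)            # close to 4/3 * pi * 10^3
#' @export
rasterize_ellipsoid <- function(voi, geometry) {
  stopifnot(inherits(voi, "ellipsoid_voi"), inherits(geometry, "grid_geometry"))
  a <- voi$semi_axes; R <- voi$rotation
  # physical half-extent of the (possibly rotated) ellipsoid along grid axes
  ext <- sqrt(rowSums((R %*% diag(a))^2))
  warn_if_clipped(voi$center - ext, voi$center + ext, geometry, "ellipsoid VOI")

  x <- axis_coords(geometry, 1) - voi$center[1]
  y <- axis_coords(geometry, 2) - voi$center[2]
  z <- axis_coords(geometry, 3) - voi$center[3]
  # quadratic form M = R diag(1/a^2) R^T; member iff d' M d <= 1
  M <- R %*% diag(1 / a^2) %*% t(R)
  n <- geometry$shape
  X <- array(rep(x, times = n[2] * n[3]), n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), n)
  Z <- array(rep(z, each = n[1] * n[2]), n)
  q <- M[1, 1] * X^2 + M[2, 2] * Y^2 + M[3, 3] * Z^2 +
    2 * (M[1, 2] * X * Y + M[1, 3] * X * Z + M[2, 3] * Y * Z)
  new_voxel_mask(q <= 1, geometry)
}

#' Rasterize a box VOI to a voxel mask
#'
#' A voxel belongs to the mask iff its centre lies within the closed
#' axis-aligned box `center +/- edge_lengths / 2` on every axis.
#'
#' @param voi A [box_voi()].
#' @param geometry A [grid_geometry()].
#' @return A `voxel_mask`.
#' @export
rasterize_box <- function(voi, geometry) {
  stopifnot(inherits(voi, "box_voi"), inherits(geometry, "grid_geometry"))
  half <- voi$edge_lengths / 2
  warn_if_clipped(voi$center - half, voi$center + half, geometry, "box VOI")
  inside <- lapply(1:3, function(ax) {
    co <- axis_coords(geometry, ax)
    co >= voi$center[ax] - half[ax] & co <= voi$center[ax] + half[ax]
  })
  members <- outer(outer(inside[[1]], inside[[2]], "&"), inside[[3]], "&")
  dim(members) <- geometry$shape
  new_voxel_mask(members, geometry)
}

#' Rasterize any VOI
#' @param voi An [ellipsoid_voi()] or [box_voi()].
#' @param geometry A [grid_geometry()].
#' @return A `voxel_mask`.
#' @export
rasterize_voi <- function(voi, geometry) {
  if (inherits(voi, "ellipsoid_voi")) rasterize_ellipsoid(voi, geometry)
  else if (inherits(voi, "box_voi")) rasterize_box(voi, geometry)
  else stop("unknown VOI type", call. = FALSE)
}

#' Is one mask a subset of another?
#' @param inner,outer Two `voxel_mask`s on the same geometry.
#' @return `TRUE` iff every member of `inner` is a member of `outer`.
#' @export
is_subset_mask <- function(inner, outer) {
  stopifnot(inherits(inner, "voxel_mask"), inherits(outer, "voxel_mask"))
  if (!same_geometry(inner$geometry, outer$geometry))
    stop("masks are on different geometries", call. = FALSE)
  !any(inner$members & !outer$members)
}

new_count_stats <- function(n_voxels, total_counts, voxel_vol_mm3) {
  mean_density <- if (n_voxels > 0) total_counts / n_voxels else NA_real_
  structure(list(n_voxels = as.integer(n_voxels),
                 total_counts = as.numeric(total_counts),
                 mean_density = mean_density,
                 size_ml = n_voxels * voxel_vol_mm3 / 1000),
            class = "count_stats")
}

#' @export
print.count_stats <- function(x, ...) {
  cat(sprintf("count_stats: %d voxels (%.2f mL), total %g counts, mean density %.4g counts/voxel\n",
              x$n_voxels, x$size_ml, x$total_counts, x$mean_density))
  invisible(x)
}

#' Count statistics of a volume over a voxel mask
#'
#' Aggregates the member voxels: total counts, mean counts per voxel
#' ("mean counts per pixel" extended to voxels) and VOI size in mL.
#'
#' @param volume A [volume_grid()].
#' @param mask A `voxel_mask` on the same geometry.
#' @return A `count_stats` object with fields `n_voxels`, `total_counts`,
#'   `mean_density` and `size_ml`.
#' @export
count_stats <- function(volume, mask) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "voxel_mask"))
  if (!same_geometry(volume$geometry, mask$geometry))
    stop("volume and mask geometries do not match", call. = FALSE)
  n <- sum(mask$members)
  if (n == 0L)
    stop("empty mask: VOI contains no voxel centres", call. = FALSE)
  new_count_stats(n, sum(volume$values[mask$members]),
                  voxel_volume_mm3(volume$geometry))
}

#' Myocardial wall statistics by lumen subtraction
#'
#' The myocardial wall is quantified as left-ventricular (heart VOI) counts
#' minus lumen counts. The caller must verify that the lumen mask is a subset
#' of the heart mask (see [is_subset_mask()]); the subtraction is refused
#' otherwise, rather than silently producing negative wall counts.
#'
#' @param heart,lumen `count_stats` for the heart and lumen VOIs on the same
#'   volume.
#' @param lumen_subset_of_heart Logical result of the subset verification.
#' @param voxel_vol_mm3 Voxel volume in mm^3 (needed to size the wall VOI).
#' @return A `count_stats` for the wall (heart minus lumen).
#' @export
wall_stats <- function(heart, lumen, lumen_subset_of_heart,
                       voxel_vol_mm3) {
  stopifnot(inherits(heart, "count_stats"), inherits(lumen, "count_stats"))
  if (!isTRUE(lumen_subset_of_heart))
    stop("lumen mask is not a subset of the heart mask; wall subtraction refused",
         call. = FALSE)
  n <- heart$n_voxels - lumen$n_voxels
  if (n <= 0L)
    stop("wall has no voxels (lumen VOI covers the entire heart VOI)",
         call. = FALSE)
  new_count_stats(n, heart$total_counts - lumen$total_counts, voxel_vol_mm3)
}

#' Check a box VOI size against the 10-15 cm^3 convention
#'
#' Box-shaped mediastinal/lung/liver VOIs are conventionally kept between 10
#' and 15 cm^3 (inclusive). Sizes outside that band trigger a warning, never
#' an error.
#'
#' @param stats A `count_stats` from a box VOI.
#' @param lower,upper Bounds in mL.
#' @return Invisibly, `TRUE` when within bounds, `FALSE` otherwise.
#' @export
validate_box_size <- function(stats, lower = 10, upper = 15) {
  stopifnot(inherits(stats, "count_stats"))
  ok <- stats$size_ml >= lower && stats$size_ml <= upper
  if (!ok)
    warning(sprintf("box VOI size %.1f mL outside the %g-%g cm^3 convention",
                    stats$size_ml, lower, upper), call. = FALSE)
  invisible(ok)
}

#' Read a named VOI set from a YAML or JSON config
#'
#' Each entry has `shape` (`"ellipsoid"` or `"box"`), `center_mm`, and either
#' `semi_axes_mm` (+ optional `rotation`, 9 row-major numbers) or `edge_mm`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [ellipsoid_voi()] / [box_voi()] objects.
#' @export
read_voi_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("VOI config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(names(cfg)) || any(names(cfg) == ""))
    stop("every VOI in the config must be named", call. = FALSE)
  lapply(cfg, function(v) {
    if (is.null(v$shape))
      stop("VOI entry missing 'shape'", call. = FALSE)
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
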