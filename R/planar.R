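#' Planar regions of interest
#'
#' 2D ROIs for anterior planar analysis, in physical mm coordinates (pixel
#' centre of index `(0, 0)` at the image origin). Three kinds are supported:
#' an explicit pixel mask, a polygon (e.g. a manually traced heart contour),
#' and an axis-aligned rectangle (the conventional mediastinal ROI).
#'
#' @param mask 2D logical array matching the image shape.
#' @param vertices Numeric matrix (>= 3 rows, 2 columns) of polygon vertices
#'   in mm, in drawing order (closed implicitly).
#' @param corner Numeric mm pair, the low corner of the rectangle.
#' @param size Positive mm pair of rectangle edge lengths.
#' @return An object of class `planar_roi`.
#' @name planar_roi
NULL

#' @rdname planar_roi
#' @export
planar_roi_mask <- function(mask) {
  mask <- as.array(mask)
  if (!is.logical(mask) || length(dim(mask)) != 2L)
    stop("mask must be a 2D logical array", call. = FALSE)
  structure(list(kind = "mask", mask = mask), class = "planar_roi")
}

#' @rdname planar_roi
#' @export
planar_roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("polygon needs >= 3 vertices with (x, y) mm columns", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("polygon vertices must be finite", call. = FALSE)
  structure(list(kind = "polygon", vertices = vertices), class = "planar_roi")
}

#' @rdname planar_roi
#' @export
planar_roi_rectangle <- function(corner, size) {
  corner <- as.numeric(corner); size <- as.numeric(size)
  stopifnot(length(corner) == 2L, length(size) == 2L)
  if (any(!is.finite(size)) || any(size <= 0))
    stop("rectangle size must be > 0 mm", call. = FALSE)
  structure(list(kind = "rectangle", corner = corner, size = size),
            class = "planar_roi")
}

#' @export
print.planar_roi <- function(x, ...) {
  cat(switch(x$kind,
    mask = sprintf("planar_roi (mask): %d member pixels\n", sum(x$mask)),
    polygon = sprintf("planar_roi (polygon): %d vertices\n", nrow(x$vertices)),
    rectangle = sprintf("planar_roi (rectangle): corner (%g, %g) mm, size (%g, %g) mm\n",
                        x$corner[1], x$corner[2], x$size[1], x$size[2])))
  invisible(x)
}

# even-odd (crossing number) point-in-polygon at pixel centres; points lying
# exactly on an edge are included
points_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-segment test via cross product + bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    if (seg_len > 0) {
      on_this <- abs(cross) <= eps * seg_len &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      on_edge <- on_edge | on_this
    }
    # crossing-number ray cast (half-open rule in y avoids double-counted vertices)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Rasterize a planar ROI to a pixel mask
#'
#' Polygon ROIs use pixel-centre even-odd rasterization with boundary pixels
#' (centre exactly on an edge) included; rectangles use closed bounds.
#'
#' @param roi A [planar_roi].
#' @param image A [planar_image()] defining the pixel lattice.
#' @return 2D logical array of member pixels.
#' @export
rasterize_roi <- function(roi, image) {
  stopifnot(inherits(roi, "planar_roi"), inherits(image, "planar_image"))
  xs <- image$origin[1] + (seq_len(image$shape[1]) - 1) * image$pixel_spacing[1]
  ys <- image$origin[2] + (seq_len(image$shape[2]) - 1) * image$pixel_spacing[2]
  switch(roi$kind,
    mask = {
      if (!identical(dim(roi$mask), dim(image$values)))
        stop("mask ROI shape does not match image shape", call. = FALSE)
      roi$mask
    },
    rectangle = {
      hi <- roi$corner + roi$size
      inx <- xs >= roi$corner[1] & xs <= hi[1]
      iny <- ys >= roi$corner[2] & ys <= hi[2]
      outer(inx, iny, "&")
    },
    polygon = {
      px <- rep(xs, times = image$shape[2])
      py <- rep(ys, each = image$shape[1])
      m <- points_in_polygon(px, py, roi$vertices[, 1], roi$vertices[, 2])
      array(m, image$shape)
    })
}

#' Mean counts per pixel over a planar ROI
#'
#' @param image A [planar_image()].
#' @param roi A [planar_roi] rasterizing to at least one pixel.
#' @return Mean counts per pixel over the member pixels.
#' @export
roi_mean_counts <- function(image, roi) {
  m <- rasterize_roi(roi, image)
  if (!any(m))
    stop("empty ROI: no pixel centre falls inside", call. = FALSE)
  mean(image$values[m])
}

#' Planar HM index report
#'
#' The planar counterpart of [spect_index_report()]: mean counts per pixel in
#' the heart and mediastinal ROIs on the early and delayed images, the
#' heart-to-mediastinum ratios `eH/eM` and `dH/dM`, the washout rate with the
#' study decay factor, and per-ROI organ washout.
#'
#' @param pair A [study_pair()] of planar images.
#' @param heart_roi,mediastinum_roi [planar_roi]s valid on both images.
#' @return An object of class `planar_report` with the same layout as a
#'   `spect_report` (single combination `"HM"`).
#' @export
planar_index_report <- function(pair, heart_roi, mediastinum_roi) {
  stopifnot(inherits(pair, "study_pair"), inherits(pair$early, "planar_image"))
  f <- decay_factor(pair$delta_t_h, pair$half_life_h)
  eH <- roi_mean_counts(pair$early, heart_roi)
  eM <- roi_mean_counts(pair$early, mediastinum_roi)
  dH <- roi_mean_counts(pair$delayed, heart_roi)
  dM <- roi_mean_counts(pair$delayed, mediastinum_roi)
  w <- washout_rate_flagged(eH, eM, dH, dM, f)
  report <- new_index_report("HM", uptake_ratio(eH, eM), uptake_ratio(dH, dM),
                             w$wor, w$flag)
  n_pix <- function(roi) sum(rasterize_roi(roi, pair$early))
  pix_ml <- prod(pair$early$pixel_spacing) / 1000  # mm^2 -> "area mL" proxy
  stats <- data.frame(
    voi = c("heart", "mediastinum"),
    early_mean_density = c(eH, eM), delayed_mean_density = c(dH, dM),
    early_total = c(eH, eM) * c(n_pix(heart_roi), n_pix(mediastinum_roi)),
    delayed_total = c(dH, dM) * c(n_pix(heart_roi), n_pix(mediastinum_roi)),
    size_ml = pix_ml * c(n_pix(heart_roi), n_pix(mediastinum_roi)),
    row.names = NULL)
  washouts <- c(heart = organ_washout(eH, dH, f),
                mediastinum = organ_washout(eM, dM, f))
  structure(list(combinations = list(HM = report), organ_washouts = washouts,
                 stats = stats, decay_factor = f),
            class = c("planar_report", "spect_report"))
}

#' Project a volume to an anterior planar image
#'
#' Sums counts along one grid axis, producing the test-harness analogue of an
#' anterior planar acquisition (no attenuation or depth weighting). Total
#' counts are conserved exactly.
#'
#' @param volume A [volume_grid()].
#' @param axis `"x"`, `"y"` or `"z"`: the axis summed over.
#' @return A [planar_image()] with pixel spacing inherited from the two
#'   remaining axes (in order) and the acquisition time preserved.
#' @export
anterior_projection <- function(volume, axis = "y") {
  stopifnot(inherits(volume, "volume_grid"))
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax))
    stop("axis must be one of 'x', 'y', 'z'", call. = FALSE)
  keep <- setdiff(1:3, ax)
  vals <- apply(volume$values, keep, sum)
  planar_image(vals, volume$geometry$spacing[keep],
               origin = volume$geometry$origin[keep],
               acquisition_time_h = volume$acquisition_time_h,
               label = volume$label)
}

#' Read planar ROIs from a YAML or JSON config
#'
#' Entries have `kind` (`"polygon"` or `"rectangle"`), with `vertices_mm`
#' (list of (x, y) pairs) or `corner_mm` + `size_mm`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [planar_roi] objects.
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ROI config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  lapply(cfg, function(r) {
    switch(r$kind,
      polygon = planar_roi_polygon(matrix(as.numeric(unlist(r$vertices_mm)),
                                          ncol = 2, byrow = TRUE)),
      rectangle = planar_roi_rectangle(unlist(r$corner_mm), unlist(r$size_mm)),
      stop(sprintf("unknown ROI kind '%s'", r$kind), call. = FALSE))
  })
}
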