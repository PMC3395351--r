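#' Read a 3D SPECT volume from a NIfTI file
#'
#' Reads a NIfTI-1 volume, takes the voxel spacing from the header and the
#' acquisition time from a JSON sidecar (`<path-without-.nii/.nii.gz>.json`
#' with a field `acquisition_time_h`) when present. Volumes containing NaN,
#' infinite or negative values are rejected: reconstructed count data must be
#' finite and nonnegative.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing 3D data.
#' @param acquisition_time_h Optional override for the acquisition time in
#'   hours post-injection; when `NULL`, the sidecar value is used, else 0.
#' @param label Optional override for the volume label; the sidecar field
#'   `label` is used when present.
#' @return A [volume_grid()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, acquisition_time_h = NULL, label = NULL) {
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  nd <- length(dim(values))
  if (nd == 4L && dim(values)[4] == 1L) {
    values <- array(values, dim(values)[1:3])
  } else if (nd != 3L) {
    stop(sprintf("expected 3D volume, got %dD data in %s", nd, path),
         call. = FALSE)
  }
  values <- array(as.vector(values), dim(values))  # drop NIfTI attributes
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("missing or invalid voxel spacing in %s", path), call. = FALSE)
  check_counts(values)

  meta <- read_sidecar(path)
  t_h <- if (!is.null(acquisition_time_h)) acquisition_time_h
         else if (!is.null(meta$acquisition_time_h)) meta$acquisition_time_h
         else 0
  lab <- if (!is.null(label)) label
         else if (!is.null(meta$label)) meta$label
         else "other"
  volume_grid(values, grid_geometry(dim(values), spacing),
              acquisition_time_h = t_h, label = lab)
}

#' Write a 3D volume to a NIfTI file
#'
#' Writes the volume as double-precision NIfTI (lossless for finite values)
#' with the voxel spacing in the header, plus a JSON sidecar carrying
#' `acquisition_time_h` and `label`.
#'
#' @param volume A [volume_grid()].
#' @param path Destination `.nii` or `.nii.gz` path; the parent directory
#'   must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$geometry$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  write_sidecar(path, list(acquisition_time_h = volume$acquisition_time_h,
                           label = volume$label))
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (identical(sc, path) || !file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

write_sidecar <- function(path, meta) {
  sc <- sidecar_path(path)
  if (identical(sc, path)) return(invisible(NULL))
  jsonlite::write_json(meta, sc, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Read a 2D planar image from a NIfTI file
#'
#' @param path Path to a NIfTI file with 2D data (or 3D with a singleton
#'   third dimension).
#' @param acquisition_time_h Optional override, hours post-injection.
#' @param label Optional label override.
#' @return A [planar_image()].
#' @export
read_planar <- function(path, acquisition_time_h = NULL, label = NULL) {
  if (!file.exists(path))
    stop(sprintf("planar image file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  d <- dim(values)
  if (length(d) == 3L && d[3] == 1L) values <- array(values, d[1:2])
  if (length(dim(values)) != 2L)
    stop(sprintf("expected 2D planar image in %s", path), call. = FALSE)
  values <- array(as.vector(values), dim(values))  # drop NIfTI attributes
  spacing <- abs(RNifti::pixdim(img))[1:2]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("missing or invalid pixel spacing in %s", path), call. = FALSE)
  check_counts(values, "pixel")
  meta <- read_sidecar(path)
  t_h <- if (!is.null(acquisition_time_h)) acquisition_time_h
         else if (!is.null(meta$acquisition_time_h)) meta$acquisition_time_h
         else 0
  lab <- if (!is.null(label)) label
         else if (!is.null(meta$label)) meta$label
         else "other"
  planar_image(values, spacing, acquisition_time_h = t_h, label = lab)
}

#' Write a 2D planar image to a NIfTI file
#'
#' @param image A [planar_image()].
#' @param path Destination path; parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_planar <- function(image, path) {
  stopifnot(inherits(image, "planar_image"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: %s", dirname(path)),
         call. = FALSE)
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- image$pixel_spacing
  RNifti::writeNifti(img, path, datatype = "double")
  write_sidecar(path, list(acquisition_time_h = image$acquisition_time_h,
                           label = image$label))
  invisible(path)
}

#' Write a voxel mask as a NIfTI file (for QC overlay)
#'
#' @param mask A [voxel_mask][rasterize_ellipsoid()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$members),
                               dim = mask$geometry$shape))
  RNifti::pixdim(img) <- mask$geometry$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
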