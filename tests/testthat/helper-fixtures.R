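# small phantom fitting the whole anatomy on a coarse grid: fast to paint,
# same organ layout as the default spec
small_phantom_spec <- function(spacing = 6.6, ...) {
  args <- list(geometry = grid_geometry(c(64, 64, 32), rep(spacing, 3)),
               psf_fwhm_mm = 0, poisson_noise = FALSE)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# tiny uniform volume for IO / stats tests
uniform_volume <- function(value = 5, n = c(8, 8, 8), spacing = c(2, 2, 2),
                           t_h = 0.25, label = "early") {
  volume_grid(array(value, n), grid_geometry(n, spacing),
              acquisition_time_h = t_h, label = label)
}

# brute-force triple-loop ellipsoid rasterization oracle (identity rotation)
brute_force_ellipsoid <- function(center, semi_axes, geometry) {
  n <- geometry$shape
  members <- array(FALSE, n)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    cxyz <- geometry$origin + (c(i, j, k) - 1) * geometry$spacing
    members[i, j, k] <- sum(((cxyz - center) / semi_axes)^2) <= 1
  }
  members
}

# random orthonormal rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
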