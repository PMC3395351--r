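test_that("a sub-voxel ellipsoid on a voxel centre captures exactly that voxel", {
  g <- grid_geometry(c(11, 11, 11), c(1, 1, 1))
  m <- rasterize_ellipsoid(ellipsoid_voi(c(5, 5, 5), c(0.6, 0.6, 0.6)), g)
  expect_equal(sum(m$members), 1)
  expect_true(m$members[6, 6, 6])
})

test_that("rasterized sphere matches the brute-force oracle and analytic volume", {
  g <- grid_geometry(c(13, 13, 13), c(1, 1, 1))
  voi <- ellipsoid_voi(c(6, 6, 6), c(5, 5, 5))
  mask <- rasterize_ellipsoid(voi, g)
  oracle <- brute_force_ellipsoid(c(6, 6, 6), c(5, 5, 5), g)
  expect_identical(mask$members, oracle)
  expect_lt(abs(sum(mask$members) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
})

test_that("sphere rasterization is rotation invariant", {
  g <- grid_geometry(c(15, 15, 15), c(1.5, 1.5, 1.5))
  set.seed(5)
  # centre off the lattice so no voxel centre sits exactly on the surface
  ctr <- c(10.2, 10.1, 9.9)
  base <- rasterize_ellipsoid(ellipsoid_voi(ctr, c(6, 6, 6)), g)
  for (i in 1:3) {
    rot <- rasterize_ellipsoid(
      ellipsoid_voi(ctr, c(6, 6, 6), random_rotation()), g)
    expect_identical(rot$members, base$members)
  }
})

test_that("rotated ellipsoid equals brute-force evaluation of the quadratic form", {
  set.seed(8)
  R <- random_rotation()
  g <- grid_geometry(c(12, 12, 12), c(2, 2, 2))
  voi <- ellipsoid_voi(c(11, 11, 11), c(8, 5, 3), R)
  mask <- rasterize_ellipsoid(voi, g)
  oracle <- array(FALSE, g$shape)
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    d <- t(R) %*% ((c(i, j, k) - 1) * 2 - voi$center)
    oracle[i, j, k] <- sum((d / c(8, 5, 3))^2) <= 1
  }
  expect_identical(mask$members, oracle)
})

test_that("box rasterization reproduces exact lattice counts", {
  # 20 x 25 x 30 mm box, faces midway between voxel centres of a 1 mm grid
  g <- grid_geometry(c(40, 40, 40), c(1, 1, 1))
  # per-axis centres chosen so every face falls midway between voxel centres
  m <- rasterize_box(box_voi(c(19.5, 20, 19.5), c(20, 25, 30)), g)
  expect_equal(sum(m$members), 20 * 25 * 30)

  # 10 mm cube on a 2 mm grid, centred on a voxel centre
  g2 <- grid_geometry(c(11, 11, 11), c(2, 2, 2))
  m2 <- rasterize_box(box_voi(c(10, 10, 10), c(10, 10, 10)), g2)
  expect_equal(sum(m2$members), 125)
  vol <- uniform_volume(1, c(11, 11, 11), c(2, 2, 2))
  expect_equal(count_stats(vol, m2)$size_ml, 1.0)
})

test_that("a box outside the grid warns and yields an empty mask", {
  g <- grid_geometry(c(10, 10, 10), c(1, 1, 1))
  expect_warning(m <- rasterize_box(box_voi(c(100, 100, 100), c(5, 5, 5)), g),
                 "clipped")
  expect_equal(sum(m$members), 0)
  vol <- uniform_volume(1, c(10, 10, 10), c(1, 1, 1))
  expect_error(count_stats(vol, m), "empty mask")
})

test_that("ellipsoid volume error shrinks when the grid is refined", {
  f_err <- function(spacing) {
    n <- ceiling(26 / spacing)
    g <- grid_geometry(rep(n, 3), rep(spacing, 3))
    c0 <- rep((n - 1) * spacing / 2, 3)
    m <- rasterize_ellipsoid(ellipsoid_voi(c0, c(10, 10, 10)), g)
    abs(sum(m$members) * spacing^3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000)
  }
  expect_lt(f_err(1), f_err(2))
})

test_that("masks are invariant under joint VOI/origin translation", {
  shift <- c(4.2, -1.7, 0.9)
  g1 <- grid_geometry(c(12, 12, 12), c(1.5, 1.5, 1.5))
  g2 <- grid_geometry(c(12, 12, 12), c(1.5, 1.5, 1.5), origin = shift)
  for (voi_pair in list(
    list(ellipsoid_voi(c(8, 8, 8), c(5, 4, 3)),
         ellipsoid_voi(c(8, 8, 8) + shift, c(5, 4, 3))),
    list(box_voi(c(8, 8, 8), c(6, 7, 8)),
         box_voi(c(8, 8, 8) + shift, c(6, 7, 8))))) {
    m1 <- rasterize_voi(voi_pair[[1]], g1)
    m2 <- rasterize_voi(voi_pair[[2]], g2)
    expect_identical(m1$members, m2$members)
  }
})

test_that("count_stats aggregates totals, densities and sizes", {
  vol <- uniform_volume(5, c(10, 10, 10), c(2, 2, 2))
  m <- rasterize_box(box_voi(c(9, 9, 9), c(8, 8, 8)), vol$geometry)
  st <- count_stats(vol, m)
  expect_equal(st$total_counts, 5 * st$n_voxels)
  expect_equal(st$mean_density, 5)
  expect_equal(st$size_ml, st$n_voxels * 8 / 1000)

  zero <- uniform_volume(0, c(10, 10, 10), c(2, 2, 2))
  st0 <- count_stats(zero, m)
  expect_equal(st0$total_counts, 0)
  expect_equal(st0$mean_density, 0)

  other <- uniform_volume(1, c(10, 10, 10), c(3, 3, 3))
  expect_error(count_stats(other, m), "geometries do not match")
})

test_that("VOI totals never exceed the whole-volume total", {
  set.seed(12)
  g <- grid_geometry(c(14, 14, 14), c(2, 2, 2))
  vol <- volume_grid(array(rpois(14^3, 6), rep(14, 3)), g)
  for (i in 1:5) {
    voi <- ellipsoid_voi(runif(3, 5, 20), runif(3, 2, 20))
    m <- suppressWarnings(rasterize_ellipsoid(voi, g))
    if (sum(m$members) == 0) next
    expect_lte(count_stats(vol, m)$total_counts, sum(vol$values))
  }
})

test_that("wall subtraction conserves counts and enforces containment", {
  heart <- structure(list(n_voxels = 120L, total_counts = 1000,
                          mean_density = 1000 / 120, size_ml = 1),
                     class = "count_stats")
  lumen <- structure(list(n_voxels = 20L, total_counts = 200,
                          mean_density = 10, size_ml = 0.2),
                     class = "count_stats")
  wall <- wall_stats(heart, lumen, TRUE, 8)
  expect_equal(wall$total_counts, 800)
  expect_equal(wall$n_voxels, 100L)
  expect_equal(wall$mean_density, 8)
  # conservation: wall + lumen = heart
  expect_equal(wall$total_counts + lumen$total_counts, heart$total_counts)
  expect_error(wall_stats(heart, lumen, FALSE, 8), "not a subset")
  expect_error(wall_stats(heart, heart, TRUE, 8), "no voxels")
})

test_that("wall/lumen/heart count conservation holds on rasterized masks", {
  set.seed(21)
  g <- grid_geometry(c(16, 16, 16), c(2, 2, 2))
  vol <- volume_grid(array(rpois(16^3, 9), rep(16, 3)), g)
  hm <- rasterize_ellipsoid(ellipsoid_voi(c(15, 15, 15), c(12, 12, 12)), g)
  lm <- rasterize_ellipsoid(ellipsoid_voi(c(15, 15, 15), c(6, 6, 6)), g)
  expect_true(is_subset_mask(lm, hm))
  h <- count_stats(vol, hm); l <- count_stats(vol, lm)
  w <- wall_stats(h, l, is_subset_mask(lm, hm), voxel_volume_mm3(g))
  expect_identical(w$total_counts + l$total_counts, h$total_counts)
})

test_that("box size validation warns outside 10-15 cm^3, inclusive bounds pass", {
  mk <- function(size_ml) structure(list(n_voxels = 1L, total_counts = 1,
                                         mean_density = 1, size_ml = size_ml),
                                    class = "count_stats")
  expect_silent(validate_box_size(mk(12.7)))
  expect_silent(validate_box_size(mk(15.0)))
  expect_silent(validate_box_size(mk(10.0)))
  expect_warning(validate_box_size(mk(9.9)), "outside")
  expect_warning(validate_box_size(mk(15.1)), "outside")
})

test_that("VOI configs round-trip through YAML", {
  cfg <- list(
    heart = list(shape = "ellipsoid", center_mm = c(10, 20, 30),
                 semi_axes_mm = c(5, 6, 7)),
    tilted = list(shape = "ellipsoid", center_mm = c(1, 2, 3),
                  semi_axes_mm = c(4, 4, 2),
                  rotation = c(0, -1, 0, 1, 0, 0, 0, 0, 1)),
    med = list(shape = "box", center_mm = c(0, 0, 0), edge_mm = c(20, 25, 30)))
  path <- file.path(tempdir(), "vois.yaml")
  yaml::write_yaml(cfg, path)
  vois <- read_voi_config(path)
  expect_s3_class(vois$heart, "ellipsoid_voi")
  expect_s3_class(vois$med, "box_voi")
  expect_equal(vois$heart$semi_axes, c(5, 6, 7))
  expect_equal(vois$tilted$rotation,
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  expect_equal(vois$med$edge_lengths, c(20, 25, 30))
})
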