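test_that("generative inversion: indices recover configured truth exactly", {
  spec <- small_phantom_spec()
  st <- generate_study(spec)
  v <- phantom_vois(spec, "matched")
  rep <- suppressWarnings(
    spect_index_report(st$pair, v$heart, v$lumen, v$mediastinum, v$lung, v$liver))
  tr <- st$truth
  expect_equal(rep$combinations$ML$early_ratio, tr$ratio_myocardium_lumen,
               tolerance = 1e-12)
  expect_equal(rep$combinations$MM$early_ratio, tr$ratio_myocardium_background,
               tolerance = 1e-12)
  expect_equal(unname(rep$organ_washouts["wall"]),
               unname(tr$washout["myocardium"]), tolerance = 1e-12)
  expect_equal(unname(rep$organ_washouts["lumen"]),
               unname(tr$washout["lumen"]), tolerance = 1e-12)
  expect_equal(unname(rep$organ_washouts["mediastinum"]),
               unname(tr$washout["background"]), tolerance = 1e-12)
  expect_equal(unname(rep$organ_washouts["lung"]),
               unname(tr$washout["lung"]), tolerance = 1e-12)
  expect_equal(unname(rep$organ_washouts["liver"]),
               unname(tr$washout["liver"]), tolerance = 1e-12)
})

test_that("zero biological washout gives delayed = decay-scaled early exactly", {
  spec <- small_phantom_spec(
    washout = c(myocardium = 0, lumen = 0, liver = 0, lung = 0, background = 0))
  st <- generate_study(spec)
  f <- st$truth$decay_factor
  expect_equal(st$pair$delayed$values, st$pair$early$values * f,
               tolerance = 1e-12)
})

test_that("a configured lung washout is recovered to machine precision", {
  spec <- small_phantom_spec(
    washout = c(myocardium = 0, lumen = 0, liver = 0, lung = 0.3,
                background = 0))
  st <- generate_study(spec)
  v <- phantom_vois(spec, "matched")
  f <- st$truth$decay_factor
  lung_mask <- rasterize_box(v$lung, spec$geometry)
  w <- organ_washout(count_stats(st$pair$early, lung_mask)$mean_density,
                     count_stats(st$pair$delayed, lung_mask)$mean_density, f)
  expect_equal(w, 0.3, tolerance = 1e-12)
})

test_that("noise is reproducible by seed and varies across seeds", {
  s1 <- small_phantom_spec(poisson_noise = TRUE, seed = 77)
  a <- generate_study(s1)
  b <- generate_study(s1)
  expect_identical(a$pair$early$values, b$pair$early$values)
  expect_identical(a$pair$delayed$values, b$pair$delayed$values)
  s2 <- small_phantom_spec(poisson_noise = TRUE, seed = 78)
  c <- generate_study(s2)
  expect_false(identical(a$pair$early$values, c$pair$early$values))
  # equal expectation: totals agree within Poisson sampling error
  tot_a <- sum(a$pair$early$values); tot_c <- sum(c$pair$early$values)
  expect_lt(abs(tot_a - tot_c), 6 * sqrt(tot_a))
})

test_that("Gaussian blur conserves counts for interior objects", {
  # hot object >= 3 FWHM from every boundary: total mass conserved < 0.1%
  arr <- array(0, c(34, 34, 34))
  arr[13:22, 13:22, 13:22] <- 50
  bl <- gaussian_blur3(arr, c(3.3, 3.3, 3.3), 15)
  expect_lt(abs(sum(bl) - sum(arr)) / sum(arr), 1e-3)
  # kernel is normalized: uniform array unchanged away from edges
  u <- array(3, c(21, 21, 21))
  bl2 <- gaussian_blur3(u, c(3, 3, 3), 10)
  expect_equal(bl2[11, 11, 11], 3, tolerance = 1e-9)
})

test_that("blur against a dense brute-force separable convolution oracle", {
  set.seed(50)
  arr <- array(runif(8 * 7 * 6), c(8, 7, 6))
  spacing <- c(2, 3, 4); fwhm <- 6
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  oracle <- arr
  for (ax in 1:3) {
    s_vox <- sigma / spacing[ax]
    r <- max(1, ceiling(4 * s_vox))
    kern <- dnorm(seq(-r, r), sd = s_vox); kern <- kern / sum(kern)
    out <- array(0, dim(oracle))
    for (i in seq_len(dim(oracle)[1]))
      for (j in seq_len(dim(oracle)[2]))
        for (k in seq_len(dim(oracle)[3]))
          for (o in seq(-r, r)) {
            idx <- c(i, j, k); idx[ax] <- idx[ax] + o
            if (idx[ax] >= 1 && idx[ax] <= dim(oracle)[ax])
              out[i, j, k] <- out[i, j, k] +
                kern[o + r + 1] * oracle[idx[1], idx[2], idx[3]]
          }
    oracle <- out
  }
  expect_equal(gaussian_blur3(arr, spacing, fwhm), oracle, tolerance = 1e-12)
})

test_that("spill-out: blur never increases the measured HM ratio", {
  hm_at <- function(fwhm) {
    spec <- small_phantom_spec(psf_fwhm_mm = fwhm)
    st <- generate_study(spec)
    v <- phantom_vois(spec, "clinical")
    rep <- suppressWarnings(
      spect_index_report(st$pair, v$heart, v$lumen, v$mediastinum, v$lung,
                         v$liver))
    rep$combinations$HM$early_ratio
  }
  hms <- vapply(c(0, 7.5, 15), hm_at, numeric(1))
  expect_true(all(diff(hms) <= 1e-9))
})

test_that("recovery experiment: zero jitter and no noise gives CV 0", {
  spec <- small_phantom_spec()
  rec <- recovery_experiment(spec, n_replicates = 3, voi_jitter_mm = 0,
                             seed = 5)
  cvs <- rec$agreement$cv_percent
  expect_true(all(cvs[is.finite(cvs)] == 0))
})

test_that("Poisson relative error: hot organs have lower density CV than cold", {
  spec <- phantom_spec(poisson_noise = TRUE, psf_fwhm_mm = 0)
  rec <- recovery_experiment(spec, n_replicates = 8, voi_jitter_mm = 0,
                             seed = 6, resample_noise = TRUE)
  a <- rec$agreement
  cv_of <- function(q) a$cv_percent[a$quantity == q]
  expect_lt(cv_of("heart_early_density"), cv_of("mediastinum_early_density"))
})

test_that("phantom spec validation", {
  expect_error(small_phantom_spec(densities = c(myocardium = -1, lumen = 5,
                                                liver = 28, lung = 12.8,
                                                background = 4.8)),
               ">= 0")
  expect_error(small_phantom_spec(washout = c(myocardium = 1.2, lumen = 0,
                                              liver = 0, lung = 0,
                                              background = 0)),
               "<= 1")
  expect_error(phantom_spec(heart_inner = ellipsoid_voi(c(165, 215, 115),
                                                        c(60, 60, 50))),
               "inside")
  expect_error(small_phantom_spec(early_time_h = 4, delayed_time_h = 2),
               "exceed")
})
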