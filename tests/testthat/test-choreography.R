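test_that("profile normalisation maps min-max to 0-1 and is affine invariant", {
  expect_equal(as.numeric(normalize_profile(c(2, 4, 6))), c(0, 0.5, 1))
  p <- c(1, 5, 2, 8, 3)
  expect_equal(as.numeric(normalize_profile(3.2 * p + 7)),
               as.numeric(normalize_profile(p)))
  const <- normalize_profile(rep(4, 5))
  expect_equal(as.numeric(const), rep(0, 5))
  expect_true(attr(const, "constant"))
})

test_that("long-axis profiles localise intensity along the cell", {
  # synthetic region: horizontal 60 x 11 px rectangle
  dim_img <- c(21, 80)
  px_idx <- as.vector(outer((5:15) + 1, (10:69) * dim_img[1], "+"))
  region <- difcycle:::region_props(px_idx, dim_img, 0.064, 1L)
  img <- matrix(2, dim_img[1], dim_img[2])
  expect_equal(as.numeric(long_axis_profile(img, region, 20)), rep(2, 20))
  # single bright spot at relative x = 0.25
  img2 <- img
  img2[11, 10 + 15 + 1] <- 100
  p <- as.numeric(long_axis_profile(img2, region, 20))
  expect_identical(which.max(p), 6L)   # floor(0.25 * 20) + 1
  expect_error(long_axis_profile(img, dplyr::mutate(region,
                                                    pixels = list(integer(0))),
                                 10),
               "zero area")
})

test_that("kymographs resample oriented, normalised profiles onto the grid", {
  # stationary mid-cell spot: single ridge at the central column
  profiles <- lapply(1:8, function(i) {
    p <- rep(0, 21); p[11] <- 5; p
  })
  ky <- cycle_kymograph(profiles, old_pole_low = TRUE, grid = c(11, 21),
                        channel = "fluor")
  expect_identical(dim(unclass(ky)), c(11L, 21L))
  expect_true(all(apply(ky, 1, which.max) == 11))
  expect_true(all(abs(apply(ky, 1, max) - 1) < 1e-12))
  expect_true(all(apply(ky, 1, min) == 0))

  # native grid: resampling is the identity up to interpolation tolerance
  set.seed(1)
  profs <- lapply(1:9, function(i) runif(31))
  ky2 <- cycle_kymograph(profs, old_pole_low = TRUE, grid = c(9, 31))
  manual <- t(vapply(profs, function(p) as.numeric(normalize_profile(p)),
                     numeric(31)))
  expect_equal(unclass(ky2), manual, tolerance = 1e-9,
               ignore_attr = TRUE)

  # orientation: old pole at the high axis end reverses columns
  ky3 <- cycle_kymograph(profs, old_pole_low = FALSE, grid = c(9, 31))
  expect_equal(unclass(ky3), manual[, 31:1], tolerance = 1e-9,
               ignore_attr = TRUE)

  # per-frame positive affine rescaling leaves the kymograph unchanged
  profs_aff <- lapply(seq_along(profs), function(i) 2 * i * profs[[i]] + i)
  ky4 <- cycle_kymograph(profs_aff, old_pole_low = TRUE, grid = c(9, 31))
  expect_equal(unclass(ky4), unclass(ky2), tolerance = 1e-12)

  expect_error(cycle_kymograph(profs, old_pole_low = NA), "polarity")
  expect_error(cycle_kymograph(profs[1], old_pole_low = TRUE),
               "at least 2")
})

test_that("consensus images are idempotent equal-weight means", {
  set.seed(2)
  a <- cycle_kymograph(lapply(1:5, function(i) runif(11)),
                       old_pole_low = TRUE, grid = c(5, 11))
  b <- cycle_kymograph(lapply(1:5, function(i) runif(11)),
                       old_pole_low = TRUE, grid = c(5, 11))
  expect_equal(unclass(consensus_image(list(a))), unclass(a),
               ignore_attr = TRUE)
  expect_equal(unclass(consensus_image(list(a, a))), unclass(a),
               ignore_attr = TRUE)
  cons <- consensus_image(list(a, b))
  expect_equal(unclass(cons), (unclass(a) + unclass(b)) / 2,
               ignore_attr = TRUE)
  expect_identical(attr(cons, "n_cells"), 2L)
  expect_true(all(cons >= 0 & cons <= 1))
  expect_error(consensus_image(list()), "non-empty")
  bad <- cycle_kymograph(lapply(1:5, function(i) runif(11)),
                         old_pole_low = TRUE, grid = c(6, 11))
  expect_error(consensus_image(list(a, bad)), "one grid")
})

test_that("septation detection ignores flat and monotone profiles", {
  set.seed(3)
  flat <- lapply(1:6, function(i) 30 + rnorm(41, sd = 0.3))
  expect_null(detect_septation(flat))
  ramp <- lapply(1:6, function(i) seq(10, 20, length.out = 41))
  expect_null(detect_septation(ramp))
  expect_error(detect_septation(flat[1:2]), "at least 3")
})

test_that("septation calls a persistent mid-cell dip and is time-translation invariant", {
  base <- rep(30, 41)
  dipped <- base
  dipped[18:24] <- 30 - c(2, 5, 8, 9, 8, 5, 2)
  profiles <- c(replicate(4, base, simplify = FALSE),
                replicate(3, dipped, simplify = FALSE))
  call <- detect_septation(profiles)
  expect_identical(call$sept_frame, 4L)
  expect_gt(call$position, 0.35)
  expect_lt(call$position, 0.65)
  # shifting the series shifts the call equally
  shifted <- c(replicate(2, base, simplify = FALSE), profiles)
  call2 <- detect_septation(shifted)
  expect_identical(call2$sept_frame, 6L)
  # single-frame classifier agrees frame by frame
  expect_false(has_constriction(base))
  expect_true(has_constriction(dipped))
})

test_that("consensus split time estimates the median separation fraction", {
  # synthetic kymographs: ridge at centre before an individual split row,
  # twin ridges after; split rows spread around 60% of the cycle
  mk <- function(split_frac) {
    profs <- lapply(seq(0, 1, length.out = 21), function(f) {
      p <- rep(0, 41)
      ridge <- c(0.4, 0.8, 1, 0.8, 0.4)    # psf-like ridge width
      if (f < split_frac) p[19:23] <- ridge else {
        p[11:15] <- ridge; p[27:31] <- ridge
      }
      p
    })
    cycle_kymograph(profs, old_pole_low = TRUE, grid = c(41, 41))
  }
  splits <- seq(0.5, 0.7, length.out = 11)
  cons <- consensus_image(lapply(splits, mk))
  est <- estimate_split_time(cons)
  expect_equal(est, median(splits), tolerance = 0.05)
  # a never-splitting population returns NA
  cons1 <- consensus_image(lapply(rep(1.01, 5), mk))
  expect_true(is.na(estimate_split_time(cons1)))
})
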