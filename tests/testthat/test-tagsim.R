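test_that("square-root contrast conversion is monotone and fixes the endpoints", {
  img <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  out <- contrast_transform(img)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 2], 1)
  expect_equal(out[2, 1], 0.5)  # sqrt(0.25)
  set.seed(11)
  x <- matrix(runif(100), 10, 10)
  o <- contrast_transform(x)
  expect_true(all((order(x) == order(o))))
})

test_that("SPAMM profile matches the explicit rotation-matrix oracle", {
  set.seed(42)
  for (i in 1:25) {
    psi <- runif(5, 0, 2 * pi)
    flip <- runif(1, 0, 180)
    w <- runif(sample(2:5, 1), 0.2, 4)
    expect_equal(simulate_spamm_profile(psi, flip, w),
                 spamm_matrix_oracle(psi, flip, w), tolerance = 1e-12)
  }
})

test_that("coherent phase gives Mz = cos(total flip); 1-1 90-degree prep matches its closed form", {
  set.seed(3)
  for (i in 1:10) {
    w <- runif(sample(2:6, 1), 0.1, 5)
    flip <- runif(1, 0, 180)
    expect_equal(simulate_spamm_profile(0, flip, w), cos(flip * pi / 180),
                 tolerance = 1e-12)
  }
  psi <- seq(0, 2 * pi, length.out = 33)
  expect_equal(simulate_spamm_profile(psi, 90, c(1, 1)), (1 - cos(psi)) / 2,
               tolerance = 1e-12)
  # magnetization stays on or inside the unit sphere
  mz <- simulate_spamm_profile(runif(200, 0, 2 * pi), 70, c(1, 3, 3, 1))
  expect_true(all(abs(mz) <= 1 + 1e-12))
})

test_that("zero flip leaves the magnetization and the image untouched", {
  cfg <- tag_config(total_flip_deg = 0)
  expect_equal(simulate_spamm_profile(seq(0, 6, 0.5), 0), rep(1, 13))
  expect_equal(make_grid_pattern(c(12, 17), cfg), matrix(1, 12, 17))

  set.seed(5)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- random_mask(32, 32)
  out <- transform_cine_to_tagged(img, mask, 0, cfg)
  expect_equal(out$image, contrast_transform(img))
  expect_identical(out$mask, mask)
})

test_that("grid pattern is separable at zero rotation and periodic in spacing", {
  cfg <- tag_config(rotation_deg = 0, spacing_px = 5)
  pat <- make_grid_pattern(c(20, 20), cfg)
  prof <- simulate_spamm_profile(2 * pi * (0:19) / 5, 70, c(1, 3, 3, 1))
  expect_equal(pat, outer(prof, prof), tolerance = 1e-12)
  # exact periodicity along both axes at the tag spacing
  expect_equal(pat[1:15, ], pat[6:20, ], tolerance = 1e-12)
  expect_equal(pat[, 1:15], pat[, 6:20], tolerance = 1e-12)
  # profile itself is 2*pi-periodic in the precession phase
  psi <- seq(0, 2 * pi, length.out = 11)
  expect_equal(simulate_spamm_profile(psi, 70), simulate_spamm_profile(psi + 2 * pi, 70),
               tolerance = 1e-12)
})

test_that("default rotated grid shows the 5-px tag period and a dark origin", {
  cfg <- tag_config()
  pat <- make_grid_pattern(c(128, 128), cfg)
  expect_equal(measure_tag_period(abs(pat), rotation_deg = 45), 5)
  # pixel (1,1) is a phase-zero point: both preps fully saturated there
  expect_equal(pat[1, 1], cos(70 * pi / 180)^2, tolerance = 1e-12)
})

test_that("T1 fading relaxes toward unity and never increases tag contrast", {
  cfg <- tag_config(fade_enabled = TRUE, t1_ms = 850, frame_interval_ms = 40)
  pat <- make_grid_pattern(c(32, 32), cfg)
  expect_equal(apply_fading(pat, 0, cfg), pat)
  # at t = T1 each pixel has decayed by exactly 1/e
  f_t1 <- apply_fading(pat, 850 / 40, cfg)
  expect_equal(f_t1, 1 + (pat - 1) / exp(1), tolerance = 1e-12)
  contrasts <- vapply(0:60, function(f) {
    fp <- apply_fading(pat, f, cfg)
    max(fp) - min(fp)
  }, numeric(1))
  expect_true(all(diff(contrasts) <= 1e-12))
  expect_lt(contrasts[61], 0.1 * contrasts[1])
  # fading disabled: untouched at any frame
  cfg_off <- tag_config(fade_enabled = FALSE)
  expect_identical(apply_fading(pat, 10, cfg_off), pat)
})

test_that("transformation transfers the mask untouched and keeps tags static across frames", {
  cfg <- tag_config()
  set.seed(9)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- random_mask(64, 64)
  o1 <- transform_cine_to_tagged(img, mask, 0, cfg)
  o2 <- transform_cine_to_tagged(img, mask, 12, cfg)
  expect_identical(o1$mask, mask)
  expect_identical(o2$mask, mask)
  expect_equal(o1$image, o2$image)  # no fading: static tags
  expect_true(all(o1$image >= 0 & o1$image <= 1))
  expect_error(transform_cine_to_tagged(img, mask[1:10, 1:10]), "grid mismatch")
})

test_that("tag config rejects unphysical parameters", {
  expect_error(tag_config(spacing_px = 1), "spacing_px")
  expect_error(tag_config(total_flip_deg = 200), "total_flip_deg")
  expect_error(tag_config(weights = c(1, -1)), "weights")
  expect_error(simulate_spamm_profile(0, 70, numeric(0)), "weights")
})
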