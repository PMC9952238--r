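test_that("Dice coefficient reproduces enumerable overlaps and conventions", {
  g <- matrix(0, 8, 8); g[3:4, 3:4] <- 1
  p <- matrix(0, 8, 8); p[3:4, 4:5] <- 1
  expect_equal(dice_coefficient(g, p), 0.5)
  expect_equal(dice_coefficient(g, g), 1)
  q <- matrix(0, 8, 8); q[7:8, 7:8] <- 1
  expect_equal(dice_coefficient(g, q), 0)
  z <- matrix(0, 8, 8)
  expect_equal(dice_coefficient(z, z), 1)   # both empty: perfect agreement
  expect_equal(dice_coefficient(g, z), 0)   # one empty
  expect_error(dice_coefficient(g, matrix(0, 4, 4)), "grid mismatch")
})

test_that("contour extraction counts boundary pixels of filled squares", {
  m4 <- matrix(0, 8, 8); m4[3:6, 3:6] <- 1
  expect_equal(nrow(extract_contour(m4)), 12)  # 16 - interior 2x2
  m3 <- matrix(0, 8, 8); m3[3:5, 3:5] <- 1
  expect_equal(nrow(extract_contour(m3)), 8)   # 9 - 1 interior
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(unname(extract_contour(single)), matrix(c(3, 3), 1, 2))
  # border foreground counts as boundary (image edge = background)
  full <- matrix(1, 3, 3)
  expect_equal(nrow(extract_contour(full)), 8)
  expect_error(extract_contour(matrix(0, 4, 4)), "empty mask")
})

test_that("directed percentile distance matches a brute-force nearest-neighbour quantile", {
  X <- cbind(seq(0, 9), rep(0, 10))
  Y <- cbind(seq(0, 9) + 2.5, rep(0, 10))
  for (q in c(0.5, 0.8, 0.95, 1)) {
    nn <- vapply(seq_len(10), function(i) min(sqrt((Y[, 1] - X[i, 1])^2 + (Y[, 2] - X[i, 2])^2)),
                 numeric(1))
    expect_equal(directed_percentile_distance(X, Y, q),
                 unname(quantile(nn, q, type = 7)), tolerance = 1e-12)
  }
  expect_equal(directed_percentile_distance(X, X, 0.95), 0)
  P <- matrix(c(0, 0), 1, 2); Q <- matrix(c(0, 3), 1, 2)
  expect_equal(directed_percentile_distance(P, Q, 0.5), 3)
})

test_that("HD-95 matches the exhaustive oracle on random small masks", {
  set.seed(77)
  for (i in 1:20) {
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    g <- random_mask(nr, nc); p <- random_mask(nr, nc)
    expect_equal(hausdorff95(g, p), hd_bruteforce(g, p), tolerance = 1e-9)
    expect_equal(dice_coefficient(g, p), dice_bruteforce(g, p), tolerance = 1e-12)
    # symmetry and quantile monotonicity
    expect_equal(hausdorff95(g, p), hausdorff95(p, g))
    expect_lte(hausdorff95(g, p), hausdorff95(g, p, q = 1))
  }
})

test_that("HD-95 scales with pixel spacing; Dice does not", {
  set.seed(8)
  g <- random_mask(10, 10); p <- random_mask(10, 10)
  expect_equal(hausdorff95(g, p, spacing_mm = 2), 2 * hausdorff95(g, p, spacing_mm = 1),
               tolerance = 1e-12)
  expect_equal(dice_coefficient(g, p), dice_coefficient(g, p))
  # two single-pixel masks 3 px apart at 1 mm/px
  a <- matrix(0, 8, 8); a[4, 2] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(hausdorff95(a, b, spacing_mm = 1), 3)
  # anisotropic spacing
  expect_equal(hausdorff95(a, b, spacing_mm = c(2, 0.5)), 1.5)
})

test_that("batch evaluation aggregates per-pair metrics and flags empty pairs", {
  g1 <- matrix(0, 8, 8); g1[3:4, 3:4] <- 1
  p1 <- matrix(0, 8, 8); p1[3:4, 4:5] <- 1
  gt <- list(a = g1, b = g1, c = g1)
  pred <- list(a = g1, b = p1, c = matrix(0, 8, 8))
  expect_warning(evaluate_masks(pred, gt), "empty")
  rep <- suppressWarnings(evaluate_masks(pred, gt))
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$per_image$dsc, c(1, 0.5, 0))
  expect_equal(rep$per_image$hd95_mm[1], 0)
  expect_true(is.na(rep$per_image$hd95_mm[3]))
  expect_equal(rep$summary$mean[rep$summary$metric == "dsc"], mean(c(1, 0.5, 0)))
  expect_equal(rep$summary$n[rep$summary$metric == "hd95_mm"], 2)
  # hand aggregation of the HD-95 mean over the two valid pairs
  expect_equal(rep$summary$mean[rep$summary$metric == "hd95_mm"],
               mean(c(0, hausdorff95(g1, p1))))
  expect_error(evaluate_masks(list(x = g1), list(y = g1)), "unmatched")
})
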