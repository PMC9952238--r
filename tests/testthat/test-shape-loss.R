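test_that("boundary sigmoid hits its fixed points and symmetry", {
  expect_equal(boundary_sigmoid(0, 0.2), 0.5, tolerance = 1e-15)
  expect_equal(boundary_sigmoid(0, 1.7), 0.5, tolerance = 1e-15)
  expect_equal(boundary_sigmoid(1, 0.2), 1 / (1 + exp(-5)), tolerance = 1e-15)
  set.seed(2)
  x <- rnorm(50)
  expect_equal(boundary_sigmoid(x, 0.2) + boundary_sigmoid(-x, 0.2), rep(1, 50),
               tolerance = 1e-12)
  expect_true(all(diff(boundary_sigmoid(sort(x), 0.3)) > 0))
  expect_error(boundary_sigmoid(1, k = 0), "k must be")
})

test_that("signed distance map matches the exhaustive all-pairs oracle", {
  set.seed(21)
  for (i in 1:20) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    m <- random_mask(nr, nc)
    expect_equal(signed_distance_map(m), sdm_bruteforce(m), tolerance = 1e-9)
  }
  expect_error(signed_distance_map(matrix(1, 4, 4)), "degenerate")
  expect_error(signed_distance_map(matrix(0, 4, 4)), "degenerate")
})

test_that("signed distance map on the 8x8 centred square has known raw values", {
  m <- square_fixture()
  raw <- signed_distance_map(m, normalize = FALSE)
  # centre foreground pixels (rows/cols 4:5) are 2 px from background
  expect_equal(raw[4, 4], 2)
  expect_equal(raw[5, 5], 2)
  # foreground pixels adjacent to background have raw distance 1
  expect_equal(raw[3, 4], 1)
  norm <- signed_distance_map(m)
  expect_equal(norm[4, 4], 2 / max(abs(raw)))
  expect_equal(max(abs(norm)), 1)
  expect_true(all(norm[m == 1] > 0))
  expect_true(all(norm[m == 0] < 0))
})

test_that("shape information peaks at the boundary, decays inward, vanishes outside", {
  m <- square_fixture(12, 3, 10)
  si <- shape_information(m, k = 0.2)
  expect_true(all(si[m == 0] == 0))
  expect_true(all(si[m == 1] > 0))
  expect_true(all(si <= boundary_sigmoid(1, 0.2) + 1e-15))
  phi <- signed_distance_map(m)
  fg <- which(m == 1)
  # strictly decreasing in phi on the foreground
  ord <- fg[order(phi[fg])]
  expect_true(all(diff(si[ord]) <= 0))
  expect_equal(max(si), boundary_sigmoid(1 - min(phi[fg]), 0.2))
})

test_that("shape loss matches a pixel-by-pixel double-sum oracle and its identities", {
  g <- square_fixture()
  si <- shape_information(g, 0.2)
  expect_equal(shape_loss(g, si, 0.2), 0, tolerance = 1e-15)

  # oracle: explicit double sum with p = g
  manual <- sum(abs(g - si)) / sum(g)
  expect_equal(shape_loss(g, g, 0.2), manual, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:5) {
    p <- matrix(runif(64), 8, 8)
    expect_gte(shape_loss(g, p, 0.2), 0)
    # invariance under simultaneous 90-degree rotations of g and p
    rot <- function(m) t(m[nrow(m):1, ])
    expect_equal(shape_loss(rot(g), rot(p), 0.2), shape_loss(g, p, 0.2),
                 tolerance = 1e-12)
  }
  expect_error(shape_loss(matrix(0, 4, 4), matrix(0, 4, 4)), "degenerate")
})

test_that("multi-channel losses average over channels", {
  g <- array(0L, c(8, 8, 2))
  g[, , 1] <- square_fixture()
  g[, , 2] <- square_fixture(8, 2, 4)
  p <- g * 0.8
  per_channel <- vapply(1:2, function(ch) shape_loss(g[, , ch], p[, , ch], 0.2),
                        numeric(1))
  expect_equal(shape_loss(g, p, 0.2), mean(per_channel), tolerance = 1e-12)
  per_dice <- vapply(1:2, function(ch) dice_loss_term(g[, , ch], p[, , ch]), numeric(1))
  expect_equal(dice_loss_term(g, p), mean(per_dice), tolerance = 1e-12)
})

test_that("soft Dice term reproduces enumerable overlaps", {
  g <- matrix(0, 8, 8); g[3:4, 3:4] <- 1          # 4-px square
  p <- matrix(0, 8, 8); p[3:4, 4:5] <- 1          # shifted by one column
  expect_equal(dice_loss_term(g, p, epsilon = 0), 0.5)  # 2*2/(4+4)
  expect_equal(dice_loss_term(g, g, epsilon = 1e-12), 1, tolerance = 1e-9)
  q <- matrix(0, 8, 8); q[7:8, 7:8] <- 1
  expect_equal(dice_loss_term(g, q, epsilon = 0), 0)
})

test_that("cross-entropy matches brute-force summation and its log identity", {
  g <- square_fixture()
  p <- matrix(1, 8, 8)
  expect_equal(cross_entropy_loss(g, p), 0)
  g1 <- matrix(0, 4, 4); g1[2, 2] <- 1
  p1 <- matrix(0.5, 4, 4); p1[2, 2] <- exp(-1)
  expect_equal(cross_entropy_loss(g1, p1), 1, tolerance = 1e-12)
  set.seed(31)
  p2 <- matrix(runif(64, 0.01, 0.99), 8, 8)
  manual <- 0
  for (i in 1:8) for (j in 1:8) manual <- manual - g[i, j] * log(p2[i, j])
  expect_equal(cross_entropy_loss(g, p2), manual, tolerance = 1e-12)
})

test_that("combined loss assembles its three terms and is monotone in gamma", {
  g <- square_fixture()
  set.seed(17)
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)

  l0 <- combined_loss(g, p, loss_config(gamma = 0))
  expect_equal(l0$total, (1 - dice_loss_term(g, p)) + cross_entropy_loss(g, p),
               tolerance = 1e-15)
  expect_equal(l0$shape, 0)

  l <- combined_loss(g, p, loss_config(k = 0.2, gamma = 0.05))
  expect_equal(l$total,
               (1 - dice_loss_term(g, p)) + cross_entropy_loss(g, p) +
                 0.05 * shape_loss(g, p, 0.2), tolerance = 1e-12)

  # perfect binary prediction, gamma = 0: loss ~ 0
  lp <- combined_loss(g, g, loss_config(gamma = 0, epsilon = 1e-12))
  expect_equal(lp$total, 0, tolerance = 1e-9)

  gammas <- c(0, 0.01, 0.05, 0.2, 1)
  totals <- vapply(gammas, function(gm) combined_loss(g, p, loss_config(gamma = gm))$total,
                   numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_error(loss_config(gamma = -1), "gamma")
  expect_error(loss_config(epsilon = 0), "epsilon")
})
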