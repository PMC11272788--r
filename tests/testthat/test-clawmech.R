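# helper: a hand-built configuration with known lever geometry.
# Fulcrum at the origin, tip on the x axis, tubercle below: 3-4-5 triangle.
lever_fixture <- function(fulcrum = c(0, 0), tip = c(10, 0), tub = c(3, -4),
                          facet = c(0, 3), base_lo = c(2, -3), base_hi = c(4, -3)) {
  scheme <- claw_landmark_scheme()
  coords <- matrix(0, 16, 2)
  coords[1, ] <- facet
  coords[2, ] <- fulcrum
  coords[3, ] <- tub
  coords[4, ] <- tip
  # dorsal semis: straight line facet -> tip
  for (i in 1:6) coords[4 + i, ] <- facet + (i / 7) * (tip - facet)
  # ventral semis: fulcrum -> tubercle, then tubercle -> tip;
  # landmarks 13 and 14 are the tubercle base endpoints
  coords[11, ] <- fulcrum + 0.3 * (base_lo - fulcrum)
  coords[12, ] <- fulcrum + 0.6 * (base_lo - fulcrum)
  coords[13, ] <- base_lo
  coords[14, ] <- base_hi
  coords[15, ] <- base_hi + 0.4 * (tip - base_hi)
  coords[16, ] <- base_hi + 0.7 * (tip - base_hi)
  landmark_table(tibble::tibble(
    specimen_id = "fix", landmark = 1:16, role = scheme$roles,
    x = coords[, 1], y = coords[, 2]
  ))
}

test_that("lever geometry recovers the 3-4-5 construction", {
  geom <- lever_geometry(lever_fixture())
  expect_equal(geom$a, 10)
  expect_equal(geom$d, 5)
  expect_equal(geom$delta, atan2(4, 3) * 180 / pi, tolerance = 1e-9) # 53.13 deg
  # facet is vertical, lever horizontal: facet normal parallel to lever
  expect_equal(geom$theta, 0, tolerance = 1e-9)
  # tubercle base: horizontal segment at y = -3, apex at y = -4
  expect_equal(geom$tubercle_base, 2)
  expect_equal(geom$tubercle_perp, 1)
})

test_that("collinear fulcrum, tubercle and tip give delta = 0", {
  geom <- lever_geometry(lever_fixture(tub = c(4, 0)))
  expect_equal(geom$delta, 0, tolerance = 1e-9)
})

test_that("user-supplied theta overrides the facet-normal convention", {
  geom <- lever_geometry(lever_fixture(), "user_theta", theta = 25)
  expect_equal(geom$theta, 25)
  expect_error(lever_geometry(lever_fixture(), "user_theta"), "requires")
})

test_that("mechanical advantage follows the closed form sin(theta + delta) d / a", {
  expect_equal(mechanical_advantage(theta = 45, delta = 45, d = 1, a = 1), 1)
  expect_equal(mechanical_advantage(theta = 0, delta = 0, d = 5, a = 10), 0)
  expect_equal(
    mechanical_advantage(theta = 30, delta = 30, d = 5, a = 10),
    sin(60 * pi / 180) * 0.5,
    tolerance = 1e-12
  )
  expect_error(mechanical_advantage(30, 30, 5, 0), "positive")
})

test_that("MA is increasing in d, decreasing in a, and similarity-invariant", {
  d_grid <- seq(1, 6, by = 0.5)
  ma_d <- mechanical_advantage(30, 40, d_grid, 10)
  expect_true(all(diff(ma_d) > 0))
  a_grid <- seq(8, 20, by = 1)
  ma_a <- mechanical_advantage(30, 40, 5, a_grid)
  expect_true(all(diff(ma_a) < 0))

  claw <- generate_claw(claw_params(seed = 17))
  s0 <- claw_scores(claw)
  moved <- claw
  m <- rigid_move(cbind(claw$x, claw$y), theta = 0.9, scale = 4.2, shift = c(-3, 12))
  moved$x <- m[, 1]
  moved$y <- m[, 2]
  s1 <- claw_scores(moved)
  expect_equal(s1$MA, s0$MA, tolerance = 1e-9)
  expect_equal(s1$DFT, s0$DFT, tolerance = 1e-9)
  expect_equal(s1$HO, s0$HO, tolerance = 1e-9)
})

test_that("DFT is perpendicular apex height over base length", {
  fix <- lever_fixture(tub = c(0, 1), base_lo = c(-1, 0), base_hi = c(1, 0))
  geom <- lever_geometry(fix)
  expect_equal(dft(geom$tubercle_perp, geom$tubercle_base), 0.5)
  # apex on the base segment: zero
  on_base <- lever_geometry(lever_fixture(tub = c(3, -3), base_lo = c(2, -3), base_hi = c(4, -3)))
  expect_equal(dft(on_base$tubercle_perp, on_base$tubercle_base), 0)
  expect_error(dft(1, 0), "positive")
})

test_that("DFT equals a vector-algebra point-to-line oracle on random configurations", {
  set.seed(91)
  for (i in 1:50) {
    apex <- rnorm(2)
    b1 <- rnorm(2)
    b2 <- b1 + rnorm(2)
    if (sqrt(sum((b2 - b1)^2)) < 1e-6) next
    geom <- lever_geometry(lever_fixture(tub = apex, base_lo = b1, base_hi = b2))
    # oracle: cross-product distance over segment length
    v <- b2 - b1
    w <- apex - b1
    oracle <- abs(v[1] * w[2] - v[2] * w[1]) / sum(v^2) # = perp / base
    expect_equal(dft(geom$tubercle_perp, geom$tubercle_base), oracle, tolerance = 1e-12)
  }
})

test_that("HO is exactly the product of DFT and MA", {
  expect_equal(hypothesized_output(0.5, 0.5), 0.25)
  expect_equal(hypothesized_output(0, 0.9), 0)
  set.seed(2)
  ma <- runif(20)
  dv <- runif(20)
  expect_identical(hypothesized_output(ma, dv), dv * ma)
  scores <- claw_scores(generate_population(n = 6, seed = 3))
  expect_equal(scores$HO, scores$DFT * scores$MA, tolerance = 0)
})

test_that("shape covariates are zero for a straight claw and similarity-invariant", {
  straight <- lever_fixture() # dorsal semis on the facet-to-tip line
  cov0 <- shape_covariates(straight)
  expect_equal(cov0$curvature, 0, tolerance = 1e-12)

  claw <- generate_claw(claw_params(seed = 29))
  c1 <- shape_covariates(claw)
  moved <- claw
  m <- rigid_move(cbind(claw$x, claw$y), theta = -1.2, scale = 0.37, shift = c(8, 1))
  moved$x <- m[, 1]
  moved$y <- m[, 2]
  c2 <- shape_covariates(moved)
  expect_equal(c2$curvature, c1$curvature, tolerance = 1e-9)
  expect_equal(c2$robustness, c1$robustness, tolerance = 1e-9)
})

test_that("the curvature index increases strictly with the spiral coefficient", {
  ks <- seq(0.05, 0.5, length.out = 10)
  cur <- vapply(ks, function(k) {
    shape_covariates(generate_claw(claw_params(spiral_k = k, noise_sd = 0, seed = 1)))$curvature
  }, numeric(1))
  expect_true(all(diff(cur) > 0))
})

test_that("recovered lever arms track the generator geometry within noise bounds", {
  p <- claw_params(spiral_k = 0.3, aspect = 0.5, tubercle_h = 0.3, size_mm = 20, noise_sd = 0)
  clean <- lever_geometry(generate_claw(p))
  noisy <- lever_geometry(generate_claw(claw_params(
    spiral_k = 0.3, aspect = 0.5, tubercle_h = 0.3, size_mm = 20,
    noise_sd = 0.01, seed = 77
  )))
  # 1% digitization noise moves each landmark by ~0.2 mm; arms are ~10-20 mm
  expect_equal(noisy$a, clean$a, tolerance = 0.1)
  expect_equal(noisy$d, clean$d, tolerance = 0.3)
})
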