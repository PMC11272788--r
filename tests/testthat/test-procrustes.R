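test_that("procrustes_distance removes similarity transforms and rejects degenerate shapes", {
  tri <- equilateral()
  expect_equal(procrustes_distance(tri, tri), 0, tolerance = 1e-14)
  moved <- rigid_move(tri, theta = 37 * pi / 180, scale = 3, shift = c(5, -2))
  expect_equal(procrustes_distance(tri, moved), 0, tolerance = 1e-10)
  degenerate <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_error(procrustes_distance(tri, degenerate), "degenerate")
  expect_error(procrustes_distance(tri, cbind(1:4, 1:4)), "equal landmark counts")
})

test_that("procrustes_distance matches an exhaustive rotation-grid search", {
  tri <- equilateral()
  bumped <- tri
  bumped[2, ] <- bumped[2, ] + c(0.1, 0)
  expect_equal(
    procrustes_distance(tri, bumped),
    grid_procrustes_distance(tri, bumped, step = 1e-4),
    tolerance = 1e-6
  )
})

test_that("procrustes_distance is a metric: symmetry and triangle inequality", {
  set.seed(101)
  for (rep in 1:20) {
    a <- matrix(rnorm(12), 6, 2)
    b <- matrix(rnorm(12), 6, 2)
    c <- matrix(rnorm(12), 6, 2)
    dab <- procrustes_distance(a, b)
    dba <- procrustes_distance(b, a)
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_lte(dab, procrustes_distance(a, c) + procrustes_distance(c, b) + 1e-9)
  }
})

test_that("single-specimen GPA returns the centred unit-scaled specimen", {
  claw <- generate_claw(claw_params(seed = 2))
  g <- gpa_align(claw)
  expect_equal(g$iterations, 1L)
  expect_true(g$converged)
  cons <- as.matrix(g$consensus[, c("x", "y")])
  expect_equal(unname(colMeans(cons)), c(0, 0), tolerance = 1e-9)
  expect_equal(sqrt(sum(cons^2)), 1, tolerance = 1e-9)
  expect_equal(procrustes_distance(cons, cbind(claw$x, claw$y)), 0, tolerance = 1e-9)
})

test_that("specimens identical up to similarity transforms align with zero residual", {
  claw <- generate_claw(claw_params(seed = 4, noise_sd = 0))
  m <- cbind(claw$x, claw$y)
  df <- dplyr::bind_rows(
    dplyr::mutate(claw, specimen_id = "a"),
    dplyr::mutate(claw, specimen_id = "b",
      x = rigid_move(m, theta = 1.1, scale = 2.5, shift = c(3, 7))[, 1],
      y = rigid_move(m, theta = 1.1, scale = 2.5, shift = c(3, 7))[, 2]
    )
  )
  tbl <- landmark_table(df)
  g <- gpa_align(tbl)
  expect_lt(tail(g$objective_trace, 1), 1e-9)
})

test_that("GPA on fixed-only triangles matches a brute-force rotation-search GPA", {
  set.seed(7)
  shapes <- lapply(1:3, function(i) equilateral() + matrix(rnorm(6, sd = 0.05), 3, 2))
  tbl <- triangle_table(shapes)
  g <- gpa_align(tbl)
  oracle <- brute_gpa(shapes)
  expect_equal(tail(g$objective_trace, 1), oracle$residual, tolerance = 1e-5)
  cons <- as.matrix(g$consensus[, c("x", "y")])
  expect_lt(procrustes_distance(cons, oracle$consensus), 1e-4)
})

test_that("aligned output is invariant to pre-applied similarity transforms of any specimen", {
  pop <- generate_population(n = 8, seed = 21)
  g0 <- gpa_align(pop)
  # perturb specimen 1 (which seeds the consensus) and specimen 5
  pert <- pop
  for (id in c("sim_001", "sim_005")) {
    sel <- pert$specimen_id == id
    m <- rigid_move(cbind(pert$x[sel], pert$y[sel]),
      theta = if (id == "sim_001") 2.2 else -0.7,
      scale = if (id == "sim_001") 0.2 else 11, shift = c(-4, 9)
    )
    pert$x[sel] <- m[, 1]
    pert$y[sel] <- m[, 2]
  }
  g1 <- gpa_align(pert)
  expect_equal(g1$coords$x, g0$coords$x, tolerance = 1e-8)
  expect_equal(g1$coords$y, g0$coords$y, tolerance = 1e-8)
})

test_that("aligned specimens are centred and the consensus has unit centroid size", {
  pop <- generate_population(n = 10, seed = 31)
  for (method in c("bending_energy", "procrustes_distance")) {
    g <- gpa_align(pop, sliding_method = method)
    per_spec <- dplyr::summarise(
      dplyr::group_by(g$coords, specimen_id),
      cx = mean(x), cy = mean(y)
    )
    expect_true(all(abs(per_spec$cx) < 1e-9))
    expect_true(all(abs(per_spec$cy) < 1e-9))
    cons <- as.matrix(g$consensus[, c("x", "y")])
    expect_equal(sqrt(sum(cons^2)), 1, tolerance = 1e-9)
    expect_equal(unname(colMeans(cons)), c(0, 0), tolerance = 1e-9)
  }
})

test_that("the Procrustes SS trace is monotone for the objective that minimizes it", {
  pop <- generate_population(n = 12, seed = 55)
  # Procrustes-distance sliding minimizes the traced SS: fully monotone
  g_pd <- gpa_align(pop, sliding_method = "procrustes_distance")
  expect_true(all(diff(g_pd$objective_trace) <= 1e-9))
  expect_true(g_pd$converged)
  # bending-energy sliding pursues a different functional during the
  # sliding passes; once sliding stops the SS decreases monotonically
  g_be <- gpa_align(pop, sliding_method = "bending_energy", slide_iter = 5L)
  tr <- g_be$objective_trace
  expect_true(all(diff(tr[5:length(tr)]) <= 1e-9))
  expect_true(g_be$converged)
})

test_that("with all landmarks fixed the sliding objective is irrelevant", {
  set.seed(12)
  shapes <- lapply(1:4, function(i) matrix(rnorm(10), 5, 2))
  tbl <- triangle_table(shapes) # empty sliders: everything fixed
  g1 <- gpa_align(tbl, sliding_method = "bending_energy")
  g2 <- gpa_align(tbl, sliding_method = "procrustes_distance")
  expect_identical(g1$coords$x, g2$coords$x)
  expect_identical(g1$coords$y, g2$coords$y)
  expect_equal(g1$sliding_method, "none")
})

test_that("semi-landmarks do not move when specimens already equal the consensus", {
  claw <- generate_claw(claw_params(seed = 8, noise_sd = 0))
  df <- dplyr::bind_rows(
    dplyr::mutate(claw, specimen_id = "a"),
    dplyr::mutate(claw, specimen_id = "b")
  )
  g <- gpa_align(landmark_table(df))
  expect_lt(tail(g$objective_trace, 1), 1e-16)
  a <- g$array[, , 1]
  cons <- as.matrix(g$consensus[, c("x", "y")])
  expect_equal(a, cons, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Procrustes-distance sliding projects the residual onto the tangent", {
  # consensus: gentle arc of 6 landmarks, ends fixed, middle four sliding
  t6 <- seq(0, 1, length.out = 6)
  cons <- cbind(t6, 0.3 * sin(pi * t6))
  cons <- sweep(cons, 2, colMeans(cons))
  cons <- cons / sqrt(sum(cons^2))
  sliders <- tibble::tibble(before = c(1L, 2L, 3L, 4L), slide = 2:5, after = c(3L, 4L, 5L, 6L))
  spec <- cons
  j <- 3L
  tangent <- (cons[4, ] - cons[2, ])
  tangent <- tangent / sqrt(sum(tangent^2))
  # displace landmark 3 along its tangent: residual is parallel to tangent
  spec[j, ] <- spec[j, ] + 0.04 * tangent
  slid <- clawmorph:::slide_one(spec, cons, sliders, "procrustes_distance")
  # the slid landmark lands at the foot of the residual: back on the consensus
  expect_equal(slid[j, ], cons[j, ], tolerance = 1e-9)
  d_before <- sum((spec - cons)^2)
  d_after <- sum((slid - cons)^2)
  expect_lt(d_after, d_before)
})

test_that("bending-energy sliding matches a fine line-search oracle on a toy arc", {
  t6 <- seq(0, 1, length.out = 6)
  cons <- cbind(t6, 0.25 * sin(pi * t6))
  sliders <- tibble::tibble(before = c(1L, 2L, 3L, 4L), slide = 2:5, after = c(3L, 4L, 5L, 6L))
  set.seed(33)
  spec <- cons
  spec[2:5, ] <- spec[2:5, ] + matrix(rnorm(8, sd = 0.015), 4, 2)
  B <- clawmorph:::bending_energy_matrix(cons)
  be_of <- function(m) {
    D <- m - cons
    sum(D[, 1] %*% B %*% D[, 1]) + sum(D[, 2] %*% B %*% D[, 2])
  }
  be_before <- be_of(spec)
  slid <- clawmorph:::slide_one(spec, cons, sliders, "bending_energy", B)
  be_after <- be_of(slid)
  expect_lte(be_after, be_before + 1e-12)

  # oracle: cyclic per-landmark line search on a 1e-3 step grid (tangents
  # fixed at their pre-slide directions, as in the implementation)
  tangents <- t(vapply(1:4, function(r) {
    ch <- spec[sliders$after[r], ] - spec[sliders$before[r], ]
    ch / sqrt(sum(ch^2))
  }, numeric(2)))
  oracle <- spec
  steps <- seq(-0.2, 0.2, by = 1e-3)
  for (sweep_i in 1:40) {
    for (r in 1:4) {
      j <- sliders$slide[r]
      base <- oracle[j, ]
      vals <- vapply(steps, function(s) {
        trial <- oracle
        trial[j, ] <- base + s * tangents[r, ]
        be_of(trial)
      }, numeric(1))
      oracle[j, ] <- base + steps[which.min(vals)] * tangents[r, ]
    }
  }
  expect_lt(abs(be_after - be_of(oracle)), 1e-4)
})
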