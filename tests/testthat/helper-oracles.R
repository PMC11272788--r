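# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately use different algorithms from the implementation
# (exhaustive search, enumeration, null-space algebra) so agreement is
# evidence, not tautology.

# --- small shape fixtures ----------------------------------------------

equilateral <- function() {
  cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
}

rigid_move <- function(m, theta = 0, scale = 1, shift = c(0, 0)) {
  ct <- cos(theta)
  st <- sin(theta)
  out <- cbind(ct * m[, 1] - st * m[, 2], st * m[, 1] + ct * m[, 2]) * scale
  sweep(out, 2, shift, "+")
}

# landmark table of raw triangles (all fixed, no sliding)
triangle_table <- function(shapes) {
  df <- dplyr::bind_rows(lapply(seq_along(shapes), function(i) {
    tibble::tibble(
      specimen_id = sprintf("tri_%d", i),
      landmark = seq_len(nrow(shapes[[i]])), role = "fixed",
      x = shapes[[i]][, 1], y = shapes[[i]][, 2]
    )
  }))
  landmark_table(df, sliders = tibble::tibble(
    before = integer(), slide = integer(), after = integer()
  ))
}

# --- Procrustes oracles -------------------------------------------------

# exhaustive rotation-grid Procrustes distance (both shapes pre-standardized)
grid_procrustes_distance <- function(a, b, step = 1e-4) {
  std <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- std(a)
  b <- std(b)
  thetas <- seq(0, 2 * pi, by = step)
  ss <- vapply(thetas, function(th) {
    ct <- cos(th)
    st <- sin(th)
    ar <- cbind(ct * a[, 1] - st * a[, 2], st * a[, 1] + ct * a[, 2])
    sum((ar - b)^2)
  }, numeric(1))
  sqrt(min(ss))
}

# brute-force GPA: iterate mean consensus with per-shape exhaustive
# rotation search (coarse-to-fine grid)
brute_gpa <- function(shapes, iters = 30) {
  std <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  shapes <- lapply(shapes, std)
  best_rot <- function(a, b) {
    f <- function(th) {
      ct <- cos(th)
      st <- sin(th)
      sum((cbind(ct * a[, 1] - st * a[, 2], st * a[, 1] + ct * a[, 2]) - b)^2)
    }
    grid <- seq(0, 2 * pi, by = 1e-3)
    th0 <- grid[which.min(vapply(grid, f, numeric(1)))]
    fine <- seq(th0 - 2e-3, th0 + 2e-3, by = 1e-6)
    fine[which.min(vapply(fine, f, numeric(1)))]
  }
  consensus <- shapes[[1]]
  for (it in seq_len(iters)) {
    shapes <- lapply(shapes, function(s) {
      th <- best_rot(s, consensus)
      ct <- cos(th)
      st <- sin(th)
      cbind(ct * s[, 1] - st * s[, 2], st * s[, 1] + ct * s[, 2])
    })
    consensus <- std(Reduce(`+`, shapes) / length(shapes))
  }
  list(
    consensus = consensus,
    residual = sum(vapply(shapes, function(s) sum((s - consensus)^2), numeric(1)))
  )
}

# --- thin-plate-spline oracle ------------------------------------------

# null-space TPS solve: eliminate the affine constraints with a QR basis
# instead of inverting the bordered system
tps_nullspace_warp <- function(ref, tar, pts) {
  k <- nrow(ref)
  kern <- function(p, q) {
    r2 <- outer(seq_len(nrow(p)), seq_len(nrow(q)), function(i, j) {
      (p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2
    })
    out <- r2
    out[r2 > 0] <- r2[r2 > 0] * log(r2[r2 > 0])
    out[r2 == 0] <- 0
    out
  }
  K <- kern(ref, ref)
  Q <- cbind(1, ref)
  Zfull <- qr.Q(qr(Q), complete = TRUE)
  N <- Zfull[, 4:k, drop = FALSE] # basis of the null space of t(Q)
  W <- N %*% solve(t(N) %*% K %*% N, t(N) %*% tar)
  A <- qr.solve(Q, tar - K %*% W)
  kern(pts, ref) %*% W + cbind(1, pts) %*% A
}

# --- parsimony oracles --------------------------------------------------

# exhaustive minimization over all internal-node state assignments
brute_force_steps <- function(phy, tip_sets, W) {
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  S <- nrow(W)
  combos <- as.matrix(expand.grid(rep(list(seq_len(S)), n_int)))
  edge <- phy$edge
  total <- rep(0, nrow(combos))
  for (e in seq_len(nrow(edge))) {
    parent_col <- edge[e, 1] - n_tip
    child <- edge[e, 2]
    ps <- combos[, parent_col]
    if (child <= n_tip) {
      allowed <- tip_sets[[child]]
      total <- total + vapply(ps, function(s) min(W[s, allowed]), numeric(1))
    } else {
      total <- total + W[cbind(ps, combos[, child - n_tip])]
    }
  }
  min(total)
}

# random rooted binary tree + random character matrix instance
random_parsimony_instance <- function(n_tip, n_states, n_char) {
  phy <- ape::rtree(n_tip, rooted = TRUE, br = NULL)
  states <- matrix(
    as.character(sample(0:(n_states - 1), n_tip * n_char, replace = TRUE)),
    n_tip, n_char
  )
  rownames(states) <- phy$tip.label
  list(phy = phy, states = states)
}

# --- synthetic populations used in several files ------------------------

curvature_only_population <- function(n = 40, noise_sd = 0.01, seed = 7) {
  rg <- claw_param_ranges()
  rg$aspect <- c(0.5, 0.5)
  rg$tubercle_h <- c(0.25, 0.25)
  rg$tubercle_pos <- c(0.3, 0.3)
  rg$size_mm <- c(15, 15)
  generate_population(n = n, ranges = rg, noise_sd = noise_sd, seed = seed)
}

two_factor_population <- function(n = 40, noise_sd = 0.01, seed = 13, f_seed = 11) {
  set.seed(f_seed)
  f2 <- runif(n)
  params <- tibble::tibble(
    aspect = 0.35 + 0.3 * f2,
    tubercle_h = 0.10 + 0.3 * f2,
    tubercle_pos = rep(0.3, n),
    size_mm = rep(15, n)
  )
  pop <- generate_population(n = n, noise_sd = noise_sd, seed = seed, params = params)
  attr(pop, "factor2") <- f2
  pop
}
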