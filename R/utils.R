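# Internal geometry helpers shared across modules. All coordinate blocks are
# k x 2 numeric matrices (columns x, y), one row per landmark.

# centroid of a k x 2 matrix
centroid <- function(m) colMeans(m)

# centroid size: sqrt of summed squared distances to the centroid
centroid_size <- function(m) {
  cm <- sweep(m, 2, colMeans(m))
  sqrt(sum(cm^2))
}

center_coords <- function(m) sweep(m, 2, colMeans(m))

# rotate row-vector coordinates by `theta` radians (counter-clockwise)
rotate_coords <- function(m, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  cbind(ct * m[, 1] - st * m[, 2], st * m[, 1] + ct * m[, 2])
}

# closed-form angle rotating `x` onto `y` (both centered), minimizing
# ||y - rotate(x, theta)||^2 over rotations only (no reflection)
optimal_rotation_angle <- function(x, y) {
  atan2(
    sum(x[, 1] * y[, 2] - x[, 2] * y[, 1]),
    sum(x[, 1] * y[, 1] + x[, 2] * y[, 2])
  )
}

# angle at the origin between two 2D vectors, degrees in [0, 180]
angle_between_deg <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("cannot take the angle of a zero-length vector")
  }
  cs <- sum(u * v) / (nu * nv)
  cs <- min(1, max(-1, cs))
  acos(cs) * 180 / pi
}

# perpendicular distance from point p to the infinite line through a and b
point_line_distance <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) abort("degenerate line: endpoints coincide")
  abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / len
}

# cumulative polyline length of a k x 2 matrix of ordered points
polyline_length <- function(m) {
  d <- diff(m)
  sum(sqrt(rowSums(d^2)))
}

# resample `n` points equally spaced by arc length along the polyline `m`
# (excluding both endpoints)
arc_length_points <- function(m, n) {
  seg <- sqrt(rowSums(diff(m)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  targets <- seq(0, total, length.out = n + 2)[2:(n + 1)]
  t(vapply(targets, function(ti) {
    j <- max(which(s <= ti + 1e-12))
    j <- min(j, nrow(m) - 1)
    frac <- if (seg[j] > 0) (ti - s[j]) / seg[j] else 0
    m[j, ] + frac * (m[j + 1, ] - m[j, ])
  }, numeric(2)))
}

# thin-plate-spline kernel on squared distance, U(r) = r^2 log(r^2)
tps_kernel <- function(r2) {
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- r2[pos] * log(r2[pos])
  out
}

# k x k kernel matrix between two point sets (k1 x 2, k2 x 2)
tps_kernel_matrix <- function(p, q) {
  r2 <- outer(seq_len(nrow(p)), seq_len(nrow(q)), function(i, j) {
    (p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2
  })
  matrix(tps_kernel(r2), nrow(p), nrow(q))
}

# bending-energy matrix of a reference configuration: the upper-left k x k
# block of L^{-1} where L = [[K, Q], [Q', 0]], Q = [1 | x | y]
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  K <- tps_kernel_matrix(ref, ref)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Linv <- tryCatch(solve(L), error = function(e) {
    abort("singular thin-plate-spline system (duplicate or collinear reference landmarks)")
  })
  (Linv[1:k, 1:k] + t(Linv[1:k, 1:k])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
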