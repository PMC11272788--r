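# Generalized Procrustes analysis with sliding semi-landmarks -----------
#
# Superimposition follows the standard partial-Procrustes recipe: every
# configuration is centred and scaled to unit centroid size, rotated onto
# the running consensus in closed form (2D, rotations only, never
# reflections), semi-landmarks slide along their local tangents once per
# iteration, and the consensus is the rescaled mean shape. Convergence is
# declared when the root-mean-square change of the consensus drops below
# `tol`.

#' Partial Procrustes distance between two configurations
#'
#' Both shapes are centred, scaled to unit centroid size, and the optimal
#' 2D rotation (reflections excluded) is found in closed form; the distance
#' is the root summed squared difference after superimposition.
#'
#' @param shape_a,shape_b k x 2 coordinate matrices with equal landmark
#'   counts.
#' @return Non-negative scalar; 0 for shapes identical up to a similarity
#'   transform (without reflection).
#' @export
#' @examples
#' tri <- cbind(c(0, 1, 0), c(0, 0, 1))
#' procrustes_distance(tri, 3 * tri) # 0: scale is removed
procrustes_distance <- function(shape_a, shape_b) {
  shape_a <- as.matrix(shape_a)
  shape_b <- as.matrix(shape_b)
  if (!all(dim(shape_a) == dim(shape_b))) {
    abort("shapes must have equal landmark counts")
  }
  a <- center_coords(shape_a)
  b <- center_coords(shape_b)
  csa <- sqrt(sum(a^2))
  csb <- sqrt(sum(b^2))
  if (csa == 0 || csb == 0) abort("degenerate shape: zero centroid size")
  a <- a / csa
  b <- b / csb
  theta <- optimal_rotation_angle(a, b)
  sqrt(sum((rotate_coords(a, theta) - b)^2))
}

#' Generalized Procrustes alignment of a landmark table
#'
#' Iteratively removes translation, scale and rotation from every
#' configuration and lets semi-landmarks slide along their outline tangents
#' against the consensus, under either the thin-plate-spline bending-energy
#' objective or the Procrustes-distance (tangent projection) objective.
#' After convergence the whole set is put in a canonical orientation
#' (consensus principal axis along x) so the output does not depend on the
#' original orientation of any input specimen.
#'
#' @param x A `landmark_tbl` (see [landmark_table()]).
#' @param sliding_method `"bending_energy"` (default) or
#'   `"procrustes_distance"`; ignored when every landmark is fixed.
#' @param tol Convergence tolerance on the root-mean-square consensus
#'   change per coordinate.
#' @param max_iter Iteration cap; hitting it records a warning in the
#'   result rather than failing.
#' @param slide Set to `FALSE` to suppress sliding even when the table has
#'   semi-landmarks.
#' @param slide_iter Number of initial iterations in which semi-landmarks
#'   slide (once per iteration); afterwards they are held fixed while the
#'   superimposition converges. Tangent sliding has a nearly flat direction
#'   (the whole parametrization drifting along the outline), so unlimited
#'   sliding creeps indefinitely; a small fixed number of passes is the
#'   conventional remedy.
#'
#' @return A `claw_gpa` object: list with `coords` (long tibble of aligned
#'   coordinates), `consensus` (tibble, unit centroid size), `centroid_size`
#'   (per-specimen sizes in input units), `iterations`, `objective_trace`
#'   (total Procrustes sum of squares per iteration), `converged`,
#'   `sliding_method`, `meta` (per-specimen metadata) and `array`
#'   (k x 2 x n aligned coordinates).
#' @export
gpa_align <- function(x, sliding_method = c("bending_energy", "procrustes_distance"),
                      tol = 1e-8, max_iter = 100, slide = TRUE, slide_iter = 5L) {
  sliding_method <- match.arg(sliding_method)
  validate_landmark_tbl(x)
  shapes <- lm_split(x)
  n <- length(shapes)
  k <- nrow(shapes[[1]])
  roles <- lm_roles(x)
  sliders <- attr(x, "sliders")
  do_slide <- slide && any(roles == "sliding")

  cs <- vapply(shapes, centroid_size, numeric(1))
  if (any(cs == 0)) abort("degenerate shape: zero centroid size")
  A <- array(NA_real_, c(k, 2, n), dimnames = list(NULL, c("x", "y"), names(shapes)))
  for (i in seq_len(n)) A[, , i] <- center_coords(shapes[[i]]) / cs[i]

  consensus <- A[, , 1]
  trace <- numeric(0)
  iterations <- 0L
  converged <- TRUE
  if (n > 1) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- it
      for (i in seq_len(n)) {
        A[, , i] <- rotate_coords(A[, , i], optimal_rotation_angle(A[, , i], consensus))
      }
      if (do_slide && it <= slide_iter) {
        be_mat <- if (sliding_method == "bending_energy") {
          bending_energy_matrix(consensus)
        } else {
          NULL
        }
        for (i in seq_len(n)) {
          slid <- slide_one(A[, , i], consensus, sliders, sliding_method, be_mat)
          slid <- center_coords(slid)
          slid <- slid / sqrt(sum(slid^2))
          A[, , i] <- rotate_coords(slid, optimal_rotation_angle(slid, consensus))
        }
      }
      new_consensus <- apply(A, c(1, 2), mean)
      new_consensus <- center_coords(new_consensus)
      new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
      new_consensus <- rotate_coords(
        new_consensus, optimal_rotation_angle(new_consensus, consensus)
      )
      delta <- sqrt(mean((new_consensus - consensus)^2))
      consensus <- new_consensus
      trace <- c(trace, sum(sweep(A, c(1, 2), consensus)^2))
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warn(sprintf("GPA did not converge in %d iterations", max_iter))
    }
  } else {
    trace <- 0
    iterations <- 1L
  }

  # canonical orientation: consensus major axis along x, first landmark
  # anchored to non-negative x (a rotation, never a reflection)
  sv <- svd(consensus)
  ang <- atan2(sv$v[2, 1], sv$v[1, 1])
  consensus <- rotate_coords(consensus, -ang)
  for (i in seq_len(n)) A[, , i] <- rotate_coords(A[, , i], -ang)
  if (consensus[1, 1] < 0) {
    consensus <- -consensus # 180 degree rotation
    for (i in seq_len(n)) A[, , i] <- -A[, , i]
  }

  meta <- lm_meta(x)
  coords <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble(
      specimen_id = names(shapes)[i], landmark = seq_len(k), role = roles,
      x = A[, 1, i], y = A[, 2, i]
    )
  }))
  coords <- dplyr::left_join(coords, meta, by = "specimen_id")
  coords <- coords[, c(
    "specimen_id", "taxon", "digit", "clade", "side",
    "landmark", "role", "x", "y"
  )]

  structure(
    list(
      coords = coords,
      consensus = tibble(landmark = seq_len(k), role = roles, x = consensus[, 1], y = consensus[, 2]),
      centroid_size = tibble(specimen_id = names(shapes), centroid_size = unname(cs)),
      iterations = iterations,
      objective_trace = trace,
      converged = converged,
      sliding_method = if (do_slide) sliding_method else "none",
      sliders = sliders,
      meta = meta,
      array = A
    ),
    class = "claw_gpa"
  )
}

# Slide the semi-landmarks of one configuration against the consensus.
# Tangent directions are the chords through each semi-landmark's two
# neighbours along its outline curve (current specimen positions).
slide_one <- function(coords, consensus, sliders, method, be_mat = NULL) {
  semis <- sliders$slide
  tangents <- matrix(0, length(semis), 2)
  keep <- rep(TRUE, length(semis))
  for (j in seq_along(semis)) {
    chord <- coords[sliders$after[j], ] - coords[sliders$before[j], ]
    len <- sqrt(sum(chord^2))
    if (len == 0) {
      warn(sprintf("semi-landmark %d has a degenerate tangent; left unmoved", semis[j]))
      keep[j] <- FALSE
      next
    }
    tangents[j, ] <- chord / len
  }
  semis <- semis[keep]
  tangents <- tangents[keep, , drop = FALSE]
  if (length(semis) == 0) {
    return(coords)
  }

  if (method == "procrustes_distance") {
    resid <- consensus[semis, , drop = FALSE] - coords[semis, , drop = FALSE]
    t_step <- rowSums(resid * tangents)
  } else {
    # minimize bending energy of the consensus->specimen deformation over
    # tangent steps t: positions p_j + t_j u_j, quadratic in t
    k <- nrow(coords)
    D <- coords - consensus
    Mx <- matrix(0, k, length(semis))
    My <- matrix(0, k, length(semis))
    Mx[cbind(semis, seq_along(semis))] <- tangents[, 1]
    My[cbind(semis, seq_along(semis))] <- tangents[, 2]
    H <- t(Mx) %*% be_mat %*% Mx + t(My) %*% be_mat %*% My
    g <- t(Mx) %*% be_mat %*% D[, 1] + t(My) %*% be_mat %*% D[, 2]
    t_step <- tryCatch(
      as.numeric(solve(H + diag(1e-12, nrow(H)), -g)),
      error = function(e) rep(0, length(semis))
    )
  }
  coords[semis, ] <- coords[semis, , drop = FALSE] + t_step * tangents
  coords
}

#' Slide semi-landmarks of an aligned set one more time
#'
#' Applies a single sliding pass (see [gpa_align()]) of every specimen
#' against the current consensus and re-superimposes. Exposed mainly for
#' inspection; [gpa_align()] already slides at every iteration.
#'
#' @param gpa A `claw_gpa` object.
#' @param method Sliding objective, as in [gpa_align()].
#' @return An updated `claw_gpa` object.
#' @export
slide_semilandmarks <- function(gpa, method = c("bending_energy", "procrustes_distance")) {
  method <- match.arg(method)
  stopifnot(inherits(gpa, "claw_gpa"))
  A <- gpa$array
  consensus <- as.matrix(gpa$consensus[, c("x", "y")])
  be_mat <- if (method == "bending_energy") bending_energy_matrix(consensus) else NULL
  for (i in seq_len(dim(A)[3])) {
    slid <- slide_one(A[, , i], consensus, gpa$sliders, method, be_mat)
    slid <- center_coords(slid)
    slid <- slid / sqrt(sum(slid^2))
    A[, , i] <- rotate_coords(slid, optimal_rotation_angle(slid, consensus))
  }
  gpa$array <- A
  gpa$coords$x <- as.vector(apply(A, 3, function(m) m[, 1]))
  gpa$coords$y <- as.vector(apply(A, 3, function(m) m[, 2]))
  gpa$objective_trace <- c(
    gpa$objective_trace,
    sum(sweep(A, c(1, 2), consensus)^2)
  )
  gpa
}

#' @export
print.claw_gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes alignment: %d specimens, %d landmarks\n",
    nrow(x$meta), nrow(x$consensus)
  ))
  cat(sprintf(
    "  sliding: %s | iterations: %d | converged: %s\n",
    x$sliding_method, x$iterations, x$converged
  ))
  if (length(x$objective_trace) > 0) {
    cat(sprintf("  final Procrustes SS: %.6g\n", tail(x$objective_trace, 1)))
  }
  invisible(x)
}

#' @rdname gpa_align
#' @param x A `claw_gpa` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy claw_gpa
#' @export
tidy.claw_gpa <- function(x, ...) x$coords

#' @rdname gpa_align
#' @method glance claw_gpa
#' @export
glance.claw_gpa <- function(x, ...) {
  tibble(
    n_specimens = nrow(x$meta),
    n_landmarks = nrow(x$consensus),
    iterations = x$iterations,
    converged = x$converged,
    sliding_method = x$sliding_method,
    procrustes_ss = if (length(x$objective_trace) > 0) tail(x$objective_trace, 1) else 0
  )
}
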