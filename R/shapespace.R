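# Shape space: PCA of Procrustes coordinates and thin-plate splines ------

#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigendecomposition of the covariance matrix (divisor n - 1) of the
#' flattened aligned coordinates. Scores are the centred data projected on
#' the eigenvectors; eigenvalues are clipped at zero. All components are
#' retained.
#'
#' @param gpa A `claw_gpa` object from [gpa_align()].
#' @return A `claw_pca` object: list with `values` (eigenvalues,
#'   descending), `vectors` (orthonormal columns, 2k x n_pc), `scores`
#'   (tibble: specimen metadata plus PC columns), `variance_fraction`,
#'   `center` (mean shape vector), `consensus`, `sign_anchor` (empty until
#'   [anchor_signs()] is applied) and `meta`.
#' @export
fit_pca <- function(gpa) {
  stopifnot(inherits(gpa, "claw_gpa"))
  A <- gpa$array
  n <- dim(A)[3]
  if (n < 2) abort("PCA needs at least 2 specimens")
  k <- dim(A)[1]
  # flatten landmark-major: x1, y1, x2, y2, ...
  X <- t(apply(A, 3, function(m) as.vector(t(m))))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- crossprod(Xc) / (n - 1)
  eig <- eigen(S, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  n_pc <- min(n - 1, ncol(X))
  vectors <- eig$vectors[, seq_len(n_pc), drop = FALSE]
  values <- values[seq_len(n_pc)]
  scores <- Xc %*% vectors
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  scores_tbl <- dplyr::left_join(
    tibble(specimen_id = dimnames(A)[[3]]), gpa$meta,
    by = "specimen_id"
  )
  scores_tbl <- dplyr::bind_cols(scores_tbl, as_tibble(scores))
  structure(
    list(
      values = values,
      vectors = vectors,
      scores = scores_tbl,
      variance_fraction = if (sum(values) > 0) values / sum(values) else values,
      center = ctr,
      consensus = gpa$consensus,
      sign_anchor = tibble(
        pc = integer(), covariate = character(),
        correlation = numeric(), flipped = logical()
      ),
      meta = gpa$meta
    ),
    class = "claw_pca"
  )
}

#' Anchor the signs of PC1 and PC2 to claw-shape covariates
#'
#' Eigenvector signs are arbitrary; this fixes them so the axes read
#' biologically: PC1 is flipped if needed so it correlates positively with
#' the claw curvature index, PC2 so it correlates positively with the
#' robustness index (short/high claws with large flexor tubercles score
#' positive). Absolute score values and eigenvalues are unchanged.
#'
#' @param pca A `claw_pca` object.
#' @param covariates Tibble with columns `specimen_id`, `curvature`,
#'   `robustness`, as returned by [shape_covariates()].
#' @return The `claw_pca` with signs fixed and `sign_anchor` filled with the
#'   per-axis correlation used.
#' @export
anchor_signs <- function(pca, covariates) {
  stopifnot(inherits(pca, "claw_pca"))
  covariates <- as_tibble(covariates)
  dat <- dplyr::left_join(
    pca$scores[, "specimen_id"], covariates,
    by = "specimen_id"
  )
  report <- list()
  for (ax in c(1L, 2L)) {
    pc_name <- paste0("PC", ax)
    cov_name <- c("curvature", "robustness")[ax]
    if (!pc_name %in% names(pca$scores)) next
    score <- pca$scores[[pc_name]]
    covar <- dat[[cov_name]]
    if (is.null(covar) || sd(covar) == 0 || sd(score) == 0) {
      warn(sprintf("zero-variance covariate or scores; sign anchoring skipped for %s", pc_name))
      next
    }
    r <- cor(score, covar)
    flipped <- r < 0
    if (flipped) {
      pca$scores[[pc_name]] <- -score
      pca$vectors[, ax] <- -pca$vectors[, ax]
      r <- -r
    }
    report[[length(report) + 1]] <- tibble(
      pc = ax, covariate = cov_name, correlation = r, flipped = flipped
    )
  }
  pca$sign_anchor <- dplyr::bind_rows(report)
  pca
}

#' Range of PC scores over a specimen set
#'
#' Max minus min of the chosen PC over the given specimens; invariant to
#' the eigenvector sign. Used to compare the within-taxon spread of claw
#' curvature (PC1) across taxa.
#'
#' @param pca A `claw_pca` object.
#' @param specimen_ids Specimen ids to include (default all).
#' @param pc Component number (default 1).
#' @return Non-negative scalar.
#' @export
pc_range <- function(pca, specimen_ids = NULL, pc = 1) {
  stopifnot(inherits(pca, "claw_pca"))
  sc <- pca$scores
  if (!is.null(specimen_ids)) {
    missing_ids <- setdiff(specimen_ids, sc$specimen_id)
    if (length(missing_ids) > 0) {
      abort(paste0("unknown specimen_id: ", paste(missing_ids, collapse = ", ")))
    }
    sc <- sc[sc$specimen_id %in% specimen_ids, ]
  }
  if (nrow(sc) == 0) abort("empty specimen set")
  v <- sc[[paste0("PC", pc)]]
  max(v) - min(v)
}

#' Per-group PC ranges
#'
#' Convenience wrapper computing [pc_range()] for every level of a grouping
#' column of the score table (e.g. taxon).
#'
#' @param pca A `claw_pca` object.
#' @param group Grouping column name (default `"taxon"`).
#' @param pc Component number.
#' @return Tibble with the group column, `n`, and `pc_range`.
#' @export
pc_range_by <- function(pca, group = "taxon", pc = 1) {
  sc <- pca$scores
  pcn <- paste0("PC", pc)
  dplyr::summarise(
    dplyr::group_by(sc, dplyr::across(dplyr::all_of(group))),
    n = dplyr::n(),
    pc_range = max(.data[[pcn]]) - min(.data[[pcn]]),
    .groups = "drop"
  )
}

#' @export
print.claw_pca <- function(x, ...) {
  cat(sprintf(
    "Shape-space PCA: %d specimens, %d components\n",
    nrow(x$scores), length(x$values)
  ))
  vf <- x$variance_fraction
  cat(sprintf(
    "  PC1 %.1f%%, PC2 %.1f%% of total variance\n",
    100 * vf[1], if (length(vf) > 1) 100 * vf[2] else 0
  ))
  if (nrow(x$sign_anchor) > 0) {
    cat("  signs anchored:", paste(
      sprintf(
        "PC%d~%s r=%.2f%s", x$sign_anchor$pc, x$sign_anchor$covariate,
        x$sign_anchor$correlation, ifelse(x$sign_anchor$flipped, " (flipped)", "")
      ),
      collapse = "; "
    ), "\n")
  }
  invisible(x)
}

#' @rdname fit_pca
#' @param x A `claw_pca` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy claw_pca
#' @export
tidy.claw_pca <- function(x, ...) x$scores

#' @rdname fit_pca
#' @method glance claw_pca
#' @export
glance.claw_pca <- function(x, ...) {
  tibble(
    n_specimens = nrow(x$scores),
    n_components = length(x$values),
    total_variance = sum(x$values),
    pc1_fraction = x$variance_fraction[1],
    pc2_fraction = if (length(x$values) > 1) x$variance_fraction[2] else NA_real_
  )
}

#' PC1-PC2 scatter of a shape space
#'
#' @param object A `claw_pca` object.
#' @param colour Metadata column mapped to colour (default `"clade"`).
#' @param shape Metadata column mapped to point shape (default `"digit"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot claw_pca
#' @export
autoplot.claw_pca <- function(object, colour = "clade", shape = "digit", ...) {
  vf <- object$variance_fraction
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(
      .data$PC1, .data$PC2,
      colour = .data[[colour]], shape = .data[[shape]]
    )
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[2])
    ) +
    ggplot2::theme_minimal()
}

# Thin-plate splines -----------------------------------------------------

#' Thin-plate-spline warp between two landmark configurations
#'
#' Fits the 2D interpolating thin-plate spline (kernel `r^2 log r^2`)
#' mapping `reference` landmarks exactly onto `target` landmarks, and maps
#' an optional grid of points through the warp. The affine part of the
#' deformation carries no bending energy, so affine targets report zero.
#'
#' @param reference,target k x 2 coordinate matrices (equal k).
#' @param grid Optional m x 2 matrix of points to map; by default a regular
#'   grid spanning the reference with a margin.
#' @param n_grid Grid resolution per axis when `grid` is `NULL`.
#' @return A `tps_grid` object: list with `reference`, `target`,
#'   `grid_before`, `grid_after`, `bending_energy` and `warp` (a function
#'   mapping an m x 2 matrix through the spline).
#' @export
#' @examples
#' ref <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' tps_warp(ref, ref)$bending_energy # identity: 0
tps_warp <- function(reference, target, grid = NULL, n_grid = 12) {
  reference <- as.matrix(reference)
  target <- as.matrix(target)
  if (!all(dim(reference) == dim(target))) {
    abort("reference and target must have the same landmark count")
  }
  k <- nrow(reference)
  if (anyDuplicated(round(reference, 12)) > 0) {
    abort("singular thin-plate-spline system: duplicate reference landmarks")
  }
  K <- tps_kernel_matrix(reference, reference)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    abort("singular thin-plate-spline system (collinear or duplicate reference landmarks)")
  })
  W <- coefs[1:k, , drop = FALSE]
  A <- coefs[(k + 1):(k + 3), , drop = FALSE]
  warp <- function(pts) {
    pts <- as.matrix(pts)
    U <- tps_kernel_matrix(pts, reference)
    cbind(1, pts) %*% A + U %*% W
  }
  if (is.null(grid)) {
    rx <- range(reference[, 1])
    ry <- range(reference[, 2])
    mx <- 0.1 * diff(rx)
    my <- 0.1 * diff(ry)
    grid <- as.matrix(expand.grid(
      x = seq(rx[1] - mx, rx[2] + mx, length.out = n_grid),
      y = seq(ry[1] - my, ry[2] + my, length.out = n_grid)
    ))
  } else {
    grid <- as.matrix(grid)
  }
  be <- sum(diag(t(W) %*% K %*% W))
  structure(
    list(
      reference = reference, target = target,
      grid_before = grid, grid_after = warp(grid),
      bending_energy = max(be, 0), warp = warp,
      n_grid = if (is.null(dim(grid))) NA_integer_ else n_grid
    ),
    class = "tps_grid"
  )
}

#' @export
print.tps_grid <- function(x, ...) {
  cat(sprintf(
    "Thin-plate-spline warp: %d landmarks, bending energy %.6g\n",
    nrow(x$reference), x$bending_energy
  ))
  invisible(x)
}

#' Deformation-grid plot of a thin-plate-spline warp
#'
#' Shows reference landmark positions (grey), target positions (black) and
#' the warped grid, in the style of classical deformation grids.
#'
#' @param object A `tps_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tps_grid
#' @export
autoplot.tps_grid <- function(object, ...) {
  g <- as_tibble(object$grid_after)
  names(g) <- c("x", "y")
  gb <- as_tibble(object$grid_before)
  names(gb) <- c("x0", "y0")
  g <- dplyr::bind_cols(g, gb)
  g$row <- round(g$y0, 9)
  g$col <- round(g$x0, 9)
  ref <- tibble(x = object$reference[, 1], y = object$reference[, 2])
  tar <- tibble(x = object$target[, 1], y = object$target[, 2])
  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = g, ggplot2::aes(.data$x, .data$y, group = .data$row),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_path(
      data = g, ggplot2::aes(.data$x, .data$y, group = .data$col),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(data = ref, ggplot2::aes(.data$x, .data$y), colour = "grey50", size = 1.5) +
    ggplot2::geom_point(data = tar, ggplot2::aes(.data$x, .data$y), colour = "black", size = 1.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Shape at a position along a principal component
#'
#' Reconstructs the landmark configuration `score` units along the chosen
#' PC from the mean shape; used with [tps_warp()] to draw the deformation
#' grids at the extremes of an axis.
#'
#' @param pca A `claw_pca` object.
#' @param pc Component number.
#' @param score Score value along the component.
#' @return k x 2 matrix of landmark coordinates.
#' @export
pc_shape <- function(pca, pc = 1, score = 0) {
  stopifnot(inherits(pca, "claw_pca"))
  v <- pca$center + score * pca$vectors[, pc]
  matrix(v, ncol = 2, byrow = TRUE)
}
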