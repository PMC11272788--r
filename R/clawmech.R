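# Lever-model biomechanics of ungual phalanges ---------------------------
#
# The claw is modeled as a class-3 lever: the flexor tendon pulls on the
# flexor tubercle (input), the joint surface at the ventroproximal corner
# of the articular facet is the fulcrum, and the claw tip is the resistance
# point. Mechanical advantage is MA = sin(theta + delta) * d / a with
#   a     output lever length, fulcrum -> tip (mm)
#   d     fulcrum -> flexor-tubercle apex length (mm)
#   theta angle of the input force vector to the output-lever line (deg)
#   delta angle between the fulcrum->tubercle line and the output-lever
#         line (deg).
# Flexor-tubercle development (DFT) is the perpendicular height of the
# tubercle apex over its base segment divided by the base length, and the
# hypothesized output force is HO = DFT * MA.

#' Default fixed-landmark role mapping
#'
#' Which landmark indices carry the anatomical roles the lever model needs.
#' The defaults follow [claw_landmark_scheme()]; pass a modified list to
#' [lever_geometry()] for datasets digitized under a different scheme.
#'
#' @return Named list: `facet_dorsal`, `fulcrum`, `tubercle`, `tip`
#'   (single indices) and `tubercle_base` (the two outline semi-landmarks
#'   flanking the tubercle apex along the ventral curve).
#' @export
landmark_roles <- function() {
  list(
    facet_dorsal = 1L, fulcrum = 2L, tubercle = 3L, tip = 4L,
    tubercle_base = c(13L, 14L)
  )
}

#' Lever geometry of each claw configuration
#'
#' Extracts the lever-model measurements from the raw (unaligned) landmark
#' coordinates of every specimen: output lever `a` (fulcrum to tip), input
#' arm `d` (fulcrum to tubercle apex), the angles `theta` and `delta`, and
#' the flexor-tubercle height/base geometry.
#'
#' `theta` depends on the force-direction convention. Under the default
#' `"facet_normal"`, the input force vector is taken perpendicular to the
#' proximal articular facet line (dorsal facet corner to fulcrum), directed
#' proximally, approximating the flexor tendon's pull across the joint;
#' `theta` is the angle between that vector and the output-lever line,
#' folded to [0, 90] degrees since only the line's orientation matters.
#' Under `"user_theta"` a per-specimen `theta` is supplied directly.
#'
#' @param x A `landmark_tbl`.
#' @param force_convention `"facet_normal"` (default) or `"user_theta"`.
#' @param theta Numeric vector of per-specimen angles in degrees (recycled),
#'   required for `"user_theta"`.
#' @param roles Landmark role mapping, see [landmark_roles()].
#' @return Tibble with one row per specimen: metadata plus `a`, `d`,
#'   `theta`, `delta`, `tubercle_perp`, `tubercle_base` (mm and degrees).
#' @export
lever_geometry <- function(x, force_convention = c("facet_normal", "user_theta"),
                           theta = NULL, roles = landmark_roles()) {
  force_convention <- match.arg(force_convention)
  validate_landmark_tbl(x)
  shapes <- lm_split(x)
  meta <- lm_meta(x)
  if (force_convention == "user_theta") {
    if (is.null(theta)) abort("force_convention 'user_theta' requires `theta`")
    theta <- rep_len(theta, length(shapes))
  }
  rows <- lapply(seq_along(shapes), function(i) {
    m <- shapes[[i]]
    fulcrum <- m[roles$fulcrum, ]
    tip <- m[roles$tip, ]
    tub <- m[roles$tubercle, ]
    facet <- m[roles$facet_dorsal, ]
    lever <- tip - fulcrum
    a <- sqrt(sum(lever^2))
    if (a == 0) abort(paste0("coincident fulcrum and tip for specimen ", names(shapes)[i]))
    arm <- tub - fulcrum
    d <- sqrt(sum(arm^2))
    delta <- if (d > 0) angle_between_deg(arm, lever) else 0
    th <- if (force_convention == "user_theta") {
      theta[i]
    } else {
      facet_vec <- facet - fulcrum
      if (sqrt(sum(facet_vec^2)) == 0) {
        abort(paste0("degenerate articular facet for specimen ", names(shapes)[i]))
      }
      # normal to the facet line, folded to the line angle in [0, 90]
      nrm <- c(-facet_vec[2], facet_vec[1])
      ang <- angle_between_deg(nrm, lever)
      min(ang, 180 - ang)
    }
    base_pts <- m[roles$tubercle_base, , drop = FALSE]
    base_len <- sqrt(sum((base_pts[2, ] - base_pts[1, ])^2))
    perp <- if (base_len > 0) point_line_distance(tub, base_pts[1, ], base_pts[2, ]) else NA_real_
    tibble(
      specimen_id = names(shapes)[i], a = a, d = d, theta = th, delta = delta,
      tubercle_perp = perp, tubercle_base = base_len
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(meta, out, by = "specimen_id")
}

#' Mechanical advantage of a claw lever
#'
#' `MA = sin(theta + delta) * d / a`: the proportion of the input force at
#' the flexor tubercle delivered at the claw tip. Angles in degrees.
#'
#' @param theta,delta Angles in degrees (see [lever_geometry()]).
#' @param d Input arm length, fulcrum to tubercle apex.
#' @param a Output lever length, fulcrum to tip; must be positive.
#' @return Numeric vector of mechanical advantages.
#' @export
#' @examples
#' mechanical_advantage(theta = 30, delta = 30, d = 5, a = 10) # sin(60) * 0.5
mechanical_advantage <- function(theta, delta, d, a) {
  if (any(a <= 0)) abort("output lever length `a` must be positive")
  sin((theta + delta) * pi / 180) * d / a
}

#' Development of the flexor tubercle
#'
#' Ratio of the perpendicular height of the tubercle apex over its base
#' segment to the base-segment length; a dimensionless proxy of the
#' flexor-muscle input force.
#'
#' @param tubercle_perp Perpendicular apex height.
#' @param tubercle_base Base-segment length; must be positive.
#' @return Numeric vector of DFT values.
#' @export
dft <- function(tubercle_perp, tubercle_base) {
  if (any(tubercle_base <= 0, na.rm = TRUE)) abort("tubercle base length must be positive")
  tubercle_perp / tubercle_base
}

#' Hypothesized output force
#'
#' The product DFT x MA: relative input force times the fraction of it
#' delivered at the tip.
#'
#' @param ma Mechanical advantage.
#' @param dft_value Development of the flexor tubercle.
#' @return Numeric vector `dft_value * ma`.
#' @export
hypothesized_output <- function(ma, dft_value) {
  dft_value * ma
}

#' Per-specimen claw function scores
#'
#' Convenience pipeline: [lever_geometry()] plus the derived MA, DFT and HO
#' columns, one row per specimen.
#'
#' @inheritParams lever_geometry
#' @return Tibble: metadata, lever measurements, and `MA`, `DFT`, `HO`.
#' @export
claw_scores <- function(x, force_convention = c("facet_normal", "user_theta"),
                        theta = NULL, roles = landmark_roles()) {
  geom <- lever_geometry(x, force_convention, theta = theta, roles = roles)
  dplyr::mutate(
    geom,
    MA = mechanical_advantage(.data$theta, .data$delta, .data$d, .data$a),
    DFT = dft(.data$tubercle_perp, .data$tubercle_base),
    HO = hypothesized_output(.data$MA, .data$DFT)
  )
}

#' Curvature and robustness indices of claw configurations
#'
#' Similarity-invariant shape covariates used to anchor PC signs
#' ([anchor_signs()]):
#' \describe{
#'   \item{curvature}{`1 - chord / polyline`, where the chord runs from the
#'     dorsoproximal corner of the articular facet to the tip and the
#'     polyline follows the dorsal-curve landmarks between those same two
#'     points; 0 for a straight claw (all dorsal landmarks on the chord),
#'     approaching 1 for strongly recurved ones.}
#'   \item{robustness}{maximum landmark height perpendicular to the
#'     facet-midpoint-to-tip chord, divided by chord length, plus DFT:
#'     short, high claws with enlarged flexor tubercles score high.}
#' }
#'
#' @param x A `landmark_tbl`.
#' @param roles Landmark role mapping, see [landmark_roles()].
#' @return Tibble with columns `specimen_id`, `curvature`, `robustness`.
#' @export
shape_covariates <- function(x, roles = landmark_roles()) {
  validate_landmark_tbl(x)
  shapes <- lm_split(x)
  scheme <- attr(x, "sliders")
  # dorsal chain: facet corner -> dorsal semis -> tip, in curve order
  dorsal_semis <- chain_order(scheme, roles$facet_dorsal, roles$tip)
  scores <- claw_scores(x, roles = roles)
  rows <- lapply(seq_along(shapes), function(i) {
    m <- shapes[[i]]
    # curvature: straightness of the dorsal curve between its own endpoints
    dors_a <- m[roles$facet_dorsal, ]
    tip <- m[roles$tip, ]
    dors_chord <- sqrt(sum((tip - dors_a)^2))
    if (dors_chord == 0) abort(paste0("degenerate chord for specimen ", names(shapes)[i]))
    poly <- polyline_length(m[c(roles$facet_dorsal, dorsal_semis, roles$tip), , drop = FALSE])
    curvature <- 1 - dors_chord / poly
    # robustness: relative height over the facet-midpoint-to-tip chord
    chord_a <- (m[roles$facet_dorsal, ] + m[roles$fulcrum, ]) / 2
    chord <- sqrt(sum((tip - chord_a)^2))
    if (chord == 0) abort(paste0("degenerate chord for specimen ", names(shapes)[i]))
    heights <- vapply(
      seq_len(nrow(m)),
      function(j) point_line_distance(m[j, ], chord_a, tip), numeric(1)
    )
    tibble(
      specimen_id = names(shapes)[i],
      curvature = curvature,
      robustness = max(heights) / chord
    )
  })
  out <- dplyr::bind_rows(rows)
  out$robustness <- out$robustness + scores$DFT[match(out$specimen_id, scores$specimen_id)]
  out
}

# order the semi-landmarks of the curve segment running from `from` to `to`
# by walking the sliders chain
chain_order <- function(sliders, from, to) {
  # walk successor semi-landmarks starting at `from` until the chain ends
  out <- integer(0)
  current <- from
  repeat {
    nxt <- sliders$slide[sliders$before == current]
    if (length(nxt) == 0 || length(out) > nrow(sliders)) break
    out <- c(out, nxt[1])
    current <- nxt[1]
  }
  out
}
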