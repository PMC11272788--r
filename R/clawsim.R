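# Synthetic claw generator -----------------------------------------------
#
# Claw outlines are built from a logarithmic-spiral midline
# r = r0 * exp(spiral_k * phi) swept over a polar angle proportional to
# spiral_k, so spiral_k = 0 is a straight claw and larger values give
# progressively more strongly curved ones. Dorsal and ventral borders are
# normal offsets of the midline whose half-width tapers to zero at the
# shared distal tip; a triangular flexor-tubercle bump of relative height
# tubercle_h is inserted on the ventral border. The 4 fixed landmarks and
# 12 semi-landmarks follow claw_landmark_scheme(); semi-landmarks are
# placed equally spaced by arc length on the noise-free borders, then
# isotropic Gaussian digitization noise is added.

#' Parameters of a synthetic claw
#'
#' @param spiral_k Curvature coefficient of the logarithmic-spiral midline
#'   (dimensionless, >= 0; 0 is straight).
#' @param aspect Height/length ratio of the claw (> 0).
#' @param tubercle_h Flexor-tubercle height as a fraction of claw height
#'   (in `[0, 1)`).
#' @param tubercle_pos Fractional arc-length position of the tubercle along
#'   the ventral border (in `(0, 1)`).
#' @param size_mm Centroid size of the noise-free configuration, mm.
#' @param noise_sd Digitization noise standard deviation as a fraction of
#'   `size_mm` (>= 0).
#' @param seed Integer seed for the noise.
#' @return A validated list of class `claw_params`.
#' @export
claw_params <- function(spiral_k = 0.25, aspect = 0.5, tubercle_h = 0.25,
                        tubercle_pos = 0.3, size_mm = 15, noise_sd = 0.005,
                        seed = 1L) {
  p <- list(
    spiral_k = spiral_k, aspect = aspect, tubercle_h = tubercle_h,
    tubercle_pos = tubercle_pos, size_mm = size_mm, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  if (p$spiral_k < 0) abort("spiral_k must be >= 0")
  if (p$aspect <= 0) abort("aspect must be > 0")
  if (p$tubercle_h < 0 || p$tubercle_h >= 1) abort("tubercle_h must be in [0, 1)")
  if (p$tubercle_pos <= 0 || p$tubercle_pos >= 1) abort("tubercle_pos must be in (0, 1)")
  if (p$size_mm <= 0) abort("size_mm must be > 0")
  if (p$noise_sd < 0) abort("noise_sd must be >= 0")
  class(p) <- "claw_params"
  p
}

# dense noise-free borders of a claw; returns list(dorsal, ventral, tip)
claw_borders <- function(p, n_dense = 400) {
  tt <- seq(0, 1, length.out = n_dense)
  phi_max <- 4 * p$spiral_k
  if (phi_max > 0) {
    phi <- tt * phi_max
    mid <- exp(p$spiral_k * phi) * cbind(cos(-phi), sin(-phi))
  } else {
    mid <- cbind(tt, 0 * tt)
  }
  # orient: chord along +x, curving ventrally (down)
  chord <- mid[n_dense, ] - mid[1, ]
  ang <- atan2(chord[2], chord[1])
  mid <- rotate_coords(sweep(mid, 2, mid[1, ]), -ang)
  if (mean(mid[, 2]) > 0) mid[, 2] <- -mid[, 2] # bend downward
  chord_len <- mid[n_dense, 1]
  mid <- mid / chord_len # unit chord length

  # unit normals pointing dorsally (up-ish)
  tang <- rbind(mid[2, ] - mid[1, ], (mid[3:n_dense, ] - mid[1:(n_dense - 2), ]) / 2,
    mid[n_dense, ] - mid[n_dense - 1, ]
  )
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2], tang[, 1])
  flip <- nrm[1, 2] < 0
  if (flip) nrm <- -nrm

  # height as fraction of (unit) chord length; linear taper so a straight
  # midline yields an exactly straight dorsal border
  h <- p$aspect
  taper <- 1 - tt
  dorsal <- mid + nrm * (h / 2) * taper
  ventral <- mid - nrm * (h / 2) * taper

  # triangular tubercle bump on the ventral border, pointing ventrally
  wd <- 0.12
  bump <- pmax(0, 1 - abs(tt - p$tubercle_pos) / wd)
  ventral <- ventral - nrm * (p$tubercle_h * h) * bump

  apex_idx <- which.min(abs(tt - p$tubercle_pos))
  list(dorsal = dorsal, ventral = ventral, tip = mid[n_dense, ], apex_idx = apex_idx)
}

#' Generate one synthetic claw configuration
#'
#' @param params A [claw_params()] object (or arguments passed on to it).
#' @param specimen_id,taxon,digit,clade,side Metadata for the configuration.
#' @param ... Parameters forwarded to [claw_params()] when `params` is
#'   `NULL`.
#' @return A `landmark_tbl` with one specimen under the default 16-landmark
#'   scheme. Deterministic for a fixed seed.
#' @export
#' @examples
#' claw <- generate_claw(claw_params(spiral_k = 0.4, seed = 7))
#' claw_scores(claw)[, c("MA", "DFT", "HO")]
generate_claw <- function(params = NULL, specimen_id = "claw_1", taxon = specimen_id,
                          digit = "unassigned", clade = "undecided", side = "left",
                          ...) {
  p <- params %||% claw_params(...)
  stopifnot(inherits(p, "claw_params"))
  b <- claw_borders(p)
  n_d <- nrow(b$dorsal)

  lm1 <- b$dorsal[1, ]
  lm2 <- b$ventral[1, ]
  lm3 <- b$ventral[b$apex_idx, ]
  lm4 <- b$tip
  dorsal_semis <- arc_length_points(b$dorsal, 6)
  vent_prox <- arc_length_points(b$ventral[1:b$apex_idx, , drop = FALSE], 3)
  vent_dist <- arc_length_points(b$ventral[b$apex_idx:n_d, , drop = FALSE], 3)
  coords <- unname(rbind(lm1, lm2, lm3, lm4, dorsal_semis, vent_prox, vent_dist))
  dimnames(coords) <- NULL

  coords <- center_coords(coords)
  coords <- coords * (p$size_mm / centroid_size(coords))
  if (p$noise_sd > 0) {
    coords <- coords + with_local_seed(p$seed, {
      matrix(rnorm(length(coords), sd = p$noise_sd * p$size_mm), ncol = 2)
    })
  }

  scheme <- claw_landmark_scheme()
  landmark_table(
    tibble(
      specimen_id = specimen_id, taxon = taxon, digit = digit, clade = clade,
      side = side, landmark = seq_len(16), role = scheme$roles,
      x = coords[, 1], y = coords[, 2]
    ),
    sliders = scheme$sliders
  )
}

# run `expr` under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default parameter ranges of the synthetic population
#'
#' Uniform sampling ranges chosen to span the spread of claw shapes in a
#' small theropod ungual sample: curvature from nearly straight to strongly
#' recurved, moderate aspect ratios, and tubercles from weak to prominent.
#'
#' @return Named list of `c(lower, upper)` ranges for `spiral_k`, `aspect`,
#'   `tubercle_h`, `tubercle_pos` and `size_mm`.
#' @export
claw_param_ranges <- function() {
  list(
    spiral_k = c(0.05, 0.5),
    aspect = c(0.35, 0.65),
    tubercle_h = c(0.10, 0.40),
    tubercle_pos = c(0.20, 0.40),
    size_mm = c(8, 30)
  )
}

# per-specimen sub-seed, below 2^31
specimen_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + as.numeric(i) * 9973) %% 2147483629)
}

#' Generate a synthetic claw population
#'
#' Draws per-specimen shape parameters uniformly from `ranges` with
#' specimen-wise sub-seeds derived from `seed` (so individual draws are
#' independent and the population is extensible), generates each claw, and
#' labels digits cyclically I, II, III across specimens. One taxon is
#' created per three consecutive specimens; the first taxon is labeled
#' troodontine, the remainder non-troodontine, mimicking a sample with one
#' focal derived taxon.
#'
#' @param n Number of specimens (>= 2).
#' @param ranges Parameter ranges as from [claw_param_ranges()]; a range
#'   collapsed to a point fixes that parameter.
#' @param noise_sd Digitization noise fraction applied to every specimen.
#' @param seed Master seed.
#' @param params Optional tibble of explicit per-specimen parameters
#'   (columns among `spiral_k`, `aspect`, `tubercle_h`, `tubercle_pos`,
#'   `size_mm`, and optionally `noise_sd`), overriding the uniform draws;
#'   used for designed populations such as single-factor or coupled-factor
#'   recovery experiments.
#' @return A `landmark_tbl` of `n` specimens carrying the true generating
#'   parameters as the `"truth"` attribute (see [population_truth()]).
#' @export
generate_population <- function(n = 20, ranges = claw_param_ranges(),
                                noise_sd = 0.005, seed = 1L, params = NULL) {
  if (n < 2) abort("population size must be >= 2")
  draws <- lapply(seq_len(n), function(i) {
    si <- specimen_seed(seed, i)
    u <- with_local_seed(si, runif(length(ranges)))
    vals <- mapply(function(rg, ui) rg[1] + ui * (rg[2] - rg[1]), ranges, u)
    out <- as.list(vals)
    out$noise_sd <- noise_sd
    if (!is.null(params)) {
      for (nm in intersect(names(params), c(
        "spiral_k", "aspect", "tubercle_h",
        "tubercle_pos", "size_mm", "noise_sd"
      ))) {
        out[[nm]] <- params[[nm]][i]
      }
    }
    out$seed <- specimen_seed(si, 77L)
    out
  })
  digits <- rep(c("I", "II", "III"), length.out = n)
  taxa <- sprintf("taxon_%02d", ceiling(seq_len(n) / 3))
  clades <- ifelse(taxa == "taxon_01", "troodontine", "non_troodontine")
  tbls <- lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    generate_claw(
      claw_params(
        spiral_k = d$spiral_k, aspect = d$aspect, tubercle_h = d$tubercle_h,
        tubercle_pos = d$tubercle_pos, size_mm = d$size_mm,
        noise_sd = d$noise_sd, seed = d$seed
      ),
      specimen_id = sprintf("sim_%03d", i), taxon = taxa[i], digit = digits[i],
      clade = clades[i]
    )
  })
  df <- dplyr::bind_rows(lapply(tbls, as_tibble))
  out <- landmark_table(df, sliders = claw_landmark_scheme()$sliders)
  truth <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    tibble(
      specimen_id = sprintf("sim_%03d", i), taxon = taxa[i], digit = digits[i],
      spiral_k = d$spiral_k, aspect = d$aspect, tubercle_h = d$tubercle_h,
      tubercle_pos = d$tubercle_pos, size_mm = d$size_mm,
      noise_sd = d$noise_sd, seed = d$seed
    )
  }))
  attr(out, "truth") <- truth
  out
}

#' True generating parameters of a synthetic population
#'
#' @param x A `landmark_tbl` produced by [generate_population()].
#' @return Tibble of the per-specimen generating parameters.
#' @export
population_truth <- function(x) {
  tr <- attr(x, "truth")
  if (is.null(tr)) abort("no truth table attached; was this table generated by generate_population()?")
  tr
}
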