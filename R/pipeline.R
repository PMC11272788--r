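# End-to-end orchestration -----------------------------------------------
#
# Thin wrappers tying the stages into the full analysis: landmarks in,
# aligned shapes, shape space, lever scores, shape-function regression and
# summaries out, every output file stamped with the configuration hash and
# seed so runs are reproducible and auditable.

#' Assemble and validate a run configuration
#'
#' @param input Path to a landmark file (TPS or CSV), or a `landmark_tbl`
#'   already in memory.
#' @param format Landmark file format, see [read_landmarks()].
#' @param sliders Sliding scheme override, see [read_landmarks()].
#' @param flip_y Negate y on input (image-origin TPS files).
#' @param sliding_method,tol,max_iter,slide_iter GPA options, see
#'   [gpa_align()].
#' @param anchor Apply [anchor_signs()] to the PCA.
#' @param force_convention,theta Lever-model options, see
#'   [lever_geometry()].
#' @param n_boot,boot_seed Bootstrap options for [sma_fit()].
#' @param out_dir Output directory (created if absent).
#' @param write_figures Also write SVG figures (requires cairo support in
#'   the R build).
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, format = "auto", sliders = NULL, flip_y = FALSE,
                       sliding_method = "bending_energy", tol = 1e-8,
                       max_iter = 100, slide_iter = 5L, anchor = TRUE,
                       force_convention = "facet_normal", theta = NULL,
                       n_boot = 2000, boot_seed = 20240725,
                       out_dir = tempfile("clawmorph_run_"),
                       write_figures = FALSE) {
  if (is.character(input) && !file.exists(input)) {
    abort(paste0("input file not found: ", input))
  }
  if (is.character(sliders) && !file.exists(sliders)) {
    abort(paste0("sliders file not found: ", sliders))
  }
  cfg <- list(
    input = input, format = format, sliders = sliders, flip_y = flip_y,
    sliding_method = match.arg(sliding_method, c("bending_energy", "procrustes_distance")),
    tol = tol, max_iter = max_iter, slide_iter = slide_iter, anchor = anchor,
    force_convention = match.arg(force_convention, c("facet_normal", "user_theta")),
    theta = theta, n_boot = n_boot, boot_seed = boot_seed,
    out_dir = out_dir, write_figures = write_figures
  )
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  key <- cfg
  key$input <- if (is.character(key$input)) key$input else "in-memory"
  rlang::hash(key)
}

stamp_line <- function(cfg) {
  sprintf(
    "# clawmorph %s | config_hash=%s | seed=%d",
    as.character(utils::packageVersion("clawmorph")), config_hash(cfg), cfg$boot_seed
  )
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, open = "wb") # binary mode: LF line endings on all platforms
  on.exit(close(con))
  writeLines(stamp, con)
  df <- as.data.frame(df)
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.12g", df[[nm]])
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full morphometric and biomechanical analysis
#'
#' Executes read (with right-side mirroring) -> generalized Procrustes
#' alignment with sliding semi-landmarks -> PCA -> sign anchoring ->
#' lever scores (MA, DFT, HO) -> SMA regression of MA on PC2 -> per-digit
#' summaries, and writes the result tables (and optionally figures) to the
#' configured output directory. All CSVs carry a header comment with the
#' configuration hash and bootstrap seed; identical configurations produce
#' byte-identical numeric output.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with `gpa`, `pca`, `covariates`, `scores`,
#'   `sma`, `summaries`, `outliers` and `files` (paths written).
#' @export
run_morpho <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  x <- if (is.character(cfg$input)) {
    read_landmarks(cfg$input, cfg$format, sliders = cfg$sliders, flip_y = cfg$flip_y)
  } else {
    cfg$input
  }
  gpa <- gpa_align(
    x,
    sliding_method = cfg$sliding_method, tol = cfg$tol,
    max_iter = cfg$max_iter, slide_iter = cfg$slide_iter
  )
  pca <- fit_pca(gpa)
  covs <- shape_covariates(x)
  if (cfg$anchor) pca <- anchor_signs(pca, covs)
  scores <- claw_scores(x, cfg$force_convention, theta = cfg$theta)
  scores_pc <- dplyr::left_join(
    scores,
    pca$scores[, c("specimen_id", intersect(c("PC1", "PC2"), names(pca$scores)))],
    by = "specimen_id"
  )
  sma <- sma_fit(scores_pc, PC2, MA, n_boot = cfg$n_boot, seed = cfg$boot_seed)
  outliers <- sma_residual_outliers(sma, ids = scores_pc$specimen_id)
  summaries <- dplyr::bind_rows(lapply(c("MA", "DFT", "HO"), function(mt) {
    gs <- group_summary(scores_pc, .data[[mt]], digit)
    gs$metric <- mt
    gs[, c("metric", setdiff(names(gs), c("metric", "outliers")))]
  }))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- stamp_line(cfg)
  files <- c(
    aligned = write_stamped_csv(
      tidy(gpa), file.path(cfg$out_dir, "aligned_coords.csv"), stamp
    ),
    pc_scores = write_stamped_csv(
      tidy(pca), file.path(cfg$out_dir, "pc_scores.csv"), stamp
    ),
    variance = write_stamped_csv(
      tibble(
        pc = seq_along(pca$values), eigenvalue = pca$values,
        variance_fraction = pca$variance_fraction
      ),
      file.path(cfg$out_dir, "variance_fractions.csv"), stamp
    ),
    scores = write_stamped_csv(
      scores_pc, file.path(cfg$out_dir, "claw_scores.csv"), stamp
    ),
    summaries = write_stamped_csv(
      summaries, file.path(cfg$out_dir, "group_summaries.csv"), stamp
    ),
    covariates = write_stamped_csv(
      covs, file.path(cfg$out_dir, "shape_covariates.csv"), stamp
    )
  )
  consensus_path <- file.path(cfg$out_dir, "consensus.tps")
  consensus_tbl <- landmark_table(
    dplyr::mutate(gpa$consensus, specimen_id = "consensus"),
    sliders = attr(x, "sliders")
  )
  write_landmarks(consensus_tbl, consensus_path, format = "tps")
  files <- c(files, consensus = consensus_path)

  fit_path <- file.path(cfg$out_dir, "sma_fit.txt")
  g <- glance(sma)
  writeLines(c(
    stamp,
    sprintf("response: MA"), sprintf("predictor: PC2"),
    sprintf("n: %d", g$nobs),
    sprintf("slope: %.10g", g$slope),
    sprintf("intercept: %.10g", g$intercept),
    sprintf("r_squared: %.10g", g$r.squared),
    sprintf("p_value: %.10g", g$p.value),
    sprintf("slope_ci: %.10g %.10g", sma$slope_ci[1], sma$slope_ci[2]),
    sprintf("bootstrap: %d resamples, seed %d", sma$n_boot, sma$seed)
  ), fit_path)
  files <- c(files, sma = fit_path)

  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(c(
    stamp,
    sprintf("n_specimens: %d", nrow(gpa$meta)),
    sprintf("sliding_method: %s", gpa$sliding_method),
    sprintf("gpa_iterations: %d", gpa$iterations),
    sprintf("gpa_converged: %s", gpa$converged),
    sprintf("anchored: %s", cfg$anchor),
    sprintf("force_convention: %s", cfg$force_convention),
    sprintf("R_version: %s", as.character(getRversion()))
  ), log_path)
  files <- c(files, log = log_path)

  if (isTRUE(cfg$write_figures) && capabilities("cairo")) {
    fig <- function(name, plot, w = 6, h = 4.5) {
      p <- file.path(cfg$out_dir, name)
      grDevices::svg(p, width = w, height = h)
      print(plot)
      grDevices::dev.off()
      p
    }
    files <- c(
      files,
      fig_pca = fig("pc_scatter.svg", autoplot(pca)),
      fig_sma = fig("sma_regression.svg", autoplot(sma)),
      fig_box = fig("score_boxplots.svg", plot_score_boxplots(scores_pc))
    )
  }

  invisible(list(
    gpa = gpa, pca = pca, covariates = covs, scores = scores_pc, sma = sma,
    summaries = summaries, outliers = outliers, files = files
  ))
}

#' Generate and write a synthetic claw population
#'
#' @param out_dir Output directory.
#' @param n,ranges,noise_sd,seed,params See [generate_population()].
#' @param format `"csv"` (default; carries taxon/digit/clade metadata) or
#'   `"tps"` (landmarks only).
#' @return Invisibly, a list with the `landmark_tbl` and the paths written
#'   (landmarks plus ground-truth parameter table).
#' @export
run_simulate <- function(out_dir, n = 20, ranges = claw_param_ranges(),
                         noise_sd = 0.005, seed = 1L, params = NULL,
                         format = c("csv", "tps")) {
  format <- match.arg(format)
  pop <- generate_population(n = n, ranges = ranges, noise_sd = noise_sd, seed = seed, params = params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lm_path <- file.path(out_dir, paste0("landmarks.", format))
  write_landmarks(pop, lm_path, format = format)
  truth_path <- file.path(out_dir, "truth.csv")
  write.table(population_truth(pop), truth_path,
    sep = ",", quote = FALSE,
    row.names = FALSE
  )
  invisible(list(population = pop, files = c(landmarks = lm_path, truth = truth_path)))
}

#' Score a character matrix on a tree and write the report
#'
#' @param matrix Path to a TNT/NEXUS matrix or a `character_matrix`.
#' @param tree Newick file, newick string or `phylo` object.
#' @param out_dir Optional output directory for `parsimony_score.txt` and
#'   `state_changes.csv`.
#' @return Invisibly, a list with `score` (a `parsimony_score`), `changes`
#'   (tibble of branch state changes) and `files`.
#' @export
run_parsimony <- function(matrix, tree, out_dir = NULL) {
  cm <- if (inherits(matrix, "character_matrix")) matrix else read_character_matrix(matrix)
  score <- fitch_length(tree, cm)
  changes <- map_changes(tree, cm)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sp <- file.path(out_dir, "parsimony_score.txt")
    writeLines(c(
      sprintf("tree_length: %d", score$tree_length),
      sprintf("ci: %s", ifelse(is.na(score$ci), "undefined", sprintf("%.6f", score$ci))),
      sprintf("ri: %s", ifelse(is.na(score$ri), "undefined", sprintf("%.6f", score$ri))),
      sprintf("n_taxa: %d", score$n_taxa),
      sprintf("n_characters: %d", score$n_char)
    ), sp)
    cp <- file.path(out_dir, "state_changes.csv")
    write.table(as.data.frame(changes), cp, sep = ",", quote = FALSE, row.names = FALSE)
    files <- c(score = sp, changes = cp)
  }
  invisible(list(score = score, changes = changes, files = files))
}
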