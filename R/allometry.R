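# Standardized major axis regression and per-digit summaries -------------

#' Standardized major axis (SMA) regression
#'
#' Symmetric line fitting for structural relationships between two
#' variables measured with error: slope = sign(r) * sd(y) / sd(x),
#' intercept through the means. Equivalently, the line minimizing the sum
#' of the triangle areas spanned by each point and the line. The p-value
#' tests r = 0 via the t statistic with n - 2 degrees of freedom
#' (two-sided); the slope confidence interval uses the standard SMA pivot
#' on r (Warton et al. 2006), and the confidence band around the fitted
#' line comes from a seeded percentile bootstrap of the fit.
#'
#' @param data Data frame containing the variables, or `NULL` to pass `x`
#'   and `y` as numeric vectors.
#' @param x,y Column names (unquoted, when `data` is given) or numeric
#'   vectors.
#' @param level Confidence level for the slope interval and the band.
#' @param n_boot Bootstrap resamples for the band.
#' @param seed Seed for the bootstrap (fixed default so reports are
#'   reproducible).
#' @return An `sma_fit` object: list with `slope`, `intercept`, `r`,
#'   `r_squared`, `n`, `p_value`, `slope_ci`, `band` (tibble `x`, `fit`,
#'   `lower`, `upper`), `level` and the input `data` tibble.
#' @export
#' @examples
#' d <- data.frame(x = 1:8, y = 2 * (1:8) + rnorm(8, sd = 0.1))
#' fit <- sma_fit(d, x, y)
#' glance(fit)
sma_fit <- function(data = NULL, x, y, level = 0.95, n_boot = 2000, seed = 20240725) {
  if (is.data.frame(data)) {
    xv <- eval_tidy(enquo(x), data)
    yv <- eval_tidy(enquo(y), data)
  } else {
    xv <- x
    yv <- y
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort("SMA regression needs at least 3 complete observations")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance in x or y")
  r <- cor(xv, yv)
  slope <- sign_or_one(r) * sd(yv) / sd(xv)
  intercept <- mean(yv) - slope * mean(xv)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p_value <- 2 * pt(-abs(tstat), df = n - 2)
  # SMA slope CI (Warton et al. 2006, Biol. Rev.): B from the F quantile
  B <- qf(level, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(slope * c(sqrt(B + 1) + sqrt(B), sqrt(B + 1) - sqrt(B)))
  band <- sma_boot_band(xv, yv, level, n_boot, seed)
  structure(
    list(
      slope = slope, intercept = intercept, r = r, r_squared = r^2,
      n = n, p_value = p_value, slope_ci = ci, band = band, level = level,
      n_boot = n_boot, seed = seed,
      data = tibble(x = xv, y = yv)
    ),
    class = "sma_fit"
  )
}

sign_or_one <- function(r) if (r < 0) -1 else 1

sma_boot_band <- function(xv, yv, level, n_boot, seed) {
  n <- length(xv)
  grid <- seq(min(xv), max(xv), length.out = 100)
  preds <- matrix(NA_real_, n_boot, length(grid))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- xv[idx]
    yb <- yv[idx]
    if (sd(xb) == 0 || sd(yb) == 0) next
    rb <- cor(xb, yb)
    sb <- sign_or_one(rb) * sd(yb) / sd(xb)
    ib <- mean(yb) - sb * mean(xb)
    preds[b, ] <- ib + sb * grid
    b <- b + 1L
  }
  alpha <- (1 - level) / 2
  qs <- apply(preds, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  r <- cor(xv, yv)
  slope <- sign_or_one(r) * sd(yv) / sd(xv)
  tibble(
    x = grid,
    fit = mean(yv) - slope * mean(xv) + slope * grid,
    lower = qs[1, ],
    upper = qs[2, ]
  )
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf(
    "SMA regression (n = %d): y = %.4g + %.4g x\n", x$n, x$intercept, x$slope
  ))
  cat(sprintf(
    "  R^2 = %.4f, p = %.3g, slope %d%% CI [%.4g, %.4g]\n",
    x$r_squared, x$p_value, round(100 * x$level), x$slope_ci[1], x$slope_ci[2]
  ))
  invisible(x)
}

#' @rdname sma_fit
#' @method tidy sma_fit
#' @export
tidy.sma_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$slope_ci[1]),
    conf.high = c(NA_real_, x$slope_ci[2])
  )
}

#' @rdname sma_fit
#' @method glance sma_fit
#' @export
glance.sma_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
    slope = x$slope, intercept = x$intercept
  )
}

#' Regression plot with confidence band
#'
#' @param object An `sma_fit` object.
#' @param ... Unused.
#' @return A ggplot object: data points, SMA line, bootstrap band.
#' @method autoplot sma_fit
#' @export
autoplot.sma_fit <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(.data$x, ymin = .data$lower, ymax = .data$upper),
      fill = "lightblue", alpha = 0.6
    ) +
    ggplot2::geom_line(
      data = object$band, ggplot2::aes(.data$x, .data$fit),
      colour = "steelblue4"
    ) +
    ggplot2::geom_point(data = object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::theme_minimal()
}

#' Points outside the SMA confidence band
#'
#' Flags observations whose y lies outside the bootstrap confidence band
#' at their x (band interpolated linearly between grid points).
#'
#' @param fit An `sma_fit` object.
#' @param ids Optional vector of labels for the observations (defaults to
#'   row numbers).
#' @return Tibble with `id`, `x`, `y`, `lower`, `upper`, `above`, `below`,
#'   `flagged`.
#' @export
sma_residual_outliers <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "sma_fit"))
  d <- fit$data
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  lo <- approx(fit$band$x, fit$band$lower, xout = d$x, rule = 2)$y
  hi <- approx(fit$band$x, fit$band$upper, xout = d$x, rule = 2)$y
  tibble(
    id = ids, x = d$x, y = d$y, lower = lo, upper = hi,
    above = d$y > hi, below = d$y < lo,
    flagged = d$y > hi | d$y < lo
  )
}

#' Five-number summaries of function scores by group
#'
#' Boxplot-style summaries (median, quartiles by linear interpolation,
#' 1.5 IQR whiskers clamped to the data, outliers beyond the whiskers) of
#' one metric per group, typically MA, DFT or HO per digit.
#'
#' @param data Data frame of per-specimen scores (see [claw_scores()]).
#' @param metric Unquoted column to summarize.
#' @param group_by Unquoted grouping column (default `digit`).
#' @return Tibble with one row per group: `n`, `min`, `whisker_low`, `q1`,
#'   `median`, `q3`, `whisker_high`, `max`, and `outliers` (list column).
#' @export
group_summary <- function(data, metric, group_by = digit) {
  mq <- enquo(metric)
  gq <- enquo(group_by)
  vals <- eval_tidy(mq, data)
  grp <- eval_tidy(gq, data)
  rows <- lapply(split(vals, grp), function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      return(NULL)
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    wl <- min(v[v >= q[1] - 1.5 * iqr])
    wh <- max(v[v <= q[3] + 1.5 * iqr])
    tibble(
      n = length(v), min = min(v), whisker_low = wl, q1 = q[1],
      median = q[2], q3 = q[3], whisker_high = wh, max = max(v),
      outliers = list(v[v < wl | v > wh])
    )
  })
  empty <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(empty) > 0) {
    warn(paste0("empty group(s) omitted: ", paste(empty, collapse = ", ")))
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- dplyr::bind_rows(rows[keep])
  dplyr::bind_cols(
    tibble(!!as_name(gq) := names(rows)[keep]),
    out
  )
}

#' Boxplots of function scores per digit
#'
#' @param data Per-specimen score table (see [claw_scores()]).
#' @param metrics Character vector of score columns to plot.
#' @return A ggplot object with one facet per metric.
#' @export
plot_score_boxplots <- function(data, metrics = c("MA", "DFT", "HO")) {
  long <- tidyr::pivot_longer(
    data[, c("digit", metrics)],
    dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(.data$digit, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "digit", y = NULL) +
    ggplot2::theme_minimal()
}
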