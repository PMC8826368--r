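#' Two-sided paired t-test
#'
#' Compares stimulus-evoked and blank-evoked values within subjects. When the
#' paired differences have zero variance the result is degenerate and is
#' reported explicitly rather than through the t distribution: `t = 0,
#' p = 1` for identical pairs, `t = +/-Inf, p = 0` for a constant nonzero
#' difference.
#'
#' @param stim_values,blank_values equal-length paired samples (n >= 2).
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
paired_t <- function(stim_values, blank_values) {
  if (length(stim_values) != length(blank_values))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(stim_values)
  if (n < 2) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- stim_values - blank_values
  if (stats::sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble::tibble(test = "paired_t", statistic = stat,
                          df = n - 1, p_value = if (stat == 0) 1 else 0,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(stim_values, blank_values, paired = TRUE)
  tibble::tibble(test = "paired_t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 degenerate = FALSE)
}

#' One-way repeated-measures ANOVA with generalized eta-squared
#'
#' Classic within-subject decomposition: conditions and subjects as crossed
#' factors, F = MS_condition / MS_error on a complete design. The effect size
#' is the generalized eta-squared
#' `SS_condition / (SS_condition + SS_subject + SS_error)`. Degrees of
#' freedom are uncorrected by default (matching the common toolkit default);
#' Greenhouse-Geisser correction is available via `gg = TRUE`.
#'
#' @param data data frame with columns `subject`, `condition`, `value`;
#'   every subject must appear in every condition exactly once.
#' @param gg apply the Greenhouse-Geisser sphericity correction.
#' @return A one-row tibble: `test`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `effect_size` (generalized eta-squared), `gg_epsilon`.
#' @export
rm_anova <- function(data, gg = FALSE) {
  stopifnot(all(c("subject", "condition", "value") %in% names(data)))
  tab <- table(data$subject, data$condition)
  if (any(tab != 1))
    stop("incomplete design: every subject needs every condition once",
         call. = FALSE)
  wide <- stats::xtabs(value ~ subject + condition, data = data)
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  f <- if (ss_cond <= 1e-300) 0 else ms_cond / ms_err
  eps <- 1
  if (gg && k > 2) {
    S <- stats::cov(wide)
    dbar <- mean(diag(S)); mbar <- mean(S); rbar <- rowMeans(S)
    eps <- (k * (dbar - mbar))^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rbar^2) + k^2 * mbar^2))
    eps <- min(1, max(eps, 1 / (k - 1)))
  }
  p <- if (f == 0) 1 else stats::pf(f, df1 * eps, df2 * eps,
                                    lower.tail = FALSE)
  ges <- if (ss_cond + ss_subj + ss_err <= 0) 0 else
    ss_cond / (ss_cond + ss_subj + ss_err)
  tibble::tibble(test = "rm_anova", statistic = f, df1 = df1 * eps,
                 df2 = df2 * eps, p_value = p, effect_size = ges,
                 gg_epsilon = eps)
}

#' Spearman correlations with Benjamini-Hochberg correction
#'
#' Computes the Spearman rank correlation (average ranks for ties) between
#' every metric column and every trait column, drops missing values
#' pairwise, and adjusts the p-values with the Benjamini-Hochberg step-up
#' procedure across the whole declared family.
#'
#' @param metrics numeric vector or data frame of response-metric columns.
#' @param traits numeric vector or data frame of trait-score columns (e.g.
#'   total AQ and the five subscales).
#' @return A tibble with one row per (metric, trait) pair: `metric`, `trait`,
#'   `n`, `rho`, `p_value`, `adj_p`.
#' @export
spearman_bh <- function(metrics, traits) {
  if (is.numeric(metrics)) metrics <- data.frame(metric = metrics)
  if (is.numeric(traits)) traits <- data.frame(trait = traits)
  rows <- list()
  for (mx in names(metrics)) {
    for (tx in names(traits)) {
      x <- metrics[[mx]]; y <- traits[[tx]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3)
        stop("Spearman correlation needs at least 3 complete pairs",
             call. = FALSE)
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: constant input vector", call. = FALSE)
      # exact null distribution when there are no ties (small cohorts);
      # asymptotic approximation otherwise
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = NULL))
      rows[[length(rows) + 1]] <- tibble::tibble(
        metric = mx, trait = tx, n = length(x),
        rho = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Ordinary least squares with a pointwise 95% confidence band
#'
#' Fits `y ~ x` and returns the slope, intercept and the 95% confidence band
#' for the mean response on a grid (used to draw the correlation plots).
#'
#' @param x,y numeric vectors (n >= 3).
#' @param grid evaluation points for the band (defaults to a 100-point grid
#'   spanning `x`).
#' @return List with `slope`, `intercept`, and `band` (tibble `x`, `fit`,
#'   `lwr`, `upr`).
#' @export
linear_fit_ci <- function(x, y, grid = NULL) {
  if (length(x) != length(y) || length(x) < 3)
    stop("linear fit needs at least 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("singular fit: constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)
  pr <- stats::predict(fit, newdata = data.frame(x = grid),
                       interval = "confidence", level = 0.95)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       band = tibble::tibble(x = grid, fit = pr[, "fit"],
                             lwr = pr[, "lwr"], upr = pr[, "upr"]))
}
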