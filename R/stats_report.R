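#' Statistical battery for derived vessel metrics
#'
#' Group comparisons follow the conventions of ex vivo vascular
#' phenotyping studies: two-group metrics by a two-tailed unpaired t test,
#' metrics measured across several pressure or stretch levels by
#' two-factor ANOVA with a global test followed by Bonferroni-adjusted
#' pairwise comparisons, and structure-function relations by ordinary
#' least squares with 95\% confidence bands.  Summaries are reported as
#' mean +/- SEM.
#'
#' @name stats-report
NULL

#' Two-tailed unpaired t test
#'
#' Pooled-variance (classical) by default; Welch by flag.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param var_equal pooled variance if TRUE (default), Welch otherwise.
#' @return list with \code{t}, \code{p}, \code{df}, and group
#'   \code{mean_sem} (data.frame).
#' @export
unpaired_t_test <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  ms <- data.frame(
    group = c("a", "b"),
    mean = c(mean(group_a), mean(group_b)),
    sem = c(stats::sd(group_a) / sqrt(length(group_a)),
            stats::sd(group_b) / sqrt(length(group_b))))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_sem = ms)
}

#' Two-factor ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Global F tests for both factors and their interaction
#' (\code{aov(value ~ A * B)}), then pairwise comparisons between the
#' levels of each factor within every level of the other, with the raw
#' pooled t-test p values multiplied by the total number of comparisons
#' (Bonferroni, capped at 1).
#'
#' @param values numeric response.
#' @param factor_group,factor_level two crossed factors (coerced).
#' @param pairwise set FALSE to skip the post-hoc comparisons (e.g. in
#'   large calibration simulations where only the global tests matter).
#' @return list with \code{anova} (data.frame of F and p per term) and
#'   \code{pairwise} (data.frame: within, level, comparison, p_raw,
#'   p_adjusted).
#' @export
two_factor_anova_bonferroni <- function(values, factor_group, factor_level,
                                        pairwise = TRUE) {
  A <- factor(factor_group); B <- factor(factor_level)
  stopifnot(length(values) == length(A), length(values) == length(B))
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("each factor needs at least 2 levels")
  tab <- table(A, B)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty design cells: ",
         paste(sprintf("(%s, %s)", levels(A)[empty[, 1]],
                       levels(B)[empty[, 2]]), collapse = ", "))
  }
  fit <- stats::aov(values ~ A * B)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  anova_tab <- data.frame(
    term = c("group", "level", "interaction")[match(
      terms[terms != "Residuals"], c("A", "B", "A:B"))],
    df = an$Df[terms != "Residuals"],
    F = an$`F value`[terms != "Residuals"],
    p = an$`Pr(>F)`[terms != "Residuals"])
  if (!pairwise)
    return(list(anova = anova_tab, pairwise = NULL, n_comparisons = 0L))
  pw <- list()
  add_comparisons <- function(within_fac, across_fac, label) {
    for (lv in levels(within_fac)) {
      sel <- within_fac == lv
      lvls <- levels(droplevels(across_fac[sel]))
      if (length(lvls) < 2) next
      cmb <- utils::combn(lvls, 2)
      for (k in seq_len(ncol(cmb))) {
        x <- values[sel & across_fac == cmb[1, k]]
        y <- values[sel & across_fac == cmb[2, k]]
        if (length(x) < 2 || length(y) < 2) next
        pw[[length(pw) + 1]] <<- data.frame(
          within = label, level = lv,
          comparison = paste(cmb[1, k], "vs", cmb[2, k]),
          p_raw = unpaired_t_test(x, y)$p)
      }
    }
  }
  add_comparisons(B, A, "level")
  add_comparisons(A, B, "group")
  pairwise <- do.call(rbind, pw)
  m <- nrow(pairwise)
  pairwise$p_adjusted <- pmin(1, m * pairwise$p_raw)
  list(anova = anova_tab, pairwise = pairwise, n_comparisons = m)
}

#' Least-squares line with R-squared and 95 percent confidence band
#'
#' Ordinary least squares of y on x; R^2 equals the squared Pearson
#' correlation; the pointwise confidence band comes from the t
#' distribution of the mean response.
#'
#' @param x,y numeric vectors, n >= 3, x not constant.
#' @param level confidence level for the band.
#' @param n_band number of grid points for the band.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p}, and \code{band} (data.frame: x, fit, lower, upper).
#' @export
pearson_fit <- function(x, y, level = 0.95, n_band = 50) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  grid <- data.frame(x = seq(min(x), max(x), length.out = n_band))
  ci <- stats::predict(fit, grid, interval = "confidence", level = level)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       band = data.frame(x = grid$x, fit = ci[, "fit"],
                         lower = ci[, "lwr"], upper = ci[, "upr"]))
}

#' Mean and standard error of the mean
#'
#' @param x numeric vector.
#' @return named vector \code{c(mean, sem, n)}.
#' @export
mean_sem <- function(x) {
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}
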