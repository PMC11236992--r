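#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether a set of per-plot rates is symmetrically centred on
#' `mu` (by default zero: no systematic trend). Exact differences equal to
#' `mu` are dropped before ranking (the standard signed-rank convention);
#' the exact null distribution is used for n <= 25 without ties, and the
#' normal approximation with tie correction otherwise. The statistic V is
#' the sum of the ranks of positive differences, bounded by
#' `[0, n(n+1)/2]`.
#'
#' @param values numeric vector (e.g. per-plot annual index changes).
#' @param mu null location (default 0).
#' @return list of class `trend_test`: `statistic` (`V`), `p_value`, `n`
#'   (after zero removal), `method`, `estimate` (the sample mean).
#' @export
wilcoxon_one_sample <- function(values, mu = 0) {
  x <- values[!is.na(values)]
  x <- x[x != mu]
  if (!length(x)) {
    stop("all values equal the null location; test undefined", call. = FALSE)
  }
  exact <- length(x) <= 25 && !any(duplicated(abs(x - mu)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, mu = mu, exact = exact, correct = !exact))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = length(x), method = if (exact) "exact" else "normal",
                 estimate = mean(values, na.rm = TRUE),
                 statistic_name = "V"),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("<trend_test> %s = %.4g, p = %.4g, n = %d%s\n",
              x$statistic_name, x$statistic, x$p_value, x$n,
              if (!is.null(x$estimate) && !is.na(x$estimate))
                sprintf(" (estimate %.4g)", x$estimate) else ""))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `reps` times, applies `statistic`,
#' and returns the percentile interval at level `conf`. Deterministic
#' under a fixed `seed`; location-equivariant for location statistics.
#'
#' @param values numeric vector, n >= 2.
#' @param statistic function of a numeric vector (default `mean`).
#' @param reps bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list `lower`, `upper`, `estimate`, `reps`, `conf`, `seed`.
#' @export
bootstrap_ci <- function(values, statistic = mean, reps = 1000,
                         conf = 0.95, seed = NULL) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stat <- vapply(seq_len(reps), function(i) {
    statistic(x[sample.int(length(x), replace = TRUE)])
  }, 0)
  a <- (1 - conf) / 2
  q <- stats::quantile(stat, c(a, 1 - a), type = 7, names = FALSE)
  list(lower = q[1], upper = q[2], estimate = statistic(x),
       reps = reps, conf = conf, seed = seed)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties and a two-sided p-value; used to
#' relate index trends to plot covariates (elevation, stem density,
#' richness, turnover) and species contributions to traits.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return `trend_test` list with `statistic` (`r_s`), `p_value`, `n`.
#' @export
spearman_trend <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(statistic = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), method = "spearman",
                 estimate = unname(ct$estimate), statistic_name = "r_s"),
            class = "trend_test")
}

#' Kruskal-Wallis rank sum test across groups
#'
#' Compares a rate across groups of plots (e.g. mountain regions), with
#' tie correction and a chi-square p on k - 1 degrees of freedom. All
#' observations identical gives H = 0.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return `trend_test` list with `statistic` (`H`), `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.factor(as.character(groups[ok]))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(structure(list(statistic = 0, p_value = 1, n = length(values),
                          df = nlevels(groups) - 1L, method = "kruskal",
                          estimate = NA_real_, statistic_name = "H"),
                     class = "trend_test"))
  }
  kt <- stats::kruskal.test(values, groups)
  structure(list(statistic = unname(kt$statistic), p_value = kt$p.value,
                 n = length(values), df = unname(kt$parameter),
                 method = "kruskal", estimate = NA_real_,
                 statistic_name = "H"),
            class = "trend_test")
}

#' Linear climate trend at a location
#'
#' Ordinary least-squares slope of an annual climate series on year -
#' the local warming (or precipitation-change) rate over the study
#' period, in variable units per year.
#'
#' @param year numeric years, n >= 3.
#' @param value annual climate values.
#' @return list `slope`, `se`, `p_value`, `n`.
#' @export
climate_trend <- function(year, value) {
  ok <- !is.na(year) & !is.na(value)
  if (sum(ok) < 3) stop("need at least 3 annual values", call. = FALSE)
  fit <- stats::lm(value[ok] ~ year[ok])
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       p_value = unname(sm[2, 4]), n = sum(ok))
}

#' Cross-sectional regression of community index on site climate
#'
#' Regresses per-plot community temperature index on per-plot mean annual
#' temperature. A slope near 1 means community composition fully tracks
#' the spatial temperature gradient; a slope below 1 (flagged as `lag`)
#' means composition changes by less than a degree of thermal affiliation
#' per degree of site temperature - the usual climatic-lag signature.
#'
#' @param mat per-plot mean annual temperature, deg C.
#' @param cti per-plot community index, n >= 3 plots.
#' @return list `slope`, `se`, `t`, `df`, `p_value`, `r_squared`, `lag`.
#' @export
cti_vs_mat_regression <- function(mat, cti) {
  ok <- !is.na(mat) & !is.na(cti)
  mat <- mat[ok]; cti <- cti[ok]
  if (length(mat) < 3) stop("need at least 3 plots", call. = FALSE)
  if (length(unique(mat)) < 2) stop("constant MAT: slope undefined",
                                    call. = FALSE)
  fit <- stats::lm(cti ~ mat)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  list(slope = unname(co[2, 1]), se = unname(co[2, 2]),
       t = unname(co[2, 3]), df = fit$df.residual,
       p_value = unname(co[2, 4]), r_squared = sm$r.squared,
       lag = unname(co[2, 1]) < 1)
}

#' Intercept-only linear model as a one-sample location check
#'
#' The parametric counterpart of [wilcoxon_one_sample()]: an
#' intercept-only least-squares fit, equivalent to a one-sample t-test,
#' reported as a secondary check on trend estimates.
#'
#' @param values numeric vector, n >= 2.
#' @return list `estimate`, `se`, `t`, `p_value`, `ci_lower`, `ci_upper`.
#' @export
intercept_only_test <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  fit <- stats::lm(x ~ 1)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  list(estimate = unname(sm[1, 1]), se = unname(sm[1, 2]),
       t = unname(sm[1, 3]), p_value = unname(sm[1, 4]),
       ci_lower = ci[1, 1], ci_upper = ci[1, 2])
}

#' Leave-one-plot-out robustness of a trend test
#'
#' Re-runs the one-sample Wilcoxon test dropping each plot in turn, to
#' check that a headline trend does not hinge on a single plot.
#'
#' @param rates named numeric vector of per-plot annual rates.
#' @return data.frame `dropped`, `estimate`, `V`, `p_value`.
#' @export
loo_robustness <- function(rates) {
  nm <- names(rates)
  if (is.null(nm)) nm <- as.character(seq_along(rates))
  do.call(rbind, lapply(seq_along(rates), function(i) {
    wt <- wilcoxon_one_sample(rates[-i])
    data.frame(dropped = nm[i], estimate = wt$estimate,
               V = wt$statistic, p_value = wt$p_value)
  }))
}
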