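## Statistical comparison battery: test-retest regressions, cross-subject
## dispersion, normalized test-retest deviation maps, pooled-variance
## two-sample tests with Cohen's d, hemispheric correlation and the
## asymmetry-vs-B1 analysis. All statistics are computed from their direct
## formulas (sums), so base R fitting functions can serve as independent
## oracles in the tests.

#' Ordinary least-squares regression with Pearson R^2
#'
#' @param x predictor vector (e.g. parcel means in the test session).
#' @param y response vector (e.g. parcel means in the retest session).
#' @return list of class `mp2r_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
tr_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 paired points")
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2); sxy <- sum((x - mx) * (y - my))
  if (sxx == 0) stop("zero variance in the predictor")
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  structure(list(slope = slope, intercept = my - slope * mx,
                 r_squared = r2, n_points = n), class = "mp2r_regression")
}

#' Cross-subject dispersion of parcel means
#'
#' The unbiased SD across subjects divided by the number of subjects, as the
#' analysis battery defines it; a conventional standard error
#' (divide by sqrt(n)) is available behind `sqrt_n = TRUE`.
#'
#' @param parcel_means_by_subject matrix, parcels x subjects.
#' @param sqrt_n divide by `sqrt(n)` instead of `n`.
#' @return per-parcel numeric vector.
#' @export
cross_subject_se <- function(parcel_means_by_subject, sqrt_n = FALSE) {
  m <- as.matrix(parcel_means_by_subject)
  n <- ncol(m)
  if (n < 2) stop("need at least 2 subjects")
  s <- apply(m, 1, sd)
  s / if (sqrt_n) sqrt(n) else n
}

#' Normalized test-retest deviation maps
#'
#' Per subject, `|test - retest| / range`, where the range is the max - min
#' of the group-average map over (finite) cortical vertices (or the 1st-99th
#' percentile range with `robust_range = TRUE`). Deviations are averaged
#' over subjects; the 25/50/75/98 percentiles of the mean map are reported
#' (linear interpolation between order statistics).
#'
#' @param test_maps,retest_maps vertices x subjects matrices (or lists of
#'   vectors) of paired surface maps.
#' @param group_map optional group-average map; defaults to the mean of all
#'   supplied test and retest maps.
#' @param robust_range use the 1-99 percentile range.
#' @return list of class `mp2r_deviation`: `mean_map`, `range`,
#'   `percentiles` (p25/p50/p75/p98), `per_subject` matrix.
#' @export
deviation_map <- function(test_maps, retest_maps, group_map = NULL,
                          robust_range = FALSE) {
  tm <- if (is.list(test_maps)) do.call(cbind, test_maps) else as.matrix(test_maps)
  rm_ <- if (is.list(retest_maps)) do.call(cbind, retest_maps) else as.matrix(retest_maps)
  stopifnot(identical(dim(tm), dim(rm_)))
  if (is.null(group_map)) group_map <- rowMeans(cbind(tm, rm_))
  g <- group_map[is.finite(group_map)]
  rng <- if (robust_range)
    diff(quantile(g, c(0.01, 0.99), names = FALSE, type = 7))
  else max(g) - min(g)
  if (rng == 0) stop("zero group range: deviation undefined")
  dev <- abs(tm - rm_) / rng
  mean_map <- rowMeans(dev)
  pct <- quantile(mean_map[is.finite(mean_map)], c(0.25, 0.5, 0.75, 0.98),
                  names = FALSE, type = 7)
  structure(list(mean_map = mean_map, range = rng,
                 percentiles = setNames(pct, c("p25", "p50", "p75", "p98")),
                 per_subject = dev),
            class = "mp2r_deviation")
}

#' Effect-size classification for Cohen's d
#' @param d Cohen's d value(s).
#' @return character vector: small (<0.5), medium (=0.5), large (>0.5),
#'   very large (>1.2), huge (>2).
#' @export
effect_size_class <- function(d) {
  a <- abs(d)
  ifelse(a > 2, "huge",
         ifelse(a > 1.2, "very large",
                ifelse(a > 0.5, "large",
                       ifelse(a == 0.5, "medium", "small"))))
}

#' Two-sample pooled-variance t-test with Cohen's d
#'
#' Student's t with `dof = n1 + n2 - 2`;
#' `d = (mean_a - mean_b) / s_pooled`,
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / dof`, i.e. the effect size is
#' weighted by the relative size of each group sample.
#'
#' @param values_a,values_b the two vertex-value samples (n >= 2 each;
#'   `NaN` dropped).
#' @return list of class `mp2r_effect`: `t_statistic`, `dof`, `cohens_d`,
#'   `p_value`, `size_class`, `n1`, `n2`.
#' @export
region_pair_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]; b <- values_b[is.finite(values_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  dof <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd(a)^2 + (n2 - 1) * sd(b)^2) / dof
  if (sp2 == 0) stop("zero pooled variance")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  t_ <- (mean(a) - mean(b)) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t_), dof)
  structure(list(t_statistic = t_, dof = dof, cohens_d = d, p_value = p,
                 size_class = effect_size_class(d), n1 = n1, n2 = n2),
            class = "mp2r_effect")
}

#' Left-right hemisphere regression of parcel means
#'
#' Regression of left-hemisphere parcel means (y) on right-hemisphere parcel
#' means (x), using the surface model's vertex/parcel correspondence.
#'
#' @param parcel_means_left,parcel_means_right paired per-parcel vectors.
#' @return `mp2r_regression` (left on the y axis).
#' @export
lr_correlation <- function(parcel_means_left, parcel_means_right) {
  tr_regression(parcel_means_right, parcel_means_left)
}

#' Correlation of hemispheric map asymmetry with B1 asymmetry
#'
#' Pearson correlation between `map_left - map_right` and
#' `b1_left - b1_right` over corresponding vertices (or parcels).
#'
#' @param map_left,map_right corresponding per-vertex (or per-parcel) values.
#' @param b1_left,b1_right corresponding transmit-field values.
#' @return correlation coefficient.
#' @export
asymmetry_vs_b1 <- function(map_left, map_right, b1_left, b1_right) {
  da <- map_left - map_right
  db <- b1_left - b1_right
  ok <- is.finite(da) & is.finite(db)
  da <- da[ok]; db <- db[ok]
  if (sd(da) == 0 || sd(db) == 0)
    stop("constant asymmetry vector: correlation undefined")
  sum((da - mean(da)) * (db - mean(db))) /
    ((length(da) - 1) * sd(da) * sd(db))
}
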