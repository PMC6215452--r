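#' Statistical procedures for bivariate allometry and scorer reliability
#'
#' Bone-size relationships are assessed with major axis regression; because
#' the residuals are typically non-normal and heteroscedastic, significance
#' of the slope is tested by permutation rather than parametrically.
#' Heteroscedasticity is checked with the Breusch-Pagan test, and the
#' reliability of categorical scorers with the two-way random-effects,
#' average-measures intraclass correlation ICC(2,k).
#'
#' @name stats-procedures
NULL

#' Categorical score table
#'
#' A bones x scorers matrix of categorical scores with NA for "n/a".
#' Feature scales: 1 = diaphyseal extent (0-3), 2 = trabecular orientation in
#' 10 degree bins (0-8), 3 = trabecular association (0-2).
#'
#' @param scores numeric matrix (bones x scorers), NAs allowed.
#' @param feature feature id in 1:3.
#' @return a `score_table`.
#' @export
score_table <- function(scores, feature = 2) {
  scores <- as.matrix(scores)
  rng <- feature_scale(feature)
  vals <- scores[!is.na(scores)]
  if (length(vals) && (any(vals < rng[1]) || any(vals > rng[2])))
    stop("scores outside the feature's scale ", rng[1], "-", rng[2])
  structure(scores, class = c("score_table", "matrix"), feature = feature)
}

feature_scale <- function(feature) {
  switch(as.character(feature),
         "1" = c(0, 3), "2" = c(0, 8), "3" = c(0, 2),
         stop("feature must be 1, 2 or 3"))
}

# closed-form major axis slope from second moments
ma_slope <- function(sxx, syy, sxy) {
  if (abs(sxy) < 1e-300) {
    # principal axis is horizontal or vertical
    return(if (syy > sxx) Inf else 0)
  }
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' Major axis regression
#'
#' Line through the first principal axis of the bivariate sample covariance
#' (minimising perpendicular distances); `r2` is the squared Pearson
#' correlation.
#'
#' @param x,y numeric vectors, n >= 3.
#' @return `regression_result`: list with `slope`, `intercept`, `r2`, `n`.
#' @export
major_axis <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx + syy < 1e-300) stop("zero total variance")
  slope <- ma_slope(sxx, syy, sxy)
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  r2 <- if (sxx < 1e-300 || syy < 1e-300) NA_real_ else
    sxy^2 / (sxx * syy)
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 n = length(x)), class = "regression_result")
}

#' Permutation test of the major axis slope
#'
#' Permutes `y` against `x` and compares each replicate with the observed
#' data; two-sided p-value with the add-one estimator
#' `p = (1 + #{extreme replicates}) / (n_perm + 1)`. Because the magnitude
#' of the major axis slope is not monotone in the strength of association
#' (it diverges towards the vertical as the permuted correlation vanishes
#' whenever `var(y) != var(x)`), the slope is tested through the
#' association statistic |r|, as in the `lmodel2` convention for model II
#' regression: the sample variances are fixed under permutation, so |r|
#' orders replicates by how far the fitted axis departs from the
#' no-association configuration.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param n_perm number of permutation replicates (100,000 by default).
#' @param seed integer seed.
#' @return `regression_result` with `p_perm`, `n_permutations`, `seed` added.
#' @export
perm_test_slope <- function(x, y, n_perm = 100000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::var(y) < 1e-300) stop("y is constant: slope test undefined")
  fit <- major_axis(x, y)
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  obs <- abs(sum(xc * yc))
  count <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(sum(xc * yc[sample.int(n)])) >= obs) hits <- hits + 1L
    }
    hits
  })
  fit$p_perm <- (1 + count) / (n_perm + 1)
  fit$n_permutations <- n_perm
  fit$seed <- seed
  fit
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Classical Lagrange-multiplier form: the squared OLS residuals of `y ~ x`
#' are regressed on `x`; `LM = n * r2` of that auxiliary regression, compared
#' with chi-squared on 1 degree of freedom. `studentize = TRUE` gives the
#' Koenker robust form.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param studentize use the Koenker studentised statistic.
#' @return list with `statistic` and `p_value`.
#' @export
breusch_pagan <- function(x, y, studentize = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  n <- length(x)
  res <- stats::lm.fit(cbind(1, x), y)$residuals
  u <- res^2
  # zero residual variance (up to numerical noise relative to the data scale)
  if (stats::var(u) < (1e-10 * (stats::var(y) + 1e-300))^2)
    return(list(statistic = 0, p_value = 1))
  if (studentize) {
    aux <- stats::lm.fit(cbind(1, x), u)
    lm_stat <- n * (1 - sum(aux$residuals^2) / sum((u - mean(u))^2))
  } else {
    # classical form: aux regression of u / mean(u) on x, LM = ESS / 2
    g <- u / mean(u)
    aux <- stats::lm.fit(cbind(1, x), g)
    ess <- sum((g - mean(g))^2) - sum(aux$residuals^2)
    lm_stat <- ess / 2
  }
  list(statistic = lm_stat,
       p_value = stats::pchisq(lm_stat, df = 1, lower.tail = FALSE))
}

#' ICC(2,k): two-way random effects, average measures
#'
#' Shrout-Fleiss ICC(2,k) from the mean squares of the two-way layout
#' (bones x scorers). Rows containing any NA are dropped first: the ICC is
#' defined only for bones scored numerically by every scorer.
#'
#' @param table a [score_table()] or plain bones x scorers matrix.
#' @return `icc_result`: list with `icc`, variance components, `k`, `n`.
#' @export
icc2k <- function(table) {
  m <- as.matrix(unclass(table))
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2)
    stop("fewer than 2 bones with complete scores: ICC cannot be calculated")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  jms <- n * sum((col_m - grand)^2) / (k - 1)
  ems <- (sum((m - outer(row_m, col_m, "+") + grand)^2)) /
    ((n - 1) * (k - 1))
  icc <- (bms - ems) / (bms + (jms - ems) / n)
  structure(list(icc = icc,
                 var_bones = (bms - ems) / k,
                 var_scorers = (jms - ems) / n,
                 var_residual = ems,
                 ms = c(bones = bms, scorers = jms, residual = ems),
                 k = k, n = n),
            class = "icc_result")
}

#' Aggregate categorical scores per bone
#'
#' The per-bone mean of the numeric scores, unless "n/a" scores outnumber
#' numeric ones, in which case the aggregate is "n/a" (NA). For features 2
#' and 3, a scorer who assigned feature 1 a score of 0 (diaphysis void of
#' cancellous bone) did not score the bone, so the corresponding cells are
#' first set to "n/a" when `feature1` is supplied.
#'
#' @param table a [score_table()].
#' @param feature1 optional [score_table()] of feature-1 scores with the same
#'   layout; applies the zero-propagation rule above.
#' @return numeric vector of per-bone mean scores (NA = "n/a").
#' @export
aggregate_scores <- function(table, feature1 = NULL) {
  m <- as.matrix(unclass(table))
  if (!is.null(feature1) && isTRUE(attr(table, "feature") %in% c(2, 3))) {
    f1 <- as.matrix(unclass(feature1))
    stopifnot(identical(dim(f1), dim(m)))
    m[!is.na(f1) & f1 == 0] <- NA
  }
  apply(m, 1, function(row) {
    n_na <- sum(is.na(row))
    n_num <- sum(!is.na(row))
    if (n_na > n_num) NA_real_ else mean(row, na.rm = TRUE)
  })
}

#' Normal probability plot coordinates of OLS residuals
#'
#' Diagnostic output (ordered residuals vs normal quantiles); the normality
#' check on regression errors is visual, so no automated decision is made.
#'
#' @param x,y numeric vectors.
#' @return data.frame with `theoretical` and `sample` quantiles.
#' @export
residual_qq <- function(x, y) {
  res <- sort(stats::lm.fit(cbind(1, x), y)$residuals)
  n <- length(res)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = res)
}
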