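#' Route a variable to the parametric or nonparametric test family
#'
#' Shapiro-Wilk normality test per group at `alpha`; any rejection (or a
#' degenerate constant group) routes the whole comparison to the
#' nonparametric path.
#'
#' @param values numeric vector.
#' @param groups grouping factor/vector, parallel to `values`.
#' @param alpha significance level of the normality screen.
#' @return list with `path` ("parametric"/"nonparametric"), per-group
#'   Shapiro p-values (`NA` for degenerate groups) and a `degenerate` flag.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  sp <- split(values, groups)
  sp <- lapply(sp, function(v) v[is.finite(v)])
  if (any(vapply(sp, length, integer(1)) < 3L))
    stop("each group needs n >= 3 for the normality screen")
  degenerate <- FALSE
  p <- vapply(sp, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)   # constant sample: Shapiro undefined
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (any(is.na(p))) degenerate <- TRUE
  path <- if (degenerate || any(p < alpha, na.rm = TRUE)) "nonparametric" else "parametric"
  list(path = path, shapiro_p = p, degenerate = degenerate)
}

#' Group comparison with normality gating and Bonferroni post-hoc
#'
#' Two groups: Welch t-test (parametric path) or Wilcoxon rank-sum.
#' More than two: one-way ANOVA or Kruskal-Wallis, followed by all pairwise
#' comparisons with the Bonferroni multiplier equal to the number of pairs
#' actually tested.
#'
#' @param data data.frame.
#' @param variable column name of the measurement.
#' @param group column name of the group id.
#' @param path "auto" (default, uses [normality_gate()]), "parametric" or
#'   "nonparametric".
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @return list of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value` (omnibus), `posthoc` data.frame (`pair`, `p_raw`, `p_adjusted`),
#'   `path`.
#' @export
compare_groups <- function(data, variable, group = "group",
                           path = c("auto", "parametric", "nonparametric"),
                           var_equal = FALSE) {
  path <- match.arg(path)
  stopifnot(variable %in% names(data), group %in% names(data))
  keep <- is.finite(data[[variable]])
  y <- data[[variable]][keep]
  g <- factor(data[[group]][keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("each group needs n >= 2")
  if (path == "auto") path <- normality_gate(y, g)$path

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pair_p <- function(a, b) {
    ya <- y[g == a]; yb <- y[g == b]
    if (path == "parametric") stats::t.test(ya, yb, var.equal = var_equal)$p.value
    else suppressWarnings(stats::wilcox.test(ya, yb, exact = FALSE)$p.value)
  }
  if (nlevels(g) == 2L) {
    if (path == "parametric") {
      ht <- stats::t.test(y[g == levels(g)[1]], y[g == levels(g)[2]],
                          var.equal = var_equal)
      test_used <- if (var_equal) "t (pooled)" else "t (Welch)"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(y[g == levels(g)[1]],
                                                y[g == levels(g)[2]], exact = FALSE))
      test_used <- "wilcoxon"
    }
    statistic <- unname(ht$statistic); p_omni <- ht$p.value
    posthoc <- data.frame(pair = paste(levels(g), collapse = " vs "),
                          p_raw = p_omni, p_adjusted = p_omni)
  } else {
    if (path == "parametric") {
      fit <- stats::aov(y ~ g)
      s <- summary(fit)[[1]]
      statistic <- s[["F value"]][1]; p_omni <- s[["Pr(>F)"]][1]
      test_used <- "anova"
    } else {
      ht <- stats::kruskal.test(y ~ g)
      statistic <- unname(ht$statistic); p_omni <- ht$p.value
      test_used <- "kruskal-wallis"
    }
    p_raw <- vapply(pairs, function(p) pair_p(p[1], p[2]), numeric(1))
    posthoc <- data.frame(pair = vapply(pairs, paste, character(1), collapse = " vs "),
                          p_raw = p_raw,
                          p_adjusted = pmin(1, p_raw * length(pairs)))
  }
  structure(list(test_used = test_used, statistic = statistic,
                 p_value = p_omni, posthoc = posthoc, path = path,
                 variable = variable),
            class = "group_comparison")
}

#' Univariable linear regression (CMR value on a histology covariate)
#'
#' Ordinary least squares of `y` on `x`; R is the Pearson correlation, the
#' two-sided p-value comes from the t distribution of the slope.
#'
#' @param data data.frame.
#' @param x,y column names (predictor, response).
#' @return list with `R`, `R2`, `p`, `slope`, `intercept`, `n`.
#' @export
univariable <- function(data, x, y) {
  stopifnot(x %in% names(data), y %in% names(data))
  d <- data[is.finite(data[[x]]) & is.finite(data[[y]]), c(x, y)]
  if (nrow(d) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(d[[x]]) == 0) stop("zero-variance predictor: ", x)
  fit <- stats::lm(stats::reformulate(x, y), data = d)
  s <- summary(fit)
  list(R = unname(sign(stats::coef(fit)[2]) * sqrt(s$r.squared)),
       R2 = s$r.squared,
       p = unname(s$coefficients[2, 4]),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(d))
}

#' Adjusted R-squared
#'
#' 1 - (1 - R2) * (n - 1) / (n - p - 1).
#'
#' @param r2 coefficient of determination.
#' @param n observations.
#' @param p number of predictors.
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  stopifnot(n > p + 1)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Multiple linear regression with variance inflation factors
#'
#' OLS on complete cases, coefficient table with standard errors and
#' p-values, per-predictor VIF from auxiliary regressions
#' (VIF_j = 1 / (1 - R2_j)), R-squared and adjusted R-squared. A rank
#' deficient design is an explicit error, never a silent pseudo-inverse.
#'
#' @param data data.frame.
#' @param y response column name.
#' @param predictors character vector of predictor column names (>= 1).
#' @return list of class `regression_result`: `coefficients` (data.frame:
#'   term, estimate, se, p), `vif` (named, `NA` for a single predictor),
#'   `r2`, `adj_r2`, `n`, `p` (predictor count).
#' @export
multiple_regression <- function(data, y, predictors) {
  stopifnot(y %in% names(data), all(predictors %in% names(data)),
            length(predictors) >= 1L)
  d <- data[, c(y, predictors), drop = FALSE]
  d <- d[stats::complete.cases(d) & apply(as.matrix(d), 1, function(r) all(is.finite(r))), ]
  n <- nrow(d); k <- length(predictors)
  if (n <= k + 1L) stop("need n > p + 1 observations (n = ", n, ", p = ", k, ")")
  X <- cbind(1, as.matrix(d[, predictors, drop = FALSE]))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient: exact multicollinearity among predictors")
  fit <- stats::lm(stats::reformulate(predictors, y), data = d)
  s <- summary(fit)
  coefs <- data.frame(term = rownames(s$coefficients),
                      estimate = s$coefficients[, 1],
                      se = s$coefficients[, 2],
                      p = s$coefficients[, 4], row.names = NULL)
  vif <- if (k >= 2L) {
    v <- vapply(predictors, function(pj) {
      aux <- stats::lm(stats::reformulate(setdiff(predictors, pj), pj), data = d)
      1 / (1 - summary(aux)$r.squared)
    }, numeric(1))
    v
  } else stats::setNames(NA_real_, predictors)
  adj <- adjusted_r2(s$r.squared, n, k)
  stopifnot(isTRUE(all.equal(adj, s$adj.r.squared)))  # identity asserted per fit
  structure(list(coefficients = coefs, vif = vif, r2 = s$r.squared,
                 adj_r2 = adj, n = n, p = k, fit = fit),
            class = "regression_result")
}

#' Drop the weakest univariable predictor and refit
#'
#' Model reduction used when the full model shows no significant predictor:
#' remove the predictor with the smallest univariable |R| and refit. A tie
#' in |R| drops the later-listed predictor (deterministic, with a message).
#'
#' @param data data.frame.
#' @param y response column name.
#' @param predictors character vector (>= 2).
#' @param univ_r named numeric vector of univariable correlations for
#'   `predictors` (signed or absolute).
#' @return a `regression_result` on the reduced predictor set, with
#'   attribute `dropped`.
#' @export
reduce_model <- function(data, y, predictors, univ_r) {
  stopifnot(length(predictors) >= 2L, all(predictors %in% names(univ_r)))
  r <- abs(univ_r[predictors])
  lo <- which(r == min(r))
  drop_idx <- lo[length(lo)]                       # tie: later-listed predictor
  if (length(lo) > 1L)
    message("tie in |R|; dropping later-listed predictor: ", predictors[drop_idx])
  kept <- predictors[-drop_idx]
  out <- multiple_regression(data, y, kept)
  attr(out, "dropped") <- predictors[drop_idx]
  out
}

#' Per-group sample size for a two-sided two-sample t-test
#'
#' Smallest integer n per group achieving the target power (classical
#' pooled-variance noncentral-t computation), optionally inflated for an
#' expected dropout fraction.
#'
#' @param delta mean difference.
#' @param sd common standard deviation.
#' @param alpha type I error (two-sided).
#' @param power target power.
#' @param dropout_fraction expected dropout in \[0, 1).
#' @return list: `n_per_group`, `enrolled_per_group` (dropout-inflated,
#'   rounded up), and for convenience `enrolled_total(groups)` as computed
#'   fields via `n_groups`.
#' @export
sample_size_two_sample_t <- function(delta, sd = 1, alpha = 0.05, power = 0.80,
                                     dropout_fraction = 0) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            dropout_fraction >= 0, dropout_fraction < 1)
  n <- tryCatch(
    stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                        power = power, type = "two.sample",
                        alternative = "two.sided")$n,
    error = function(e) 2)                          # power below alpha: floor
  n <- max(2L, as.integer(ceiling(n - 1e-9)))
  enrolled <- as.integer(ceiling(n / (1 - dropout_fraction) - 1e-9))
  list(n_per_group = n, enrolled_per_group = enrolled)
}

#' Format a p-value in reporting style
#'
#' @param p p-value.
#' @param digits decimals.
#' @return character, "<0.001" below the reporting floor.
#' @export
format_p <- function(p, digits = 3) {
  ifelse(p < 10^(-digits), paste0("<", format(10^(-digits), scientific = FALSE)),
         formatC(round(p, digits), format = "f", digits = digits))
}
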