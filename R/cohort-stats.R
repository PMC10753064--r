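test_result <- function(test, statistic, df = NA_real_, p_value,
                        tails = "two", effect = NA_real_,
                        effect_name = NA_character_) {
  tibble::tibble(test = test, statistic = statistic, df = df,
                 p_value = p_value, tails = tails, effect = effect,
                 effect_name = effect_name)
}

#' Flag clinical scores beyond their abnormality cut-offs
#'
#' Applies the per-scale cut-offs (MoCA strictly below 26; the other six
#' scales at or above their cut-off: FSS >= 36, PSQI >= 8, PHQ-9 >= 10,
#' GAD-7 >= 10, HAMD >= 17, HAMA >= 14) to the patients of a cohort and
#' returns the count and percentage flagged per scale. Cut-offs,
#' directions and strictness are configurable through `scales`.
#'
#' @param cohort A cohort tibble with the scale columns of
#'   [simulate_cohort()]; only rows with a non-missing score enter each
#'   scale's denominator.
#' @param scales Scale definition tibble (see [clinical_scales()]);
#'   a `strict` logical column may be added to switch any scale between
#'   strict and inclusive comparison (default: "below" scales strict,
#'   "above" scales inclusive).
#' @return A tibble with `scale`, `n`, `count`, `pct` (one decimal).
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(seed = 1))
#' flag_thresholds(dplyr::filter(cohort, cohort == "patient"))
#' @export
flag_thresholds <- function(cohort, scales = clinical_scales()) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!"strict" %in% names(scales)) {
    scales$strict <- scales$direction == "below"
  }
  present <- scales$scale[scales$scale %in% names(cohort)]
  if (length(present) == 0) stop("no scale columns present in cohort")
  purrr::map_dfr(present, function(sc) {
    row <- scales[scales$scale == sc, ]
    x <- cohort[[sc]][!is.na(cohort[[sc]])]
    flag <- if (row$direction == "below") {
      if (row$strict) x < row$cutoff else x <= row$cutoff
    } else {
      if (row$strict) x > row$cutoff else x >= row$cutoff
    }
    tibble::tibble(scale = sc, n = length(x), count = sum(flag),
                   pct = round(100 * sum(flag) / length(x), 1))
  })
}

#' Compare two samples with a normality-gated test policy
#'
#' The `"auto"` policy mirrors a common clinical-statistics workflow:
#' Shapiro-Wilk on each sample at alpha = 0.05; if both pass, a pooled-
#' variance (Student) t test; otherwise a two-sided Mann-Whitney test
#' (exact when both samples have at most 20 untied observations,
#' otherwise the normal approximation with tie correction and no
#' continuity correction). Explicit policies bypass the gate.
#'
#' @param x,y Numeric samples.
#' @param policy `"auto"`, `"student"`, `"welch"` or `"mannwhitney"`.
#' @return A one-row test-result tibble (`test`, `statistic`, `df`,
#'   `p_value`, `tails`).
#' @examples
#' two_sample_compare(rnorm(10), rnorm(10))
#' two_sample_compare(c(1, 2, 3), c(4, 5, 6), policy = "mannwhitney")
#' @export
two_sample_compare <- function(x, y,
                               policy = c("auto", "student", "welch",
                                          "mannwhitney")) {
  policy <- match.arg(policy)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("insufficient data: need at least 2 observations per sample")
  }
  if (policy == "auto") {
    if (length(x) < 3 || length(y) < 3) {
      stop("insufficient data: auto policy needs n >= 3 per sample")
    }
    normal <- function(s) {
      if (stats::sd(s) == 0) return(FALSE)
      stats::shapiro.test(s)$p.value >= 0.05
    }
    policy <- if (normal(x) && normal(y)) "student" else "mannwhitney"
  }
  if (policy %in% c("student", "welch")) {
    fit <- stats::t.test(x, y, var.equal = policy == "student")
    test_result(paste0(policy, "-t"), unname(fit$statistic),
                unname(fit$parameter), fit$p.value)
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) <= 20 && length(y) <= 20
    fit <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    test_result("mann-whitney", unname(fit$statistic), NA_real_,
                fit$p.value)
  }
}

#' Two-sample t test from printed summary statistics
#'
#' Recomputes the t statistic and two-sided p-value from group means,
#' SDs and sizes, as needed to check published tables. `"student"` uses
#' the pooled-variance form with `n1 + n2 - 2` df; `"welch"` the
#' Satterthwaite approximation.
#'
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs, sizes.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A one-row test-result tibble.
#' @examples
#' summary_t_test(1.66, 0.13, 37, 1.39, 0.20, 24)  # t approx 6.40
#' @export
summary_t_test <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) stop("undefined statistic: zero variance and equal means")
    return(test_result(paste0(variant, "-t"), sign(m1 - m2) * Inf,
                       n1 + n2 - 2, 0))
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  test_result(paste0(variant, "-t"), t_stat, df,
              2 * stats::pt(-abs(t_stat), df))
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference `(m1 - m2) / s_pooled` with the
#' pooled SD `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @inheritParams summary_t_test
#' @return The effect size (scalar).
#' @examples
#' cohens_d(1.66, 0.13, 37, 1.39, 0.20, 24)  # approx 1.68
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    stop("undefined effect: zero pooled SD with unequal means")
  }
  (m1 - m2) / sp
}

#' One-tailed Pearson correlation
#'
#' Pearson r with a directional p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))`: the probability of a correlation at
#' least as negative (or positive) as observed under the null.
#'
#' @param x,y Numeric vectors.
#' @param direction `"negative"` or `"positive"`, the alternative
#'   hypothesis; must be stated explicitly.
#' @return A one-row test-result tibble with `effect` = r.
#' @examples
#' pearson_one_tailed(1:10, -(1:10) + rnorm(10), "negative")
#' @export
pearson_one_tailed <- function(x, y, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient data: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(x, y)
  df <- n - 2
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- stats::pt(t_stat, df, lower.tail = direction == "negative")
  test_result("pearson-one-tailed", t_stat, df, p, tails = "one",
              effect = r, effect_name = "r")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1; `a`/`b` are the first group's
#' two outcome counts and `c`/`d` the second group's.
#'
#' @param a,b,c,d Cell counts (non-negative).
#' @return A one-row test-result tibble.
#' @examples
#' chi2_2x2(29, 32, 17, 21)  # p approx 0.786
#' @export
chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("undefined test: zero marginal total")
  stat <- n * (a * d - b * c)^2 / prod(marg)
  test_result("chi-square", stat, 1, stats::pchisq(stat, 1,
                                                   lower.tail = FALSE))
}

#' Standardized multiple linear regression
#'
#' z-scores the outcome and every covariate, fits ordinary least squares,
#' and returns the standardized coefficient (beta) and two-sided t-test
#' p-value per covariate — the form in which regression effects of left
#' and right ALPS indices on clinical scores are reported.
#'
#' @param outcome Numeric vector.
#' @param covariates Numeric matrix or data frame, one column per
#'   covariate; no constant columns.
#' @return A tibble with `term`, `beta`, `p_value`.
#' @examples
#' x <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("l", "r")))
#' standardized_regression(x[, 1] + rnorm(40, sd = 0.1), x)
#' @export
standardized_regression <- function(outcome, covariates) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(outcome)
  if (n != nrow(X)) stop("outcome and covariates lengths differ")
  if (n <= ncol(X) + 1) {
    stop("insufficient data: need n > number of covariates + 1")
  }
  if (any(apply(X, 2, stats::sd) == 0)) {
    stop("constant covariate: cannot standardize")
  }
  Xz <- scale(X)
  if (kappa(cbind(1, Xz), exact = TRUE) > 1e8) {
    stop("collinearity error: covariate condition number exceeds 1e8")
  }
  yz <- as.vector(scale(outcome))
  fit <- stats::lm(yz ~ Xz)
  sm <- summary(fit)$coefficients
  tibble::tibble(term = colnames(X),
                 beta = unname(sm[-1, 1]),
                 p_value = unname(sm[-1, 4]))
}

#' All patient-vs-control contrasts of a cohort
#'
#' Runs [two_sample_compare()] on every shared continuous variable and
#' [chi2_2x2()] on sex, returning one tidy row per test — the engine
#' behind the demographics table.
#'
#' @param cohort A cohort tibble.
#' @param variables Continuous columns to contrast; defaults to age and
#'   the ALPS columns (the variables both cohorts carry).
#' @param policy Test policy passed to [two_sample_compare()].
#' @return A tibble with `variable` plus test-result columns.
#' @export
cohort_contrasts <- function(cohort,
                             variables = c("age", "alps_left", "alps_right",
                                           "alps_diff"),
                             policy = "auto") {
  pat <- cohort[cohort$cohort == "patient", ]
  ctl <- cohort[cohort$cohort == "control", ]
  cont <- purrr::map_dfr(variables, function(v) {
    if (all(is.na(ctl[[v]])) || all(is.na(pat[[v]]))) return(NULL)
    dplyr::bind_cols(tibble::tibble(variable = v),
                     two_sample_compare(pat[[v]], ctl[[v]], policy = policy))
  })
  if ("sex" %in% names(cohort) && nrow(pat) > 0 && nrow(ctl) > 0) {
    sex <- dplyr::bind_cols(
      tibble::tibble(variable = "sex"),
      chi2_2x2(sum(pat$sex == "male"), sum(pat$sex == "female"),
               sum(ctl$sex == "male"), sum(ctl$sex == "female")))
    cont <- dplyr::bind_rows(cont, sex)
  }
  cont
}
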