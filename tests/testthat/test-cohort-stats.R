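test_that("threshold flagging reproduces percentages from exact counts", {
  co <- cohort_with_counts()
  fl <- flag_thresholds(co)
  expect_equal(fl$pct[fl$scale == "moca"], 18.0)
  expect_equal(fl$pct[fl$scale == "fss"], 31.1)
  expect_equal(fl$pct[fl$scale == "psqi"], 21.3)
  expect_equal(fl$count[fl$scale == "moca"], 11)
  # percentages always recompute from counts
  expect_equal(fl$pct, round(100 * fl$count / fl$n, 1))
})

test_that("healthy-extreme scores flag nothing and strictness is configurable", {
  n <- 10
  healthy <- tibble::tibble(moca = rep(30, n), fss = rep(9, n),
                            psqi = rep(0, n), phq9 = rep(0, n),
                            gad7 = rep(0, n), hamd = rep(0, n),
                            hama = rep(0, n))
  expect_true(all(flag_thresholds(healthy)$pct == 0))

  at_cut <- tibble::tibble(fss = rep(36, n))
  expect_equal(flag_thresholds(at_cut)$count, n)   # inclusive by default
  strict <- dplyr::mutate(clinical_scales(), strict = TRUE)
  expect_equal(flag_thresholds(at_cut, scales = strict)$count, 0)
  expect_error(flag_thresholds(healthy[0, ]), "empty cohort")
})

test_that("identical samples give a null t result", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5)
  res <- two_sample_compare(x, x, policy = "student")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the auto policy gates on Shapiro-Wilk normality", {
  set.seed(31)
  norm1 <- stats::rnorm(30)
  norm2 <- stats::rnorm(30)
  expect_match(two_sample_compare(norm1, norm2)$test, "student-t")
  skewed <- stats::rexp(30)^3
  expect_match(two_sample_compare(norm1, skewed)$test, "mann-whitney")
})

test_that("exact Mann-Whitney matches the printed small-sample example", {
  res <- two_sample_compare(c(1, 2, 3), c(4, 5, 6), policy = "mannwhitney")
  expect_equal(res$statistic, 0)     # U = 0
  expect_equal(res$p_value, 0.1)
})

test_that("exact Mann-Whitney equals full enumeration for n1 = n2 <= 5", {
  for (n in 2:5) {
    splits <- utils::combn(2 * n, n)
    vals <- seq_len(2 * n)
    for (j in seq_len(ncol(splits))) {
      x <- vals[splits[, j]]
      y <- vals[-splits[, j]]
      mine <- two_sample_compare(x, y, policy = "mannwhitney")$p_value
      expect_equal(mine, mw_enum_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("summary-statistic t tests reproduce closed-form values", {
  expect_equal(summary_t_test(5, 1, 10, 5, 2, 10)$statistic, 0)
  expect_equal(summary_t_test(5, 1, 10, 5, 2, 10)$p_value, 1)

  tab2 <- summary_t_test(1.66, 0.13, 37, 1.39, 0.20, 24)
  expect_equal(tab2$statistic, 6.40, tolerance = 0.005)
  expect_lt(tab2$p_value, 0.001)
  expect_equal(tab2$df, 59)

  expect_equal(summary_t_test(0, 1, 10, 1, 1, 10)$statistic,
               -1 / sqrt(2 / 10), tolerance = 1e-12)
  expect_error(summary_t_test(1, 0, 5, 1, 0, 5), "undefined statistic")
})

test_that("summary t equals the raw-data t.test for both variants", {
  set.seed(17)
  x <- stats::rnorm(14, 1, 1.3)
  y <- stats::rnorm(9, 0.2, 0.7)
  for (v in c("student", "welch")) {
    mine <- summary_t_test(mean(x), stats::sd(x), length(x),
                           mean(y), stats::sd(y), length(y), variant = v)
    ref <- stats::t.test(x, y, var.equal = v == "student")
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("Cohen's d follows the pooled-SD formula and is antisymmetric", {
  expect_equal(cohens_d(5, 1, 10, 5, 2, 10), 0)
  expect_equal(cohens_d(1, 1, 8, 0, 1, 8), 1)
  expect_equal(cohens_d(1.66, 0.13, 37, 1.39, 0.20, 24), 1.68,
               tolerance = 0.005)
  set.seed(9)
  for (i in 1:10) {
    m <- stats::rnorm(2)
    s <- stats::runif(1, 0.5, 2)
    expect_equal(cohens_d(m[1], s, 12, m[2], s, 12),
                 -cohens_d(m[2], s, 12, m[1], s, 12))
  }
})

test_that("one-tailed Pearson correlation handles the canonical cases", {
  x <- 1:20
  perfect <- pearson_one_tailed(x, 2 * x + 1, "positive")
  expect_equal(perfect$effect, 1)
  expect_lt(perfect$p_value, 1e-10)
  expect_equal(pearson_one_tailed(x, -x, "negative")$effect, -1)
  expect_error(pearson_one_tailed(x, rep(1, 20), "negative"),
               "zero variance")
  # directional p-values from the two tails sum to 1 (continuous t)
  set.seed(3)
  y <- stats::rnorm(20)
  p_neg <- pearson_one_tailed(x, y, "negative")$p_value
  p_pos <- pearson_one_tailed(x, y, "positive")$p_value
  expect_equal(p_neg + p_pos, 1, tolerance = 1e-12)
})

test_that("simulated aging cohorts give mostly negative age correlations", {
  rs <- vapply(1:50, function(seed) {
    co <- simulate_cohort(cohort_sim_params(seed = seed))
    pat <- co[co$cohort == "patient", ]
    pearson_one_tailed(pat$age, pat$alps_left, "negative")$effect
  }, numeric(1))
  expect_lt(stats::median(rs), 0)
})

test_that("the 2x2 chi-square matches hand computation and stats::chisq.test", {
  res <- chi2_2x2(29, 32, 17, 21)
  expect_equal(res$statistic, 99 * (29 * 21 - 32 * 17)^2 /
                 (61 * 38 * 46 * 53), tolerance = 1e-12)
  expect_equal(res$p_value, 0.78, tolerance = 0.01)
  ref <- stats::chisq.test(matrix(c(29, 32, 17, 21), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  expect_equal(chi2_2x2(10, 10, 5, 5)$statistic, 0)
  expect_equal(chi2_2x2(10, 10, 5, 5)$p_value, 1)
  expect_lt(chi2_2x2(20, 0, 0, 20)$p_value, 0.001)
  expect_error(chi2_2x2(5, 5, 0, 0), "zero marginal")
})

test_that("standardized regression recovers coefficients on noise-free data", {
  set.seed(23)
  X <- matrix(stats::rnorm(200), ncol = 2,
              dimnames = list(NULL, c("left", "right")))
  y <- 0.3 * X[, 1] + 0.5 * X[, 2]
  fit <- standardized_regression(y, X)
  # normal-equations oracle on standardized variables
  Xz <- scale(X); yz <- as.vector(scale(y))
  beta_oracle <- solve(crossprod(Xz), crossprod(Xz, yz))
  expect_equal(fit$beta, as.vector(beta_oracle), tolerance = 1e-10)

  perfect <- standardized_regression(X[, 1], X[, 1, drop = FALSE])
  expect_equal(perfect$beta, 1, tolerance = 1e-10)
  expect_lt(perfect$p_value, 1e-10)
})

test_that("orthogonal covariates give betas equal to simple correlations", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)   # exactly orthogonal to x1
  set.seed(5)
  y <- 0.4 * x1 - 0.2 * x2 + stats::rnorm(n)
  fit <- standardized_regression(y, cbind(a = x1, b = x2))
  expect_equal(fit$beta, c(stats::cor(y, x1), stats::cor(y, x2)),
               tolerance = 1e-10)
})

test_that("degenerate regression inputs are rejected", {
  y <- stats::rnorm(10)
  expect_error(standardized_regression(y, cbind(rep(1, 10))),
               "constant covariate")
  x <- stats::rnorm(10)
  expect_error(standardized_regression(y, cbind(x, x)), "collinearity")
  expect_error(standardized_regression(y[1:3], cbind(x, x + rnorm(10))[1:3, ]),
               "insufficient data")
})

test_that("tests are order-invariant and shift-invariant", {
  set.seed(41)
  x <- stats::rnorm(12)
  y <- stats::rnorm(12, 0.5)
  perm <- sample(12)
  for (pol in c("student", "mannwhitney")) {
    base <- two_sample_compare(x, y, policy = pol)
    expect_equal(two_sample_compare(x[perm], y[perm], policy = pol)$p_value,
                 base$p_value, tolerance = 1e-12)
    expect_equal(two_sample_compare(x + 3, y + 3, policy = pol)$p_value,
                 base$p_value, tolerance = 1e-9)
  }
})
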