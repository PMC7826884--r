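# helper: quick synthetic model-data frame from the generator
make_model_data <- function(seed, beta = NULL, n_years = NULL) {
  cfg <- if (is.null(beta)) test_config(seed = seed) else
    test_config(seed = seed, beta = beta)
  ds <- simulate_breeding_population(cfg)
  rec <- ds$records
  adults <- unique(c(rec$female_id, rec$male_id))
  sc <- score_population(ds$genotypes[adults, ],
                         rec[, c("female_id", "male_id", "year")])
  ind <- sc$individuals
  data.frame(rec, relatedness = sc$dyads$r,
             F = ind$F[match(rec$male_id, ind$individual_id)],
             Hs = ind$Hs[match(rec$male_id, ind$individual_id)])
}

test_that("GLMM reduces to plain logistic regression when variance is null", {
  # data generated without any group structure: random-effect variances hit
  # the boundary and the Laplace fit coincides with glm
  set.seed(18)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  g1 = sample(letters[1:8], n, TRUE),
                  g2 = sample(LETTERS[1:5], n, TRUE))
  eta <- -1 + 0.8 * d$x1
  d$y <- as.integer(runif(n) < plogis(eta))
  fit <- fit_binomial_glmm(d, "y", c("x1", "x2"), c("g1", "g2"))
  # both variance components must sit on the boundary for exact reduction
  vc <- as.data.frame(lme4::VarCorr(fit$fit))$vcov
  expect_true(all(vc < 1e-10))
  ref <- glm(y ~ x1 + x2, binomial, d)
  ct <- coefficient_table(fit)
  expect_true(fit$singular)
  expect_equal(ct$Estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # k counts intercept + fixed effects + one variance component per RE
  expect_equal(fit$k, 3 + 2)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$k)
  expect_equal(fit$deviance, -2 * fit$loglik)
  # estimates recover the generating coefficients loosely at this n
  expect_lt(abs(ct$Estimate[2] - 0.8), 0.35)
})

test_that("intercept-only fit on a balanced response centres near zero", {
  set.seed(2)
  d <- data.frame(y = rep(c(0, 1), 40), g = sample(letters[1:6], 80, TRUE),
                  h = sample(letters[7:10], 80, TRUE))
  fit <- fit_binomial_glmm(d, "y", character(0), c("g", "h"))
  expect_lt(abs(coefficient_table(fit)$Estimate[1]), 0.3)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12),
                  z = rep(1, 6), g = letters[1:6])
  expect_error(fit_binomial_glmm(d, "y", "x", "g"), "separation.*x")
  expect_error(fit_binomial_glmm(d, "y", "z", "g"), "constant")
  expect_error(fit_binomial_glmm(d, "y", "x", character(0)), "random")
  d$y2 <- 1
  expect_error(fit_binomial_glmm(d, "y2", "x", "g"), "constant")
})

test_that("likelihood-ratio test follows the chi-squared formula", {
  d <- make_model_data(301)
  full <- fit_binomial_glmm(d, "double", c("stripe", "relatedness"),
                            c("male_id", "year"))
  red <- fit_binomial_glmm(d, "double", "stripe", c("male_id", "year"))
  lrt <- lr_test(full, red)
  expect_equal(lrt$statistic, max(0, 2 * (full$loglik - red$loglik)))
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_gte(lrt$statistic, 0)

  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  other <- fit_binomial_glmm(d, "double", "tarsus", c("male_id", "year"))
  expect_error(lr_test(full, other), "nested")
})

test_that("all_subsets enumerates the full model lattice", {
  p6 <- all_subsets(c("a", "b", "c", "d", "e", "f"))
  expect_length(p6, 64)
  expect_equal(sum(lengths(p6) == 0), 1)
  expect_length(all_subsets(character(0)), 1)
  p2 <- all_subsets(c("x", "y"))
  expect_length(p2, 4)
  expect_setequal(vapply(p2, paste, character(1), collapse = "+"),
                  c("", "x", "y", "x+y"))
  expect_error(all_subsets(letters[1:17]), "16")
})

test_that("AICc follows its closed form and limits", {
  # AIC = 10 with k = 3: loglik = (10 - 6)/(-2) = -2
  expect_equal(aicc(-2, 3, 30), 10 + 2 * 3 * 4 / 26)
  expect_equal(round(aicc(-2, 3, 30), 4), 10.9231)
  # the study-sized correction: k = 7, n = 73 adds 112/65
  expect_equal(aicc(0, 7, 73) - (2 * 7), 112 / 65, tolerance = 1e-12)
  expect_equal(round(112 / 65, 4), 1.7231)
  # large-n limit recovers AIC
  expect_lt(abs(aicc(-50, 4, 1e7) - (100 + 8)), 1e-5)
  expect_error(aicc(-2, 10, 11), "exceed")
})

test_that("Akaike weights and deltas follow the definition", {
  mk <- function(ll, k) structure(list(loglik = ll, k = k, n = 73,
                                       deviance = -2 * ll, converged = TRUE,
                                       fixed = letters[seq_len(k - 3)]),
                                  class = "glmm_fit")
  # two models with delta = (0, 2)
  f1 <- mk(-10, 4)
  f2 <- mk(-11, 4)  # same k, loglik lower by 1 -> delta AICc = 2
  tab <- rank_models(list(f1, f2), n = 73)
  expect_equal(tab$delta_AICc, c(0, 2))
  expect_equal(tab$weight, c(exp(0), exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(round(tab$weight, 4), c(0.7311, 0.2689))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)

  single <- rank_models(list(f1), n = 73)
  expect_equal(single$delta_AICc, 0)
  expect_equal(single$weight, 1)

  # weight ratio for delta = (0, 0.98) matches exp(0.49), consistent with the
  # published weight pair 0.34/0.21 up to printed rounding
  f3 <- mk(-10 - 0.49, 4)
  tab2 <- rank_models(list(f1, f3), n = 73)
  expect_equal(tab2$weight[1] / tab2$weight[2], exp(0.49), tolerance = 1e-12)
  expect_equal(round(exp(0.49), 3), 1.632)
})

test_that("rank_models output is invariant to input order", {
  d <- make_model_data(302)
  fits <- lapply(list(c("stripe"), c("relatedness"), c("stripe", "Hs")),
                 function(fx) fit_binomial_glmm(d, "double", fx,
                                                c("male_id", "year")))
  t1 <- rank_models(fits)
  t2 <- rank_models(rev(fits))
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_equal(t1$delta_AICc[1], 0)
})

test_that("VIF matches hand values and flags collinearity", {
  set.seed(8)
  n <- 400
  x1 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  v <- vif(d, c("x1", "x2", "x3"))
  expect_true(all(v < 2))

  # two predictors with sample correlation r have VIF = 1/(1 - r^2)
  x2 <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * scale(rnorm(n))[, 1]
  d2 <- data.frame(a = x1, b = x2)
  r2 <- cor(d2$a, d2$b)^2
  v2 <- vif(d2, c("a", "b"))
  expect_equal(unname(v2["a"]), 1 / (1 - r2), tolerance = 1e-8)

  d3 <- data.frame(a = x1, b = 2 * x1 + 3)
  expect_true(is.infinite(max(vif(d3, c("a", "b")))))
  expect_equal(round(1 / (1 - 0.81), 3), 5.263)
})

test_that("Welch t from summaries reproduces the published group contrasts", {
  expect_equal(welch_t_from_summary(1, 1, 10, 1, 1, 10)$statistic, 0)
  expect_equal(welch_t_from_summary(1, 1, 10, 1, 1, 10)$p, 1)

  # relatedness: DB -0.096 +- 0.037 (n=22) vs SB 0.070 +- 0.030 (n=51)
  t_rel <- welch_t_from_summary(-0.096, 0.037, 22, 0.070, 0.030, 51)
  expect_lt(abs(t_rel$abs_t - 3.489) / 3.489, 0.01)
  expect_lt(t_rel$p, 0.01)

  # stripe width: DB 10.838 +- 0.561 vs SB 9.525 +- 0.256
  t_st <- welch_t_from_summary(10.838, 0.561, 22, 9.525, 0.256, 51)
  expect_lt(abs(t_st$abs_t - 2.144) / 2.144, 0.01)
})

test_that("rank-sum test matches enumeration and handles ties by midranks", {
  rs <- rank_sum_test(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(rs$statistic, 3)  # rank sum of x; U = 0
  expect_equal(rs$U, 0)
  expect_equal(rs$p, 1 / 6)      # 1 of C(4,2) arrangements as extreme

  same <- rank_sum_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p, 1)

  # normal approximation close to exact enumeration at n1 = n2 = 6
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("compare_hypotheses fits the three models on one row set", {
  d <- make_model_data(303)
  cmp <- compare_hypotheses(d, nAGQ = 0L)
  expect_named(cmp$fits, c("good", "compatible", "both"))
  expect_equal(cmp$fits$good$fixed,
               c("F", "Hs", "stripe", "tarsus", "repertoire"))
  expect_equal(cmp$fits$compatible$fixed, "relatedness")
  expect_length(cmp$fits$both$fixed, 6)
  expect_equal(unique(vapply(cmp$fits, `[[`, numeric(1), "n")), nrow(d))
  expect_equal(cmp$ranking$AIC, sort(cmp$ranking$AIC))
})
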