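# Regression and model-selection layer: binomial-logit mixed models (Laplace
# ML via lme4), likelihood-ratio tests, the three-hypothesis AIC comparison,
# all-subsets AICc selection with Akaike weights, VIF screening, and the
# two-sample tests used for group contrasts.

#' Fit a binomial-logit GLMM
#'
#' Wraps [lme4::glmer()] (Laplace-approximated maximum likelihood) for a
#' binary response with random intercepts, exposing the quantities the
#' selection layer needs: per-coefficient estimates, SEs, Wald Z and p,
#' log-likelihood, AIC, deviance, and the parameter count `k` (intercept +
#' fixed effects + one variance component per random effect). A random-effect
#' variance estimated at 0 is permitted and flagged (`singular`);
#' non-convergence is flagged, not raised.
#'
#' @param data data.frame containing the response, predictors and grouping
#'   factors.
#' @param response name of the binary (0/1) response column.
#' @param fixed character vector of fixed-effect predictor names (may be
#'   empty: intercept-only model).
#' @param random character vector of random-intercept grouping factors (must
#'   be non-empty).
#' @param nAGQ integer passed to `glmer` (0 = faster penalized-likelihood
#'   step, 1 = Laplace; default 1).
#' @return class `glmm_fit`: list with `loglik`, `AIC`, `deviance`, `k`, `n`,
#'   `converged`, `singular`, `fixed`, `random`, and the underlying `merMod`
#'   in `fit`; the Wald coefficient table is computed on demand by
#'   [coefficient_table()].
#' @export
fit_binomial_glmm <- function(data, response, fixed, random, nAGQ = 1L) {
  y <- data[[response]]
  if (is.null(y)) stop("response column not found: ", response)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("response is constant")
  if (!length(random)) stop("at least one random-effect grouping factor required")
  for (v in fixed) {
    x <- data[[v]]
    if (is.null(x)) stop("predictor not found: ", v)
    if (stats::var(x) == 0) stop("predictor is constant: ", v)
    # complete separation on a single predictor makes the MLE diverge
    if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
      stop("complete separation on predictor: ", v)
    }
  }
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 sprintf("(1 | %s)", random)), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  converged <- TRUE
  quiet_glmer <- function(nagq) {
    withCallingHandlers(
      lme4::glmer(fml, data = data, family = stats::binomial(link = "logit"),
                  nAGQ = nagq),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        # lme4 reports boundary (singular) fits as messages; the singular
        # flag below carries the information
        invokeRestart("muffleMessage")
      })
  }
  fit <- tryCatch(quiet_glmer(nAGQ), error = function(e) e)
  if (inherits(fit, "error") && nAGQ == 0L) {
    # the penalized-likelihood step can fail where full Laplace succeeds
    converged <- FALSE
    fit <- tryCatch(quiet_glmer(1L), error = function(e) e)
  }
  if (inherits(fit, "error")) {
    # near-certain (quasi-)separation of the binary response by the joint
    # predictor set: the MLE diverges and no mixed fit exists
    stop("GLMM could not be fitted (", conditionMessage(fit),
         "); the predictors likely separate the response: ",
         paste(fixed, collapse = ", "))
  }
  ll <- stats::logLik(fit)
  structure(list(
    loglik = as.numeric(ll),
    AIC = -2 * as.numeric(ll) + 2 * attr(ll, "df"),
    deviance = -2 * as.numeric(ll),
    k = attr(ll, "df"),
    n = stats::nobs(fit),
    converged = converged,
    singular = lme4::isSingular(fit),
    fixed = fixed, random = random, response = response,
    fit = fit
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("binomial-logit GLMM: %s ~ %s + (1 | %s)\n", x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              paste(x$random, collapse = ") + (1 | ")))
  print(coefficient_table(x), digits = 4, row.names = FALSE)
  cat(sprintf("logLik %.3f  AIC %.2f  deviance %.2f  k %d  n %d%s%s\n",
              x$loglik, x$AIC, x$deviance, x$k, x$n,
              if (!x$converged) "  [non-convergence flagged]" else "",
              if (x$singular) "  [singular random effects]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of nested GLMMs
#'
#' @param fit_full,fit_reduced [fit_binomial_glmm()] results; the reduced
#'   model's fixed effects must be a subset of the full model's, with
#'   identical random effects and response.
#' @return class `test_result`: list with `statistic_name = "chisq"`,
#'   `statistic`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  if (!all(fit_reduced$fixed %in% fit_full$fixed) ||
      !setequal(fit_reduced$random, fit_full$random) ||
      fit_reduced$response != fit_full$response) {
    stop("models are not nested")
  }
  chisq <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  df <- fit_full$k - fit_reduced$k
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  structure(list(statistic_name = "chisq", statistic = chisq, df = df, p = p),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  lab <- switch(x$statistic_name, chisq = "chi-squared", x$statistic_name)
  extra <- if (!is.null(x$df)) sprintf(", df = %s", paste(round(x$df, 2), collapse = ",")) else ""
  cat(sprintf("%s = %.4g%s, p = %.4g\n", lab, x$statistic, extra, x$p))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Compare the good-genes, compatibility and combined hypothesis models
#'
#' Fits three binomial-logit GLMMs for male pairing status in double breeding
#' (male identity and year as random intercepts): (a) good genes — individual
#' F, Hs, breast stripe width, tarsus length, repertoire size; (b) compatible
#' genes — pair relatedness; (c) both — all six predictors. Returns the fits
#' and an AIC-ordered ranking.
#'
#' @param data data.frame with columns `double` (0/1), `F`, `Hs`, `stripe`,
#'   `tarsus`, `repertoire`, `relatedness`, `male_id`, `year` (or supply
#'   custom names via the arguments).
#' @param response,random column names.
#' @param good,compatible character vectors naming the predictors of the two
#'   hypothesis models; the combined model uses their union.
#' @param nAGQ passed to [fit_binomial_glmm()].
#' @return list with `fits` (named list: good, compatible, both) and `ranking`
#'   (data.frame: model, AIC, loglik, k, ordered by AIC).
#' @export
compare_hypotheses <- function(data, response = "double",
                               random = c("male_id", "year"),
                               good = c("F", "Hs", "stripe", "tarsus", "repertoire"),
                               compatible = "relatedness",
                               nAGQ = 1L) {
  specs <- list(good = good, compatible = compatible,
                both = union(good, compatible))
  fits <- lapply(specs, function(fx) {
    fit_binomial_glmm(data, response, fx, random, nAGQ = nAGQ)
  })
  ranking <- data.frame(
    model = names(fits),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    row.names = NULL, stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$AIC), ]
  list(fits = fits, ranking = ranking)
}

#' Enumerate all subsets of a predictor set
#'
#' @param predictors character vector (at most 16 names).
#' @return list of `2^length(predictors)` character vectors, from the empty
#'   (intercept-only) model upward, ordered by subset size then
#'   lexicographically.
#' @export
all_subsets <- function(predictors) {
  p <- length(predictors)
  if (p > 16L) stop("at most 16 predictors supported")
  if (p == 0L) return(list(character(0)))
  subsets <- lapply(0:(2^p - 1), function(mask) {
    predictors[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0L]
  })
  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, character(1), collapse = "\r")
  subsets[order(sizes, keys)]
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations (must exceed `k + 1`).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc with Akaike weights
#'
#' @param fits list of [fit_binomial_glmm()] results (the full candidate set).
#' @param n number of observations used for the AICc correction (default:
#'   taken from the first fit; all fits must share the row set).
#' @param delta_threshold retention threshold on ΔAICc (default 4).
#' @return class `model_selection_table`: data.frame with columns `model`
#'   (predictor set as a string), `np`, `deviance`, `AICc`, `delta_AICc`,
#'   `weight`, `retained`, sorted by AICc; weights are normalized over the
#'   full candidate set.
#' @export
rank_models <- function(fits, n = fits[[1]]$n, delta_threshold = 4) {
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) stop("no converged fit to rank")
  tab <- data.frame(
    model = vapply(fits, function(f) {
      if (length(f$fixed)) paste(sort(f$fixed), collapse = " + ")
      else "(intercept only)"
    }, character(1)),
    np = vapply(fits, `[[`, numeric(1), "k"),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    AICc = vapply(fits, function(f) aicc(f$loglik, f$k, n), numeric(1)),
    converged = conv,
    row.names = NULL, stringsAsFactors = FALSE)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  tab$retained <- tab$delta_AICc < delta_threshold
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  attr(tab, "n") <- n
  attr(tab, "delta_threshold") <- delta_threshold
  class(tab) <- c("model_selection_table", "data.frame")
  tab
}

#' @export
print.model_selection_table <- function(x, max_rows = 10L, ...) {
  cat(sprintf("model selection over %d candidate models (n = %d, retain dAICc < %g)\n",
              nrow(x), attr(x, "n"), attr(x, "delta_threshold")))
  df <- as.data.frame(x)[, c("model", "np", "delta_AICc", "deviance", "weight")]
  print(utils::head(df, max_rows), digits = 3)
  if (nrow(df) > max_rows) cat("... and", nrow(df) - max_rows, "more models\n")
  invisible(x)
}

#' Fit every subset of a predictor set and rank by AICc
#'
#' All-subsets (dredge-style) selection: fits `2^p` binomial-logit GLMMs on
#' the same row set and ranks them with [rank_models()].
#'
#' @inheritParams fit_binomial_glmm
#' @param predictors character vector of candidate fixed effects.
#' @param delta_threshold retention threshold on ΔAICc.
#' @return list with `table` (a [rank_models()] result) and `fits` (list, in
#'   the same order as [all_subsets()]).
#' @export
fit_all_subsets <- function(data, response, predictors, random,
                            delta_threshold = 4, nAGQ = 1L) {
  subsets <- all_subsets(predictors)
  fits <- lapply(subsets, function(fx) {
    fit_binomial_glmm(data, response, fx, random, nAGQ = nAGQ)
  })
  list(table = rank_models(fits, delta_threshold = delta_threshold),
       fits = fits)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from the least-squares regression of
#' predictor j on the remaining predictors. Perfect collinearity is reported
#' as `Inf`.
#'
#' @param data data.frame containing the predictors.
#' @param predictors character vector (>= 2 names, each non-constant).
#' @return named numeric vector of VIFs, with attribute `max_vif`.
#' @export
vif <- function(data, predictors) {
  if (length(predictors) < 2L) stop("VIF needs at least 2 predictors")
  for (v in predictors) {
    if (stats::var(data[[v]]) == 0) stop("predictor is constant: ", v)
  }
  out <- vapply(predictors, function(v) {
    fml <- stats::as.formula(paste(v, "~", paste(setdiff(predictors, v),
                                                 collapse = " + ")))
    # summary.lm warns on essentially perfect fits; that case is exactly the
    # infinite-VIF flag below
    r2 <- suppressWarnings(summary(stats::lm(fml, data = data))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  attr(out, "max_vif") <- max(out)
  out
}

#' Welch two-sample t-test from group summaries
#'
#' `t = (m2 - m1) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite degrees of
#' freedom computed from the standard errors; two-tailed p. This unpooled form
#' reproduces published t statistics computed from group means and SEs.
#'
#' @param m1,se1,n1 mean, standard error and size of group 1.
#' @param m2,se2,n2 mean, standard error and size of group 2.
#' @return class `test_result` with `statistic_name = "t"`, `statistic`
#'   (absolute t also stored as `abs_t`), `df`, `p`, `n1`, `n2`.
#' @export
welch_t_from_summary <- function(m1, se1, n1, m2, se2, n2) {
  stopifnot(se1 > 0, se2 > 0, n1 >= 2, n2 >= 2)
  v1 <- se1^2; v2 <- se2^2
  t <- (m2 - m1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(statistic_name = "t", statistic = t, abs_t = abs(t),
                 df = df, p = p, n1 = n1, n2 = n2),
            class = "test_result")
}

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' The reported statistic `W` is the rank sum of the first sample (midranks
#' for ties); `U = W - n1(n1+1)/2` is also returned. The p-value comes from
#' [stats::wilcox.test()]: exact enumeration when `n1 + n2 <= 12` with no
#' ties, otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return class `test_result` with `statistic_name = "W"`, `statistic` (rank
#'   sum of `x`), `U`, `n1`, `n2`, `p`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  if (stats::var(c(x, y)) == 0) {
    # every observation tied: midranks are all equal and no evidence exists
    return(structure(list(statistic_name = "W",
                          statistic = n1 * (n1 + n2 + 1) / 2,
                          U = n1 * n2 / 2, n1 = n1, n2 = n2, p = 1,
                          note = "all observations tied"),
                     class = "test_result"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = !exact))
  u <- unname(wt$statistic)
  structure(list(statistic_name = "W", statistic = u + n1 * (n1 + 1) / 2,
                 U = u, n1 = n1, n2 = n2, p = wt$p.value,
                 note = if (exact) "exact enumeration"
                        else "normal approximation with tie correction"),
            class = "test_result")
}

#' Coefficient table of a fitted GLMM in publication layout
#'
#' Wald estimates, standard errors, Z and two-tailed p per fixed effect.
#'
#' @param fit a [fit_binomial_glmm()] result.
#' @return data.frame with columns Variable, Estimate, se, Z, p.
#' @export
coefficient_table <- function(fit) {
  cf <- summary(fit$fit)$coefficients
  data.frame(Variable = rownames(cf),
             Estimate = cf[, "Estimate"],
             se = cf[, "Std. Error"],
             df = 1L,  # Wald tests: one degree of freedom per coefficient
             Z = cf[, "z value"],
             p = cf[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
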