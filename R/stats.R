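# Choice-proportion modelling (binomial GLMM with per-bee random intercept)
# and the randomization test on final-window choice proportions.

#' Fit a logistic choice curve with per-bee random intercepts
#'
#' Models per-trip proportions of choices to vertical flowers against the
#' cumulative number of completed drinks at trip end, as a binomial GLMM
#' with a random intercept per bee (delegated to [lme4::glmer()]). Reports
#' the model-predicted mean proportion (MPMP: population-level prediction,
#' random effects at zero) at requested predictor values, with percentile
#' bootstrap confidence intervals from [lme4::bootMer()] (parametric
#' bootstrap; default 10,000 simulations, scale down for interactive work).
#'
#' The predictor is internally rescaled (divided by 100) for optimizer
#' stability; reported quantities are on the response scale.
#'
#' @param data data.frame as returned by [proportion_vertical()]: columns
#'   bee_id, cum_drinks, k_vertical, n (one row per trip per bee).
#' @param at Predictor values (cumulative drinks) for predictions.
#' @param nboot Bootstrap simulations for the CI (0 skips the bootstrap).
#' @param level Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `choice_curve`: list with `fitted` (data.frame:
#'   at, mpmp, lwr, upr), `model` (the merMod), `coef` (fixed effects on
#'   the rescaled predictor), `coef_ci` (bootstrap CIs for intercept and
#'   slope), `nboot`, `level`.
#' @export
fit_choice_curve <- function(data, at, nboot = 10000, level = 0.95,
                             seed = NULL) {
  need <- c("bee_id", "cum_drinks", "k_vertical", "n")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_beeforage("schema", "choice data missing column(s): ",
                   paste(miss, collapse = ", "))
  if (length(unique(data$bee_id)) < 2)
    stop_beeforage("config", "need at least two bees to fit a mixed model")
  if (any(data$n < 1) || any(data$k_vertical > data$n))
    stop_beeforage("validation", "need 0 <= k_vertical <= n, n >= 1")
  d <- data.frame(bee_id = factor(data$bee_id),
                  x = data$cum_drinks / 100,
                  k = data$k_vertical, n = data$n)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(cbind(k, n - k) ~ x + (1 | bee_id), data = d,
                  family = stats::binomial()),
      error = function(e)
        stop_beeforage("convergence", "choice-curve fit failed: ",
                       conditionMessage(e))),
    warning = function(w) {
      if (grepl("failed to converge|unable to evaluate",
                conditionMessage(w)))
        stop_beeforage("convergence", "choice-curve fit did not converge: ",
                       conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(fit)
  if (length(beta) < 2 || anyNA(beta))
    stop_beeforage("convergence",
                   "choice-curve fit is rank deficient (constant or ",
                   "collinear predictor)")
  boot_stat <- function(model) {
    b <- lme4::fixef(model)
    c(b[[1]], b[[2]], stats::plogis(b[[1]] + b[[2]] * (at / 100)))
  }
  est <- boot_stat(fit)
  fitted <- data.frame(at = at, mpmp = est[-(1:2)],
                       lwr = NA_real_, upr = NA_real_)
  coef_ci <- data.frame(term = c("intercept", "slope"), estimate = est[1:2],
                        lwr = NA_real_, upr = NA_real_)
  if (nboot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bs <- suppressWarnings(
      lme4::bootMer(fit, boot_stat, nsim = nboot, use.u = FALSE,
                    type = "parametric"))
    alpha <- (1 - level) / 2
    qs <- apply(bs$t, 2, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE)
    coef_ci$lwr <- qs[1, 1:2]
    coef_ci$upr <- qs[2, 1:2]
    fitted$lwr <- qs[1, -(1:2)]
    fitted$upr <- qs[2, -(1:2)]
  }
  structure(list(fitted = fitted, model = fit, coef = beta,
                 coef_ci = coef_ci, nboot = nboot, level = level),
            class = "choice_curve")
}

#' @export
print.choice_curve <- function(x, ...) {
  cat("Binomial GLMM choice curve (random intercept per bee)\n")
  cat(sprintf("  logit(p) = %.4f + %.4f * (drinks/100)\n",
              x$coef[[1]], x$coef[[2]]))
  print(transform(x$fitted, mpmp = signif(mpmp, 4), lwr = signif(lwr, 4),
                  upr = signif(upr, 4)), row.names = FALSE)
  invisible(x)
}

#' Randomization test for a difference in group mean proportions
#'
#' Two-group randomization (permutation) test using the difference of group
#' means as the statistic: the pooled values are repeatedly re-split at the
#' original group sizes without replacement, and the p-value is the add-one
#' corrected fraction of resampled |differences| at least as large as the
#' observed |difference| (two-sided default; one-sided alternatives use the
#' signed difference a - b). With `unit = "choices"`, supply per-bee counts
#' (data.frames with columns k, n): individual choice outcomes are pooled
#' and re-split instead of per-bee proportions.
#'
#' @param group_a,group_b Numeric vectors of per-bee proportions (unit
#'   "bees"), or data.frames with columns `k`, `n` (unit "choices").
#' @param n_resamples Number of resampled null values (default 100,000).
#' @param seed Optional RNG seed (recorded in the result).
#' @param alternative "two.sided" (default), "greater" (a > b) or "less".
#' @param unit Resample per-bee proportions ("bees") or pooled choice
#'   outcomes ("choices").
#' @return Object of class `randomization_result`: observed statistic, null
#'   draw count, p-value, seed, alternative, unit.
#' @export
randomization_test <- function(group_a, group_b, n_resamples = 100000,
                               seed = NULL,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               unit = c("bees", "choices")) {
  alternative <- match.arg(alternative)
  unit <- match.arg(unit)
  if (n_resamples < 1)
    stop_beeforage("config", "n_resamples must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (unit == "choices") {
    for (g in list(group_a, group_b))
      if (!is.data.frame(g) || !all(c("k", "n") %in% names(g)))
        stop_beeforage("config",
                       "unit='choices' needs data.frames with columns k, n")
    xa <- rep(c(1, 0), c(sum(group_a$k), sum(group_a$n) - sum(group_a$k)))
    xb <- rep(c(1, 0), c(sum(group_b$k), sum(group_b$n) - sum(group_b$k)))
  } else {
    xa <- as.numeric(group_a); xb <- as.numeric(group_b)
  }
  na <- length(xa); nb <- length(xb)
  if (!na || !nb)
    stop_beeforage("config", "both groups must be non-empty")
  pool <- c(xa, xb)
  observed <- mean(xa) - mean(xb)
  total <- sum(pool); n <- na + nb
  # re-split without replacement; resampling from the *sorted* pool leaves
  # the null distribution unchanged (exchangeability) and makes the p-value
  # exactly invariant to group labelling and location shifts at fixed seed
  pool_s <- sort(pool)
  null_stats <- vapply(seq_len(n_resamples), function(i) {
    sa <- sum(pool_s[sample.int(n, na)])
    sa / na - (total - sa) / nb
  }, numeric(1))
  exceed <- switch(alternative,
                   two.sided = sum(abs(null_stats) >= abs(observed) - 1e-12),
                   greater = sum(null_stats >= observed - 1e-12),
                   less = sum(null_stats <= observed + 1e-12))
  p <- (exceed + 1) / (n_resamples + 1)
  structure(list(observed_stat = observed, null_draws = n_resamples,
                 p_value = p, n_exceed = exceed, seed = seed,
                 alternative = alternative, unit = unit,
                 group_sizes = c(a = na, b = nb)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "Randomization test (%s, unit=%s): diff = %.4g, p = %.4g (%d/%d draws)\n",
    x$alternative, x$unit, x$observed_stat, x$p_value, x$n_exceed,
    x$null_draws))
  invisible(x)
}
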