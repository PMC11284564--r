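#' Inverse-variance-weighted MR estimate
#'
#' The IVW estimate is the inverse-variance-weighted mean of the Wald
#' ratios, algebraically equal to weighted least squares of outcome effects
#' on exposure effects through the origin with weights \eqn{1/SE_{out}^2}:
#' \deqn{\hat\theta = \frac{\sum_j \beta_{exp,j}\beta_{out,j}/SE_{out,j}^2}
#'   {\sum_j \beta_{exp,j}^2/SE_{out,j}^2},\qquad
#'   SE(\hat\theta) = \Big(\sum_j \beta_{exp,j}^2/SE_{out,j}^2\Big)^{-1/2}.}
#' Unbiased only when all instruments are valid; serves as the baseline the
#' pleiotropy-robust estimators are compared against.
#'
#' @param iv An `instrument_set` (at least 3 instruments; fewer raises an
#'   error of class `mr_refusal`).
#' @return A one-row `mr_estimate` tibble: `method`, `estimate` (log-OR per
#'   exposure unit), `se`, `pvalue`, `or`, `ci_low`, `ci_high`, `n_iv`,
#'   `intercept`, `intercept_p`.
#' @examples
#' iv <- as_instrument_set(tibble::tibble(
#'   beta_exp = c(0.2, 0.3, 0.25), se_exp = 0.02,
#'   beta_out = c(0.06, 0.09, 0.075), se_out = 0.01))
#' mr_ivw(iv)
#' @export
mr_ivw <- function(iv) {
  check_min_ivs(iv, "ivw")
  iv <- mr_wald_ratios(iv)
  check_min_ivs(iv, "ivw")
  wsum <- sum(iv$beta_exp^2 / iv$se_out^2)
  est <- sum(iv$beta_exp * iv$beta_out / iv$se_out^2) / wsum
  new_mr_estimate("ivw", est, sqrt(1 / wsum), nrow(iv))
}

#' Weighted median estimator (WME)
#'
#' Orders the Wald ratios and takes the value at cumulative normalized
#' inverse-variance weight 0.5 (linear interpolation between adjacent
#' ratios). Consistent as long as instruments contributing less than half of
#' the total weight are invalid. The standard error is the standard
#' deviation of the estimate over `n_boot` parametric bootstrap replicates
#' (effect pairs redrawn from `N(beta, se^2)`), and the P-value uses the
#' normal approximation.
#'
#' @param iv An `instrument_set`.
#' @param n_boot Bootstrap replicates (at least 100).
#' @param seed Seed for the bootstrap.
#' @return A one-row `mr_estimate` tibble (method `"wme"`).
#' @export
mr_weighted_median <- function(iv, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) abort("n_boot must be at least 100.")
  check_min_ivs(iv, "wme")
  ratios <- mr_wald_ratios(iv)
  check_min_ivs(ratios, "wme")
  est <- weighted_median_point(ratios$ratio, 1 / ratios$ratio_se^2)

  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    be <- rnorm(nrow(iv), iv$beta_exp, iv$se_exp)
    bo <- rnorm(nrow(iv), iv$beta_out, iv$se_out)
    keep <- be != 0
    r <- bo[keep] / be[keep]
    w <- (be[keep] / iv$se_out[keep])^2
    weighted_median_point(r, w)
  }, numeric(1))
  se <- sd(boot)
  new_mr_estimate("wme", est, se, nrow(ratios),
                  extra = list(bootstrap_seed = seed))
}

# Weighted median by linear interpolation of cumulative normalized weights.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  csum <- cumsum(w) - w / 2
  if (csum[1] >= 0.5) return(x[1])
  if (csum[length(x)] <= 0.5) return(x[length(x)])
  stats::approx(csum, x, xout = 0.5, ties = "ordered")$y
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects *with*
#' an intercept, weights \eqn{1/SE_{out}^2}, after orienting every exposure
#' effect to be non-negative. The slope estimates the causal effect under
#' the InSIDE assumption; the intercept estimates the average directional
#' pleiotropy and carries its own test. Standard errors use multiplicative
#' residual overdispersion floored at 1, and inference (P-values, the 95%
#' interval) is on the t-distribution with `n_iv - 2` degrees of freedom —
#' the overdispersion is estimated from few instruments, and the normal
#' approximation visibly undercovers at typical instrument counts.
#'
#' @param iv An `instrument_set`.
#' @return A one-row `mr_estimate` tibble (method `"egger"`) with
#'   `intercept` and `intercept_p` filled, plus `intercept_se` and `df`.
#' @export
mr_egger <- function(iv) {
  check_min_ivs(iv, "egger")
  flip <- sign(iv$beta_exp)
  flip[flip == 0] <- 1
  be <- iv$beta_exp * flip
  bo <- iv$beta_out * flip
  w <- 1 / iv$se_out^2
  fit <- lm(bo ~ be, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  df <- nrow(iv) - 2L
  est <- coef(fit)[["be"]]
  se <- sm$coefficients["be", "Std. Error"] / sm$sigma * scale
  icpt <- coef(fit)[["(Intercept)"]]
  icpt_se <- sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma * scale
  out <- new_mr_estimate("egger", est, se, nrow(iv),
                         intercept = icpt,
                         intercept_p = 2 * stats::pt(-abs(icpt / icpt_se), df),
                         extra = list(intercept_se = icpt_se, df = df))
  q <- stats::qt(0.975, df)
  out$pvalue <- 2 * stats::pt(-abs(est / se), df)
  out$ci_low <- exp(est - q * se)
  out$ci_high <- exp(est + q * se)
  out
}

#' Heterogeneity-penalized MR estimate
#'
#' Augments the instrument-level model with one direct-effect
#' (heterogeneity) parameter per instrument,
#' \eqn{\beta_{out,j} = \theta\,\beta_{exp,j} + \alpha_j + \epsilon_j}, and
#' shrinks the \eqn{\alpha_j} with an L1 penalty chosen by cross-validation
#' while the common slope \eqn{\theta} stays unpenalized
#' (`penalty.factor = 0`). Instruments with genuine horizontal pleiotropy
#' absorb their own \eqn{\alpha_j} instead of biasing \eqn{\theta}; under no
#' pleiotropy all \eqn{\alpha_j} shrink to zero and the estimate collapses
#' to IVW. Confidence intervals come from a parametric bootstrap at the
#' selected penalty.
#'
#' @param iv An `instrument_set`.
#' @param seed Seed for cross-validation folds and the bootstrap.
#' @param n_boot Bootstrap replicates for the SE (default 200).
#' @return A one-row `mr_estimate` tibble (method `"het_penalized"`) with
#'   `n_het_nonzero` counting instruments whose heterogeneity term stayed
#'   nonzero.
#' @export
mr_het_penalized <- function(iv, seed = 1L, n_boot = 200L) {
  check_min_ivs(iv, "het_penalized")
  n <- nrow(iv)
  w <- 1 / iv$se_out^2
  Xd <- cbind(exposure = iv$beta_exp, diag(n))
  pf <- c(0, rep(1, n))
  set.seed(seed)
  foldid <- make_folds(n, min(5L, n), seed)
  cvfit <- glmnet::cv.glmnet(Xd, iv$beta_out, weights = w, alpha = 1,
                             penalty.factor = pf, intercept = FALSE,
                             standardize = FALSE, foldid = foldid,
                             grouped = FALSE)
  lam <- cvfit$lambda.min
  cf <- as.numeric(coef(cvfit, s = lam))[-1L]
  est <- cf[1L]
  alphas <- cf[-1L]

  boot <- vapply(seq_len(n_boot), function(b) {
    be <- rnorm(n, iv$beta_exp, iv$se_exp)
    bo <- rnorm(n, iv$beta_out, iv$se_out)
    fit_b <- glmnet::glmnet(cbind(be, diag(n)), bo, weights = w, alpha = 1,
                            penalty.factor = pf, intercept = FALSE,
                            standardize = FALSE, lambda = lam)
    as.numeric(coef(fit_b))[2L]
  }, numeric(1))
  se <- sd(boot)
  new_mr_estimate("het_penalized", est, se, n,
                  extra = list(n_het_nonzero = sum(alphas != 0),
                               lambda = lam, bootstrap_seed = seed))
}

#' Run a set of MR estimators on one instrument set
#'
#' @param iv An `instrument_set`.
#' @param methods Subset of `c("ivw", "wme", "egger", "het_penalized")`.
#' @param n_boot,seed Passed to the bootstrap-based estimators.
#' @return An `mr_estimate` tibble, one row per method.
#' @export
mr_all_methods <- function(iv, methods = c("ivw", "wme", "egger",
                                           "het_penalized"),
                           n_boot = 1000L, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  # lapply, not purrr::map: refusal conditions must propagate unwrapped
  rows <- lapply(methods, function(m) {
    switch(m,
           ivw = mr_ivw(iv),
           wme = mr_weighted_median(iv, n_boot = n_boot, seed = seed),
           egger = mr_egger(iv),
           het_penalized = mr_het_penalized(iv, seed = seed,
                                            n_boot = min(n_boot, 200L)))
  })
  out <- list_rbind(rows)
  class(out) <- c("mr_estimate", class(out))
  out
}
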