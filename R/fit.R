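#' Fit a Mendelian randomization estimator to summarized data
#'
#' The single entry point for causal-effect estimation. Given per-variant
#' exposure and outcome associations, estimates the causal effect of the risk
#' factor on the outcome under the instrumental-variable decomposition
#' beta_Yj = alpha_j + theta * beta_Xj, where alpha_j is the direct
#' (pleiotropic) effect of variant j on the outcome.
#'
#' Methods:
#' \describe{
#'   \item{`ivw`}{Inverse-variance weighted estimate: the weighted mean of the
#'     per-variant ratio estimates with weights `se_y^-2 * beta_x^2`,
#'     equivalently the no-intercept weighted regression of `beta_y` on
#'     `beta_x` with weights `se_y^-2`. Consistent when every variant is a
#'     valid instrument, or when pleiotropy is balanced and the InSIDE
#'     assumption (instrument strength independent of direct effect) holds.}
#'   \item{`egger`}{MR-Egger: the same weighted regression with a free
#'     intercept. The intercept estimates the average directional pleiotropic
#'     effect (intercept test); the slope estimates the causal effect under
#'     InSIDE (causal test). Requires the variants to be oriented first (see
#'     [orient_variants()]); a warning is raised if any `beta_x < 0`.}
#'   \item{`simple_median` / `weighted_median`}{Median of the per-variant
#'     ratio estimates (equal weights, or inverse-variance weights from the
#'     first-order delta-method variance `se_y^2 / beta_x^2`), consistent when
#'     at least half the (weight of the) variants are valid instruments.
#'     Standard errors by parametric bootstrap.}
#'   \item{`robust`}{Robust variant of IVW: no-intercept weighted regression
#'     fitted by MM-type iteratively reweighted least squares with Tukey's
#'     bisquare objective, bounding the contribution of any single variant.}
#' }
#'
#' When the dataset carries a correlation matrix, `ivw` and `egger` use
#' generalized weighted least squares with weighting matrix
#' `Omega[j1, j2] = se_y[j1] * se_y[j2] * rho[j1, j2]` (see [build_omega()]);
#' median and robust methods require uncorrelated variants.
#'
#' Variance models: under the fixed-effect model the residual standard error
#' sigma is fixed at 1, matching a fixed-effect meta-analysis of the ratio
#' estimates. Under the multiplicative random-effects model sigma is estimated
#' from the regression residuals; because underdispersion (sigma < 1) has no
#' biological mechanism for uncorrelated variants, coefficient standard errors
#' are divided by `min(sigma_hat, 1)` by default, so the random-effects model
#' is never more precise than the fixed-effect model. The untruncated
#' `sigma_hat` is always reported so underdispersion can be inspected.
#' A random-effects analysis is the default, and is always recommended for
#' MR-Egger since pleiotropy manifests as overdispersion.
#'
#' @param data an [mr_dataset()].
#' @param method estimator to fit.
#' @param variance_model `"random_multiplicative"` (default) or `"fixed"`.
#' @param truncate_sigma_at_one divide standard errors by `min(sigma_hat, 1)`
#'   under the random-effects model (default `TRUE`).
#' @param df_rule `"t_residual_df"` (default): t inference with residual
#'   degrees of freedom (J-1 for IVW, J-2 for MR-Egger); `"normal"` for
#'   normal-quantile inference.
#' @param ci_level confidence level, in (0, 1).
#' @param boot bootstrap settings for the median methods, from
#'   [mr_boot_config()].
#' @param tuning tuning constant for the bisquare objective of the robust
#'   method (default 4.685, 95% Gaussian efficiency).
#' @param second_order_weights use the second-order delta-method variance
#'   `se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4` for the weighted-median
#'   weights (default `FALSE`).
#'
#' @return An object of class `mr_fit` (additionally `mr_egger` for
#'   `method = "egger"`) with components `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `p_value`, `sigma_hat` (untruncated), `n_variants`, and for
#'   MR-Egger an `intercept` record, the instrument-strength `i2_gx` and the
#'   weighted mean exposure association `beta_x_bar`. Supports `print()`,
#'   `summary()`, `coef()`, `confint()`, `plot()` and `residuals()`.
#' @examples
#' sim <- simulate_mr(mr_scenario_config("no_pleiotropy", theta = 0.3, seed = 7))
#' mr_fit(sim$data, "ivw")
#' summary(mr_fit(orient_variants(sim$data), "egger"))
#' @references Burgess S, Thompson SG. Interpreting findings from Mendelian
#'   randomization using the MR-Egger method. Eur J Epidemiol 2017.
#' @export
mr_fit <- function(data,
                   method = c("ivw", "egger", "simple_median",
                              "weighted_median", "robust"),
                   variance_model = c("random_multiplicative", "fixed"),
                   truncate_sigma_at_one = TRUE,
                   df_rule = c("t_residual_df", "normal"),
                   ci_level = 0.95,
                   boot = mr_boot_config(),
                   tuning = 4.685,
                   second_order_weights = FALSE) {
  stopifnot(inherits(data, "mr_dataset"))
  method <- match.arg(method)
  variance_model <- match.arg(variance_model)
  df_rule <- match.arg(df_rule)
  if (!(is.numeric(ci_level) && length(ci_level) == 1L &&
        ci_level > 0 && ci_level < 1)) {
    stop("ci_level must be a single number in (0, 1)", call. = FALSE)
  }
  cfg <- list(variance_model = variance_model,
              truncate_sigma_at_one = truncate_sigma_at_one,
              df_rule = df_rule, ci_level = ci_level)

  correlated <- !is.null(attr(data, "correlation"))
  fit <- switch(method,
    ivw = if (correlated) .fit_ivw_correlated(data, cfg) else .fit_ivw(data, cfg),
    egger = if (correlated) .fit_egger_correlated(data, cfg) else .fit_egger(data, cfg),
    simple_median = .fit_median(data, cfg, weighting = "simple", boot = boot,
                                second_order = second_order_weights),
    weighted_median = .fit_median(data, cfg, weighting = "weighted", boot = boot,
                                  second_order = second_order_weights),
    robust = .fit_robust(data, cfg, tuning = tuning))
  fit$outcome_scale <- attr(data, "outcome_scale")
  fit$data <- data
  fit
}

#' Bootstrap configuration for the median estimators
#'
#' @param n_iterations number of parametric-bootstrap iterations (>= 100;
#'   default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return A list with class `mr_boot_config`.
#' @export
mr_boot_config <- function(n_iterations = 10000L, seed = 1L) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 100L) {
    stop("n_iterations must be at least 100", call. = FALSE)
  }
  structure(list(n_iterations = n_iterations, seed = as.integer(seed)),
            class = "mr_boot_config")
}

## ---- shared inference machinery ----------------------------------------

# Turns an unscaled (sigma = 1) standard error plus the estimated residual
# scale into the reported SE/CI/p under the requested variance model.
# Under the random-effects model with truncation the SE multiplier is
# max(sigma_hat, 1): equivalently, the regression SE sigma_hat * se_unit is
# divided by min(sigma_hat, 1).
.mr_inference <- function(estimate, se_unit, sigma_hat, resid_df, cfg) {
  if (cfg$variance_model == "fixed") {
    mult <- 1
  } else if (!is.finite(sigma_hat)) {
    mult <- 1   # no residual degrees of freedom: fall back to sigma = 1
  } else {
    mult <- if (cfg$truncate_sigma_at_one) max(sigma_hat, 1) else sigma_hat
  }
  se <- se_unit * mult
  use_t <- cfg$df_rule == "t_residual_df" && resid_df >= 1L
  alpha <- 1 - cfg$ci_level
  crit <- if (use_t) stats::qt(1 - alpha / 2, df = resid_df) else
    stats::qnorm(1 - alpha / 2)
  z <- estimate / se
  p <- if (use_t) 2 * stats::pt(-abs(z), df = resid_df) else
    2 * stats::pnorm(-abs(z))
  list(estimate = estimate, se = se,
       ci_lower = estimate - crit * se, ci_upper = estimate + crit * se,
       p_value = p, df = if (use_t) resid_df else NA_integer_)
}

.new_mr_fit <- function(method, inf, sigma_hat, J, cfg, extra = list(),
                        subclass = NULL) {
  out <- c(list(method = method,
                estimate = inf$estimate, se = inf$se,
                ci_lower = inf$ci_lower, ci_upper = inf$ci_upper,
                ci_level = cfg$ci_level, p_value = inf$p_value, df = inf$df,
                variance_model = cfg$variance_model,
                sigma_hat = sigma_hat, n_variants = J),
           extra)
  class(out) <- c(subclass, "mr_fit")
  out
}

## ---- per-variant ratio estimates ---------------------------------------

#' Per-variant ratio (Wald) estimates
#'
#' The causal estimate from a single valid instrument is the ratio
#' `beta_y / beta_x`; its first-order delta-method standard error is
#' `se_y / |beta_x|` (optionally augmented with the second-order term
#' `beta_y^2 se_x^2 / beta_x^4`).
#'
#' @param data an [mr_dataset()].
#' @param second_order add the second-order delta-method variance term.
#' @param ci_level confidence level for the per-variant normal CIs.
#' @return A data.frame with one row per variant: `variant_id`, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `p_value`.
#' @examples
#' d <- mr_dataset(data.frame(variant_id = "rs1", beta_x = 0.25, se_x = 0.02,
#'                            beta_y = 0.5, se_y = 0.1))
#' mr_ratio(d)   # estimate 2, se 0.4
#' @export
mr_ratio <- function(data, second_order = FALSE, ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"))
  df <- as.data.frame(data)
  zero <- df$beta_x == 0
  if (any(zero)) {
    stop("ratio estimate undefined (beta_x = 0) for variant(s): ",
         paste(df$variant_id[zero], collapse = ", "), call. = FALSE)
  }
  est <- df$beta_y / df$beta_x
  v <- df$se_y^2 / df$beta_x^2
  if (second_order) v <- v + df$beta_y^2 * df$se_x^2 / df$beta_x^4
  se <- sqrt(v)
  crit <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(variant_id = df$variant_id, estimate = est, se = se,
             ci_lower = est - crit * se, ci_upper = est + crit * se,
             p_value = 2 * stats::pnorm(-abs(est / se)),
             stringsAsFactors = FALSE)
}

## ---- IVW ----------------------------------------------------------------

# Closed-form inverse-variance weighted pooled estimate: the weighted mean of
# the ratio estimates with first-order delta-method weights, identical to the
# no-intercept weighted regression of beta_y on beta_x with weights se_y^-2.
.fit_ivw <- function(data, cfg) {
  df <- as.data.frame(data)
  J <- nrow(df)
  w <- df$se_y^-2
  sxx <- sum(w * df$beta_x^2)
  if (sxx == 0) {
    stop("all beta_x are zero; the IVW estimate is undefined", call. = FALSE)
  }
  theta <- sum(w * df$beta_x * df$beta_y) / sxx
  se_unit <- 1 / sqrt(sxx)
  resid <- df$beta_y - theta * df$beta_x
  sigma_hat <- if (J > 1L) sqrt(sum(w * resid^2) / (J - 1L)) else NA_real_
  inf <- .mr_inference(theta, se_unit, sigma_hat, J - 1L, cfg)
  .new_mr_fit("ivw", inf, sigma_hat, J, cfg,
              extra = list(weights = w, fitted = theta * df$beta_x,
                           residuals = resid))
}

## ---- MR-Egger -----------------------------------------------------------

.fit_egger <- function(data, cfg) {
  df <- as.data.frame(data)
  J <- nrow(df)
  if (J < 3L) {
    stop("MR-Egger requires at least 3 variants (two parameters plus one ",
         "residual degree of freedom); got ", J, call. = FALSE)
  }
  if (any(df$beta_x < 0)) {
    warning("some beta_x < 0: the MR-Egger intercept depends on variant ",
            "orientation; consider orient_variants() first", call. = FALSE)
  }
  w <- df$se_y^-2
  xbar <- sum(w * df$beta_x) / sum(w)
  sxx <- sum(w * (df$beta_x - xbar)^2)
  if (sxx <= 0 || isTRUE(all.equal(min(df$beta_x), max(df$beta_x)))) {
    stop("all beta_x are (numerically) equal: the MR-Egger intercept and ",
         "slope are not identified and the instrument-strength I-squared ",
         "is zero", call. = FALSE)
  }
  ybar <- sum(w * df$beta_y) / sum(w)
  slope <- sum(w * (df$beta_x - xbar) * (df$beta_y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * df$beta_x
  resid <- df$beta_y - fitted
  sigma_hat <- sqrt(sum(w * resid^2) / (J - 2L))
  se_slope_unit <- 1 / sqrt(sxx)
  se_int_unit <- sqrt(1 / sum(w) + xbar^2 / sxx)

  inf_slope <- .mr_inference(slope, se_slope_unit, sigma_hat, J - 2L, cfg)
  inf_int <- .mr_inference(intercept, se_int_unit, sigma_hat, J - 2L, cfg)
  .new_mr_fit("egger", inf_slope, sigma_hat, J, cfg, subclass = "mr_egger",
              extra = list(
                intercept = inf_int,
                i2_gx = i_squared_gx(data),
                beta_x_bar = xbar,
                weights = w, fitted = fitted, residuals = resid))
}

## ---- median estimators --------------------------------------------------

# Interpolated weighted median: sort values (stable, ties broken by id),
# normalize weights, form cumulative midpoints s_j = cumsum(w)_j - w_j / 2,
# and linearly interpolate the value whose cumulative midpoint is 0.5.
# With equal weights this reproduces the usual sample median (mean of the
# two central order statistics for even J).
.weighted_median <- function(x, w, ids = as.character(seq_along(x))) {
  ord <- order(x, ids)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(x[1L])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  k <- max(which(s <= 0.5))
  x[k] + (x[k + 1L] - x[k]) * (0.5 - s[k]) / (s[k + 1L] - s[k])
}

.median_weights <- function(bx, by, sey, sex, weighting, second_order) {
  if (weighting == "simple") return(rep(1, length(bx)))
  v <- sey^2 / bx^2
  if (second_order) v <- v + by^2 * sex^2 / bx^4
  1 / v
}

.fit_median <- function(data, cfg, weighting, boot, second_order) {
  df <- as.data.frame(data)
  if (!is.null(attr(data, "correlation"))) {
    stop("median estimators assume uncorrelated variants; remove the ",
         "correlation matrix or use method = 'ivw'/'egger'", call. = FALSE)
  }
  zero <- df$beta_x == 0
  if (any(zero)) {
    warning("excluding variant(s) with undefined ratio estimate (beta_x = 0) ",
            "from the median analysis: ",
            paste(df$variant_id[zero], collapse = ", "), call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  J <- nrow(df)
  if (J < 3L) {
    stop("median estimators require at least 3 variants with defined ratio ",
         "estimates; got ", J, call. = FALSE)
  }
  if (!inherits(boot, "mr_boot_config")) boot <- do.call(mr_boot_config, boot)

  ratios <- df$beta_y / df$beta_x
  w <- .median_weights(df$beta_x, df$beta_y, df$se_y, df$se_x,
                       weighting, second_order)
  est <- .weighted_median(ratios, w, df$variant_id)

  # Parametric bootstrap: resample the association estimates from normal
  # distributions at their reported SEs, recompute the (weighted) median.
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(boot$seed)
  B <- boot$n_iterations
  bx_star <- matrix(stats::rnorm(B * J, mean = df$beta_x, sd = df$se_x),
                    nrow = J)
  by_star <- matrix(stats::rnorm(B * J, mean = df$beta_y, sd = df$se_y),
                    nrow = J)
  boot_est <- vapply(seq_len(B), function(b) {
    bx <- bx_star[, b]
    ok <- bx != 0
    .weighted_median(by_star[ok, b] / bx[ok],
                     .median_weights(bx[ok], by_star[ok, b], df$se_y[ok],
                                     df$se_x[ok], weighting, second_order),
                     df$variant_id[ok])
  }, numeric(1))
  se <- stats::sd(boot_est)

  crit <- stats::qnorm(1 - (1 - cfg$ci_level) / 2)
  inf <- list(estimate = est, se = se,
              ci_lower = est - crit * se, ci_upper = est + crit * se,
              p_value = 2 * stats::pnorm(-abs(est / se)), df = NA_integer_)
  method <- if (weighting == "simple") "simple_median" else "weighted_median"
  .new_mr_fit(method, inf, NA_real_, J, cfg,
              extra = list(ratio_estimates = stats::setNames(ratios, df$variant_id),
                           ratio_weights = w / sum(w),
                           boot = list(n_iterations = B, seed = boot$seed)))
}

## ---- robust IVW ---------------------------------------------------------

# MM-type robust fit of the no-intercept weighted regression, written on the
# weight-transformed scale ys = beta_y * sqrt(w), xs = beta_x * sqrt(w):
#   1. initial estimate: L1 (least absolute deviations) fit, which for a
#      one-parameter no-intercept regression is the weighted median of
#      ys/xs with weights |xs|;
#   2. fixed robust scale: MAD (about zero) of the initial residuals;
#   3. IRLS with Tukey bisquare weights at tuning constant c until the
#      estimate changes by < 1e-10 (max 200 iterations).
.fit_robust <- function(data, cfg, tuning, max_iter = 200L, tol = 1e-10) {
  df <- as.data.frame(data)
  if (!is.null(attr(data, "correlation"))) {
    stop("the robust estimator assumes uncorrelated variants", call. = FALSE)
  }
  J <- nrow(df)
  if (J < 3L) stop("robust IVW requires at least 3 variants", call. = FALSE)
  if (!(is.numeric(tuning) && tuning > 0)) {
    stop("tuning must be a positive number", call. = FALSE)
  }
  w <- df$se_y^-2
  xs <- df$beta_x * sqrt(w)
  ys <- df$beta_y * sqrt(w)

  theta <- .weighted_median(ys / xs, abs(xs), df$variant_id)   # LAD init
  s <- stats::mad(ys - theta * xs, center = 0)
  se_unit <- 1 / sqrt(sum(xs^2))

  if (s < 1e-12) {
    # (near-)exact fit: no downweighting possible, robust SE degenerates;
    # report the fixed-model IVW standard error
    inf <- .mr_inference(theta, se_unit, 1, J - 1L,
                         utils::modifyList(cfg, list(variance_model = "fixed")))
    return(.new_mr_fit("robust_ivw", inf, 0, J, cfg,
                       extra = list(tuning = tuning, iterations = 0L,
                                    converged = TRUE, scale = s,
                                    robust_weights = rep(1, J))))
  }

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    u <- (ys - theta * xs) / (s * tuning)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    denom <- sum(rw * xs^2)
    if (denom == 0) {
      stop("robust IVW failed: all variants downweighted to zero at ",
           "estimate ", format(theta), call. = FALSE)
    }
    theta_new <- sum(rw * xs * ys) / denom
    if (abs(theta_new - theta) < tol) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop("robust IVW did not converge after ", max_iter,
         " iterations; last estimate ", format(theta), call. = FALSE)
  }

  # asymptotic sandwich variance for an M-estimator with fixed scale
  r <- ys - theta * xs
  u <- r / s
  psi <- ifelse(abs(u) < tuning, u * (1 - (u / tuning)^2)^2, 0)
  dpsi <- ifelse(abs(u) < tuning,
                 (1 - (u / tuning)^2) * (1 - 5 * (u / tuning)^2), 0)
  kappa <- J * sum(psi^2) / (sum(dpsi)^2)
  se <- sqrt(s^2 * kappa / sum(xs^2)) * sqrt(J / (J - 1L))
  crit <- if (cfg$df_rule == "t_residual_df") stats::qt(1 - (1 - cfg$ci_level) / 2, J - 1L)
          else stats::qnorm(1 - (1 - cfg$ci_level) / 2)
  pfun <- if (cfg$df_rule == "t_residual_df") {
    function(z) 2 * stats::pt(-abs(z), J - 1L)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  inf <- list(estimate = theta, se = se, ci_lower = theta - crit * se,
              ci_upper = theta + crit * se, p_value = pfun(theta / se),
              df = if (cfg$df_rule == "t_residual_df") J - 1L else NA_integer_)
  rw <- ifelse(abs(u) < tuning, (1 - (u / tuning)^2)^2, 0)
  .new_mr_fit("robust_ivw", inf, NA_real_, J, cfg,
              extra = list(tuning = tuning, iterations = iter,
                           converged = converged, scale = s,
                           robust_weights = rw))
}

## ---- RNG state helpers --------------------------------------------------

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
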