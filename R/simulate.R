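#' Scenario configuration for the summary-statistics simulator
#'
#' Defines a data-generating scenario under the decomposition
#' `beta_Yj = alpha_j + theta * beta_Xj`: a true causal effect `theta` plus a
#' per-variant direct (pleiotropic) effect `alpha_j`. Scenarios differ in how
#' the `alpha_j` arise:
#' \describe{
#'   \item{`no_pleiotropy`}{`alpha_j = 0`: all variants are valid instruments.}
#'   \item{`balanced_direct`}{`alpha_j ~ N(0, alpha_sd^2)`, independent of
#'     instrument strength (InSIDE holds; zero average pleiotropy).}
#'   \item{`directional_direct`}{`alpha_j ~ N(alpha_mean, alpha_sd^2)` with
#'     `alpha_mean != 0`, still independent of instrument strength (InSIDE
#'     holds; directional pleiotropy — the IVW estimate is biased, the
#'     MR-Egger intercept recovers `alpha_mean`).}
#'   \item{`via_single_confounder`}{every variant's pleiotropic effect acts
#'     through one shared confounder: variant j affects the confounder by
#'     `gamma_j`, which contributes `gamma_j` to the instrument strength and
#'     `gamma_j` to the direct effect, so `alpha_j` and `beta_Xj` are
#'     positively correlated (InSIDE violated).}
#'   \item{`via_multiple_confounders`}{each variant acts through its own
#'     confounder with variant-specific effect multipliers (drawn
#'     `U(0.5, 1.5)`) on the risk factor and the outcome; instrument
#'     strengths and direct effects still rise together with `gamma_j`, so
#'     InSIDE is still violated.}
#' }
#'
#' Defaults place the analysis at the scale of a typical multi-variant MR
#' study of a continuous risk factor: J = 25 variants with exposure
#' associations `U(0.05, 0.15)` (in risk-factor SD units per allele) measured
#' with standard error 0.005, outcome associations measured with standard
#' error 0.01, pleiotropic effects of a magnitude comparable to the indirect
#' effects they contaminate, and confounder effects `N(0.05, 0.02^2)`.
#'
#' @param scenario one of the five scenario names above.
#' @param J number of genetic variants.
#' @param theta true causal effect of the risk factor on the outcome.
#' @param alpha_mean,alpha_sd mean and SD of the direct effects (used by the
#'   `*_direct` scenarios; `alpha_mean` defaults to 0.01 for
#'   `directional_direct` and 0 otherwise).
#' @param beta_x_min,beta_x_max range of the uniform distribution of true
#'   exposure associations.
#' @param se_x,se_y sampling standard errors of the exposure and outcome
#'   association estimates (treated as known).
#' @param confounder_mean,confounder_sd distribution of the per-variant
#'   confounder effects `gamma_j` (the `via_*` scenarios).
#' @param seed RNG seed; the whole draw is a deterministic function of the
#'   configuration.
#' @return A list of class `mr_scenario_config`.
#' @export
mr_scenario_config <- function(scenario = c("no_pleiotropy", "balanced_direct",
                                            "directional_direct",
                                            "via_single_confounder",
                                            "via_multiple_confounders"),
                               J = 25L, theta = 0,
                               alpha_mean = NULL, alpha_sd = 0.004,
                               beta_x_min = 0.05, beta_x_max = 0.15,
                               se_x = 0.005, se_y = 0.01,
                               confounder_mean = 0.05, confounder_sd = 0.02,
                               seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(alpha_mean)) {
    alpha_mean <- if (scenario == "directional_direct") 0.01 else 0
  }
  J <- as.integer(J)
  stopifnot(J >= 1L, se_x > 0, se_y > 0, beta_x_max >= beta_x_min,
            alpha_sd >= 0, confounder_sd >= 0)
  structure(list(scenario = scenario, J = J, theta = theta,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_x_min = beta_x_min, beta_x_max = beta_x_max,
                 se_x = se_x, se_y = se_y,
                 confounder_mean = confounder_mean,
                 confounder_sd = confounder_sd,
                 seed = as.integer(seed)),
            class = "mr_scenario_config")
}

#' Simulate a summarized MR dataset
#'
#' Draws true per-variant parameters according to the scenario, sets the true
#' outcome associations by `beta_Yj = alpha_j + theta * beta_Xj`, and returns
#' observed association estimates equal to the truth plus independent normal
#' sampling noise at the configured standard errors (which are reported as
#' the known SEs). Alongside the dataset it returns the generating truth,
#' including the inverse-variance weighted covariance between the direct
#' effects and the instrument strengths — the quantity whose vanishing makes
#' the MR-Egger slope consistent for a fixed set of variants (it is
#' systematically positive in the confounder scenarios).
#'
#' @param cfg an [mr_scenario_config()].
#' @return A list of class `mr_simulation` with elements `data` (an
#'   [mr_dataset()]) and `truth` (list: `true_theta`, `true_alphas`,
#'   `true_beta_x`, `inside_weighted_covariance`).
#' @examples
#' sim <- simulate_mr(mr_scenario_config("directional_direct", seed = 42))
#' cor(sim$truth$true_alphas, sim$truth$true_beta_x)   # ~0: InSIDE holds
#' @export
simulate_mr <- function(cfg) {
  stopifnot(inherits(cfg, "mr_scenario_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed)

  J <- cfg$J
  bx0 <- stats::runif(J, cfg$beta_x_min, cfg$beta_x_max)

  if (cfg$scenario %in% c("via_single_confounder", "via_multiple_confounders")) {
    gamma <- stats::rnorm(J, cfg$confounder_mean, cfg$confounder_sd)
    if (cfg$scenario == "via_single_confounder") {
      # one confounder: its effects on risk factor and outcome are common
      # to all variants (taken as 1 in the units of gamma)
      ux <- rep(1, J); uy <- rep(1, J)
    } else {
      # one confounder per variant, each with its own effect sizes
      ux <- stats::runif(J, 0.5, 1.5)
      uy <- stats::runif(J, 0.5, 1.5)
    }
    bx_true <- bx0 + gamma * ux
    alpha <- gamma * uy
  } else {
    bx_true <- bx0
    alpha <- switch(cfg$scenario,
                    no_pleiotropy = rep(0, J),
                    balanced_direct = stats::rnorm(J, 0, cfg$alpha_sd),
                    directional_direct = stats::rnorm(J, cfg$alpha_mean,
                                                      cfg$alpha_sd))
  }

  if (cfg$beta_x_min == cfg$beta_x_max &&
      cfg$scenario %in% c("balanced_direct", "directional_direct",
                          "no_pleiotropy")) {
    warning("degenerate beta_x distribution: all true instrument strengths ",
            "are equal, so the MR-Egger parameters are not identified",
            call. = FALSE)
  }

  by_true <- alpha + cfg$theta * bx_true
  bx_hat <- bx_true + stats::rnorm(J, 0, cfg$se_x)
  by_hat <- by_true + stats::rnorm(J, 0, cfg$se_y)

  data <- mr_dataset(data.frame(
    variant_id = sprintf("snp_%03d", seq_len(J)),
    beta_x = bx_hat, se_x = rep(cfg$se_x, J),
    beta_y = by_hat, se_y = rep(cfg$se_y, J),
    stringsAsFactors = FALSE))
  truth <- list(true_theta = cfg$theta,
                true_alphas = alpha,
                true_beta_x = bx_true,
                inside_weighted_covariance =
                  weighted_covariance(alpha, bx_true, rep(cfg$se_y^-2, J)))
  structure(list(data = data, truth = truth, config = cfg),
            class = "mr_simulation")
}

#' Weighted covariance between direct effects and instrument strengths
#'
#' With weights normalized to sum to one,
#' `sum_j w_j (a_j - a_bar_w)(b_j - b_bar_w)`. The MR-Egger slope is a
#' consistent estimate of the causal effect (for a fixed variant set, as
#' sample sizes grow) exactly when this covariance between the pleiotropic
#' effects and the exposure associations, taken with the inverse-variance
#' weights `se_y^-2`, is zero.
#'
#' @param alphas,beta_xs numeric vectors of equal length (>= 2).
#' @param weights positive weights.
#' @return The weighted covariance.
#' @examples
#' weighted_covariance(c(1, 2, 3), c(3, 2, 1), rep(1, 3))  # -2/3
#' @export
weighted_covariance <- function(alphas, beta_xs, weights) {
  if (length(alphas) != length(beta_xs) || length(alphas) != length(weights)) {
    stop("alphas, beta_xs and weights must have equal length", call. = FALSE)
  }
  if (length(alphas) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  w <- weights / sum(weights)
  sum(w * (alphas - sum(w * alphas)) * (beta_xs - sum(w * beta_xs)))
}

#' Monte-Carlo bias study across estimators
#'
#' Repeats [simulate_mr()] `n_replicates` times (replicate r uses seed
#' `cfg$seed + r`), orients each dataset, applies the requested estimators,
#' and summarizes estimate distributions. Median-method p-values use a
#' reduced parametric bootstrap per replicate (seed `cfg$seed + r + 500000`).
#'
#' @param cfg an [mr_scenario_config()]; its `seed` is the master seed.
#' @param n_replicates number of Monte-Carlo replicates (>= 100).
#' @param methods subset of `c("ivw", "egger", "simple_median",
#'   "weighted_median", "robust")`.
#' @param variance_model,df_rule passed to [mr_fit()].
#' @param boot_iterations bootstrap iterations per replicate for the median
#'   methods.
#' @return A data.frame of class `mr_bias_study` with one row per method:
#'   `method`, `mean_estimate`, `empirical_se`, `bias`
#'   (`mean_estimate - theta`), `rejection_rate_at_0.05`, and for `egger`
#'   an extra `egger_intercept` row summarizing the intercept estimates
#'   (its `bias` column is relative to zero).
#' @export
mr_bias_study <- function(cfg, n_replicates = 500L,
                          methods = c("ivw", "egger", "simple_median",
                                      "weighted_median"),
                          variance_model = "random_multiplicative",
                          df_rule = "t_residual_df",
                          boot_iterations = 200L) {
  stopifnot(inherits(cfg, "mr_scenario_config"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 100L) stop("n_replicates must be >= 100", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("ivw", "egger", "simple_median",
                                   "weighted_median", "robust"))

  draws <- array(NA_real_, dim = c(n_replicates, length(methods), 2),
                 dimnames = list(NULL, methods, c("estimate", "p")))
  icpt <- matrix(NA_real_, n_replicates, 2,
                 dimnames = list(NULL, c("estimate", "p")))
  for (r in seq_len(n_replicates)) {
    rcfg <- cfg
    rcfg$seed <- cfg$seed + r
    sim <- simulate_mr(rcfg)
    d <- orient_variants(sim$data)
    for (m in methods) {
      f <- mr_fit(d, method = if (m == "robust") "robust" else m,
                  variance_model = variance_model, df_rule = df_rule,
                  boot = mr_boot_config(boot_iterations,
                                        seed = cfg$seed + r + 500000L))
      draws[r, m, "estimate"] <- f$estimate
      draws[r, m, "p"] <- f$p_value
      if (m == "egger") {
        icpt[r, "estimate"] <- f$intercept$estimate
        icpt[r, "p"] <- f$intercept$p_value
      }
    }
  }

  summarize <- function(name, est, p, truth) {
    data.frame(method = name,
               mean_estimate = mean(est),
               empirical_se = stats::sd(est),
               bias = mean(est) - truth,
               rejection_rate_at_0.05 = mean(p < 0.05),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(methods, function(m)
    summarize(m, draws[, m, "estimate"], draws[, m, "p"], cfg$theta)))
  if ("egger" %in% methods) {
    out <- rbind(out, summarize("egger_intercept", icpt[, "estimate"],
                                icpt[, "p"], 0))
  }
  structure(out, class = c("mr_bias_study", "data.frame"),
            n_replicates = n_replicates, scenario = cfg$scenario,
            theta = cfg$theta, seed = cfg$seed)
}

#' @export
print.mr_bias_study <- function(x, digits = 4, ...) {
  cat("Monte-Carlo bias study: scenario ", attr(x, "scenario"),
      ", theta = ", attr(x, "theta"), ", ", attr(x, "n_replicates"),
      " replicates (master seed ", attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
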