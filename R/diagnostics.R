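#' Instrument-strength I-squared for MR-Egger
#'
#' Heterogeneity-style statistic measuring the spread of the exposure
#' associations relative to their precision. Values near 1 indicate that the
#' MR-Egger estimate does not suffer from weak-instrument (regression
#' dilution) bias; when all exposure associations are exactly equal neither
#' MR-Egger parameter is identified and the statistic is 0.
#'
#' `Q = sum_j w_j (beta_xj - beta_x_bar)^2` with `beta_x_bar` the
#' `w`-weighted mean, and the statistic is `max(0, (Q - (J - 1)) / Q)`
#' (0 when `Q = 0`). The default weights are `se_x^-2` (the instrument-
#' strength definition); `weight_rule = "se_y"` uses the outcome-association
#' weights `se_y^-2` that appear in the MR-Egger variance formula.
#'
#' @param data an [mr_dataset()] with at least 2 variants.
#' @param weight_rule `"se_x"` (default) or `"se_y"`.
#' @return A number in \[0, 1\].
#' @export
i_squared_gx <- function(data, weight_rule = c("se_x", "se_y")) {
  stopifnot(inherits(data, "mr_dataset"))
  weight_rule <- match.arg(weight_rule)
  df <- as.data.frame(data)
  J <- nrow(df)
  if (J < 2L) stop("I^2 requires at least 2 variants", call. = FALSE)
  w <- if (weight_rule == "se_x") df$se_x^-2 else df$se_y^-2
  xbar <- sum(w * df$beta_x) / sum(w)
  Q <- sum(w * (df$beta_x - xbar)^2)
  if (Q == 0) return(0)
  max(0, (Q - (J - 1)) / Q)
}

# weighted regression behind the ivw (no intercept) or egger (intercept) fit,
# as a base lm object so the standard influence machinery applies
.mr_lm <- function(data, method) {
  df <- as.data.frame(data)
  w <- df$se_y^-2
  if (method == "ivw") {
    stats::lm(beta_y ~ beta_x - 1, data = df, weights = w)
  } else {
    stats::lm(beta_y ~ beta_x, data = df, weights = w)
  }
}

#' Per-variant influence measures for an MR regression
#'
#' Computes weighted-least-squares leverages, Cook's distances and externally
#' studentized residuals for the regression underlying the IVW (no-intercept)
#' or MR-Egger (free-intercept) fit. Large Cook's distance flags a variant
#' with strong influence on the coefficients (a conventional reference point
#' is 4/J); a large |studentized residual| flags an outlying variant
#' (conventionally |t| > 3). The measures flag variants for inspection; no
#' automatic removal is performed.
#'
#' @param data an [mr_dataset()]; at least 2 variants for `ivw`, 3 for
#'   `egger`.
#' @param method `"ivw"` or `"egger"`.
#' @return A data.frame keyed by `variant_id` with columns `leverage`,
#'   `cooks_distance`, `studentized_residual`. A variant with leverage 1
#'   yields infinite influence with a warning.
#' @export
mr_influence <- function(data, method = c("ivw", "egger")) {
  stopifnot(inherits(data, "mr_dataset"))
  method <- match.arg(method)
  df <- as.data.frame(data)
  J <- nrow(df)
  p <- if (method == "egger") 2L else 1L
  if (J < p + 1L) {
    stop("influence measures for '", method, "' require at least ", p + 1L,
         " variants", call. = FALSE)
  }
  fit <- .mr_lm(data, method)
  h <- stats::hatvalues(fit)
  exact <- h >= 1 - 1e-12
  if (any(exact)) {
    warning("variant(s) with leverage 1 (infinite influence): ",
            paste(df$variant_id[exact], collapse = ", "), call. = FALSE)
  }
  if (stats::sigma(fit) < 1e-14) {
    # exact fit: zero residuals carry zero influence, but the standard
    # formulas divide by the residual scale
    cd <- rep(0, J)
    rs <- rep(0, J)
  } else {
    cd <- stats::cooks.distance(fit)
    rs <- stats::rstudent(fit)
  }
  cd[exact] <- Inf
  rs[exact] <- NaN
  data.frame(variant_id = df$variant_id,
             leverage = unname(h),
             cooks_distance = unname(cd),
             studentized_residual = unname(rs),
             stringsAsFactors = FALSE)
}

#' Leave-one-out analysis
#'
#' Re-fits the chosen estimator J times, each time with one variant removed,
#' to show how much any single variant drives the causal estimate.
#'
#' @param data an [mr_dataset()]; at least 3 variants for `ivw`, 4 for
#'   `egger` (so every reduced fit is well defined).
#' @param method `"ivw"` or `"egger"`.
#' @param ... further arguments passed to [mr_fit()] (variance model, etc.).
#' @return A data.frame with one row per left-out variant: `variant_id`,
#'   `estimate` (the MR-Egger slope for `method = "egger"`), `se`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
mr_loo <- function(data, method = c("ivw", "egger"), ...) {
  stopifnot(inherits(data, "mr_dataset"))
  method <- match.arg(method)
  J <- nrow(data)
  min_j <- if (method == "egger") 4L else 3L
  if (J < min_j) {
    stop("leave-one-out with '", method, "' requires at least ", min_j,
         " variants", call. = FALSE)
  }
  rows <- lapply(seq_len(J), function(j) {
    f <- mr_fit(data[-j, ], method = method, ...)
    data.frame(variant_id = data$variant_id[j], estimate = f$estimate,
               se = f$se, ci_lower = f$ci_lower, ci_upper = f$ci_upper,
               p_value = f$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Heterogeneity Q statistic of an MR regression
#'
#' `Q = sum_j se_yj^-2 (beta_yj - fitted_j)^2` from the IVW or MR-Egger
#' regression, compared to a chi-square distribution with residual degrees of
#' freedom (J-1 or J-2). Under the fixed-effect model Q tests the assumption
#' of no heterogeneity between the per-variant causal estimates;
#' `Q / df` equals the squared residual scale `sigma_hat^2` of the
#' multiplicative random-effects fit.
#'
#' @param data an [mr_dataset()].
#' @param method `"ivw"` or `"egger"`.
#' @return A list with `q_statistic`, `df`, `p_value`.
#' @export
heterogeneity_q <- function(data, method = c("ivw", "egger")) {
  stopifnot(inherits(data, "mr_dataset"))
  method <- match.arg(method)
  df <- as.data.frame(data)
  J <- nrow(df)
  p <- if (method == "egger") 2L else 1L
  if (J < p + 1L) {
    stop("heterogeneity Q for '", method, "' requires at least ", p + 1L,
         " variants", call. = FALSE)
  }
  cfg <- list(variance_model = "random_multiplicative",
              truncate_sigma_at_one = TRUE, df_rule = "t_residual_df",
              ci_level = 0.95)
  fit <- if (method == "ivw") .fit_ivw(data, cfg) else .fit_egger(data, cfg)
  w <- df$se_y^-2
  Q <- sum(w * (df$beta_y - fit$fitted)^2)
  list(q_statistic = Q, df = J - p,
       p_value = stats::pchisq(Q, df = J - p, lower.tail = FALSE))
}

#' Full diagnostics report for an MR analysis
#'
#' Assembles per-variant influence measures and leave-one-out estimates with
#' the dataset-level heterogeneity Q, instrument-strength I-squared (both
#' weighting rules) and residual scale into a single report.
#'
#' @param data an [mr_dataset()]; at least 3 variants for `ivw`, 4 for
#'   `egger`.
#' @param method `"ivw"` or `"egger"`.
#' @param ... passed to [mr_fit()] for the leave-one-out refits.
#' @return An object of class `mr_diagnostics`: a list with `per_variant`
#'   (variant_id, leverage, cooks_distance, studentized_residual,
#'   loo_estimate, loo_se), `q_statistic`, `q_df`, `q_p_value`, `i2_gx`
#'   (se_x weights), `i2_gx_sey` (se_y weights), `sigma_hat` and
#'   `fitted_method`.
#' @export
mr_diagnostics <- function(data, method = c("ivw", "egger"), ...) {
  method <- match.arg(method)
  infl <- mr_influence(data, method)
  loo <- mr_loo(data, method, ...)
  per_variant <- merge(infl, stats::setNames(
    loo[, c("variant_id", "estimate", "se")],
    c("variant_id", "loo_estimate", "loo_se")), by = "variant_id", sort = FALSE)
  per_variant <- per_variant[match(data$variant_id, per_variant$variant_id), ]
  rownames(per_variant) <- NULL
  q <- heterogeneity_q(data, method)
  cfg <- list(variance_model = "random_multiplicative",
              truncate_sigma_at_one = TRUE, df_rule = "t_residual_df",
              ci_level = 0.95)
  fit <- if (method == "ivw") .fit_ivw(data, cfg) else .fit_egger(data, cfg)
  structure(list(per_variant = per_variant,
                 q_statistic = q$q_statistic, q_df = q$df,
                 q_p_value = q$p_value,
                 i2_gx = i_squared_gx(data, "se_x"),
                 i2_gx_sey = i_squared_gx(data, "se_y"),
                 sigma_hat = fit$sigma_hat,
                 fitted_method = method),
            class = "mr_diagnostics")
}

#' @export
print.mr_diagnostics <- function(x, digits = 4, ...) {
  J <- nrow(x$per_variant)
  cat("MR regression diagnostics (", x$fitted_method, ", ", J,
      " variants)\n", sep = "")
  cat(sprintf("  heterogeneity Q = %.*g on %d df (p = %.*g); sigma_hat = %.*g\n",
              digits, x$q_statistic, x$q_df, digits, x$q_p_value,
              digits, x$sigma_hat))
  cat(sprintf("  instrument-strength I^2: %.*g (se_x weights), %.*g (se_y weights)\n",
              digits, x$i2_gx, digits, x$i2_gx_sey))
  cat("  reference points: Cook's distance 4/J = ", format(4 / J, digits = 3),
      ", |studentized residual| > 3\n", sep = "")
  print(x$per_variant, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.mr_diagnostics <- function(x, ...) x$per_variant

#' Write a diagnostics report
#'
#' Writes the per-variant table as CSV and, optionally, the dataset-level
#' summary (Q, I-squared, residual scale) as JSON.
#'
#' @param x an [mr_diagnostics()] report.
#' @param path CSV output path for the per-variant table.
#' @param summary_path optional JSON output path for the summary.
#' @return `path`, invisibly.
#' @export
write_mr_diagnostics <- function(x, path, summary_path = NULL) {
  stopifnot(inherits(x, "mr_diagnostics"))
  utils::write.csv(x$per_variant, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(fitted_method = x$fitted_method, q_statistic = x$q_statistic,
           q_df = x$q_df, q_p_value = x$q_p_value, i2_gx = x$i2_gx,
           i2_gx_sey = x$i2_gx_sey, sigma_hat = x$sigma_hat),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
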