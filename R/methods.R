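#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  label <- switch(x$method,
                  ivw = "Inverse-variance weighted",
                  egger = "MR-Egger",
                  simple_median = "Simple median",
                  weighted_median = "Weighted median",
                  robust_ivw = "Robust IVW (Tukey bisquare)",
                  x$method)
  cat(label, " estimate (", x$n_variants, " variants, ",
      x$variance_model, " variance model)\n", sep = "")
  cat(sprintf("  causal estimate: %.*g  (se %.*g)\n",
              digits, x$estimate, digits, x$se))
  cat(sprintf("  %g%% CI: (%.*g, %.*g)   p = %.*g\n",
              100 * x$ci_level, digits, x$ci_lower, digits, x$ci_upper,
              digits, x$p_value))
  if (identical(x$outcome_scale, "log_odds")) {
    cat(sprintf("  odds ratio: %.*g  (%.*g, %.*g)\n",
                digits, exp(x$estimate), digits, exp(x$ci_lower),
                digits, exp(x$ci_upper)))
  }
  if (inherits(x, "mr_egger")) {
    cat(sprintf("  intercept (avg pleiotropic effect): %.*g  (se %.*g)  p = %.*g\n",
                digits, x$intercept$estimate, digits, x$intercept$se,
                digits, x$intercept$p_value))
  }
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  if (is.finite(fit$sigma_hat)) {
    cat(sprintf("  residual scale sigma_hat: %.*g%s\n", digits, fit$sigma_hat,
                if (fit$sigma_hat < 1 && fit$variance_model == "random_multiplicative")
                  " (underdispersion: SEs use sigma = 1)" else ""))
    if (fit$sigma_hat < 1 && !is.null(attr(fit$data, "correlation"))) {
      cat("  note: with correlated variants, sigma_hat < 1 can reflect\n",
          "  genuine underdispersion rather than chance\n", sep = "")
    }
  }
  if (inherits(fit, "mr_egger")) {
    cat(sprintf("  instrument-strength I^2 (exposure associations): %.*g\n",
                digits, fit$i2_gx))
    cat(sprintf("  weighted mean beta_x: %.*g\n", digits, fit$beta_x_bar))
  }
  if (!is.null(fit$data) && is.null(attr(fit$data, "correlation")) &&
      fit$method %in% c("ivw", "egger") &&
      fit$n_variants > (if (fit$method == "egger") 2L else 1L)) {
    q <- heterogeneity_q(fit$data, method = fit$method)
    cat(sprintf("  heterogeneity Q = %.*g on %d df, p = %.*g\n",
                digits, q$q_statistic, q$df, digits, q$p_value))
  }
  if (!is.null(fit$boot)) {
    cat("  SE from parametric bootstrap (", fit$boot$n_iterations,
        " iterations, seed ", fit$boot$seed, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (inherits(object, "mr_egger")) {
    c(intercept = object$intercept$estimate, slope = object$estimate)
  } else {
    stats::setNames(object$estimate, object$method)
  }
}

#' @export
confint.mr_fit <- function(object, parm, level, ...) {
  if (!missing(level) && !is.null(level) && level != object$ci_level) {
    stop("refit with ci_level = ", level, " to change the confidence level",
         call. = FALSE)
  }
  if (inherits(object, "mr_egger")) {
    m <- rbind(intercept = c(object$intercept$ci_lower, object$intercept$ci_upper),
               slope = c(object$ci_lower, object$ci_upper))
  } else {
    m <- matrix(c(object$ci_lower, object$ci_upper), nrow = 1,
                dimnames = list(object$method, NULL))
  }
  colnames(m) <- sprintf("%g %%", 100 * c((1 - object$ci_level) / 2,
                                          1 - (1 - object$ci_level) / 2))
  m
}

#' @export
residuals.mr_fit <- function(object, type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  if (is.null(object$residuals)) {
    stop("residuals are only defined for the regression-based methods ",
         "(ivw, egger, robust)", call. = FALSE)
  }
  r <- object$residuals
  if (type == "weighted") r <- r * sqrt(object$weights)
  stats::setNames(r, object$data$variant_id)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  row <- function(method, inf_est, inf_se, lo, hi, p) {
    data.frame(method = method, estimate = inf_est, se = inf_se,
               ci_lower = lo, ci_upper = hi, ci_level = x$ci_level,
               p_value = p, variance_model = x$variance_model,
               sigma_hat = x$sigma_hat, n_variants = x$n_variants,
               stringsAsFactors = FALSE)
  }
  out <- row(x$method, x$estimate, x$se, x$ci_lower, x$ci_upper, x$p_value)
  if (inherits(x, "mr_egger")) {
    out <- rbind(out,
                 row("egger_intercept", x$intercept$estimate, x$intercept$se,
                     x$intercept$ci_lower, x$intercept$ci_upper,
                     x$intercept$p_value))
  }
  out
}

#' Scatter plot of outcome against exposure associations
#'
#' Plots per-variant outcome associations against exposure associations with
#' 95% confidence bars, and overlays the fitted causal line: through the
#' origin for IVW/robust fits, with a free intercept for MR-Egger.
#'
#' @param x an `mr_fit` or `mr_dataset`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  plot(x$data, ...)
  if (inherits(x, "mr_egger")) {
    graphics::abline(a = x$intercept$estimate, b = x$estimate, lty = 2)
  } else if (x$method %in% c("ivw", "robust_ivw")) {
    graphics::abline(a = 0, b = x$estimate)
  } else {
    graphics::abline(a = 0, b = x$estimate, lty = 3)
  }
  invisible(x)
}

#' @rdname plot.mr_fit
#' @export
plot.mr_dataset <- function(x, ...) {
  df <- as.data.frame(x)
  args <- list(...)
  defaults <- list(x = df$beta_x, y = df$beta_y,
                   xlab = "Genetic association with risk factor",
                   ylab = "Genetic association with outcome",
                   xlim = range(0, df$beta_x - 1.96 * df$se_x,
                                df$beta_x + 1.96 * df$se_x),
                   ylim = range(0, df$beta_y - 1.96 * df$se_y,
                                df$beta_y + 1.96 * df$se_y),
                   pch = 19)
  do.call(graphics::plot, utils::modifyList(defaults, args))
  graphics::segments(df$beta_x - 1.96 * df$se_x, df$beta_y,
                     df$beta_x + 1.96 * df$se_x, df$beta_y, col = "grey60")
  graphics::segments(df$beta_x, df$beta_y - 1.96 * df$se_y,
                     df$beta_x, df$beta_y + 1.96 * df$se_y, col = "grey60")
  graphics::abline(h = 0, v = 0, col = "grey85")
  invisible(x)
}
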