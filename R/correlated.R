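#' Weighting matrix for correlated variants
#'
#' For variants in linkage disequilibrium the per-variant outcome
#' associations are correlated, and the simple inverse-variance weights are
#' replaced by the inverse of the weighting matrix
#' `Omega[j1, j2] = se_y[j1] * se_y[j2] * rho[j1, j2]`, where `rho` is the
#' between-variant correlation. With an identity correlation Omega is
#' diagonal with entries `se_y^2` and the generalized fits reduce to the
#' uncorrelated estimators.
#'
#' User-supplied LD matrices are often numerically indefinite; if the
#' correlation matrix has an eigenvalue below the tolerance it is
#' regularized by clipping eigenvalues at `1e-8`, rescaling back to unit
#' diagonal, with a warning.
#'
#' @param data an [mr_dataset()] carrying a correlation matrix.
#' @return A list of class `mr_omega` with elements `omega` (the J x J
#'   matrix), `correlation` (possibly regularized), and `regularized`
#'   (logical).
#' @export
build_omega <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  rho <- attr(data, "correlation")
  if (is.null(rho)) {
    stop("no correlation matrix in the dataset; use the uncorrelated ",
         "estimators (mr_fit with method 'ivw'/'egger') instead",
         call. = FALSE)
  }
  reg <- FALSE
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    rho <- ev$vectors %*% (vals * t(ev$vectors))
    rho <- stats::cov2cor(rho)
    rho <- (rho + t(rho)) / 2
    dimnames(rho) <- list(data$variant_id, data$variant_id)
    reg <- TRUE
    warning("correlation matrix is not positive definite; eigenvalues ",
            "clipped at 1e-8 and diagonal rescaled to 1", call. = FALSE)
  }
  sey <- as.data.frame(data)$se_y
  omega <- tcrossprod(sey) * rho
  structure(list(omega = omega, correlation = rho, regularized = reg),
            class = "mr_omega")
}

# Generalized weighted least squares of y on X (no weighting applied to X
# beforehand) under covariance Omega. Two algebraically identical routes:
#  - "cholesky": premultiply X and y by the inverse of the lower Cholesky
#    factor of Omega, then ordinary least squares (the default);
#  - "matrix": direct solve of the normal equations with Omega^-1.
# Returns coefficients, their sigma=1 standard errors, and the residual
# scale estimate sqrt(RSS_Omega / (n - p)).
.gls_fit <- function(X, y, omega, route = c("cholesky", "matrix")) {
  route <- match.arg(route)
  n <- length(y)
  p <- ncol(X)
  if (route == "cholesky") {
    R <- chol(omega)                        # omega = t(R) %*% R
    Xt <- backsolve(R, X, transpose = TRUE) # solve(t(R), X)
    yt <- backsolve(R, y, transpose = TRUE)
    xtx <- crossprod(Xt)
    coefs <- solve(xtx, crossprod(Xt, yt))
    resid_t <- yt - Xt %*% coefs
    rss <- sum(resid_t^2)
    cov_unit <- solve(xtx)
  } else {
    oi <- solve(omega)
    xtx <- crossprod(X, oi %*% X)
    coefs <- solve(xtx, crossprod(X, oi %*% y))
    resid <- y - X %*% coefs
    rss <- drop(crossprod(resid, oi %*% resid))
    cov_unit <- solve(xtx)
  }
  list(coefficients = drop(coefs),
       se_unit = sqrt(diag(cov_unit)),
       sigma_hat = if (n > p) sqrt(rss / (n - p)) else NA_real_,
       fitted = drop(X %*% coefs))
}

.fit_ivw_correlated <- function(data, cfg, route = "cholesky") {
  df <- as.data.frame(data)
  J <- nrow(df)
  om <- build_omega(data)
  X <- matrix(df$beta_x, ncol = 1)
  g <- .gls_fit(X, df$beta_y, om$omega, route)
  inf <- .mr_inference(g$coefficients, g$se_unit, g$sigma_hat, J - 1L, cfg)
  .new_mr_fit("ivw", inf, g$sigma_hat, J, cfg,
              extra = list(fitted = g$fitted,
                           residuals = df$beta_y - g$fitted,
                           omega = om, correlated = TRUE))
}

.fit_egger_correlated <- function(data, cfg, route = "cholesky") {
  df <- as.data.frame(data)
  J <- nrow(df)
  if (J < 3L) {
    stop("MR-Egger requires at least 3 variants; got ", J, call. = FALSE)
  }
  if (any(df$beta_x < 0)) {
    warning("some beta_x < 0: the MR-Egger intercept depends on variant ",
            "orientation; consider orient_variants() first", call. = FALSE)
  }
  if (isTRUE(all.equal(min(df$beta_x), max(df$beta_x)))) {
    stop("all beta_x are (numerically) equal: the MR-Egger intercept and ",
         "slope are not identified", call. = FALSE)
  }
  om <- build_omega(data)
  X <- cbind(1, df$beta_x)
  g <- .gls_fit(X, df$beta_y, om$omega, route)
  inf_slope <- .mr_inference(g$coefficients[2L], g$se_unit[2L], g$sigma_hat,
                             J - 2L, cfg)
  inf_int <- .mr_inference(g$coefficients[1L], g$se_unit[1L], g$sigma_hat,
                           J - 2L, cfg)
  w <- df$se_y^-2
  .new_mr_fit("egger", inf_slope, g$sigma_hat, J, cfg, subclass = "mr_egger",
              extra = list(intercept = inf_int,
                           i2_gx = i_squared_gx(data),
                           beta_x_bar = sum(w * df$beta_x) / sum(w),
                           fitted = g$fitted,
                           residuals = df$beta_y - g$fitted,
                           omega = om, correlated = TRUE))
}

#' Correlated-variant IVW and MR-Egger fits with an explicit route
#'
#' [mr_fit()] dispatches to the generalized (correlation-aware) fits
#' automatically when the dataset carries a correlation matrix; this helper
#' additionally exposes the computational route — the Cholesky
#' transform-then-OLS route (default) or the direct matrix-algebra solve —
#' which are algebraically identical and agree to numerical precision.
#'
#' @param data an [mr_dataset()] with a correlation matrix.
#' @param method `"ivw"` or `"egger"`.
#' @param route `"cholesky"` or `"matrix"`.
#' @param variance_model,truncate_sigma_at_one,df_rule,ci_level as in
#'   [mr_fit()].
#' @return An `mr_fit` object (see [mr_fit()]).
#' @export
mr_fit_correlated <- function(data, method = c("ivw", "egger"),
                              route = c("cholesky", "matrix"),
                              variance_model = c("random_multiplicative", "fixed"),
                              truncate_sigma_at_one = TRUE,
                              df_rule = c("t_residual_df", "normal"),
                              ci_level = 0.95) {
  method <- match.arg(method)
  route <- match.arg(route)
  cfg <- list(variance_model = match.arg(variance_model),
              truncate_sigma_at_one = truncate_sigma_at_one,
              df_rule = match.arg(df_rule), ci_level = ci_level)
  fit <- if (method == "ivw") .fit_ivw_correlated(data, cfg, route)
         else .fit_egger_correlated(data, cfg, route)
  fit$outcome_scale <- attr(data, "outcome_scale")
  fit$data <- data
  fit
}
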