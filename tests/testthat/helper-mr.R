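# Fixture builders: all test data are generated in code.

make_dataset <- function(bx, by,
                         sex = rep(0.01, length(bx)),
                         sey = rep(0.01, length(bx)),
                         ids = paste0("v", seq_along(bx)),
                         ...) {
  mr_dataset(data.frame(variant_id = ids, beta_x = bx, se_x = sex,
                        beta_y = by, se_y = sey, stringsAsFactors = FALSE),
             ...)
}

# generic random summarized dataset (not tied to the simulator module, so it
# can serve as an independent source of instances for property tests)
random_dataset <- function(J, seed, theta = 0.2, alpha_mean = 0,
                           alpha_sd = 0.005) {
  set.seed(seed)
  bx <- stats::runif(J, 0.05, 0.3)
  sex <- stats::runif(J, 0.005, 0.02)
  sey <- stats::runif(J, 0.01, 0.05)
  by <- stats::rnorm(J, alpha_mean, alpha_sd) + theta * bx +
    stats::rnorm(J, 0, sey)
  make_dataset(bx, by, sex, sey)
}

# reference IVW via the no-intercept weighted regression (base lm), the
# regression formulation that must agree with the closed-form pooled estimate
lm_ivw <- function(d) {
  df <- as.data.frame(d)
  fit <- stats::lm(beta_y ~ beta_x - 1, data = df, weights = df$se_y^-2)
  s <- summary(fit)
  list(estimate = unname(coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2] / s$sigma),
       sigma = s$sigma)
}

lm_egger <- function(d) {
  df <- as.data.frame(d)
  fit <- stats::lm(beta_y ~ beta_x, data = df, weights = df$se_y^-2)
  s <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_int_unit = unname(s$coefficients[1, 2] / s$sigma),
       se_slope_unit = unname(s$coefficients[2, 2] / s$sigma),
       sigma = s$sigma)
}

random_correlation <- function(J, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(J * J), J)
  stats::cov2cor(crossprod(A) + J * diag(J))
}
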