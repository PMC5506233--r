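test_that("ratio estimates follow the delta-method arithmetic", {
  d <- make_dataset(0.25, 0.5, sex = 0.02, sey = 0.1)
  r <- mr_ratio(d)
  expect_equal(r$estimate, 2.0)
  expect_equal(r$se, 0.4)

  # null outcome association gives a null ratio
  expect_equal(mr_ratio(make_dataset(0.3, 0, sey = 0.1))$estimate, 0)

  # negative denominator: estimate -1, se = 0.05 / 0.243
  r2 <- mr_ratio(make_dataset(-0.243, 0.243, sey = 0.05))
  expect_equal(r2$estimate, -1.0)
  expect_equal(r2$se, 0.05 / 0.243, tolerance = 1e-12)

  expect_error(mr_ratio(make_dataset(c(0, 0.1), c(0.2, 0.2))), "v1")

  # second-order option adds the beta_y^2 se_x^2 / beta_x^4 term
  r3 <- mr_ratio(make_dataset(0.25, 0.5, sex = 0.02, sey = 0.1),
                 second_order = TRUE)
  expect_equal(r3$se, sqrt(0.1^2 / 0.25^2 + 0.5^2 * 0.02^2 / 0.25^4))
})

test_that("IVW reduces to the single-variant ratio estimate", {
  d <- make_dataset(0.25, 0.5, sex = 0.02, sey = 0.1)
  f <- mr_fit(d, "ivw", variance_model = "fixed", df_rule = "normal")
  expect_equal(f$estimate, 2.0)
  expect_equal(f$se, 0.4)
})

test_that("IVW on exact-fit data reports untruncated sigma below one", {
  theta <- 0.5
  d <- make_dataset(c(1, 2), theta * c(1, 2))
  f <- mr_fit(d, "ivw", variance_model = "random_multiplicative")
  expect_equal(f$estimate, theta)
  expect_equal(f$sigma_hat, 0)            # untruncated value is reported
  fixed <- mr_fit(d, "ivw", variance_model = "fixed")
  expect_equal(f$se, fixed$se)            # truncation: sigma set to one
})

test_that("closed-form IVW equals the no-intercept weighted regression", {
  for (seed in 1:100) {
    d <- random_dataset(J = sample(3:30, 1), seed = seed,
                        theta = stats::runif(1, -1, 1),
                        alpha_mean = stats::runif(1, -0.01, 0.01))
    f <- mr_fit(d, "ivw", variance_model = "fixed")
    ref <- lm_ivw(d)
    expect_equal(f$estimate, ref$estimate, tolerance = 1e-10)
    expect_equal(f$se, ref$se_fixed, tolerance = 1e-10)
    expect_equal(mr_fit(d, "ivw")$sigma_hat, ref$sigma, tolerance = 1e-10)
  }
})

test_that("IVW matches a fixed-effect meta-analysis of the ratio estimates", {
  skip_if_not_installed("metafor")
  d <- random_dataset(12, seed = 404)
  r <- mr_ratio(d)
  meta <- metafor::rma.uni(yi = r$estimate, sei = r$se, method = "FE")
  f <- mr_fit(d, "ivw", variance_model = "fixed", df_rule = "normal")
  expect_equal(f$estimate, as.numeric(meta$beta), tolerance = 1e-10)
  expect_equal(f$se, meta$se, tolerance = 1e-10)
})

test_that("MR-Egger recovers exact linear structure", {
  # points on a line through the origin: intercept 0, slope equals IVW
  d <- make_dataset(c(0.1, 0.2, 0.3, 0.4), 0.7 * c(0.1, 0.2, 0.3, 0.4))
  f <- mr_fit(d, "egger")
  expect_equal(f$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(f$estimate, 0.7, tolerance = 1e-10)
  expect_equal(f$estimate, mr_fit(d, "ivw")$estimate, tolerance = 1e-10)

  # points on beta_y = a + b beta_x with a != 0: both recovered
  a <- 0.05; b <- -0.4
  d2 <- make_dataset(c(0.1, 0.15, 0.3, 0.42), a + b * c(0.1, 0.15, 0.3, 0.42))
  f2 <- mr_fit(d2, "egger")
  expect_equal(f2$intercept$estimate, a, tolerance = 1e-10)
  expect_equal(f2$estimate, b, tolerance = 1e-10)
})

test_that("MR-Egger matches the weighted regression with intercept", {
  d <- random_dataset(15, seed = 77, alpha_mean = 0.01)
  ref <- lm_egger(d)
  f <- mr_fit(d, "egger", variance_model = "random_multiplicative",
              truncate_sigma_at_one = FALSE)
  expect_equal(f$estimate, ref$slope, tolerance = 1e-10)
  expect_equal(f$intercept$estimate, ref$intercept, tolerance = 1e-10)
  expect_equal(f$sigma_hat, ref$sigma, tolerance = 1e-10)
  expect_equal(f$se, ref$se_slope_unit * ref$sigma, tolerance = 1e-10)
  expect_equal(f$intercept$se, ref$se_int_unit * ref$sigma, tolerance = 1e-10)

  # slope variance matches the weighted-variance formula
  df <- as.data.frame(d)
  w <- df$se_y^-2
  xbar <- sum(w * df$beta_x) / sum(w)
  expect_equal(f$se^2, ref$sigma^2 / sum(w * (df$beta_x - xbar)^2),
               tolerance = 1e-10)
  expect_equal(f$beta_x_bar, xbar)
})

test_that("MR-Egger refuses degenerate designs and warns on orientation", {
  expect_error(mr_fit(make_dataset(c(0.1, 0.2), c(0.1, 0.2)), "egger"),
               "at least 3")
  expect_error(mr_fit(make_dataset(rep(0.1, 4), c(0.1, 0.12, 0.09, 0.11)),
                      "egger"),
               "not identified")
  expect_warning(mr_fit(make_dataset(c(-0.1, 0.2, 0.3), c(0.1, 0.1, 0.2)),
                        "egger"),
                 "orientation")
})

test_that("median estimators follow the interpolated weighted definition", {
  # ratios (1, 2, 3) with equal weights: median 2
  d <- make_dataset(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3))
  f <- mr_fit(d, "simple_median", boot = mr_boot_config(200, 1))
  expect_equal(f$estimate, 2)

  # nearly all weight on one variant: weighted median is that ratio
  d2 <- make_dataset(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.3),
                     sey = c(1, 1e-4, 1))
  f2 <- mr_fit(d2, "weighted_median", boot = mr_boot_config(200, 1))
  expect_equal(f2$estimate, 2)

  # equal ratio variances: weighted and simple medians coincide
  d3 <- make_dataset(c(0.1, 0.1, 0.1, 0.1), c(0.1, 0.25, 0.3, 0.05))
  fs <- mr_fit(d3, "simple_median", boot = mr_boot_config(200, 1))
  fw <- mr_fit(d3, "weighted_median", boot = mr_boot_config(200, 1))
  expect_equal(fs$estimate, fw$estimate)
  # even J: mean of the two central order statistics
  expect_equal(fs$estimate, (1 + 2.5) / 2)

  # interpolated definition, computed longhand on an uneven-weight case:
  # ratios (1, 2, 4) with normalized weights (0.2, 0.3, 0.5);
  # cumulative midpoints s = (0.1, 0.35, 0.75); 0.5 falls between the 2nd
  # and 3rd order statistics: 2 + (4 - 2) * (0.5 - 0.35) / (0.75 - 0.35)
  d4 <- make_dataset(c(0.1, 0.1, 0.1), c(0.1, 0.2, 0.4),
                     sey = 0.1 * c(1 / sqrt(0.2), 1 / sqrt(0.3),
                                   1 / sqrt(0.5)))
  f4 <- mr_fit(d4, "weighted_median", boot = mr_boot_config(200, 1))
  expect_equal(f4$estimate, 2 + 2 * 0.15 / 0.4, tolerance = 1e-10)
})

test_that("median bootstrap is seeded and reproducible", {
  d <- random_dataset(10, seed = 21)
  f1 <- mr_fit(d, "weighted_median", boot = mr_boot_config(300, 42))
  f2 <- mr_fit(d, "weighted_median", boot = mr_boot_config(300, 42))
  expect_identical(f1$se, f2$se)
  f3 <- mr_fit(d, "weighted_median", boot = mr_boot_config(300, 43))
  expect_false(identical(f1$se, f3$se))
  expect_gt(f1$se, 0)
})

test_that("variants with zero beta_x are excluded from medians with a warning", {
  d <- make_dataset(c(0, 0.1, 0.1, 0.1), c(0.5, 0.1, 0.2, 0.3))
  expect_warning(f <- mr_fit(d, "simple_median", boot = mr_boot_config(200, 1)),
                 "v1")
  expect_equal(f$estimate, 2)
  expect_equal(f$n_variants, 3L)
})

test_that("robust IVW bounds the influence of a gross outlier", {
  # clean data: no downweighting, equals IVW
  theta <- 0.5
  d <- make_dataset(seq(0.1, 0.5, length.out = 5),
                    theta * seq(0.1, 0.5, length.out = 5))
  f <- mr_fit(d, "robust")
  expect_equal(f$estimate, mr_fit(d, "ivw")$estimate, tolerance = 1e-8)

  # 9 on-model variants plus one gross outlier (simulated with a seed):
  # the robust estimate stays within 5% of theta, plain IVW is pulled
  # off by more than 5%
  set.seed(88)
  bx <- stats::runif(9, 0.1, 0.4)
  by <- theta * bx + stats::rnorm(9, 0, 0.005)
  d2 <- make_dataset(c(bx, 0.35), c(by, 0.35 * theta + 0.25),
                     sey = rep(0.01, 10))
  robust <- mr_fit(d2, "robust")$estimate
  ivw <- mr_fit(d2, "ivw")$estimate
  expect_lt(abs(robust - theta) / theta, 0.05)
  expect_gt(abs(ivw - theta) / theta, 0.05)

  # bisquare -> least squares as the tuning constant grows
  d3 <- random_dataset(12, seed = 12)
  f_inf <- mr_fit(d3, "robust", tuning = 1e6)
  expect_equal(f_inf$estimate, mr_fit(d3, "ivw")$estimate, tolerance = 1e-6)
})

test_that("robust IVW agrees with an independent MM-estimator", {
  skip_if_not_installed("MASS")
  set.seed(99)
  bx <- stats::runif(15, 0.1, 0.4)
  by <- 0.3 * bx + stats::rnorm(15, 0, 0.01)
  by[4] <- by[4] + 0.15
  d <- make_dataset(bx, by, sey = rep(0.02, 15))
  f <- mr_fit(d, "robust")
  ref <- suppressWarnings(
    MASS::rlm(by ~ bx - 1, weights = rep(0.02, 15)^-2,
              wt.method = "inv.var", method = "MM",
              psi = MASS::psi.bisquare, c = 4.685, maxit = 100))
  expect_equal(f$estimate, unname(coef(ref)[1]), tolerance = 0.05)
})

test_that("random-effects SEs are never smaller than fixed-effect SEs", {
  for (seed in 1:25) {
    d <- random_dataset(J = sample(4:20, 1), seed = 1000 + seed,
                        alpha_mean = stats::runif(1, -0.02, 0.02),
                        alpha_sd = stats::runif(1, 0, 0.02))
    for (m in c("ivw", "egger")) {
      fr <- mr_fit(d, m, variance_model = "random_multiplicative")
      ff <- mr_fit(d, m, variance_model = "fixed")
      expect_gte(fr$se, ff$se)
      if (m == "egger") expect_gte(fr$intercept$se, ff$intercept$se)
    }
  }
})

test_that("IVW is orientation-invariant; the MR-Egger intercept is not", {
  d <- random_dataset(8, seed = 31, alpha_mean = 0.01)
  base_ivw <- mr_fit(d, "ivw")
  base_egger <- mr_fit(d, "egger")
  set.seed(5)
  flip <- sample(c(TRUE, FALSE), 8, replace = TRUE)
  flip[1] <- TRUE
  df <- as.data.frame(d)
  df$beta_x[flip] <- -df$beta_x[flip]
  df$beta_y[flip] <- -df$beta_y[flip]
  d_flipped <- mr_dataset(df)
  expect_equal(mr_fit(d_flipped, "ivw")$estimate, base_ivw$estimate,
               tolerance = 1e-12)
  expect_equal(mr_fit(d_flipped, "ivw")$se, base_ivw$se, tolerance = 1e-12)

  # flipping a single variant moves the intercept on a generic instance
  df1 <- as.data.frame(d)
  df1$beta_x[1] <- -df1$beta_x[1]
  df1$beta_y[1] <- -df1$beta_y[1]
  f1 <- suppressWarnings(mr_fit(mr_dataset(df1), "egger"))
  expect_gt(abs(f1$intercept$estimate - base_egger$intercept$estimate), 1e-6)
})

test_that("estimators recover the causal effect as sampling error vanishes", {
  theta <- 0.35
  set.seed(17)
  bx <- stats::runif(20, 0.05, 0.3)
  d <- make_dataset(bx, theta * bx, sex = rep(1e-6, 20), sey = rep(1e-6, 20))
  expect_equal(mr_fit(d, "ivw")$estimate, theta, tolerance = 1e-6)
  expect_equal(mr_fit(d, "egger")$estimate, theta, tolerance = 1e-6)
  expect_equal(mr_fit(d, "simple_median",
                      boot = mr_boot_config(200, 1))$estimate,
               theta, tolerance = 1e-6)
})

test_that("fit objects expose standard accessors", {
  d <- random_dataset(10, seed = 55)
  f <- mr_fit(d, "egger")
  expect_named(coef(f), c("intercept", "slope"))
  ci <- confint(f)
  expect_equal(dim(ci), c(2, 2))
  expect_lte(ci["slope", 1], f$estimate)
  expect_gte(ci["slope", 2], f$estimate)
  expect_length(residuals(f), 10)
  expect_equal(unname(residuals(f, "weighted")),
               f$residuals * sqrt(f$weights))
  tab <- as.data.frame(f)
  expect_equal(nrow(tab), 2L)
  expect_output(print(summary(f)), "instrument-strength")

  # invariant: ci_lower <= estimate <= ci_upper across methods
  for (m in c("ivw", "simple_median", "robust")) {
    fm <- mr_fit(d, m, boot = mr_boot_config(200, 1))
    expect_lte(fm$ci_lower, fm$estimate)
    expect_gte(fm$ci_upper, fm$estimate)
    expect_gt(fm$se, 0)
  }
})
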