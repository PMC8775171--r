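test_that("fractional conversion curve has the exact boundary/half-life/asymptote", {
  expect_equal(eval_fractional_conversion(0, Ci = 12, Cf = 90, k = 0.02), 12)
  expect_equal(eval_fractional_conversion(30, Ci = 0, Cf = 100,
                                          k = log(2) / 30), 50)
  expect_equal(eval_fractional_conversion(20 / 0.018 + 100, 0, 91.67, 0.018),
               91.67, tolerance = 1e-6)
})

test_that("logistic curve hits Cf/(1+e^2) at t = lambda and kmax at the inflection", {
  expect_equal(eval_logistic(11, Starchf = 100, kmax = 1.3, lambda = 11),
               100 / (1 + exp(2)))
  expect_equal(eval_logistic(5000, 91, 1.3, 11), 91, tolerance = 1e-8)
  # inflection at t = lambda + Starchf / (2 kmax); slope there equals kmax
  Sf <- 100; kmax <- 1.3; lam <- 11
  t_inf <- lam + Sf / (2 * kmax)
  h <- 1e-5
  slope <- (eval_logistic(t_inf + h, Sf, kmax, lam) -
            eval_logistic(t_inf - h, Sf, kmax, lam)) / (2 * h)
  expect_equal(slope, kmax, tolerance = 1e-6)
})

test_that("noiseless data identify both models to 1e-6 relative error", {
  truth_fc <- c(Ci = 0, Cf = 91.67, k = 0.018)
  tc <- generate_digestion_timecourse(
    make_truth_preset("fractional_conversion", truth_fc), "starch",
    times = seq(0, 180, by = 5), noise_sd = 0, seed = 1)
  fit <- fit_kinetic_model(tc, "fractional_conversion")
  expect_equal(coef(fit)[c("Cf", "k")], truth_fc[c("Cf", "k")],
               tolerance = 1e-6)
  expect_lt(abs(coef(fit)[["Ci"]]), 1e-4)

  truth_lg <- c(Starchf = 100, kmax = 1.3, lambda = 11)
  tcl <- generate_digestion_timecourse(
    make_truth_preset("logistic", truth_lg), "starch",
    noise_sd = 0, seed = 1)
  fitl <- fit_kinetic_model(tcl, "logistic")
  expect_equal(coef(fitl), truth_lg, tolerance = 1e-6)
})

test_that("fitting is invariant to observation order and uses tube-level SSE", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                      noise_sd = 2, seed = 9)
  fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
  perm <- withr::with_seed(1, sample.int(nrow(tc)))
  tc2 <- digestion_timecourse(tc$time_min[perm], tc$value[perm],
                              tc$replicate[perm], analyte = "starch")
  fit2 <- fit_kinetic_model(tc2, "fractional_conversion", fix_ci = 0)
  expect_equal(coef(fit), coef(fit2), tolerance = 1e-8)
  expect_equal(fit$sse, sum((tc$value - predict(fit))^2), tolerance = 1e-10)
  # adjusted R2 recomputed directly
  r2 <- 1 - fit$sse / sum((tc$value - mean(tc$value))^2)
  n <- fit$n_obs; p <- length(fit$fitted_params)
  expect_equal(fit$r2_adjusted, 1 - (1 - r2) * (n - 1) / (n - p - 1))
})

test_that("monotone bounded curves: FC between Ci and Cf, logistic nondecreasing", {
  t <- seq(0, 180, by = 1)
  fc <- eval_fractional_conversion(t, Ci = 5, Cf = 90, k = 0.02)
  expect_true(all(diff(fc) > 0))
  expect_true(all(fc >= 5 & fc <= 90))
  lg <- eval_logistic(t, 91, 1.3, 11)
  expect_true(all(diff(lg) > 0))
  expect_true(all(lg <= 91))
})

test_that("initial reaction rate is the analytic tangent slope at t = 0", {
  # fractional conversion anchored at the reported protein estimates
  tc <- generate_digestion_timecourse(
    make_truth_preset("fractional_conversion", c(Ci = 0, Cf = 36.84, k = 0.021),
                      analyte = "bioaccessible_protein"),
    "bioaccessible_protein", noise_sd = 0, seed = 1)
  fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
  expect_equal(round(initial_reaction_rate(fit), 2), 0.77)
  expect_equal(initial_reaction_rate(fit), fd_slope(fit, 0), tolerance = 1e-6)

  flat <- generate_digestion_timecourse(
    make_truth_preset("fractional_conversion", c(Ci = 40, Cf = 40.0001, k = 0.02)),
    "starch", noise_sd = 0, seed = 1)
  fit_flat <- fit_kinetic_model(flat, "fractional_conversion", fix_ci = 40)
  expect_equal(initial_reaction_rate(fit_flat), 0, tolerance = 1e-4)

  tcl <- generate_digestion_timecourse(
    make_truth_preset("logistic", c(Starchf = 100, kmax = 1.3, lambda = 11)),
    "starch", noise_sd = 0, seed = 1)
  fitl <- fit_kinetic_model(tcl, "logistic")
  expect_equal(initial_reaction_rate(fitl), fd_slope(fitl, 0),
               tolerance = 1e-6)
})

test_that("model discrimination recovers the generating family", {
  lag <- generate_digestion_timecourse("BB_ICC_60", "starch",
                                       noise_sd = 0.5, seed = 21)
  expect_identical(discriminate_models(lag)$choice, "logistic")

  nolag <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                         noise_sd = 0.5, seed = 22)
  expect_identical(discriminate_models(nolag)$choice, "fractional_conversion")

  # lambda = 0 logistic data behave like a steep first-order curve: the lag
  # CI must contain 0 and the lag is not declared significant
  zl <- generate_digestion_timecourse(
    make_truth_preset("logistic", c(Starchf = 91, kmax = 1.3, lambda = 0)),
    "starch", noise_sd = 1, seed = 23)
  d <- discriminate_models(zl)
  expect_lte(d$diagnostics$lambda_ci[1L], 0)
  expect_identical(d$choice, "fractional_conversion")
})

test_that("normalized digestion correlation pairs plateau-scaled curves", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                      noise_sd = 0, seed = 1)
  fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
  same <- normalized_digestion_correlation(fit, fit)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$starch_norm, same$protein_norm)

  fast <- fit_kinetic_model(generate_digestion_timecourse(
    make_truth_preset("fractional_conversion", c(Ci = 0, Cf = 36, k = 0.2),
                      analyte = "bioaccessible_protein"),
    "bioaccessible_protein", noise_sd = 0, seed = 2),
    "fractional_conversion", fix_ci = 0)
  res <- normalized_digestion_correlation(fit, fast)
  expect_true(all(res$protein_norm >= res$starch_norm - 1e-12))
  # direct-summation Pearson oracle on the tabulated curves
  x <- res$starch_norm; y <- res$protein_norm; n <- length(x)
  r_direct <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(res$pearson_r, r_direct, tolerance = 1e-12)
})

test_that("degenerate fitting inputs are rejected", {
  short <- digestion_timecourse(c(0, 10, 30, 60), c(0, 10, 30, 50),
                                analyte = "starch")
  expect_error(fit_kinetic_model(short, "fractional_conversion"),
               class = "invalid_timecourse")
  expect_error(fit_kinetic_model(
    digestion_timecourse(c(0, 10, 30, 60, 90), c(0, 10, 30, 50, 60),
                         analyte = "starch"), "logistic", fix_ci = 0),
    class = "invalid_model")
  expect_error(digestion_timecourse(c(-1, 5), c(1, 2), analyte = "starch"),
               class = "invalid_timecourse")
})
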