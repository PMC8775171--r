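make_linear_sse_fit <- function(seed = 5, n = 15) {
  set.seed(seed)
  t <- seq(0, 10, length.out = n)
  y <- 2 + 0.8 * t + stats::rnorm(n, 0, 0.5)
  X <- cbind(1, t)
  fit <- stats::lm(y ~ t)
  sse_surface_fit(
    sse_fn = function(theta) sum((y - theta[["a"]] - theta[["b"]] * t)^2),
    estimate = c(a = unname(stats::coef(fit)[1L]),
                 b = unname(stats::coef(fit)[2L])),
    se = c(a = summary(fit)$coefficients[1L, 2L],
           b = summary(fit)$coefficients[2L, 2L]),
    sse = sum(stats::resid(fit)^2), n_obs = n)
}

test_that("grid contour of a linear model matches the closed-form ellipse area", {
  fit <- make_linear_sse_fit()
  region <- jcr_boundary(fit, pair = c("a", "b"), alpha = 0.05)
  # linear model: SSE(theta) = SSE_hat + (theta-hat)' X'X (theta-hat), so the
  # region {SSE <= SSE_hat (1 + 2/(n-2) F)} is the ellipse
  # (theta-hat)' X'X (theta-hat) <= c with area pi * c / sqrt(det(X'X))
  n <- fit$n_obs
  t <- seq(0, 10, length.out = n)
  XtX <- crossprod(cbind(1, t))
  cc <- fit$sse * 2 / (n - 2) * stats::qf(0.95, 2, n - 2)
  area_exact <- pi * cc / sqrt(det(XtX))
  expect_equal(jcr_area(region), area_exact, tolerance = 0.02)
})

test_that("regions nest in alpha and always enclose the estimate", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                      noise_sd = 2, seed = 31)
  fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
  r05 <- jcr_boundary(fit, pair = c("k", "Cf"), alpha = 0.05)
  r20 <- jcr_boundary(fit, pair = c("k", "Cf"), alpha = 0.20)
  expect_gt(r05$sse_threshold, r20$sse_threshold)
  inside <- pracma::inpolygon(r20$boundary[, 1L], r20$boundary[, 2L],
                              r05$boundary[, 1L], r05$boundary[, 2L])
  expect_true(all(inside))
  expect_true(pracma::inpolygon(r05$estimate[1L], r05$estimate[2L],
                                r05$boundary[, 1L], r05$boundary[, 2L]))
  expect_gt(jcr_area(r05), jcr_area(r20))
})

test_that("the threshold reduces to the optimal SSE as alpha -> 1", {
  thr <- pulsekinetics:::jcr_threshold(10, n = 20, p = 2, alpha = 1 - 1e-9,
                                       df_convention = "n-p")
  expect_equal(thr, 10, tolerance = 1e-6)
  # printed-convention variant differs only through the second F df
  thr_np <- pulsekinetics:::jcr_threshold(10, 20, 2, 0.05, "n-p")
  thr_n1 <- pulsekinetics:::jcr_threshold(10, 20, 2, 0.05, "n-1")
  expect_equal(thr_n1, 10 * (1 + 2 / 18 * stats::qf(0.95, 2, 19)))
  expect_false(isTRUE(all.equal(thr_np, thr_n1)))
})

test_that("overlap detects self-identity, separation and resampled closeness", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                      noise_sd = 2, seed = 41)
  fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
  reg <- jcr_boundary(fit, pair = c("k", "Cf"))
  self <- jcr_overlap(reg, reg)
  expect_true(self$overlaps)
  expect_equal(self$overlap_area_fraction, 1, tolerance = 0.02)

  # rates 10x apart at low noise produce disjoint regions
  slow <- fit_kinetic_model(generate_digestion_timecourse(
    make_truth_preset("fractional_conversion", c(Ci = 0, Cf = 90, k = 0.005)),
    "starch", noise_sd = 0.5, seed = 42), "fractional_conversion", fix_ci = 0)
  fast <- fit_kinetic_model(generate_digestion_timecourse(
    make_truth_preset("fractional_conversion", c(Ci = 0, Cf = 90, k = 0.05)),
    "starch", noise_sd = 0.5, seed = 43), "fractional_conversion", fix_ci = 0)
  sep <- jcr_overlap(jcr_boundary(slow, pair = c("k", "Cf")),
                     jcr_boundary(fast, pair = c("k", "Cf")))
  expect_false(sep$overlaps)

  # two resamples of one dataset give overlapping regions
  tc_a <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                        noise_sd = 2, seed = 44)
  tc_b <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                        noise_sd = 2, seed = 45)
  ov <- jcr_overlap(
    jcr_boundary(fit_kinetic_model(tc_a, "fractional_conversion", fix_ci = 0),
                 pair = c("k", "Cf")),
    jcr_boundary(fit_kinetic_model(tc_b, "fractional_conversion", fix_ci = 0),
                 pair = c("k", "Cf")))
  expect_true(ov$overlaps)
  expect_gt(ov$overlap_area_fraction, 0.2)

  expect_error(jcr_overlap(reg, jcr_boundary(fit, pair = c("Cf", "k"))),
               class = "invalid_pair")
})

test_that("membership test agrees with the extracted contour", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                      noise_sd = 2, seed = 51)
  fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
  reg <- jcr_boundary(fit, pair = c("k", "Cf"))
  pts <- rbind(reg$estimate,
               reg$estimate * c(1.001, 1.001),
               reg$estimate * c(2, 1.2))
  for (i in seq_len(nrow(pts))) {
    in_poly <- pracma::inpolygon(pts[i, 1L], pts[i, 2L],
                                 reg$boundary[, 1L], reg$boundary[, 2L])
    expect_identical(jcr_covers(fit, pts[i, ], pair = c("k", "Cf")),
                     as.logical(in_poly))
  }
})
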