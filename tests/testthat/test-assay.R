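test_that("linear calibration recovers an exact line and flags degenerate input", {
  std <- data.frame(concentration = c(0.5, 1, 1.5, 2),
                    absorbance = c(0.25, 0.5, 0.75, 1))
  cal <- fit_linear_calibration(std)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$valid_range, c(0.5, 2))
  expect_error(fit_linear_calibration(std[1:2, ]), class = "calibration_error")
  dup <- data.frame(concentration = rep(1, 4), absorbance = rep(0.5, 4))
  expect_error(fit_linear_calibration(dup), class = "calibration_error")
})

test_that("noisy calibration slope falls within 3 SE of truth (closed-form OLS oracle)", {
  set.seed(11)
  absb <- seq(0.1, 1, length.out = 12)
  conc <- 2 * absb + 0.05 + stats::rnorm(12, 0, 0.02)
  cal <- fit_linear_calibration(data.frame(concentration = conc,
                                           absorbance = absb))
  # closed-form OLS: slope = Sxy/Sxx, SE = sqrt(SSE/(n-2)/Sxx)
  sxx <- sum((absb - mean(absb))^2)
  slope_hat <- sum((absb - mean(absb)) * (conc - mean(conc))) / sxx
  resid <- conc - (mean(conc) + slope_hat * (absb - mean(absb)))
  se <- sqrt(sum(resid^2) / (12 - 2) / sxx)
  expect_equal(cal$slope, slope_hat, tolerance = 1e-10)
  expect_lt(abs(cal$slope - 2), 3 * se)
})

test_that("out-of-range absorbances are extrapolated with a warning", {
  cal <- default_calibration("maltose")
  expect_warning(apply_calibration(cal, 5), class = "calibration_extrapolation")
  expect_silent(apply_calibration(cal, 0.5))
})

test_that("digested starch percent applies the 0.95 factor over total starch", {
  expect_equal(digested_starch_percent(starch_assay_reading(50, 50)), 95)
  expect_equal(digested_starch_percent(starch_assay_reading(0, 50)), 0)
  expect_equal(digested_starch_percent(starch_assay_reading(42.1, 50)), 79.99)
  expect_error(starch_assay_reading(10, 0), class = "division_error")
  # linearity in maltose equivalents
  m <- c(1, 2, 5, 8)
  v <- vapply(m, function(x)
    digested_starch_percent(starch_assay_reading(x, 40)), numeric(1))
  expect_equal(v, m * v[1L])
})

test_that("protein percentages follow the free-NH2 difference expressions", {
  r <- protein_assay_readings(10, 200, nh2_hydrolyzed = 110, nh2_tca = 10)
  expect_equal(digested_soluble_protein_percent(r), 50)
  expect_equal(readily_bioaccessible_protein_percent(r), 0)
  r2 <- protein_assay_readings(0, 100, nh2_hydrolyzed = 100, nh2_tca = 37)
  expect_equal(digested_soluble_protein_percent(r2), 100)
  expect_equal(readily_bioaccessible_protein_percent(r2), 37)
  expect_error(digested_soluble_protein_percent(
    suppressWarnings(protein_assay_readings(0, 0, nh2_hydrolyzed = 1))),
    class = "division_error")
  expect_warning(
    digested_soluble_protein_percent(
      suppressWarnings(protein_assay_readings(5, 100, nh2_hydrolyzed = 3))),
    class = "negative_percent")
})

test_that("bioaccessible <= soluble whenever TCA <= hydrolyzed; both scale-invariant", {
  set.seed(3)
  for (i in 1:30) {
    initial <- stats::runif(1, 0, 10)
    total <- stats::runif(1, 50, 200)
    hyd <- stats::runif(1, initial, total)
    tca <- stats::runif(1, initial, hyd)
    r <- protein_assay_readings(initial, total, hyd, tca)
    sol <- digested_soluble_protein_percent(r)
    bio <- readily_bioaccessible_protein_percent(r)
    expect_lte(bio, sol)
    s <- stats::runif(1, 0.1, 10)
    rs <- protein_assay_readings(initial * s, total * s, hyd * s, tca * s)
    expect_equal(digested_soluble_protein_percent(rs), sol)
    expect_equal(readily_bioaccessible_protein_percent(rs), bio)
  }
})

test_that("a generated plate round-trips through quantification at zero noise", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                      noise_sd = 0, seed = 1)
  cal <- default_calibration("maltose")
  plate <- generate_assay_plate(tc, cal, totals = list(total_starch = 1.8))
  got <- suppressWarnings(
    quantify_plate(plate, maltose_cal = cal, totals = list(total_starch = 1.8)))
  expect_equal(got$value_percent, tc$value, tolerance = 1e-9)

  tcp <- generate_digestion_timecourse("CP_ICC_30", "bioaccessible_protein",
                                       noise_sd = 0, seed = 1)
  scal <- default_calibration("L-serine")
  totals <- list(nh2_total = 80, nh2_initial = 5)
  plate_p <- generate_assay_plate(tcp, scal, totals = totals)
  expect_true(all(plate_p$assay == "OPA_TCA"))
  got_p <- suppressWarnings(quantify_plate(plate_p, serine_cal = scal,
                                           totals = totals))
  expect_equal(got_p$value_percent, tcp$value, tolerance = 1e-9)
})
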