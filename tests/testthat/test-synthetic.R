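test_that("digestion generator is exact at zero noise and seed-deterministic", {
  tc0 <- generate_digestion_timecourse("CP_ICC_30", "starch",
                                       noise_sd = 0, seed = 1)
  truth <- pulse_presets("CP_ICC_30")$kinetics$starch$params
  expect_equal(tc0$value,
               eval_fractional_conversion(tc0$time_min, truth[["Ci"]],
                                          truth[["Cf"]], truth[["k"]]))
  a <- generate_digestion_timecourse("BB_ICC_60", "starch", seed = 99)
  b <- generate_digestion_timecourse("BB_ICC_60", "starch", seed = 99)
  expect_identical(a, b)
  c <- generate_digestion_timecourse("BB_ICC_60", "starch", seed = 100)
  expect_false(identical(a$value, c$value))
  expect_error(generate_digestion_timecourse("BB_ICC_60", "starch"),
               class = "seed_required")
  expect_error(generate_digestion_timecourse("BB_ICC_60", "lipid", seed = 1),
               class = "unknown_analyte")
})

test_that("generator noise SD matches the requested level", {
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch", times = 60,
                                      noise_sd = 2, n_replicates = 1000L,
                                      seed = 8)
  expect_lt(abs(stats::sd(tc$value) - 2) / 2, 0.05)
})

test_that("hardness generator reproduces mean-proportional scatter", {
  h0 <- generate_hardness_measurements("CP_ICC_30", cv = 0, seed = 1)
  truth <- pulse_presets("CP_ICC_30")$hardness
  mu <- eval_fractional_conversion(h0$cook_time_min, truth[["Ci"]],
                                   truth[["Cf"]], truth[["k"]])
  expect_equal(h0$force_n, mu)

  h <- generate_hardness_measurements("CP_ICC_30",
                                      cook_times = c(0, 30, 60, 120),
                                      n_seeds = 4000L, cv = 0.10, seed = 2)
  for (tt in c(0, 120)) {
    f <- h$force_n[h$cook_time_min == tt]
    expect_lt(abs(stats::sd(f) / mean(f) - 0.10), 0.01)
  }
  # plateau-time means sit at the residual hardness
  expect_equal(mean(h$force_n[h$cook_time_min == 120]), truth[["Cf"]],
               tolerance = 0.01)
})

test_that("analytic PSD generation is deterministic and normalised", {
  spec <- pulse_presets("BB_ICC_60")$psd
  p1 <- generate_psd(spec)
  p2 <- generate_psd(spec)
  expect_identical(p1, p2)
  expect_equal(sum(p1$volume_percent), 100, tolerance = 1e-9)
  expect_gt(icc_yield(p1), 85)  # narrow unimodal cell peak sits in-window
  expect_error(generate_psd(data.frame(median_um = 100, gsd = 1.2,
                                       share = 0.9)),
               class = "invalid_psd")
})

test_that("assay-plate generation inverts quantification", {
  cal <- default_calibration("maltose")
  # 0 % digested maps to a blank-level absorbance (zero with a zero intercept)
  tc0 <- digestion_timecourse(c(0, 5, 10, 15, 30), rep(0, 5),
                              analyte = "starch", label = "blank")
  plate0 <- generate_assay_plate(tc0, cal, totals = list(total_starch = 1.8))
  expect_equal(max(abs(plate0$absorbance)), 0, tolerance = 1e-12)

  # noisy absorbances stay unbiased after quantification
  tc <- generate_digestion_timecourse("CP_ICC_30", "starch", times = 90,
                                      noise_sd = 0, n_replicates = 400L,
                                      seed = 3)
  plate <- generate_assay_plate(tc, cal, totals = list(total_starch = 1.8),
                                absorbance_noise = 0.005, seed = 4)
  got <- suppressWarnings(quantify_plate(plate, maltose_cal = cal,
                                         totals = list(total_starch = 1.8)))
  expect_equal(mean(got$value_percent), mean(tc$value), tolerance = 0.01)

  # unrepresentable concentrations are rejected
  huge <- digestion_timecourse(c(0, 5, 10, 15, 30), rep(1e7, 5),
                               analyte = "starch", label = "x")
  expect_error(generate_assay_plate(huge, cal,
                                    totals = list(total_starch = 1.8)),
               class = "dilution_error")
})

test_that("zero-noise generation followed by fitting recovers every preset truth", {
  for (nm in names(pulse_presets())) {
    preset <- pulse_presets(nm)
    for (an in names(preset$kinetics)) {
      truth <- preset$kinetics[[an]]
      tc <- generate_digestion_timecourse(preset, an, noise_sd = 0, seed = 1)
      fit <- if (truth$model == "fractional_conversion") {
        fit_kinetic_model(tc, "fractional_conversion",
                          fix_ci = truth$params[["Ci"]])
      } else {
        fit_kinetic_model(tc, "logistic")
      }
      expect_equal(coef(fit), truth$params[names(coef(fit))],
                   tolerance = 1e-6,
                   label = paste(nm, an, "recovered parameters"))
    }
  }
})
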