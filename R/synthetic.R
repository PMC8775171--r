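resolve_preset <- function(preset) {
  if (is.character(preset)) pulse_presets(preset) else preset
}

#' Default small-intestinal sampling grid (min)
#'
#' Independent single-reactor tubes quenched at 0-180 min of simulated
#' small-intestinal digestion, denser early where the curves bend.
#'
#' @return Numeric vector of times (min).
#' @export
default_digestion_times <- function() c(0, 5, 10, 15, 30, 60, 90, 120, 180)

#' Simulate a digestion time course from a preset truth
#'
#' Evaluates the preset's true kinetic curve for the analyte and adds
#' i.i.d. Gaussian assay noise. Each replicate is an independent tube.
#'
#' @param preset A preset name (see [pulse_presets()]) or preset list.
#' @param analyte `"starch"`, `"soluble_protein"` or
#'   `"bioaccessible_protein"`.
#' @param times Sampling times (min) within 0-180.
#' @param noise_sd Additive Gaussian noise SD in percent-digested units
#'   (default 2).
#' @param n_replicates Tubes per time point (default 2, duplicate assays).
#' @param seed Mandatory RNG seed; generation never touches the global RNG
#'   state.
#' @return A [digestion_timecourse()].
#' @export
generate_digestion_timecourse <- function(preset, analyte,
                                          times = default_digestion_times(),
                                          noise_sd = 2, n_replicates = 2L,
                                          seed) {
  preset <- resolve_preset(preset)
  if (missing(seed)) stop_pk("seed is a mandatory argument",
                             class = "seed_required")
  if (any(times < 0 | times > 180))
    stop_pk("times must lie in [0, 180] min", class = "invalid_timecourse")
  if (noise_sd < 0) stop_pk("noise_sd must be >= 0", class = "domain_error")
  truth <- preset$kinetics[[analyte]]
  if (is.null(truth))
    stop_pk("preset '", preset$name, "' has no '", analyte, "' truth; has: ",
            paste(names(preset$kinetics), collapse = ", "),
            class = "unknown_analyte")
  tt <- rep(times, each = n_replicates)
  mu <- model_fun(truth$model)(tt, truth$params)
  vals <- withr::with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  digestion_timecourse(tt, vals,
                       replicate = rep(seq_len(n_replicates), length(times)),
                       analyte = analyte, label = preset$name)
}

#' Simulate per-seed hardness measurements
#'
#' Per-seed compression forces at each cook time: the pulse's true
#' fractional-conversion softening curve with mean-proportional scatter,
#' `force = truth(t) * (1 + N(0, cv))`, truncated to stay positive (the
#' observed hardness spread shrinks with the mean at long cook times).
#'
#' @param preset Preset name or list (its `hardness` truth is used).
#' @param cook_times Cook times (min).
#' @param n_seeds Seeds measured per cook time (default 25).
#' @param cv Coefficient of variation of the per-seed scatter (default
#'   0.10).
#' @param seed Mandatory RNG seed.
#' @return A [hardness_profile()].
#' @export
generate_hardness_measurements <- function(preset,
                                           cook_times = c(0, 5, 10, 15, 20,
                                                          30, 45, 60, 90, 120),
                                           n_seeds = 25L, cv = 0.10, seed) {
  preset <- resolve_preset(preset)
  if (missing(seed)) stop_pk("seed is a mandatory argument",
                             class = "seed_required")
  if (cv < 0) stop_pk("cv must be >= 0", class = "domain_error")
  h <- preset$hardness
  tt <- rep(cook_times, each = n_seeds)
  mu <- eval_fractional_conversion(tt, h[["Ci"]], h[["Cf"]], h[["k"]])
  forces <- withr::with_seed(seed,
                             mu * (1 + stats::rnorm(length(mu), 0, cv)))
  forces <- pmax(forces, .Machine$double.eps)
  hardness_profile(tt, forces, pulse = preset$pulse)
}

#' Default log-spaced particle-size bin edges (um)
#'
#' 101 edges (100 bins) spanning 0.5-2000 um, covering free intracellular
#' material (tens of um), cotyledon cells (76-133 um) and seed-coat
#' clusters (> 200 um).
#'
#' @return Numeric vector of bin edges.
#' @export
default_psd_bins <- function() exp(seq(log(0.5), log(2000), length.out = 101L))

#' Build a particle size distribution from log-normal modes
#'
#' Places analytic log-normal volume mass into the bins (deterministic, no
#' sampling): each mode contributes
#' `share * (Plnorm(high) - Plnorm(low))` per bin, and the binned mass is
#' renormalised to 100 (truncation to the binned range).
#'
#' @param mode_spec Data frame with columns `median_um`, `gsd` (geometric
#'   SD, > 1) and `share` (volume shares summing to 1).
#' @param bin_edges Increasing bin edges (um), default [default_psd_bins()].
#' @param label Sample label.
#' @return A [particle_size_distribution()].
#' @export
generate_psd <- function(mode_spec, bin_edges = default_psd_bins(),
                         label = "") {
  stopifnot(all(c("median_um", "gsd", "share") %in% names(mode_spec)))
  if (abs(sum(mode_spec$share) - 1) > 1e-8)
    stop_pk("mode shares must sum to 1, got ", sum(mode_spec$share),
            class = "invalid_psd")
  if (any(mode_spec$gsd <= 1))
    stop_pk("geometric SDs must be > 1", class = "invalid_psd")
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1L]
  vol <- rep(0, length(lo))
  for (i in seq_len(nrow(mode_spec))) {
    mlog <- log(mode_spec$median_um[i])
    slog <- log(mode_spec$gsd[i])
    vol <- vol + mode_spec$share[i] *
      (stats::plnorm(hi, mlog, slog) - stats::plnorm(lo, mlog, slog))
  }
  particle_size_distribution(lo, hi, vol, label = label, normalize = TRUE)
}

#' Default colorimetric calibration curves
#'
#' Idealised maltose (DNS, 0.5-2.0 mg/mL) and L-serine (OPA, 12.5-100 mg/L)
#' calibration lines used by the plate generator and examples.
#'
#' @param analyte `"maltose"` or `"L-serine"`.
#' @return A `calibration_curve`.
#' @export
default_calibration <- function(analyte = c("maltose", "L-serine")) {
  analyte <- match.arg(analyte)
  if (analyte == "maltose") {
    std <- data.frame(concentration = c(0.5, 1.0, 1.5, 2.0),
                      absorbance = c(0.25, 0.50, 0.75, 1.00))
  } else {
    std <- data.frame(concentration = c(12.5, 25, 50, 100),
                      absorbance = c(0.125, 0.25, 0.50, 1.00))
  }
  fit_linear_calibration(std, analyte = analyte)
}

#' Simulate a plate of assay readings from a digestion time course
#'
#' Inverts the assay arithmetic and the calibration line: for each
#' observation the generator computes the concentration the assay would
#' have seen, picks the smallest allowed dilution bringing it into the
#' calibration range, and emits the corresponding absorbance (plus optional
#' Gaussian absorbance noise). At zero noise, [quantify_plate()] applied to
#' the plate recovers the time-course values to round-trip precision.
#'
#' @param tc A [digestion_timecourse()].
#' @param calibration `calibration_curve` matching the analyte (maltose for
#'   starch, L-serine for protein).
#' @param totals As in [quantify_plate()]; units must match the
#'   calibration's concentration units.
#' @param absorbance_noise Gaussian SD added to absorbances (default 0).
#' @param seed RNG seed (required when `absorbance_noise > 0`).
#' @param dilutions Allowed dilution factors.
#' @return Plate data frame (`sample_id`, `time_min`, `assay`,
#'   `absorbance`, `dilution_factor`).
#' @export
generate_assay_plate <- function(tc, calibration, totals,
                                 absorbance_noise = 0, seed = NULL,
                                 dilutions = c(1, 2, 5, 10, 20, 50, 100,
                                               200, 500, 1000)) {
  stopifnot(inherits(tc, "digestion_timecourse"),
            inherits(calibration, "calibration_curve"))
  analyte <- attr(tc, "analyte")
  assay <- switch(analyte, starch = "DNS", soluble_protein = "OPA_HYD",
                  bioaccessible_protein = "OPA_TCA",
                  stop_pk("no assay emits analyte '", analyte, "'",
                          class = "unknown_analyte"))
  conc <- if (analyte == "starch") {
    tc$value / 100 * totals$total_starch / 0.95
  } else {
    totals$nh2_initial + tc$value / 100 * totals$nh2_total
  }
  dilutions <- sort(dilutions)
  rng <- calibration$valid_range
  pick <- vapply(conc, function(cc) {
    ok <- dilutions[cc / dilutions <= rng[2L]]
    if (!length(ok))
      stop_pk("concentration ", signif(cc, 4), " not representable within ",
              "the calibration range at any allowed dilution",
              class = "dilution_error")
    in_range <- ok[cc / ok >= rng[1L]]
    if (length(in_range)) in_range[1L] else ok[1L]
  }, numeric(1))
  absorbance <- (conc / pick - calibration$intercept) / calibration$slope
  if (absorbance_noise > 0) {
    if (is.null(seed)) stop_pk("seed required when absorbance_noise > 0",
                               class = "seed_required")
    absorbance <- withr::with_seed(seed,
      absorbance + stats::rnorm(length(absorbance), 0, absorbance_noise))
  }
  data.frame(sample_id = attr(tc, "label"),
             time_min = tc$time_min,
             assay = assay,
             absorbance = absorbance,
             dilution_factor = pick,
             stringsAsFactors = FALSE)
}
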