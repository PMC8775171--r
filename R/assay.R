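#' Fit a linear calibration curve
#'
#' Ordinary least-squares line mapping absorbance to analyte concentration,
#' as used for maltose (DNS, reducing sugars) and L-serine (OPA, free
#' alpha-amino groups) standard series. The fitted intercept is retained
#' rather than forced through the origin.
#'
#' @param standards Data frame (or list) with columns/fields `concentration`
#'   and `absorbance`; at least 3 distinct points.
#' @param analyte `"maltose"` or `"L-serine"` (metadata).
#' @return An object of class `calibration_curve` with fields `slope`
#'   (concentration units per absorbance), `intercept`, `r_squared`,
#'   `valid_range` (range of the standard concentrations) and `analyte`.
#' @examples
#' std <- data.frame(concentration = c(0.5, 1, 1.5, 2),
#'                   absorbance = c(0.25, 0.5, 0.75, 1.0))
#' fit_linear_calibration(std)
#' @export
fit_linear_calibration <- function(standards, analyte = c("maltose", "L-serine")) {
  analyte <- match.arg(analyte)
  conc <- standards$concentration
  absb <- standards$absorbance
  if (length(conc) < 3L || length(absb) != length(conc))
    stop_pk("calibration needs >= 3 (concentration, absorbance) standards",
            class = "calibration_error")
  if (stats::sd(absb) == 0)
    stop_pk("calibration standards have zero absorbance variance",
            class = "calibration_error")
  fit <- stats::lm(conc ~ absb)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop_pk("calibration slope must be finite and positive, got ", slope,
            class = "calibration_error")
  structure(list(analyte = analyte,
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 valid_range = range(conc)),
            class = "calibration_curve")
}

#' Convert absorbance to concentration through a calibration curve
#'
#' Absorbances whose implied concentration falls outside the standard range
#' are extrapolated with a warning (the single-reactor sampling design
#' leaves no re-dilution path once a tube is quenched).
#'
#' @param cal A `calibration_curve`.
#' @param absorbance Numeric vector of blank-corrected absorbances.
#' @param dilution_factor Multiplier applied after conversion (default 1).
#' @return Concentrations in the calibration's units.
#' @export
apply_calibration <- function(cal, absorbance, dilution_factor = 1) {
  stopifnot(inherits(cal, "calibration_curve"))
  conc <- cal$intercept + cal$slope * absorbance
  out_of_range <- conc < cal$valid_range[1L] - 1e-12 |
    conc > cal$valid_range[2L] + 1e-12
  if (any(out_of_range))
    warn_pk(sum(out_of_range), " reading(s) outside the calibration range [",
            cal$valid_range[1L], ", ", cal$valid_range[2L],
            "]; extrapolating", class = "calibration_extrapolation")
  conc * dilution_factor
}

#' Starch assay reading (DNS, maltose equivalents)
#'
#' @param maltose_equivalents Maltose equivalents measured in the digestive
#'   supernatant (mass, same basis as `total_starch`).
#' @param total_starch Total starch initially present (mass, > 0).
#' @return Object of class `starch_assay_reading`.
#' @export
starch_assay_reading <- function(maltose_equivalents, total_starch) {
  if (!is_number(maltose_equivalents) || maltose_equivalents < 0)
    stop_pk("maltose_equivalents must be a nonnegative number",
            class = "invalid_reading")
  if (!is_number(total_starch) || total_starch <= 0)
    stop_pk("total_starch must be > 0", class = "division_error")
  structure(list(maltose_equivalents = maltose_equivalents,
                 total_starch = total_starch),
            class = "starch_assay_reading")
}

#' Digested starch percentage
#'
#' Maltose equivalents are converted to anhydroglucose starch equivalents by
#' the hydrolysis-water factor 0.95 and expressed relative to the starch
#' initially present:
#' `digested starch (%) = maltose_equivalents * 0.95 / total_starch * 100`.
#'
#' @param r A [starch_assay_reading()].
#' @return Percent digested starch.
#' @examples
#' digested_starch_percent(starch_assay_reading(42.1, 50))  # 79.99
#' @export
digested_starch_percent <- function(r) {
  stopifnot(inherits(r, "starch_assay_reading"))
  r$maltose_equivalents * 0.95 / r$total_starch * 100
}

#' Protein assay readings (OPA, L-serine equivalents)
#'
#' Free alpha-amino group contents on a common amount basis: the undigested
#' sample after full acid hydrolysis (`nh2_total`), the oral-phase baseline
#' (`nh2_initial`), the acid-hydrolysed digestive supernatant
#' (`nh2_hydrolyzed`) and the TCA-soluble supernatant fraction (`nh2_tca`).
#' Ordering violations (e.g. hydrolyzed below initial) are flagged with a
#' warning, not rejected: they occur as baseline noise early in digestion.
#'
#' @param nh2_initial,nh2_total Baseline and total free-NH2 content.
#' @param nh2_hydrolyzed,nh2_tca Supernatant contents; either may be `NA`
#'   when only one evaluation approach was run.
#' @return Object of class `protein_assay_readings`.
#' @export
protein_assay_readings <- function(nh2_initial, nh2_total,
                                   nh2_hydrolyzed = NA_real_,
                                   nh2_tca = NA_real_) {
  vals <- c(nh2_initial = nh2_initial, nh2_total = nh2_total,
            nh2_hydrolyzed = nh2_hydrolyzed, nh2_tca = nh2_tca)
  for (nm in names(vals))
    if (!is_number(vals[[nm]], allow_na = TRUE))
      stop_pk(nm, " must be a single numeric value", class = "invalid_reading")
  if (nh2_initial < 0)
    stop_pk("nh2_initial must be >= 0", class = "invalid_reading")
  if (!is.na(nh2_hydrolyzed) &&
      (nh2_hydrolyzed < nh2_initial || nh2_total < nh2_hydrolyzed))
    warn_pk("expected nh2_total >= nh2_hydrolyzed >= nh2_initial; readings ",
            "violate the ordering (kept as-is)", class = "reading_order")
  if (!is.na(nh2_tca) && nh2_tca < nh2_initial)
    warn_pk("nh2_tca below nh2_initial (kept as-is)", class = "reading_order")
  structure(as.list(vals), class = "protein_assay_readings")
}

digested_protein_fraction <- function(numerator, nh2_initial, nh2_total, what) {
  if (!is_number(nh2_total) || nh2_total <= 0)
    stop_pk("nh2_total must be > 0 to express ", what, class = "division_error")
  value <- (numerator - nh2_initial) / nh2_total * 100
  if (value < 0)
    warn_pk(what, " is negative (", round(value, 3),
            "%): pre-digestion baseline noise", class = "negative_percent")
  value
}

#' Digested soluble protein percentage
#'
#' Solubilised protein quantified after full acid hydrolysis of the
#' digestive supernatant, relative to the total free-NH2 content of the
#' undigested sample:
#' `(nh2_hydrolyzed - nh2_initial) / nh2_total * 100`.
#'
#' @param r A [protein_assay_readings()] with `nh2_hydrolyzed` present.
#' @return Percent digested soluble protein.
#' @export
digested_soluble_protein_percent <- function(r) {
  stopifnot(inherits(r, "protein_assay_readings"))
  if (is.na(r$nh2_hydrolyzed))
    stop_pk("nh2_hydrolyzed missing", class = "invalid_reading")
  digested_protein_fraction(r$nh2_hydrolyzed, r$nh2_initial, r$nh2_total,
                            "digested soluble protein")
}

#' Readily bioaccessible protein percentage
#'
#' TCA-soluble free amino acids and small oligopeptides, relative to the
#' total free-NH2 content: `(nh2_tca - nh2_initial) / nh2_total * 100`.
#'
#' @param r A [protein_assay_readings()] with `nh2_tca` present.
#' @return Percent readily bioaccessible protein.
#' @export
readily_bioaccessible_protein_percent <- function(r) {
  stopifnot(inherits(r, "protein_assay_readings"))
  if (is.na(r$nh2_tca))
    stop_pk("nh2_tca missing", class = "invalid_reading")
  digested_protein_fraction(r$nh2_tca, r$nh2_initial, r$nh2_total,
                            "readily bioaccessible protein")
}

#' Quantify a plate of assay readings into digested percentages
#'
#' Applies the calibration to each plate row and converts concentrations to
#' digested-percent values: DNS rows through [digested_starch_percent()],
#' OPA rows through the soluble / bioaccessible protein expressions.
#'
#' @param plate Data frame with columns `sample_id`, `time_min`, `assay`
#'   (one of `DNS`, `OPA_TCA`, `OPA_HYD`), `absorbance`, `dilution_factor`.
#' @param maltose_cal,serine_cal `calibration_curve` objects (either may be
#'   `NULL` when the corresponding assay is absent from the plate).
#' @param totals List with `total_starch` (maltose-equivalent units),
#'   `nh2_total` and `nh2_initial` (L-serine-equivalent units), on the same
#'   basis as the converted concentrations.
#' @return Data frame `sample_id`, `analyte`, `time_min`, `value_percent`.
#' @export
quantify_plate <- function(plate, maltose_cal = NULL, serine_cal = NULL,
                           totals) {
  need <- c("sample_id", "time_min", "assay", "absorbance", "dilution_factor")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop_pk("plate lacks column(s): ", paste(miss, collapse = ", "),
            class = "schema_error")
  analyte_of <- c(DNS = "starch", OPA_HYD = "soluble_protein",
                  OPA_TCA = "bioaccessible_protein")
  bad <- setdiff(unique(plate$assay), names(analyte_of))
  if (length(bad))
    stop_pk("unknown assay code(s): ", paste(bad, collapse = ", "),
            class = "schema_error")
  value <- vapply(seq_len(nrow(plate)), function(i) {
    row <- plate[i, ]
    if (row$assay == "DNS") {
      if (is.null(maltose_cal))
        stop_pk("plate has DNS rows but no maltose calibration",
                class = "calibration_error")
      conc <- apply_calibration(maltose_cal, row$absorbance, row$dilution_factor)
      digested_starch_percent(starch_assay_reading(conc, totals$total_starch))
    } else {
      if (is.null(serine_cal))
        stop_pk("plate has OPA rows but no L-serine calibration",
                class = "calibration_error")
      conc <- apply_calibration(serine_cal, row$absorbance, row$dilution_factor)
      r <- suppressWarnings(protein_assay_readings(
        nh2_initial = totals$nh2_initial, nh2_total = totals$nh2_total,
        nh2_hydrolyzed = if (row$assay == "OPA_HYD") conc else NA_real_,
        nh2_tca = if (row$assay == "OPA_TCA") conc else NA_real_))
      if (row$assay == "OPA_HYD") digested_soluble_protein_percent(r)
      else readily_bioaccessible_protein_percent(r)
    }
  }, numeric(1))
  data.frame(sample_id = plate$sample_id,
             analyte = unname(analyte_of[plate$assay]),
             time_min = plate$time_min,
             value_percent = value,
             stringsAsFactors = FALSE)
}
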