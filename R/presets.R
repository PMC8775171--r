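# Point-estimate "truths" for the three pulses (chickpea CP, pea PE, black
# bean BB) and their processed fractions (whole seed material WSM, isolated
# cotyledon cells ICC, cooked t min). Digestion and texture parameters are
# transcriptions of reported estimates; values never printed (hardness Ci,
# logistic kmax, per-mode PSD widths) are package choices documented in the
# methods vignette.

kinetic_truth_table <- function() {
  fc <- function(Ci, Cf, k) list(model = "fractional_conversion",
                                 params = c(Ci = Ci, Cf = Cf, k = k))
  lg <- function(Sf, kmax, lambda) list(model = "logistic",
                                        params = c(Starchf = Sf, kmax = kmax,
                                                   lambda = lambda))
  list(
    CP_ICC_30 = list(starch = fc(0, 91.67, 0.021),
                     bioaccessible_protein = fc(2, 36.84, 0.021),
                     soluble_protein = fc(26, 88.73, 0.039)),
    CP_ICC_60 = list(starch = fc(0, 100.30, 0.017),
                     bioaccessible_protein = fc(2, 35.05, 0.026)),
    CP_ICC_90 = list(starch = fc(0, 97.17, 0.020),
                     bioaccessible_protein = fc(2, 35.43, 0.034)),
    PE_ICC_30 = list(starch = fc(0, 88.75, 0.015),
                     bioaccessible_protein = fc(2, 34.35, 0.027),
                     soluble_protein = fc(38, 95.50, 0.031)),
    BB_ICC_60 = list(starch = lg(91, 1.3, 11),
                     bioaccessible_protein = fc(2, 36.68, 0.011),
                     soluble_protein = fc(38, 94.22, 0.016)),
    BB_ICC_90 = list(starch = lg(96.68, 1.3, 5),
                     bioaccessible_protein = fc(2, 44.70, 0.015)),
    BB_ICC_120 = list(starch = lg(95.58, 1.3, 3),
                      bioaccessible_protein = fc(2, 43.13, 0.020)),
    CP_WSM_30 = list(starch = fc(0, 84.37, 0.023),
                     bioaccessible_protein = fc(2, 35.83, 0.027)),
    PE_WSM_30 = list(starch = fc(0, 82.09, 0.019),
                     bioaccessible_protein = fc(2, 37.78, 0.026)),
    BB_WSM_60 = list(starch = fc(0, 93.61, 0.018),
                     bioaccessible_protein = fc(2, 26.10, 0.022))
  )
}

hardness_truths <- function() {
  list(CP = c(Ci = 140, Cf = 42, k = 0.12),
       PE = c(Ci = 140, Cf = 42, k = 0.11),
       BB = c(Ci = 140, Cf = 42, k = 0.046))
}

psd_mode_specs <- function() {
  modes <- function(median_um, gsd, share)
    data.frame(median_um = median_um, gsd = gsd, share = share)
  list(
    CP = list(icc = modes(118, 1.25, 1),
              wsm = modes(c(30, 118, 300), c(1.6, 1.25, 1.4),
                          c(0.32, 0.38, 0.30))),
    PE = list(icc = modes(124.84, 1.22, 1),
              wsm = modes(c(30, 124.84, 300), c(1.6, 1.22, 1.4),
                          c(0.32, 0.38, 0.30))),
    BB = list(icc = modes(104.66, 1.15, 1),
              wsm = modes(c(25, 104.66, 280), c(1.6, 1.15, 1.4),
                          c(0.27, 0.50, 0.23)))
  )
}

seedcoat_fractions <- function() {
  c(CP = 0.123, PE = 0.131, BB = 0.103)
}

#' Pulse presets: kinetic, texture, composition and PSD truths
#'
#' Named presets for chickpea (CP), pea (PE) and black bean (BB) samples —
#' raw seeds, whole seed material (WSM) and isolated cotyledon cells (ICC)
#' cooked for the stated times (min). Each preset carries the true kinetic
#' parameters per analyte, the pulse's hardness-softening truth, a PSD mode
#' specification and the sample's proximate composition, and is consumed by
#' the `generate_*()` synthetic-data functions.
#'
#' @param name Optional preset name; omit to get the full named list.
#' @return A preset (list with `name`, `pulse`, `kinetics`, `hardness`,
#'   `psd`, `composition`, `seedcoat_fraction`) or the list of all presets.
#' @examples
#' names(pulse_presets())
#' pulse_presets("BB_ICC_60")$kinetics$starch
#' @export
pulse_presets <- function(name = NULL) {
  kin <- kinetic_truth_table()
  hard <- hardness_truths()
  psd <- psd_mode_specs()
  sc <- seedcoat_fractions()
  comp <- pulse_composition_table()
  presets <- lapply(names(kin), function(nm) {
    pulse <- sub("_.*$", "", nm)
    fraction <- if (grepl("_ICC_", nm)) "icc" else "wsm"
    row <- comp[comp$label == gsub("_", " ", nm), ]
    composition <- if (nrow(row) == 1L)
      proximate_composition(row$starch, row$protein, row$lipid, row$ash,
                            row$moisture, basis = row$basis,
                            label = row$label)
    else NULL
    list(name = nm, pulse = pulse,
         kinetics = kin[[nm]],
         hardness = hard[[pulse]],
         psd = psd[[pulse]][[fraction]],
         composition = composition,
         seedcoat_fraction = unname(sc[pulse]))
  })
  names(presets) <- names(kin)
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop_pk("unknown preset '", name, "'; available: ",
            paste(names(presets), collapse = ", "), class = "unknown_preset")
  presets[[name]]
}

#' Proximate composition table for all pulse samples
#'
#' Compositions (g/100 g; raw seeds as-is, processed fractions on dry
#' matter) for the raw seeds and every WSM/ICC sample. Processed fractions
#' are characterised for starch, protein and moisture only (`NA`
#' elsewhere), so FRR is available for the raw seeds alone.
#'
#' @return Data frame with columns `label`, `starch`, `protein`, `lipid`,
#'   `ash`, `moisture`, `basis`.
#' @export
pulse_composition_table <- function() {
  rbind(
    data.frame(label = c("CP raw", "PE raw", "BB raw"),
               starch = c(39.73, 40.90, 33.34),
               protein = c(19.39, 19.73, 20.64),
               lipid = c(7.29, 2.79, 2.45),
               ash = c(2.17, 1.87, 3.70),
               moisture = c(3.89, 7.43, 7.23),
               basis = "as-is"),
    data.frame(label = c("CP WSM 30", "PE WSM 30", "BB WSM 60",
                         "PE ICC 30", "CP ICC 30", "CP ICC 60", "CP ICC 90",
                         "BB ICC 60", "BB ICC 90", "BB ICC 120"),
               starch = c(41.24, 45.48, 38.61,
                          61.21, 54.96, 55.33, 54.56, 47.64, 51.31, 50.44),
               protein = c(19.65, 17.60, 18.67,
                           17.74, 16.94, 16.57, 17.33, 19.98, 21.06, 22.10),
               lipid = NA_real_, ash = NA_real_,
               moisture = NA_real_,
               basis = "dry-matter")
  )
}
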