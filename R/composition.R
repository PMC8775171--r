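#' Proximate composition of a pulse sample
#'
#' Bundles the five proximate components (g/100 g) of a pulse ingredient or
#' fraction, on either an as-is or a dry-matter basis. The remainder after
#' subtracting all five from 100 is the calculated fiber-rich residue (FRR),
#' a proxy for cell-wall material; see [compute_frr()].
#'
#' Partial compositions (e.g. processed fractions characterised only for
#' starch, protein and moisture) are allowed by passing `NA` for the missing
#' components; FRR and FRR-based ratios are then unavailable.
#'
#' @param starch,protein,lipid,ash,moisture Component contents in g/100 g.
#'   `lipid`, `ash` and `moisture` may be `NA` for partial compositions.
#' @param basis `"as-is"` or `"dry-matter"`. Carried as metadata only; no
#'   basis conversion is attempted.
#' @param label Free-text sample label.
#' @return An object of class `proximate_composition`.
#' @examples
#' cp <- proximate_composition(39.73, 19.39, 7.29, 2.17, 3.89, label = "CP raw")
#' compute_frr(cp)
#' @export
proximate_composition <- function(starch, protein, lipid = NA_real_,
                                  ash = NA_real_, moisture = NA_real_,
                                  basis = c("as-is", "dry-matter"),
                                  label = "") {
  basis <- match.arg(basis)
  comp <- c(starch = starch, protein = protein, lipid = lipid,
            ash = ash, moisture = moisture)
  for (nm in names(comp)) {
    if (!is_number(comp[[nm]], allow_na = TRUE))
      stop_pk(nm, " must be a single numeric value", class = "invalid_composition")
    if (!is.na(comp[[nm]]) && comp[[nm]] < 0)
      stop_pk(nm, " must be >= 0, got ", comp[[nm]], class = "invalid_composition")
  }
  total <- sum(comp, na.rm = TRUE)
  if (total > 100 + 1e-9)
    stop_pk("components sum to ", round(total, 4),
            " g/100 g (> 100); fiber-rich residue would be negative",
            class = "invalid_composition")
  structure(list(starch = starch, protein = protein, lipid = lipid,
                 ash = ash, moisture = moisture, basis = basis, label = label),
            class = "proximate_composition")
}

#' @export
print.proximate_composition <- function(x, ...) {
  cat("Proximate composition", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "(", x$basis, ", g/100 g)\n")
  comp <- unlist(x[c("starch", "protein", "lipid", "ash", "moisture")])
  print(round(comp, 2))
  if (!anyNA(comp)) cat("FRR (calculated):", round(compute_frr(x), 2), "\n")
  invisible(x)
}

#' Fiber-rich residue (FRR) by difference
#'
#' FRR is the composition remainder after moisture, protein, starch, lipid
#' and ash: `100 - (moisture + protein + starch + lipid + ash)`. It serves as
#' a proxy for cell-wall content when dietary fiber is not assayed directly.
#'
#' @param c A [proximate_composition()] with all five components present.
#' @return FRR in g/100 g (equivalently, percent).
#' @examples
#' compute_frr(proximate_composition(39.73, 19.39, 7.29, 2.17, 3.89))  # 27.53
#' @export
compute_frr <- function(c) {
  stopifnot(inherits(c, "proximate_composition"))
  comp <- unlist(c[c("starch", "protein", "lipid", "ash", "moisture")])
  if (anyNA(comp))
    stop_pk("FRR needs all five components; missing: ",
            paste(names(comp)[is.na(comp)], collapse = ", "),
            class = "incomplete_composition")
  100 - sum(comp)
}

#' Structural macronutrient ratios
#'
#' Starch/protein (a proxy for how densely protein packs around intracellular
#' starch) and starch/FRR (starch relative to cell-wall material). FRR is
#' computed with [compute_frr()] unless supplied.
#'
#' @param c A [proximate_composition()].
#' @param frr Optional FRR value (percent) overriding the computed one.
#' @return Named list with `starch_protein` and `starch_frr` (the latter `NA`
#'   when the composition is partial and `frr` is not given).
#' @examples
#' macronutrient_ratios(proximate_composition(39.73, 19.39, 7.29, 2.17, 3.89))
#' @export
macronutrient_ratios <- function(c, frr = NULL) {
  stopifnot(inherits(c, "proximate_composition"))
  if (is.na(c$protein) || c$protein <= 0)
    stop_pk("starch/protein ratio undefined: protein is ",
            c$protein, class = "zero_denominator")
  if (is.null(frr)) {
    frr <- tryCatch(compute_frr(c), pulsekinetics_error = function(e) NA_real_)
  }
  starch_frr <- if (is.na(frr)) {
    NA_real_
  } else if (frr <= 0) {
    stop_pk("starch/FRR ratio undefined: FRR is ", frr, class = "zero_denominator")
  } else {
    c$starch / frr
  }
  list(starch_protein = c$starch / c$protein, starch_frr = starch_frr)
}

#' Seed coat to cotyledon mass ratio
#'
#' Converts the seed-coat fraction of the whole seed (dry basis) into the
#' seed-coat/cotyledon mass ratio `w / (1 - w)`.
#'
#' @param seedcoat_fraction Proportion of whole-seed dry mass in the seed
#'   coat, strictly between 0 and 1.
#' @return The mass ratio (dimensionless).
#' @examples
#' seedcoat_cotyledon_ratio(0.123)  # ~0.14
#' @export
seedcoat_cotyledon_ratio <- function(seedcoat_fraction) {
  if (!is_number(seedcoat_fraction) || seedcoat_fraction <= 0 ||
      seedcoat_fraction >= 1)
    stop_pk("seedcoat_fraction must lie strictly in (0, 1), got ",
            seedcoat_fraction, class = "domain_error")
  seedcoat_fraction / (1 - seedcoat_fraction)
}

#' Read proximate compositions from CSV or JSON
#'
#' CSV schema: one row per sample with columns `label`, `starch`, `protein`,
#' `lipid`, `ash`, `moisture`, `basis`. A JSON file holding an array of
#' objects with the same fields is accepted too (by extension `.json`).
#'
#' @param path File path.
#' @return A named list of [proximate_composition()] objects (names from
#'   `label`).
#' @export
read_composition_csv <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("label", "starch", "protein", "lipid", "ash", "moisture", "basis")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop_pk("composition table lacks column(s): ", paste(miss, collapse = ", "),
            class = "schema_error")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    proximate_composition(rows$starch[i], rows$protein[i], rows$lipid[i],
                          rows$ash[i], rows$moisture[i],
                          basis = rows$basis[i], label = rows$label[i])
  })
  names(out) <- rows$label
  out
}
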