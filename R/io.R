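read_csv_checked <- function(path, numeric_cols, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_pk(basename(path), " lacks column(s): ", paste(miss, collapse = ", "),
            class = "schema_error")
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      raw <- as.character(df[[col]])
      bad <- which(is.na(suppressWarnings(as.numeric(raw))) | grepl(",", raw))
      hint <- if (any(grepl(",", raw)))
        " (decimal commas found: use '.' as the decimal separator)" else ""
      stop_pk(basename(path), " column '", col, "' is not numeric at row(s) ",
              paste(utils::head(bad, 5L), collapse = ", "), hint,
              class = "schema_error")
    }
  }
  df
}

#' Read digestion time courses from CSV
#'
#' Schema: `sample_id`, `analyte`, `time_min`, `value_percent`,
#' `replicate`. Values must use `.` as the decimal separator; negative
#' times are rejected naming the offending rows.
#'
#' @param path CSV file path.
#' @return A single [digestion_timecourse()] when the file holds one
#'   sample-analyte combination, otherwise a named list
#'   (`"sample_id::analyte"`).
#' @export
read_timecourse_csv <- function(path) {
  df <- read_csv_checked(path,
                         numeric_cols = c("time_min", "value_percent"),
                         required = c("sample_id", "analyte", "time_min",
                                      "value_percent", "replicate"))
  if (any(df$time_min < 0))
    stop_pk(basename(path), ": negative time_min at row(s) ",
            paste(which(df$time_min < 0), collapse = ", "),
            class = "schema_error")
  key <- paste(df$sample_id, df$analyte, sep = "::")
  out <- lapply(split(df, key), function(d)
    digestion_timecourse(d$time_min, d$value_percent, d$replicate,
                         analyte = d$analyte[1L], label = d$sample_id[1L]))
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a digestion time course to CSV
#'
#' @param tc A [digestion_timecourse()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "digestion_timecourse"))
  utils::write.csv(data.frame(sample_id = attr(tc, "label"),
                              analyte = attr(tc, "analyte"),
                              time_min = tc$time_min,
                              value_percent = tc$value,
                              replicate = tc$replicate),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read per-seed hardness measurements from CSV
#'
#' Schema: `pulse`, `cook_time_min`, `seed_index`, `force_N`.
#'
#' @param path CSV file path.
#' @return A [hardness_profile()] (or a named list, one per pulse).
#' @export
read_hardness_csv <- function(path) {
  df <- read_csv_checked(path, numeric_cols = c("cook_time_min", "force_N"),
                         required = c("pulse", "cook_time_min", "seed_index",
                                      "force_N"))
  out <- lapply(split(df, df$pulse), function(d)
    hardness_profile(d$cook_time_min, d$force_N, pulse = d$pulse[1L]))
  if (length(out) == 1L) out[[1L]] else out
}

#' Read binned particle size distributions from CSV
#'
#' Schema: `sample`, `bin_low_um`, `bin_high_um`, `volume_percent`.
#'
#' @param path CSV file path.
#' @return A [particle_size_distribution()] (or a named list, one per
#'   sample).
#' @export
read_psd_csv <- function(path) {
  df <- read_csv_checked(path,
                         numeric_cols = c("bin_low_um", "bin_high_um",
                                          "volume_percent"),
                         required = c("sample", "bin_low_um", "bin_high_um",
                                      "volume_percent"))
  out <- lapply(split(df, df$sample), function(d)
    particle_size_distribution(d$bin_low_um, d$bin_high_um,
                               d$volume_percent, label = d$sample[1L]))
  if (length(out) == 1L) out[[1L]] else out
}

#' Serialize a kinetic fit to JSON
#'
#' Parameters, standard errors, covariance, fit diagnostics and the
#' underlying observations, written at full numeric precision so that
#' write-then-read round-trips losslessly (see [read_fit_json()]).
#'
#' @param fit A `kinetic_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  payload <- list(model = fit$model,
                  params = as.list(fit$params),
                  fixed_params = as.list(fit$fixed_params),
                  se = as.list(fit$se),
                  covariance = fit$covariance,
                  sse = fit$sse,
                  n_obs = fit$n_obs,
                  r_squared = fit$r_squared,
                  r2_adjusted = fit$r2_adjusted,
                  time_range = fit$time_range,
                  converged = fit$converged,
                  data = list(time_min = fit$data$time_min,
                              value = fit$data$value,
                              replicate = fit$data$replicate,
                              analyte = attr(fit$data, "analyte"),
                              label = attr(fit$data, "label")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a kinetic fit back from JSON
#'
#' @param path JSON path written by [write_fit_json()].
#' @return A `kinetic_fit`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  params <- unlist(x$params)
  fixed <- if (length(x$fixed_params)) unlist(x$fixed_params) else numeric(0)
  fitted <- params[setdiff(names(params), names(fixed))]
  cov <- as.matrix(x$covariance)
  dimnames(cov) <- list(names(fitted), names(fitted))
  tc <- digestion_timecourse(x$data$time_min, x$data$value,
                             x$data$replicate, analyte = x$data$analyte,
                             label = x$data$label)
  structure(list(model = x$model, params = params, fitted_params = fitted,
                 fixed_params = fixed, se = unlist(x$se), covariance = cov,
                 sse = x$sse, n_obs = x$n_obs, r_squared = x$r_squared,
                 r2_adjusted = x$r2_adjusted, time_range = x$time_range,
                 data = tc, converged = x$converged),
            class = "kinetic_fit")
}
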