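#' Digestion (or softening) time course
#'
#' Tube-level observations of a digested-percent (or hardness, N) quantity
#' over small-intestinal digestion time. Replicates are individual,
#' independent reaction tubes; they enter model fits individually, never as
#' per-time means.
#'
#' @param time_min Observation times (min), >= 0.
#' @param value Observed values (percent digested, or N for hardness).
#' @param replicate Replicate/tube identifier (recycled).
#' @param analyte One of `"starch"`, `"soluble_protein"`,
#'   `"bioaccessible_protein"`, `"hardness"`.
#' @param label Sample label.
#' @return Object of class `digestion_timecourse`: a data frame with columns
#'   `time_min`, `value`, `replicate` plus `analyte`/`label` attributes.
#' @export
digestion_timecourse <- function(time_min, value, replicate = 1L,
                                 analyte = c("starch", "soluble_protein",
                                             "bioaccessible_protein",
                                             "hardness"),
                                 label = "") {
  analyte <- match.arg(analyte)
  if (length(time_min) != length(value))
    stop_pk("time_min and value lengths differ", class = "invalid_timecourse")
  if (any(!is.finite(time_min)) || any(time_min < 0))
    stop_pk("times must be finite and >= 0", class = "invalid_timecourse")
  if (any(!is.finite(value)))
    stop_pk("values must be finite", class = "invalid_timecourse")
  df <- data.frame(time_min = time_min, value = value,
                   replicate = rep_len(replicate, length(value)))
  structure(df, analyte = analyte, label = label,
            class = c("digestion_timecourse", "data.frame"))
}

#' Fractional conversion model
#'
#' First-order kinetics towards a non-zero plateau:
#' `C(t) = Cf + (Ci - Cf) * exp(-k t)`. Describes hardness decay during
#' cooking and starch/protein digestion curves without a lag phase.
#'
#' @param t Time (min), >= 0.
#' @param Ci Value at t = 0 (percent, or N for hardness).
#' @param Cf Plateau value at extended times.
#' @param k Reaction rate constant (1/min), > 0.
#' @return Model value(s) at `t`.
#' @examples
#' eval_fractional_conversion(30, Ci = 0, Cf = 100, k = log(2) / 30)  # 50
#' @export
eval_fractional_conversion <- function(t, Ci, Cf, k) {
  stopifnot(k > 0, all(t >= 0))
  Cf + (Ci - Cf) * exp(-k * t)
}

#' Lag-phase logistic model
#'
#' Logistic digestion curve parameterised by its plateau, maximum rate and
#' lag duration:
#' `C(t) = Cf / (1 + exp(4 kmax / Cf * (lambda - t) + 2))`,
#' with `Cf` the plateau (percent), `kmax` the maximum (inflection-point)
#' rate in percent/min, and `lambda` the lag phase (min) defined by the
#' intercept of the inflection tangent with the time axis.
#'
#' @param t Time (min).
#' @param Starchf Plateau digested percent, > 0.
#' @param kmax Maximum reaction rate (percent/min), > 0.
#' @param lambda Lag-phase duration (min), >= 0.
#' @return Model value(s) at `t`.
#' @examples
#' eval_logistic(11, Starchf = 100, kmax = 1.3, lambda = 11)  # 100/(1+e^2)
#' @export
eval_logistic <- function(t, Starchf, kmax, lambda) {
  stopifnot(Starchf > 0, kmax > 0, lambda >= 0)
  Starchf / (1 + exp(4 * kmax / Starchf * (lambda - t) + 2))
}

model_fun <- function(model) {
  switch(model,
         fractional_conversion = function(t, p)
           p[["Cf"]] + (p[["Ci"]] - p[["Cf"]]) * exp(-p[["k"]] * t),
         logistic = function(t, p)
           p[["Starchf"]] /
             (1 + exp(4 * p[["kmax"]] / p[["Starchf"]] * (p[["lambda"]] - t) + 2)),
         stop_pk("unknown model: ", model, class = "invalid_model"))
}

# Heuristic starting values from the data (per-time means).
start_values <- function(times, values, model, fix_ci) {
  tm <- sort(unique(times))
  ybar <- vapply(tm, function(tt) mean(values[times == tt]), numeric(1))
  rng <- diff(range(values))
  if (rng == 0) rng <- max(abs(values), 1)
  if (model == "fractional_conversion") {
    Ci0 <- if (!is.null(fix_ci)) fix_ci else ybar[1L]
    Cf0 <- ybar[length(ybar)]
    if (abs(Cf0 - Ci0) < 1e-8 * rng) Cf0 <- Ci0 + rng
    # log-linearise the first two thirds of the curve for k
    idx <- seq_len(max(3L, ceiling(2 * length(tm) / 3)))
    z <- (Cf0 - ybar[idx]) / (Cf0 - Ci0)
    ok <- is.finite(z) & z > 1e-8 & tm[idx] >= 0
    k0 <- if (sum(ok) >= 2) {
      sl <- stats::coef(stats::lm(log(z[ok]) ~ tm[idx][ok]))[2L]
      max(min(-unname(sl), 1), 1e-4)
    } else 0.02
    p <- c(Ci = Ci0, Cf = Cf0, k = k0)
    if (!is.null(fix_ci)) p <- p[c("Cf", "k")]
    p
  } else {
    Sf0 <- max(max(ybar), 1e-3) * 1.02
    sl <- diff(ybar) / diff(tm)
    kmax0 <- max(max(sl, na.rm = TRUE), 1e-3)
    above <- tm[ybar > 0.12 * Sf0]
    lambda0 <- if (length(above)) max(min(above), 0) else 0
    c(Starchf = Sf0, kmax = kmax0, lambda = lambda0)
  }
}

param_bounds <- function(pnames) {
  lower <- c(Ci = -Inf, Cf = -Inf, k = 1e-8,
             Starchf = 1e-8, kmax = 1e-8, lambda = 0)
  upper <- c(Ci = Inf, Cf = Inf, k = Inf,
             Starchf = Inf, kmax = Inf, lambda = Inf)
  list(lower = unname(lower[pnames]), upper = unname(upper[pnames]))
}

# Deterministic Latin-hypercube perturbations of the heuristic start.
multistart_points <- function(start, n_starts, data_range) {
  if (n_starts <= 1L) return(matrix(start, nrow = 1L,
                                    dimnames = list(NULL, names(start))))
  p <- length(start)
  u <- withr::with_seed(20220117L, lhs::randomLHS(n_starts - 1L, p))
  pts <- matrix(NA_real_, n_starts, p, dimnames = list(NULL, names(start)))
  pts[1L, ] <- start
  for (j in seq_len(p)) {
    nm <- names(start)[j]
    if (nm %in% c("k", "kmax")) {
      # log-uniform between 0.2x and 5x the heuristic rate
      pts[-1L, j] <- start[j] * exp((u[, j] * 2 - 1) * log(5))
    } else if (nm == "lambda") {
      pts[-1L, j] <- u[, j] * max(3 * start[j], 30)
    } else {
      pts[-1L, j] <- start[j] + (u[, j] * 2 - 1) * 0.5 * data_range
    }
  }
  pts
}

#' Fit a kinetic model to a digestion time course
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with a deterministic Latin-hypercube multistart around
#' data-driven starting values. All tube-level observations enter the sum of
#' squares individually. Standard errors and the parameter covariance come
#' from the Jacobian at the optimum
#' (`cov = SSE / (n - p) * (J'J)^-1`).
#'
#' @param tc A [digestion_timecourse()] with >= 5 distinct times.
#' @param model `"fractional_conversion"` or `"logistic"`.
#' @param fix_ci Optional fixed value for `Ci` (fractional conversion only).
#'   Starch digestion is conventionally fitted with `fix_ci = 0`: with
#'   salivary amylase substituted by water no starch is digested at t = 0.
#' @param n_starts Number of multistart points (default 10).
#' @return Object of class `kinetic_fit`: list with `model`, `params`
#'   (all model parameters, fixed ones included), `fitted_params`,
#'   `fixed_params`, `se`, `covariance`, `sse`, `n_obs`, `r_squared`,
#'   `r2_adjusted`, `time_range`, `data`, `converged`.
#' @examples
#' tc <- generate_digestion_timecourse("CP_ICC_30", "starch",
#'                                     noise_sd = 0, seed = 1)
#' fit <- fit_kinetic_model(tc, "fractional_conversion", fix_ci = 0)
#' coef(fit)
#' @export
fit_kinetic_model <- function(tc, model = c("fractional_conversion", "logistic"),
                              fix_ci = NULL, n_starts = 10L) {
  model <- match.arg(model)
  stopifnot(inherits(tc, "digestion_timecourse"))
  if (!is.null(fix_ci) && model != "fractional_conversion")
    stop_pk("fix_ci only applies to the fractional conversion model",
            class = "invalid_model")
  times <- tc$time_min
  values <- tc$value
  if (length(unique(times)) < 5L)
    stop_pk("need >= 5 distinct times to fit, got ", length(unique(times)),
            class = "invalid_timecourse")
  fixed <- if (!is.null(fix_ci)) c(Ci = fix_ci) else numeric(0)
  fn <- model_fun(model)
  resid_fn <- function(theta) {
    values - fn(times, c(theta, fixed))
  }
  start <- start_values(times, values, model, fix_ci)
  n <- length(values)
  p <- length(start)
  if (n <= p)
    stop_pk("n = ", n, " observations cannot identify ", p, " parameters",
            class = "fit_failure")
  bounds <- param_bounds(names(start))
  starts <- multistart_points(start, n_starts, diff(range(values)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(starts[i, ], bounds$lower), bounds$upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = bounds$lower, upper = bounds$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop_pk("kinetic fit failed to converge from any start",
            class = "fit_failure")
  theta <- stats::setNames(best$par, names(start))
  sse <- best$deviance
  # Jacobian-based covariance at the optimum
  J <- pracma::jacobian(function(th) fn(times, c(stats::setNames(th, names(theta)),
                                                 fixed)), theta)
  sigma2 <- sse / (n - p)
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ),
                  error = function(e) sigma2 * pracma::pinv(JtJ))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(theta), names(theta))
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot > 0) 1 - sse / ss_tot else NA_real_
  r2_adj <- if (!is.na(r2) && n - p - 1 > 0)
    1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  structure(list(model = model,
                 params = c(theta, fixed)[full_param_names(model)],
                 fitted_params = theta,
                 fixed_params = fixed,
                 se = stats::setNames(sqrt(pmax(diag(cov), 0)), names(theta)),
                 covariance = cov,
                 sse = sse,
                 n_obs = n,
                 r_squared = r2,
                 r2_adjusted = r2_adj,
                 time_range = range(times),
                 data = tc,
                 converged = best$info %in% 1:4),
            class = "kinetic_fit")
}

full_param_names <- function(model) {
  if (model == "fractional_conversion") c("Ci", "Cf", "k")
  else c("Starchf", "kmax", "lambda")
}

#' @export
coef.kinetic_fit <- function(object, ...) object$params

#' @export
predict.kinetic_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_min
  model_fun(object$model)(times, object$params)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit:", x$model, "\n")
  est <- x$params[names(x$fitted_params)]
  tab <- data.frame(estimate = round(est, 4),
                    se = round(x$se, 4))
  print(tab)
  if (length(x$fixed_params))
    cat("fixed:", paste(names(x$fixed_params), "=", x$fixed_params,
                        collapse = ", "), "\n")
  cat(sprintf("SSE %.4g on %d obs; R2_adj %.4f\n",
              x$sse, x$n_obs, x$r2_adjusted))
  invisible(x)
}

#' Initial reaction rate (tangent slope at t = 0)
#'
#' Analytic derivative of the fitted curve at the start of the reaction.
#' Fractional conversion: `k * (Cf - Ci)`. Logistic:
#' `4 kmax e^(u0) / (1 + e^(u0))^2` with `u0 = 4 kmax lambda / Cf + 2`.
#'
#' @param fit A `kinetic_fit`.
#' @return Initial rate in percent/min (or N/min for hardness).
#' @export
initial_reaction_rate <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  p <- fit$params
  if (fit$model == "fractional_conversion") {
    unname(p[["k"]] * (p[["Cf"]] - p[["Ci"]]))
  } else {
    u0 <- 4 * p[["kmax"]] * p[["lambda"]] / p[["Starchf"]] + 2
    unname(4 * p[["kmax"]] * exp(u0) / (1 + exp(u0))^2)
  }
}

#' Corrected Akaike information criterion of a kinetic fit
#'
#' Gaussian-likelihood AICc with the noise variance counted as a parameter:
#' `n log(SSE/n) + 2 p' + 2 p'(p'+1)/(n - p' - 1)` with
#' `p' = #fitted parameters + 1`.
#'
#' @param fit A `kinetic_fit`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  n <- fit$n_obs
  p <- length(fit$fitted_params) + 1
  n * log(fit$sse / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Discriminate between lag-phase and first-order digestion models
#'
#' Fits both the fractional conversion and the logistic model and selects
#' the logistic only if (a) the estimated lag phase is positive with its 95%
#' confidence interval excluding zero and (b) the logistic has the lower
#' corrected AIC. Otherwise the fractional conversion model is retained
#' ("no meaningful lag estimate").
#'
#' @param tc A [digestion_timecourse()].
#' @param fix_ci Fixed `Ci` for the fractional conversion fit (default 0,
#'   the starch-digestion convention).
#' @return List with `choice` (`"logistic"` or `"fractional_conversion"`),
#'   `fits` (both fits, `NULL` where a fit failed), and `diagnostics`
#'   (lambda estimate, its CI, both AICc values, failure flags).
#' @export
discriminate_models <- function(tc, fix_ci = 0) {
  fit_fc <- tryCatch(fit_kinetic_model(tc, "fractional_conversion",
                                       fix_ci = fix_ci),
                     error = function(e) NULL)
  fit_lg <- tryCatch(fit_kinetic_model(tc, "logistic"),
                     error = function(e) NULL)
  if (is.null(fit_fc) && is.null(fit_lg))
    stop_pk("both model fits failed", class = "fit_failure")
  diag <- list(lambda = NA_real_, lambda_ci = c(NA_real_, NA_real_),
               aicc_fc = if (!is.null(fit_fc)) aicc(fit_fc) else NA_real_,
               aicc_logistic = if (!is.null(fit_lg)) aicc(fit_lg) else NA_real_,
               fc_failed = is.null(fit_fc), logistic_failed = is.null(fit_lg))
  if (is.null(fit_fc)) {
    warn_pk("fractional conversion fit failed; returning logistic",
            class = "fit_failure_partial")
    return(list(choice = "logistic", fits = list(fractional_conversion = NULL,
                                                 logistic = fit_lg),
                diagnostics = diag))
  }
  if (is.null(fit_lg)) {
    warn_pk("logistic fit failed; returning fractional conversion",
            class = "fit_failure_partial")
    return(list(choice = "fractional_conversion",
                fits = list(fractional_conversion = fit_fc, logistic = NULL),
                diagnostics = diag))
  }
  lam <- fit_lg$params[["lambda"]]
  se <- fit_lg$se[["lambda"]]
  tq <- stats::qt(0.975, fit_lg$n_obs - length(fit_lg$fitted_params))
  ci <- c(lam - tq * se, lam + tq * se)
  diag$lambda <- lam
  diag$lambda_ci <- ci
  lag_significant <- lam > 0 && ci[1L] > 0
  choice <- if (lag_significant && diag$aicc_logistic < diag$aicc_fc)
    "logistic" else "fractional_conversion"
  list(choice = choice,
       fits = list(fractional_conversion = fit_fc, logistic = fit_lg),
       diagnostics = diag)
}

#' Normalized starch-protein digestion correlation
#'
#' Evaluates two fitted digestion curves on a common time grid, normalizes
#' each by its own plateau (`Cf` or `Starchf`, mapping both curves onto the
#' unit interval), and correlates the paired trajectories.
#'
#' @param starch_fit,protein_fit Converged `kinetic_fit` objects.
#' @param grid Time grid (min) on which to evaluate both curves.
#' @return List with `times`, `starch_norm`, `protein_norm` and `pearson_r`.
#' @export
normalized_digestion_correlation <- function(starch_fit, protein_fit,
                                             grid = seq(0, 180, by = 5)) {
  plateau <- function(fit) {
    p <- if (fit$model == "fractional_conversion") fit$params[["Cf"]]
         else fit$params[["Starchf"]]
    if (p <= 0) stop_pk("plateau parameter must be > 0 to normalize, got ",
                        p, class = "invalid_plateau")
    p
  }
  s <- predict(starch_fit, grid) / plateau(starch_fit)
  pr <- predict(protein_fit, grid) / plateau(protein_fit)
  list(times = grid, starch_norm = s, protein_norm = pr,
       pearson_r = stats::cor(s, pr))
}
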