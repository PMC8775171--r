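#' Wrap an arbitrary least-squares fit for joint-confidence-region analysis
#'
#' [jcr_boundary()] only needs an SSE surface, the point estimate, standard
#' errors (to scale the search grid), the optimal SSE and the number of
#' observations. This constructor packages those for models fitted outside
#' [fit_kinetic_model()] (e.g. a straight-line calibration fit).
#'
#' @param sse_fn Function mapping a full named parameter vector to the SSE.
#' @param estimate Named vector of least-squares estimates.
#' @param se Named vector of standard errors (same names).
#' @param sse SSE at the optimum.
#' @param n_obs Number of observations.
#' @return Object of class `sse_surface_fit`.
#' @export
sse_surface_fit <- function(sse_fn, estimate, se, sse, n_obs) {
  stopifnot(is.function(sse_fn), length(estimate) == length(se),
            !is.null(names(estimate)))
  structure(list(sse_fn = sse_fn, fitted_params = estimate, se = se,
                 sse = sse, n_obs = n_obs),
            class = "sse_surface_fit")
}

fit_sse_fn <- function(fit) {
  if (inherits(fit, "sse_surface_fit")) return(fit$sse_fn)
  fn <- model_fun(fit$model)
  times <- fit$data$time_min
  values <- fit$data$value
  fixed <- fit$fixed_params
  function(theta) sum((values - fn(times, c(theta, fixed)))^2)
}

jcr_threshold <- function(sse_opt, n, p, alpha, df_convention) {
  df2 <- if (df_convention == "n-1") n - 1 else n - p
  sse_opt * (1 + p / (n - p) * stats::qf(1 - alpha, p, df2))
}

#' Joint confidence region boundary for a parameter pair
#'
#' SSE-contour (F-ratio) region for two simultaneously estimated
#' parameters. The region is the set of pair values whose SSE — with any
#' remaining parameters fixed at their estimates (default) or re-optimised
#' (`profile = TRUE`) — does not exceed
#' `SSE(est) * (1 + p/(n-p) * F(p, df2, 1-alpha))` with `p = 2`.
#' The conventional second F degree of freedom is `n - p`
#' (`df_convention = "n-p"`, the default); `"n-1"` reproduces the variant
#' sometimes printed in the food-kinetics literature (numerically close for
#' the sample sizes involved).
#'
#' The boundary is extracted as the contour of the SSE surface on a grid
#' centred at the estimates; the grid is auto-expanded (doubling, up to
#' `max_expand` times) until the contour closes inside it.
#'
#' @param fit A `kinetic_fit` or [sse_surface_fit()].
#' @param pair Character vector of the two parameter names (default the
#'   first two fitted parameters).
#' @param alpha Significance level (default 0.05).
#' @param grid_points Grid resolution per axis (default 201).
#' @param expand Initial half-width of the grid in units of each
#'   parameter's standard error (default 6).
#' @param df_convention `"n-p"` or `"n-1"` (see Details).
#' @param profile Re-optimise nuisance parameters at every grid node
#'   instead of fixing them at their estimates.
#' @param max_expand Maximum number of grid doublings before giving up.
#' @return Object of class `jcr_region`: `param_pair`, `alpha`,
#'   `sse_threshold`, `sse_optimum`, `boundary` (closed two-column matrix),
#'   `estimate`, `grid_range`, `df_convention`, and the SSE function used.
#' @export
jcr_boundary <- function(fit, pair = NULL, alpha = 0.05, grid_points = 201L,
                         expand = 6, df_convention = c("n-p", "n-1"),
                         profile = FALSE, max_expand = 5L) {
  df_convention <- match.arg(df_convention)
  est_all <- fit$fitted_params
  if (is.null(pair)) pair <- names(est_all)[1:2]
  if (!all(pair %in% names(est_all)))
    stop_pk("pair must name fitted parameters; have: ",
            paste(names(est_all), collapse = ", "), class = "invalid_pair")
  p <- 2L
  n <- fit$n_obs
  threshold <- jcr_threshold(fit$sse, n, p, alpha, df_convention)
  sse_full <- fit_sse_fn(fit)
  nuisance <- setdiff(names(est_all), pair)
  sse_pair <- if (!length(nuisance)) {
    function(xy) sse_full(stats::setNames(xy, pair))
  } else if (!profile) {
    function(xy) sse_full(c(stats::setNames(xy, pair), est_all[nuisance]))
  } else {
    function(xy) {
      res <- stats::optim(est_all[nuisance], function(nu)
        sse_full(c(stats::setNames(xy, pair), stats::setNames(nu, nuisance))),
        method = "BFGS")
      res$value
    }
  }
  se <- pmax(fit$se[pair], 1e-8 * pmax(abs(est_all[pair]), 1))
  center <- est_all[pair]
  half <- expand * se
  for (attempt in seq_len(max_expand + 1L)) {
    x <- seq(center[1L] - half[1L], center[1L] + half[1L],
             length.out = grid_points)
    y <- seq(center[2L] - half[2L], center[2L] + half[2L],
             length.out = grid_points)
    z <- matrix(NA_real_, grid_points, grid_points)
    for (j in seq_along(y)) z[, j] <- vapply(x, function(xi)
      sse_pair(c(xi, y[j])), numeric(1))
    cl <- grDevices::contourLines(x, y, z, levels = threshold)
    if (length(cl)) {
      eps_x <- diff(range(x)) * 1e-9
      eps_y <- diff(range(y)) * 1e-9
      for (ct in cl) {
        touches <- any(ct$x <= min(x) + eps_x | ct$x >= max(x) - eps_x |
                       ct$y <= min(y) + eps_y | ct$y >= max(y) - eps_y)
        if (touches) next
        inside <- pracma::inpolygon(center[1L], center[2L], ct$x, ct$y)
        if (!inside) next
        boundary <- cbind(ct$x, ct$y)
        boundary <- rbind(boundary, boundary[1L, ])
        colnames(boundary) <- pair
        return(structure(list(param_pair = pair, alpha = alpha,
                              sse_threshold = threshold,
                              sse_optimum = fit$sse,
                              boundary = boundary,
                              estimate = center,
                              grid_range = list(x = range(x), y = range(y)),
                              grid_points = grid_points,
                              df_convention = df_convention,
                              sse_pair_fn = sse_pair),
                         class = "jcr_region"))
      }
    }
    half <- half * 2
  }
  stop_pk("joint confidence region did not close within the search grid; ",
          "increase `expand` or `max_expand`", class = "jcr_open")
}

#' @export
print.jcr_region <- function(x, ...) {
  cat(sprintf("Joint confidence region (alpha = %g, F df convention %s)\n",
              x$alpha, x$df_convention))
  cat(sprintf("  pair (%s, %s): estimate (%.5g, %.5g)\n", x$param_pair[1L],
              x$param_pair[2L], x$estimate[1L], x$estimate[2L]))
  cat(sprintf("  SSE optimum %.5g, threshold %.5g, area %.5g\n",
              x$sse_optimum, x$sse_threshold, jcr_area(x)))
  invisible(x)
}

#' Area enclosed by a joint confidence region boundary
#'
#' @param region A `jcr_region`.
#' @return Area in the product of the two parameters' units.
#' @export
jcr_area <- function(region) {
  stopifnot(inherits(region, "jcr_region"))
  polygon_area(region$boundary)
}

#' Membership test for a joint confidence region
#'
#' Tests whether a parameter pair lies inside the SSE-ratio region of a fit
#' directly (no contour extraction): the point is covered when its SSE does
#' not exceed the F-ratio threshold. Used for coverage simulations.
#'
#' @param fit A `kinetic_fit` or [sse_surface_fit()].
#' @param point Named (or ordered) values of the two parameters.
#' @param pair Parameter pair (default the first two fitted parameters).
#' @inheritParams jcr_boundary
#' @return Logical.
#' @export
jcr_covers <- function(fit, point, pair = NULL, alpha = 0.05,
                       df_convention = c("n-p", "n-1")) {
  df_convention <- match.arg(df_convention)
  est_all <- fit$fitted_params
  if (is.null(pair)) pair <- names(est_all)[1:2]
  threshold <- jcr_threshold(fit$sse, fit$n_obs, 2L, alpha, df_convention)
  sse_full <- fit_sse_fn(fit)
  nuisance <- setdiff(names(est_all), pair)
  theta <- c(stats::setNames(unname(point[seq_along(pair)]), pair),
             est_all[nuisance])
  sse_full(theta) <= threshold
}

#' Overlap between two joint confidence regions
#'
#' Rasterised polygon-intersection test over the union bounding box. The
#' overlap area fraction is reported relative to the smaller region, making
#' the qualitative "regions overlap, hence similar kinetics" call explicit.
#'
#' @param a,b `jcr_region` objects for the same parameter pair.
#' @param resolution Raster resolution per axis (default 250).
#' @return List with `overlaps` (logical) and `overlap_area_fraction`.
#' @export
jcr_overlap <- function(a, b, resolution = 250L) {
  stopifnot(inherits(a, "jcr_region"), inherits(b, "jcr_region"))
  if (!identical(a$param_pair, b$param_pair))
    stop_pk("regions are for different parameter pairs: (",
            paste(a$param_pair, collapse = ", "), ") vs (",
            paste(b$param_pair, collapse = ", "), ")",
            class = "invalid_pair")
  xr <- range(a$boundary[, 1L], b$boundary[, 1L])
  yr <- range(a$boundary[, 2L], b$boundary[, 2L])
  # quick reject on bounding boxes
  if (max(a$boundary[, 1L]) < min(b$boundary[, 1L]) ||
      max(b$boundary[, 1L]) < min(a$boundary[, 1L]) ||
      max(a$boundary[, 2L]) < min(b$boundary[, 2L]) ||
      max(b$boundary[, 2L]) < min(a$boundary[, 2L]))
    return(list(overlaps = FALSE, overlap_area_fraction = 0))
  x <- seq(xr[1L], xr[2L], length.out = resolution)
  y <- seq(yr[1L], yr[2L], length.out = resolution)
  gx <- rep(x, times = resolution)
  gy <- rep(y, each = resolution)
  in_a <- pracma::inpolygon(gx, gy, a$boundary[, 1L], a$boundary[, 2L])
  in_b <- pracma::inpolygon(gx, gy, b$boundary[, 1L], b$boundary[, 2L])
  cell <- diff(x[1:2]) * diff(y[1:2])
  overlap_area <- sum(in_a & in_b) * cell
  smaller <- min(jcr_area(a), jcr_area(b))
  list(overlaps = overlap_area > 0,
       overlap_area_fraction = if (smaller > 0) overlap_area / smaller else 0)
}
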