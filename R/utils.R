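#' @keywords internal
"_PACKAGE"

# Numeric scalar check used by most constructors; NA allowed only on request.
is_number <- function(x, allow_na = FALSE) {
  is.numeric(x) && length(x) == 1L && (allow_na || (!is.na(x) && is.finite(x)))
}

stop_pk <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "pulsekinetics_error")))
}

warn_pk <- function(..., class) {
  warning(warningCondition(paste0(...), class = c(class, "pulsekinetics_warning")))
}

# Centered 3-point moving average with shrinking windows at the edges.
moving_average3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  out <- y
  out[1L] <- mean(y[1:2])
  out[n] <- mean(y[(n - 1L):n])
  out[2:(n - 1L)] <- (y[1:(n - 2L)] + y[2:(n - 1L)] + y[3:n]) / 3
  out
}

# Shoelace polygon area (absolute), closed or open vertex list.
polygon_area <- function(xy) {
  abs(pracma::polyarea(xy[, 1L], xy[, 2L]))
}
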