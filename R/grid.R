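#' Discretized concentration axis
#'
#' The candidate marker concentration is discretized into equal-width
#' intervals; inference is carried out on the interval midpoints. The default
#' grid spans 0 to 3000 copies/L with midpoints every 5 copies/L (601
#' intervals, half-width `delta` = 2.5 copies/L). The upper bound is chosen so
#' the survey protocol's sensitivity saturates at 1 at the top of the grid:
#' above it, every water sample would test positive and positive fractions
#' would carry no concentration information.
#'
#' @param theta_min Lower bound (copies/L). Default 0, the physical minimum.
#' @param theta_max Upper bound (copies/L). Default 3000.
#' @param step Midpoint spacing (copies/L) = full interval width. Default 5.
#' @return An object of class `concentration_grid` with elements
#'   `theta_min`, `theta_max`, `midpoints`, `delta`.
#' @examples
#' g <- concentration_grid()
#' length(g$midpoints)  # 601
#' g$delta              # 2.5
#' @export
concentration_grid <- function(theta_min = 0, theta_max = 3000, step = 5) {
  theta_min <- as.numeric(theta_min)
  theta_max <- as.numeric(theta_max)
  step <- as.numeric(step)
  if (!is.finite(theta_min) || !is.finite(theta_max) || !is.finite(step))
    stop("grid bounds and step must be finite")
  if (theta_min < 0) stop("theta_min must be >= 0")
  if (theta_max <= theta_min) stop("theta_max must exceed theta_min")
  if (step <= 0) stop("step must be > 0")
  n_span <- (theta_max - theta_min) / step
  if (abs(n_span - round(n_span)) > 1e-9)
    stop("grid span must be an integer multiple of step")
  g <- list(
    theta_min = theta_min,
    theta_max = theta_max,
    midpoints = theta_min + step * seq.int(0L, round(n_span)),
    delta = step / 2
  )
  class(g) <- "concentration_grid"
  g
}

#' @export
print.concentration_grid <- function(x, ...) {
  cat(sprintf(
    "Concentration grid: %d interval midpoints on [%g, %g] copies/L (delta = %g)\n",
    length(x$midpoints), x$theta_min, x$theta_max, x$delta))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$midpoints, b$midpoints, tolerance = 0)) &&
    a$delta == b$delta
}
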