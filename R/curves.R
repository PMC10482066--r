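#' Uniformly sampled curve
#'
#' Numeric carrier for continuous-time curves (AIFs, dispersed signals,
#' background patterns) on a uniform fine grid.
#'
#' @param grid Strictly increasing, uniformly spaced times (seconds).
#' @param values Finite numeric values, one per grid point.
#' @return An object of class `sampled_curve`.
#' @export
sampled_curve <- function(grid, values) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values) || length(grid) < 2L)
    stop("grid and values must have equal length >= 2")
  dt <- diff(grid)
  if (any(dt <= 0) || diff(range(dt)) > 1e-8 * mean(dt))
    stop("grid must be uniform and strictly increasing")
  if (any(!is.finite(values))) stop("curve values must be finite")
  structure(list(grid = grid, values = values, dt = mean(dt)),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("sampled curve: %d points on [%.3g, %.3g] s (dt = %.3g), peak %.4g\n",
              length(x$grid), x$grid[1L], x$grid[length(x$grid)], x$dt,
              max(x$values)))
  invisible(x)
}

#' Default fine evaluation grid for a study
#'
#' The grid starts at 0 and extends a little beyond the study end. The step
#' adapts to the study duration so that short bolus studies are resolved at
#' 0.05 s while long studies use a coarser step, keeping the grid around
#' 6000-7000 points.
#'
#' @param study_end End of the study (seconds).
#' @param dt Optional explicit step (seconds).
#' @return Numeric grid vector starting at 0.
#' @export
default_grid <- function(study_end, dt = NULL) {
  if (!is.finite(study_end) || study_end <= 0) stop("study_end must be positive")
  if (is.null(dt)) dt <- min(1, max(0.05, study_end / 6000))
  seq(0, study_end * 1.02 + dt, by = dt)
}

#' Interpolate a sampled curve
#'
#' Linear interpolation; zero for `t < 0` and before the first grid point,
#' constant extension beyond the last grid point.
#'
#' @param curve A [sampled_curve()].
#' @param t Times (seconds).
#' @return Interpolated values.
#' @export
curve_value <- function(curve, t) {
  stopifnot(inherits(curve, "sampled_curve"))
  v <- stats::approx(curve$grid, curve$values, xout = t,
                     yleft = 0, rule = c(1, 2))$y
  v[t < curve$grid[1L]] <- 0
  v
}

#' Mono-exponential dispersion of a curve
#'
#' Convolution with the dispersion kernel `E_phi(u) = exp(-u/phi)/phi`,
#' the Kety-Schmidt vascular smearing model. Computed by the exact recursive
#' update for an exponential kernel applied to the piecewise-linear
#' interpolant of the input on its uniform grid: causal, unconditionally
#' stable for any `phi > 0`, and mass-preserving up to truncation of the
#' kernel tail at the end of the grid.
#'
#' @param curve A [sampled_curve()], assumed zero for `t < grid[1]`.
#' @param phi Dispersion time constant (seconds), `> 0`.
#' @return Dispersed [sampled_curve()] on the same grid.
#' @export
disperse <- function(curve, phi) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (!is.finite(phi) || phi <= 0) stop("phi must be a positive time constant")
  sampled_curve(curve$grid, exp_kernel_filter(curve$values, curve$dt, phi))
}

# Exact recursion for y = E_phi * x with x piecewise linear on a uniform grid.
# With a = exp(-dt/phi) and r = (phi/dt) * (1 - a):
#   y[n] = a * y[n-1] + (r - a) * x[n-1] + (1 - r) * x[n],  y[1] = 0.
# Accepts a matrix and filters each column (compiled inner loop).
exp_kernel_filter <- function(x, dt, phi) {
  a <- exp(-dt / phi)
  r <- (phi / dt) * (1 - a)
  if (is.matrix(x)) exp_filter_cpp(x, a, r)
  else as.numeric(exp_filter_cpp(matrix(x, ncol = 1L), a, r))
}

# fast linear interpolation of matrix columns sampled on a uniform grid:
# zero below the grid start, constant extension beyond the end
interp_cols <- function(grid, M, times) {
  dt <- grid[2L] - grid[1L]
  n <- nrow(M)
  pos <- (times - grid[1L]) / dt
  pos <- pmin(pmax(pos, -1), n - 1)
  i0 <- floor(pos)
  frac <- pos - i0
  lo <- i0 < 0
  i0[lo] <- 0
  i1 <- as.integer(i0) + 1L
  i2 <- pmin(i1 + 1L, n)
  out <- M[i1, , drop = FALSE] * (1 - frac) + M[i2, , drop = FALSE] * frac
  if (any(lo)) out[lo, ] <- 0
  out
}

#' Time-shift a curve
#'
#' Returns the curve delayed by `delta`: `y(t) = x(t - delta)`, zero where
#' `t - delta` falls before the grid origin. Negative `delta` advances the
#' curve. Values between grid points are obtained by linear interpolation,
#' so non-integer multiples of the grid step are supported.
#'
#' @param curve A [sampled_curve()].
#' @param delta Shift (seconds).
#' @return Shifted [sampled_curve()] on the same grid.
#' @export
shift_curve <- function(curve, delta) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (delta == 0) return(curve)
  sampled_curve(curve$grid, curve_value(curve, curve$grid - delta))
}

#' Cumulative integral of a curve
#'
#' Running trapezoid integral from the grid origin; used for Patlak-style
#' background patterns and spillover terms.
#'
#' @param curve A [sampled_curve()].
#' @return A [sampled_curve()] of the cumulative integral.
#' @export
curve_cumint <- function(curve) {
  stopifnot(inherits(curve, "sampled_curve"))
  v <- curve$values
  n <- length(v)
  inc <- curve$dt * (v[-1L] + v[-n]) / 2
  sampled_curve(curve$grid, c(0, cumsum(inc)))
}

#' Definite integral of a curve over an interval
#'
#' @param curve A [sampled_curve()].
#' @param from,to Integration limits (seconds); defaults to the whole grid.
#' @return Trapezoid integral of the interpolated curve.
#' @export
curve_integral <- function(curve, from = NULL, to = NULL) {
  stopifnot(inherits(curve, "sampled_curve"))
  g <- curve$grid
  if (is.null(from)) from <- g[1L]
  if (is.null(to)) to <- g[length(g)]
  if (to <= from) return(0)
  inside <- g[g > from & g < to]
  xs <- c(from, inside, to)
  trapz_integral(xs, curve_value(curve, xs))
}
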