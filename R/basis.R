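#' Knot vector for the impulse-response basis
#'
#' Knots `0 = t_0 < t_1 < ... < t_K` define `K` piecewise-linear basis
#' elements (see [basis_eval()]). The last knot must lie beyond the temporal
#' duration of the study the basis is built for, so that the slowest basis
#' element is still declining at the end of the data.
#'
#' @param knots Strictly increasing numeric vector starting at 0 (seconds).
#' @return An object of class `knot_vector`. `K`, the number of basis
#'   elements, is `length(knots) - 1`.
#' @export
knot_vector <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L) stop("need at least 3 knots (K >= 2 basis elements)")
  if (knots[1L] != 0) stop("first knot must be 0")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  structure(list(knots = knots, K = length(knots) - 1L), class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat(sprintf("knot vector: K = %d basis elements, knots 0 ... %.4g s\n",
              x$K, x$knots[length(x$knots)]))
  invisible(x)
}

#' Construct tracer knots by geometric spacing
#'
#' Places `K` knots geometrically from `first_knot` to `1.2 * study_end`,
#' prepended with 0. Geometric spacing concentrates resolution where the
#' impulse response changes fastest (the first tens of seconds for typical
#' tracers, whose circulation half-lives are 10-80 s) while still covering
#' the slow late decline; the last knot lies beyond the study end as
#' required.
#'
#' @param study_end Temporal duration of the PET study (seconds).
#' @param K Number of basis elements (>= 3).
#' @param first_knot First positive knot (seconds), `< study_end`.
#' @return A [knot_vector()] with `K + 1` knots.
#' @examples
#' make_knots(5400, K = 12, first_knot = 5)
#' @export
make_knots <- function(study_end, K = 12L, first_knot = 5) {
  if (K < 3L) stop("K must be at least 3")
  if (!is.finite(first_knot) || first_knot <= 0 || first_knot >= study_end)
    stop("first_knot must satisfy 0 < first_knot < study_end")
  last <- 1.2 * study_end
  pos <- exp(seq(log(first_knot), log(last), length.out = K))
  knot_vector(c(0, pos))
}

#' Piecewise-linear basis element
#'
#' Basis element `B_k` is 1 on the plateau `[0, t_{k-1})`, declines linearly
#' to 0 across `[t_{k-1}, t_k)`, and is 0 for `t >= t_k` (and for `t < 0`).
#' Any non-negative combination of these elements is non-negative and
#' non-increasing, the defining shape constraints of a circulatory impulse
#' response.
#'
#' @param knots A [knot_vector()].
#' @param k Basis index in `1..K`.
#' @param t Evaluation times (seconds).
#' @return `B_k(t)`, vectorised over `t`.
#' @export
basis_eval <- function(knots, k, t) {
  stopifnot(inherits(knots, "knot_vector"))
  if (k < 1L || k > knots$K) stop("basis index k out of range")
  t0 <- knots$knots[k]
  t1 <- knots$knots[k + 1L]
  out <- numeric(length(t))
  out[t >= 0 & t < t0] <- 1
  ramp <- t >= t0 & t < t1
  out[ramp] <- 1 - (t[ramp] - t0) / (t1 - t0)
  out
}

#' Antiderivative of a basis element
#'
#' `int_0^x B_k(u) du` in closed form (piecewise quadratic); the work-horse
#' for exact convolution of the basis with square-wave injections.
#'
#' @inheritParams basis_eval
#' @param x Upper limits (seconds); values `< 0` give 0.
#' @return Vector of integrals.
#' @export
basis_antideriv <- function(knots, k, x) {
  stopifnot(inherits(knots, "knot_vector"))
  t0 <- knots$knots[k]
  t1 <- knots$knots[k + 1L]
  h <- t1 - t0
  x <- pmax(x, 0)
  out <- numeric(length(x))
  lo <- x <= t0
  out[lo] <- x[lo]
  mid <- x > t0 & x < t1
  u <- x[mid] - t0
  out[mid] <- t0 + u - u^2 / (2 * h)
  out[x >= t1] <- (t0 + t1) / 2
  out
}

# total integral of B_k: trapezoid area of plateau + ramp
basis_integral <- function(knots, k) {
  (knots$knots[k] + knots$knots[k + 1L]) / 2
}

# first moment int t B_k(t) dt, closed form:
# plateau t0^2/2 plus ramp t0*h/2 + h^2/6
basis_t_moment <- function(knots, k) {
  t0 <- knots$knots[k]
  h <- knots$knots[k + 1L] - t0
  t0^2 / 2 + t0 * h / 2 + h^2 / 6
}

#' Impulse response
#'
#' `R(t | theta) = sum_k theta_k B_k(t)` with `theta >= 0`, guaranteeing a
#' non-negative, non-increasing impulse response.
#'
#' @param knots A [knot_vector()].
#' @param theta Non-negative coefficients, length `K`.
#' @return An object of class `impulse_response`.
#' @export
impulse_response <- function(knots, theta) {
  stopifnot(inherits(knots, "knot_vector"))
  theta <- as.numeric(theta)
  if (length(theta) != knots$K) stop("theta must have length K")
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (any(theta < -1e-10)) stop("theta must be non-negative")
  structure(list(knots = knots, theta = pmax(theta, 0)),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("impulse response: K = %d, R(0) = %.4g, integral = %.4g\n",
              x$knots$K, sum(x$theta), ir_integral(x)))
  invisible(x)
}

#' Evaluate an impulse response
#'
#' @param ir An [impulse_response()].
#' @param t Times (seconds).
#' @return `R(t)`, non-increasing over increasing `t`.
#' @export
ir_eval <- function(ir, t) {
  stopifnot(inherits(ir, "impulse_response"))
  out <- numeric(length(t))
  for (k in seq_len(ir$knots$K)) {
    if (ir$theta[k] != 0)
      out <- out + ir$theta[k] * basis_eval(ir$knots, k, t)
  }
  out
}

#' Total integral of an impulse response
#'
#' Exact closed form from the trapezoid areas of the basis elements.
#'
#' @param ir An [impulse_response()].
#' @return `int_0^Inf R(t) dt`.
#' @export
ir_integral <- function(ir) {
  stopifnot(inherits(ir, "impulse_response"))
  sum(ir$theta * (ir$knots$knots[-length(ir$knots$knots)] +
                    ir$knots$knots[-1L]) / 2)
}

#' Normalise an impulse response to unit integral
#'
#' Rescales `theta` so `int R dt = 1`, the convention under which the
#' mean residence time and contrast-ratio constraints are stated and under
#' which population summaries of impulse responses are comparable.
#'
#' @param ir An [impulse_response()].
#' @return Normalised [impulse_response()].
#' @export
normalize_ir <- function(ir) {
  tot <- ir_integral(ir)
  if (tot <= 0) stop("cannot normalise an identically zero impulse response")
  impulse_response(ir$knots, ir$theta / tot)
}

#' Mean residence time of an impulse response
#'
#' `int t R(t) dt / int R(t) dt`, in seconds; the quantity pinned by the
#' dispersion-identifiability constraint.
#'
#' @param ir An [impulse_response()].
#' @return Mean residence time (seconds).
#' @export
ir_mrt <- function(ir) {
  stopifnot(inherits(ir, "impulse_response"))
  tot <- ir_integral(ir)
  if (tot <= 0) stop("zero impulse response has no mean residence time")
  mom <- sum(ir$theta * vapply(seq_len(ir$knots$K), function(k)
    basis_t_moment(ir$knots, k), numeric(1)))
  mom / tot
}

#' Convolve a basis element or impulse response with an injection profile
#'
#' Computes `(f * C_I)(t) = int_0^t f(t - s) C_I(s) ds`. For square-wave
#' injections the convolution of a piecewise-linear `f` is piecewise
#' quadratic and is evaluated in closed form via [basis_antideriv()]:
#' `(B_k * C_I)(t) = height * (IB_k(t) - IB_k(max(0, t - d)))`. Bolus
#' injections act as a Dirac mass (`f * C_I = mass * f`); measured profiles
#' are convolved by FFT on a fine uniform grid and interpolated.
#'
#' @param object A [knot_vector()] together with `k` (single basis element),
#'   or an [impulse_response()].
#' @param injection An [injection_profile()].
#' @param eval_times Non-negative times (seconds) at which to evaluate.
#' @param k Basis index, required when `object` is a knot vector.
#' @return Vector of convolution values at `eval_times`.
#' @export
convolve_with_injection <- function(object, injection, eval_times, k = NULL) {
  stopifnot(inherits(injection, "injection_profile"))
  if (any(eval_times < 0)) stop("eval_times must be non-negative")
  if (inherits(object, "knot_vector")) {
    if (is.null(k)) stop("supply basis index k for a knot vector")
    f_eval <- function(t) basis_eval(object, k, t)
    f_anti <- function(x) basis_antideriv(object, k, x)
  } else if (inherits(object, "impulse_response")) {
    f_eval <- function(t) ir_eval(object, t)
    f_anti <- function(x) {
      out <- numeric(length(x))
      for (j in seq_len(object$knots$K)) {
        if (object$theta[j] != 0)
          out <- out + object$theta[j] * basis_antideriv(object$knots, j, x)
      }
      out
    }
  } else stop("object must be a knot_vector or impulse_response")

  switch(injection$kind,
    bolus = injection$mass * f_eval(eval_times),
    square = injection$height *
      (f_anti(eval_times) - f_anti(pmax(0, eval_times - injection$duration))),
    measured = {
      end <- max(eval_times, injection$samples[, 1L])
      grid <- default_grid(end, dt = min(0.05, end / 4000))
      ci <- injection_eval(injection, grid)
      fv <- f_eval(grid)
      conv <- grid_convolve(fv, ci, grid[2L] - grid[1L])
      stats::approx(grid, conv, xout = eval_times, rule = 2)$y
    })
}

# discrete causal convolution on a uniform grid (trapezoid weights via FFT)
grid_convolve <- function(f, g, dt) {
  n <- length(f)
  full <- stats::convolve(f, rev(g), type = "open")[seq_len(n)] * dt
  # trapezoid end-point correction: subtract half of the two end contributions
  full - dt * (f * g[1L] + f[1L] * g) / 2
}
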