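#' PET frame schedule
#'
#' A frame schedule records the acquisition frames of a dynamic PET study:
#' frame start and end times (seconds) plus the isotope decay constant used
#' for the frame weighting. Frames are half-open intervals `[start, end)`,
#' so abutting frames (end of one equal to start of the next) are valid.
#'
#' @param frame_start Numeric vector of frame start times (seconds).
#' @param frame_end Numeric vector of frame end times (seconds).
#' @param decay_constant Isotope decay constant (1/seconds); `log(2) / half-life`.
#'   Use 0 for decay-corrected weighting without a decay factor.
#' @return An object of class `frame_schedule` with elements `frame_start`,
#'   `frame_end`, `decay_constant` and derived `mid` (frame mid-times) and
#'   `dur` (frame durations).
#' @examples
#' sch <- frame_schedule(seq(0, 240, by = 60), seq(60, 300, by = 60))
#' sch$mid
#' @export
frame_schedule <- function(frame_start, frame_end, decay_constant = 0) {
  frame_start <- as.numeric(frame_start)
  frame_end <- as.numeric(frame_end)
  if (length(frame_start) != length(frame_end) || length(frame_start) == 0L)
    stop("frame_start and frame_end must be non-empty vectors of equal length")
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end)))
    stop("frame times must be finite")
  if (any(frame_end <= frame_start))
    stop("every frame must satisfy frame_end > frame_start")
  if (length(frame_start) > 1L &&
      any(frame_start[-1L] < frame_end[-length(frame_end)]))
    stop("frames must be ordered and non-overlapping")
  if (!is.numeric(decay_constant) || length(decay_constant) != 1L ||
      decay_constant < 0)
    stop("decay_constant must be a single non-negative number")
  structure(
    list(frame_start = frame_start, frame_end = frame_end,
         decay_constant = decay_constant,
         mid = (frame_start + frame_end) / 2,
         dur = frame_end - frame_start),
    class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("PET frame schedule: %d frames, %.0f-%.0f s, decay constant %.3g /s\n",
              length(x$mid), x$frame_start[1L],
              x$frame_end[length(x$frame_end)], x$decay_constant))
  invisible(x)
}

#' Build a frame schedule from a run-length description
#'
#' Convenience constructor for protocol descriptions of the form
#' "4 frames of 15 s, 4 of 30 s, ...".
#'
#' @param n_frames Integer vector, number of frames per block.
#' @param durations Numeric vector, frame duration (seconds) per block.
#' @param start Time of the first frame start (seconds).
#' @inheritParams frame_schedule
#' @return A [frame_schedule()].
#' @export
frame_schedule_blocks <- function(n_frames, durations, start = 0,
                                  decay_constant = 0) {
  if (length(n_frames) != length(durations))
    stop("n_frames and durations must have the same length")
  dur <- rep(durations, times = n_frames)
  ends <- start + cumsum(dur)
  frame_schedule(c(start, ends[-length(ends)]), ends, decay_constant)
}

#' Default frame weights
#'
#' Frame weights are taken inversely proportional to the approximate variance
#' of a decay-corrected frame activity measurement: the variance grows like
#' `exp(decay_constant * t_i) / dur_i`, so
#' `w_i = dur_i * exp(-decay_constant * t_i)`. Weights are rescaled to mean 1;
#' the overall scale of the weights does not affect the weighted
#' least-squares minimiser.
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of positive weights with mean 1.
#' @export
default_weights <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  w <- schedule$dur * exp(-schedule$decay_constant * schedule$mid)
  w / mean(w)
}

#' ROI time-activity curve
#'
#' Couples decay-corrected frame activities to a frame schedule, with
#' per-frame fitting weights.
#'
#' @param schedule A [frame_schedule()].
#' @param z Numeric vector of decay-corrected activities (e.g. kBq/ml), one
#'   per frame. Negative values are allowed (they arise in low-count data).
#' @param w Optional positive weights, one per frame; defaults to
#'   [default_weights()].
#' @return An object of class `roi_tac`.
#' @export
roi_timecourse <- function(schedule, z, w = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  z <- as.numeric(z)
  if (length(z) != length(schedule$mid))
    stop("length(z) must equal the number of frames")
  if (any(!is.finite(z))) stop("activities must be finite")
  if (is.null(w)) w <- default_weights(schedule)
  w <- as.numeric(w)
  if (length(w) != length(z)) stop("length(w) must equal the number of frames")
  if (any(!is.finite(w)) || any(w <= 0)) stop("all weights must be positive")
  structure(list(schedule = schedule, z = z, w = w), class = "roi_tac")
}

#' @export
print.roi_tac <- function(x, ...) {
  cat(sprintf("ROI time course: %d frames, peak activity %.4g at t = %.0f s\n",
              length(x$z), max(x$z), x$schedule$mid[which.max(x$z)]))
  invisible(x)
}

#' Tracer injection profile
#'
#' The known delivery wave-form `C_I(t)` of the tracer at the injection
#' site. Three kinds are supported: a square wave of given duration (constant
#' infusion), an idealised instantaneous bolus (Dirac mass), and a measured
#' profile given by sampled points.
#'
#' @param kind One of `"square"`, `"bolus"`, `"measured"`.
#' @param duration Square-wave duration `d` in seconds (square kind only).
#' @param height Square-wave height (activity rate). Defaults to
#'   `1 / duration` so the total injected mass integrates to 1.
#' @param samples Two-column matrix or data frame `(time, value)` for the
#'   measured kind; values must be non-negative. Interpolated linearly, zero
#'   outside the sampled range.
#' @param mass Total mass of an instantaneous bolus (default 1).
#' @return An object of class `injection_profile`.
#' @examples
#' injection_profile("square", duration = 60)  # 1-minute infusion
#' injection_profile("bolus")                  # idealised bolus
#' @export
injection_profile <- function(kind = c("square", "bolus", "measured"),
                              duration = NULL, height = NULL,
                              samples = NULL, mass = 1) {
  kind <- match.arg(kind)
  obj <- list(kind = kind)
  if (kind == "square") {
    if (is.null(duration) || !is.finite(duration) || duration <= 0)
      stop("square injection requires a positive duration (seconds)")
    if (is.null(height)) height <- 1 / duration
    if (height <= 0) stop("square injection height must be positive")
    obj$duration <- duration
    obj$height <- height
    obj$total <- duration * height
  } else if (kind == "bolus") {
    if (!is.finite(mass) || mass <= 0) stop("bolus mass must be positive")
    obj$mass <- mass
    obj$total <- mass
  } else {
    samples <- as.matrix(samples)
    if (is.null(samples) || ncol(samples) != 2L || nrow(samples) < 2L)
      stop("measured injection requires a two-column (time, value) table")
    if (any(!is.finite(samples))) stop("injection samples must be finite")
    if (any(samples[, 2L] < 0)) stop("injection profile must be non-negative")
    if (is.unsorted(samples[, 1L], strictly = TRUE))
      stop("injection sample times must be strictly increasing")
    obj$samples <- samples
    tot <- trapz_integral(samples[, 1L], samples[, 2L])
    if (tot <= 0) stop("measured injection must have positive total integral")
    obj$total <- tot
  }
  structure(obj, class = "injection_profile")
}

#' @export
print.injection_profile <- function(x, ...) {
  msg <- switch(x$kind,
    square = sprintf("square wave, duration %.3g s, height %.3g", x$duration, x$height),
    bolus = sprintf("instantaneous bolus, mass %.3g", x$mass),
    measured = sprintf("measured profile, %d samples", nrow(x$samples)))
  cat("Injection profile:", msg, "\n")
  invisible(x)
}

#' Evaluate an injection profile
#'
#' @param injection An [injection_profile()]. Bolus profiles have no
#'   pointwise density; evaluating one is an error (convolutions treat the
#'   bolus as a Dirac mass instead).
#' @param t Times (seconds).
#' @return `C_I(t)`, zero for `t < 0` and outside the support.
#' @export
injection_eval <- function(injection, t) {
  stopifnot(inherits(injection, "injection_profile"))
  switch(injection$kind,
    square = ifelse(t >= 0 & t < injection$duration, injection$height, 0),
    bolus = stop("an instantaneous bolus has no pointwise values; use convolution"),
    measured = {
      v <- stats::approx(injection$samples[, 1L], injection$samples[, 2L],
                         xout = t, yleft = 0, yright = 0)$y
      v[t < 0] <- 0
      v
    })
}

# trapezoid rule on possibly non-uniform abscissae
trapz_integral <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
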