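#' Read an ROI time-activity curve from CSV
#'
#' Expects columns `frame_start`, `frame_end`, `activity` and optionally
#' `weight`. Times are seconds unless the file carries a header comment
#' `# time_unit: min`. Lines beginning with `#` are treated as comments.
#' When the weight column is absent, weights are filled by
#' [default_weights()] using `decay_constant`.
#'
#' @param path CSV file path.
#' @param decay_constant Isotope decay constant (1/seconds) for default
#'   weighting; ignored when the file provides weights.
#' @return An [roi_timecourse()].
#' @export
read_tac <- function(path, decay_constant = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  unit <- read_time_unit(path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame_start", "frame_end", "activity")
  if (!all(need %in% names(df)))
    stop("TAC CSV must have columns: ", paste(need, collapse = ", "))
  fac <- if (unit == "min") 60 else 1
  sch <- frame_schedule(df$frame_start * fac, df$frame_end * fac,
                        decay_constant)
  w <- if ("weight" %in% names(df)) {
    if (any(df$weight <= 0)) stop("weights must be positive")
    df$weight
  } else NULL
  roi_timecourse(sch, df$activity, w)
}

#' Write an ROI time-activity curve to CSV
#'
#' @param roi An [roi_timecourse()].
#' @param path Output path. Times are written in seconds.
#' @return `path`, invisibly.
#' @export
write_tac <- function(roi, path) {
  stopifnot(inherits(roi, "roi_tac"))
  df <- data.frame(frame_start = roi$schedule$frame_start,
                   frame_end = roi$schedule$frame_end,
                   activity = roi$z, weight = roi$w)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_unit: s", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read arterial blood samples from CSV
#'
#' Expects columns `time`, `activity` (`# time_unit:` comment honoured).
#'
#' @param path CSV file path.
#' @return A two-column matrix `(time, activity)` in seconds.
#' @export
read_blood_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  unit <- read_time_unit(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "activity") %in% names(df)))
    stop("blood-sample CSV must have columns: time, activity")
  fac <- if (unit == "min") 60 else 1
  cbind(time = df$time * fac, activity = df$activity)
}

read_time_unit <- function(path) {
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  m <- regmatches(head_lines,
                  regexpr("#\\s*time_unit:\\s*(s|min)", head_lines))
  if (length(m) == 0L) return("s")
  sub(".*time_unit:\\s*", "", m[[1L]])
}

#' Population prior over impulse-response coefficients
#'
#' Holds the mean `mu_theta` and covariance `sigma_theta` of impulse-response
#' coefficients fitted to a collection of directly sampled arterial curves,
#' with the derived identifiability-constraint values: the mean residence
#' time `mu1` and the contrast ratio `mu2 = R(Tb)/R(Ta)`.
#'
#' @param knots A [knot_vector()].
#' @param mu_theta Mean coefficient vector (length `K`, non-negative).
#' @param sigma_theta `K x K` symmetric positive semidefinite covariance.
#' @param mu1 Mean residence time (seconds).
#' @param mu2 Contrast ratio in `(0, 1]`.
#' @param Ta,Tb Contrast times (seconds), `Ta < Tb`.
#' @return An object of class `aif_prior`.
#' @export
aif_prior <- function(knots, mu_theta, sigma_theta, mu1, mu2, Ta, Tb) {
  stopifnot(inherits(knots, "knot_vector"))
  mu_theta <- as.numeric(mu_theta)
  sigma_theta <- as.matrix(sigma_theta)
  K <- knots$K
  if (length(mu_theta) != K)
    stop("mu_theta length does not match the knot vector (expected ", K, ")")
  if (any(mu_theta < -1e-10)) stop("mu_theta must be non-negative")
  if (!all(dim(sigma_theta) == c(K, K)))
    stop("sigma_theta dimensions do not match the knot vector")
  if (max(abs(sigma_theta - t(sigma_theta))) >
      1e-8 * max(1, max(abs(sigma_theta))))
    stop("sigma_theta is not symmetric")
  ev <- eigen(sigma_theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev)))
    stop("sigma_theta has a negative eigenvalue (not a covariance matrix)")
  if (!is.finite(mu1) || mu1 <= 0) stop("mu1 must be a positive time")
  if (!is.finite(mu2) || mu2 <= 0 || mu2 > 1) stop("mu2 must lie in (0, 1]")
  if (!(Ta < Tb)) stop("Ta must be smaller than Tb")
  structure(list(knots = knots, mu_theta = pmax(mu_theta, 0),
                 sigma_theta = sigma_theta, mu1 = mu1, mu2 = mu2,
                 Ta = Ta, Tb = Tb),
            class = "aif_prior")
}

#' @export
print.aif_prior <- function(x, ...) {
  cat(sprintf(
    "AIF population prior: K = %d, mu1 = %.4g s, mu2 = %.4g (Ta = %.3g, Tb = %.3g s)\n",
    x$knots$K, x$mu1, x$mu2, x$Ta, x$Tb))
  invisible(x)
}

#' Write / read a prior as JSON
#'
#' Round-trips all fields losslessly (full double precision).
#'
#' @param prior An [aif_prior()].
#' @param path JSON file path.
#' @return `read_prior` returns an [aif_prior()]; `write_prior` returns
#'   `path` invisibly.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "aif_prior"))
  obj <- list(knots = prior$knots$knots, mu_theta = prior$mu_theta,
              sigma_theta = prior$sigma_theta, mu1 = prior$mu1,
              mu2 = prior$mu2, Ta = prior$Ta, Tb = prior$Tb)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  aif_prior(knot_vector(obj$knots), obj$mu_theta, obj$sigma_theta,
            obj$mu1, obj$mu2, obj$Ta, obj$Tb)
}

#' Write / read a fit result as JSON
#'
#' Serialises the estimated coefficients, nuisance parameters and
#' diagnostics of an [fit_roi()] result. Curves and design matrices are not
#' stored; they are reconstructed from the coefficients when needed.
#'
#' @param fit An `aif_fit` object.
#' @param path JSON file path.
#' @return `read_fit` returns a list with the stored fields (including a
#'   rebuilt `knots` [knot_vector()]); `write_fit` returns `path` invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "aif_fit"))
  obj <- list(knots = fit$knots$knots, theta = fit$theta, alpha3 = fit$alpha3,
              pi = fit$pi, phi = fit$phi, delta = fit$delta, wrss = fit$wrss,
              sigma2 = fit$sigma2, lambda = fit$lambda)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$knots <- knot_vector(obj$knots)
  obj
}
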