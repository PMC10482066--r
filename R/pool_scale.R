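#' Variance ratio of a fitted ROI
#'
#' The proportion of the spillover-corrected time-course variance left
#' unexplained by the fitted model:
#' `sigma2 = sum_i w_i (z_i - X_i' theta)^2 / sum_i w_i (z_i - alpha3 S_i)^2`.
#' Small values mark ROIs whose blood signal is well captured; the inverse
#' ratios are the pooling weights.
#'
#' @param fit An `aif_fit` from [fit_roi()] (roi mode).
#' @return The ratio, also stored in the returned fit's `sigma2` field.
#' @export
sigma2_ratio <- function(fit) {
  stopifnot(inherits(fit, "aif_fit"))
  num <- fit$wrss
  resid_bg <- fit$z - fit$alpha3 * fit$S
  den <- sum(fit$w * resid_bg^2)
  if (den <= 0)
    stop("spillover-corrected variance is zero; the ROI carries no blood signal")
  fit$sigma2 <- num / den
  fit
}

#' Pool impulse-response estimates across ROIs
#'
#' Inverse-variance weighted average of per-ROI coefficient estimates,
#' `theta_bar = sum_j sigma_j^-2 theta_j / sum_j sigma_j^-2`, the
#' simplification of covariance-weighted pooling under proportional
#' covariances. The nuisance parameters `(pi, phi, delta)` are ROI-specific
#' and are not pooled.
#'
#' @param fits List of `aif_fit` objects on common knots, each with
#'   `sigma2` filled (see [sigma2_ratio()]) and positive.
#' @return List with `theta` (pooled coefficients), `weights` (summing
#'   to 1), and `ir` (the pooled [impulse_response()]).
#' @export
pool_fits <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit")
  if (!all(vapply(fits, inherits, logical(1), "aif_fit")))
    stop("fits must be aif_fit objects")
  knots <- fits[[1L]]$knots
  for (f in fits[-1L]) {
    if (!isTRUE(all.equal(f$knots$knots, knots$knots)))
      stop("all fits must share the same knots")
  }
  s2 <- vapply(fits, function(f) f$sigma2, numeric(1))
  if (any(!is.finite(s2) | s2 <= 0))
    stop("every fit needs a positive sigma2; run sigma2_ratio first")
  wts <- (1 / s2) / sum(1 / s2)
  Theta <- do.call(rbind, lapply(fits, function(f) f$theta))
  theta_bar <- as.numeric(crossprod(Theta, wts))
  list(theta = theta_bar, weights = wts,
       ir = impulse_response(knots, theta_bar))
}

#' Scale an AIF by a single blood sample
#'
#' Rescales the unscaled extracted AIF so it passes through a direct blood
#' measurement: `C_p(t_B) = d_B`.
#'
#' @param aif A [sampled_curve()] (unscaled AIF).
#' @param t_B Sample time (seconds); pick a time where arterial and venous
#'   activity have equilibrated.
#' @param d_B Measured blood activity at `t_B`.
#' @return List with `curve` (scaled [sampled_curve()]) and `factor`.
#' @export
scale_blood_sample <- function(aif, t_B, d_B) {
  stopifnot(inherits(aif, "sampled_curve"))
  v <- curve_value(aif, t_B)
  if (v <= 0)
    stop("unscaled AIF is non-positive at t_B = ", t_B,
         " s; choose a later sample time")
  factor <- d_B / v
  list(curve = sampled_curve(aif$grid, factor * aif$values), factor = factor)
}

#' Scale an AIF by physiologic expectation for a vascular ROI
#'
#' A pure vascular network (e.g. aorta) has unit integrated tissue residue:
#' analysing its TAC against the correctly scaled AIF should give a residue
#' integrating to 1 over the study. The vascular TAC is deconvolved against
#' the unscaled AIF (non-negative monotone residue on the impulse-response
#' basis, time shift optimised, no dispersion or spillover terms) and the
#' integrated residue is the scale factor. Factors outside `[0.2, 1.2]` are
#' flagged as suspect: retention at the study end or poor recovery in a
#' small ROI both bias this scaling.
#'
#' @param aif A [sampled_curve()], the unscaled AIF.
#' @param vascular_roi An [roi_timecourse()] for a blood-rich structure.
#' @param knots [knot_vector()] for the residue basis.
#' @param delta_bounds Time-shift search bounds (seconds).
#' @param control Optimiser knobs.
#' @return List with `curve` (scaled AIF), `factor` (the integrated
#'   residue), `suspect` (logical flag) and `residue_fit` (the underlying
#'   `aif_fit`).
#' @export
scale_physiologic <- function(aif, vascular_roi, knots,
                              delta_bounds = c(0, 60), control = list()) {
  stopifnot(inherits(aif, "sampled_curve"),
            inherits(vascular_roi, "roi_tac"))
  inj <- injection_profile("measured",
                           samples = cbind(aif$grid, pmax(aif$values, 0)))
  nb <- default_nl_bounds()
  nb$delta <- delta_bounds
  fit <- fit_tac(vascular_roi$schedule$mid, vascular_roi$z, vascular_roi$w,
                 inj, knots, spec = NULL, background = NULL,
                 mode = "arterial", nl_bounds = nb, control = control)
  residue <- impulse_response(knots, fit$theta)
  factor <- ir_integral(residue)
  if (factor <= 0) stop("residue deconvolution returned a zero residue")
  list(curve = sampled_curve(aif$grid, factor * aif$values),
       factor = factor, suspect = factor > 1.2 || factor < 0.2,
       residue_fit = fit)
}

#' Nadler total blood volume
#'
#' Anthropometric blood-volume estimate: for males
#' `0.3669 h^3 + 0.03219 w + 0.6041` litres, for females
#' `0.3561 h^3 + 0.03308 w + 0.1833` litres, with height `h` in metres and
#' weight `w` in kilograms.
#'
#' @param height Height (m), in `[0.5, 2.5]`.
#' @param weight Weight (kg), in `[2, 300]`.
#' @param sex `"M"` or `"F"`.
#' @return Blood volume (litres).
#' @export
nadler_bv <- function(height, weight, sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (!is.finite(height) || height < 0.5 || height > 2.5)
    stop("height must be in metres, between 0.5 and 2.5")
  if (!is.finite(weight) || weight < 2 || weight > 300)
    stop("weight must be in kg, between 2 and 300")
  if (sex == "M") 0.3669 * height^3 + 0.03219 * weight + 0.6041
  else 0.3561 * height^3 + 0.03308 * weight + 0.1833
}

#' Scale an AIF by injected dose per unit blood volume
#'
#' Targets a predicted late blood activity: the AIF is rescaled so that
#' `C_p(T_E) = beta_hat * tau_act * V_I / BV`, where `tau_act` is the
#' injected activity per ml, `V_I` the injected volume (ml), `BV` the
#' subject's blood volume (litres, e.g. from [nadler_bv()]) and `beta_hat`
#' an empirical coefficient from historical arterial data (see
#' [estimate_beta()]).
#'
#' @param aif A [sampled_curve()], the unscaled AIF.
#' @param V_I Injection volume (ml).
#' @param tau_act Injected activity per ml.
#' @param bv Blood volume (litres).
#' @param beta_hat Historical proportionality coefficient.
#' @param T_E Late reference time (seconds).
#' @return List with `curve` (scaled AIF) and `factor`.
#' @export
scale_dose_bv <- function(aif, V_I, tau_act, bv, beta_hat, T_E) {
  stopifnot(inherits(aif, "sampled_curve"))
  if (bv <= 0) stop("blood volume must be positive")
  v <- curve_value(aif, T_E)
  if (v <= 0)
    stop("unscaled AIF is non-positive at T_E = ", T_E,
         " s; choose an earlier reference time")
  target <- beta_hat * tau_act * V_I / bv
  factor <- target / v
  list(curve = sampled_curve(aif$grid, factor * aif$values), factor = factor)
}

#' Estimate the dose-scaling coefficient from historical data
#'
#' No-intercept weighted least-squares slope of observed late arterial
#' activity on injected dose per unit blood volume.
#'
#' @param late_activity Observed blood activities at the late reference
#'   time, one per historical study.
#' @param dose_per_bv Corresponding `tau_act * V_I / BV` values.
#' @param weights Optional positive weights.
#' @return The slope `beta_hat`.
#' @export
estimate_beta <- function(late_activity, dose_per_bv, weights = NULL) {
  if (length(late_activity) != length(dose_per_bv) ||
      length(late_activity) < 2L)
    stop("need at least 2 paired historical records")
  if (is.null(weights)) weights <- rep(1, length(late_activity))
  sxx <- sum(weights * dose_per_bv^2)
  if (sxx <= 0) stop("degenerate predictors: dose per blood volume all zero")
  sum(weights * dose_per_bv * late_activity) / sxx
}
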