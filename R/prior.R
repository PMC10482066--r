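#' Fit a directly sampled arterial curve
#'
#' Arterial samples are assumed free of dispersion and spillover, so the
#' fit fixes `pi = 0` and `alpha3 = 0` and optimises only the time shift
#' `delta`; no identifiability constraints are imposed (they are what this
#' analysis is used to calibrate). Sample weights are uniform.
#'
#' @param samples Two-column matrix or data frame `(time, activity)` with
#'   times in seconds; needs at least `K + 2` samples spanning the peak.
#' @param injection An [injection_profile()].
#' @param knots A [knot_vector()].
#' @param delta_bounds Search bounds for the time shift (seconds).
#' @param weighting `"inverse"` (default) weights samples by the reciprocal
#'   of their activity, floored at 1% of the peak -- the right scheme when
#'   counting noise scales with activity, and essential for recovering the
#'   late tail, which sits orders of magnitude below the peak. `"uniform"`
#'   weights all samples equally.
#' @param control Optimiser knobs, see [fit_roi()].
#' @return An `aif_fit` in arterial mode; its normalised impulse response
#'   (see [fit_ir()]) is the input to population summaries.
#' @export
fit_arterial_curve <- function(samples, injection, knots,
                               delta_bounds = c(-30, 60),
                               weighting = c("inverse", "uniform"),
                               control = list()) {
  weighting <- match.arg(weighting)
  samples <- as.matrix(samples)
  if (ncol(samples) != 2L) stop("samples must be a (time, activity) table")
  if (nrow(samples) < knots$K + 2L)
    stop("need at least K + 2 = ", knots$K + 2L,
         " samples; use fewer knots (smaller K) for sparse data")
  o <- order(samples[, 1L])
  samples <- samples[o, , drop = FALSE]
  z <- samples[, 2L]
  w <- if (weighting == "inverse" && max(z) > 0)
    1 / pmax(z, 0.01 * max(z)) else rep(1, length(z))
  w <- w / mean(w)
  nb <- default_nl_bounds()
  nb$delta <- delta_bounds
  fit_tac(samples[, 1L], z, w, injection,
          knots, spec = NULL, background = NULL, mode = "arterial",
          nl_bounds = nb, control = control)
}

#' Build a population prior from fitted impulse responses
#'
#' Takes the coordinate-wise mean and sample covariance of the coefficient
#' vectors as `(mu_theta, Sigma_theta)`. The coefficients are used on the
#' scale they are supplied: arterial fits carry the activity scale of their
#' blood data (the direct-signal coefficient is fixed at 1), and the
#' Mahalanobis penalty compares ROI-fitted coefficients to the prior on
#' that same scale, so the curves behind a prior should be in the same
#' activity units as the data the prior will regularise. The constraint
#' values are scale-free: `mu1` is the mean residence time of the
#' normalised mean response and the contrast ratio `mu2` is the
#' across-curve mean of `R(Tb)/R(Ta)`.
#'
#' @param irs List of [impulse_response()] objects on a common knot vector
#'   (at least 2).
#' @param Ta,Tb Contrast times (seconds). Defaults are the knots at the 25%
#'   and 75% positions of the knot vector, spanning the informative range
#'   of the response: a `Tb` where the response has fallen to noise level
#'   would make the ratio constraint vacuous.
#' @return An [aif_prior()].
#' @export
build_prior <- function(irs, Ta = NULL, Tb = NULL) {
  if (length(irs) < 2L) stop("need at least 2 impulse responses")
  if (!all(vapply(irs, inherits, logical(1), "impulse_response")))
    stop("irs must be a list of impulse_response objects")
  knots <- irs[[1L]]$knots
  for (ir in irs[-1L]) {
    if (!isTRUE(all.equal(ir$knots$knots, knots$knots)))
      stop("all impulse responses must share the same knots")
  }
  Theta <- do.call(rbind, lapply(irs, function(ir) ir$theta))
  mu_theta <- colMeans(Theta)
  sigma_theta <- stats::cov(Theta)
  kk <- knots$knots
  if (is.null(Ta)) Ta <- kk[max(2L, ceiling(0.25 * length(kk)))]
  if (is.null(Tb)) Tb <- kk[ceiling(0.75 * length(kk))]
  mean_ir <- normalize_ir(impulse_response(knots, mu_theta))
  mu1 <- ir_mrt(mean_ir)
  ratios <- vapply(irs, function(ir) {
    ra <- ir_eval(ir, Ta)
    rb <- ir_eval(ir, Tb)
    if (ra <= 0) NA_real_ else rb / ra
  }, numeric(1))
  if (all(is.na(ratios)))
    stop("no curve has positive response at Ta; choose an earlier Ta")
  mu2 <- min(max(mean(ratios, na.rm = TRUE), 1e-12), 1)
  aif_prior(knots, mu_theta, sigma_theta, mu1, mu2, Ta, Tb)
}

#' Circulation-time percentiles of an impulse response
#'
#' Interprets the decline of the normalised impulse response past a short
#' reference time as the survival curve of tracer molecules in circulation:
#' the `p`-th percentile is the earliest time `t >= ref_time` at which
#' `R(t)/R(ref_time) <= 1 - p`. The 50th percentile is then the circulation
#' half-life of the tracer. The crossing is computed exactly on the
#' piecewise-linear form.
#'
#' @param ir An [impulse_response()] with `R(ref_time) > 0`.
#' @param probs Percentile levels in `(0, 1)`, e.g. `c(0.25, 0.5, 0.95)`.
#' @param ref_time Reference time (seconds); default 5 s skips the initial
#'   transit spike.
#' @return Named vector of times (seconds). If the curve never falls below
#'   the target before the last knot, that percentile is reported as the
#'   last knot with attribute `censored` set.
#' @export
ir_percentiles <- function(ir, probs = c(0.25, 0.5, 0.95), ref_time = 5) {
  stopifnot(inherits(ir, "impulse_response"))
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  r0 <- ir_eval(ir, ref_time)
  if (r0 <= 0) stop("impulse response is zero at the reference time")
  kk <- ir$knots$knots
  tK <- kk[length(kk)]
  breaks <- sort(unique(c(ref_time, kk[kk > ref_time], tK)))
  vals <- ir_eval(ir, breaks) / r0
  out <- numeric(length(probs))
  censored <- logical(length(probs))
  for (j in seq_along(probs)) {
    target <- 1 - probs[j]
    idx <- which(vals <= target)
    if (length(idx) == 0L) {
      out[j] <- tK
      censored[j] <- TRUE
      next
    }
    i <- idx[1L]
    if (i == 1L) { out[j] <- breaks[1L]; next }
    # linear segment between breaks[i-1] and breaks[i]
    v0 <- vals[i - 1L]; v1 <- vals[i]
    out[j] <- if (v0 == v1) breaks[i] else
      breaks[i - 1L] + (v0 - target) / (v0 - v1) * (breaks[i] - breaks[i - 1L])
  }
  names(out) <- paste0("q", format(100 * probs, trim = TRUE))
  attr(out, "censored") <- censored
  out
}

#' Effective dimension of a collection of impulse responses
#'
#' The number of principal components of the correlation matrix of the
#' coefficient vectors needed to account for a given fraction of its trace.
#' Coordinates with zero variance across the collection (knots never
#' activated) are dropped before the eigen-analysis.
#'
#' @param irs List of [impulse_response()] objects on common knots (>= 2).
#' @param threshold Fraction of total correlation to account for (default
#'   0.9).
#' @return Integer count. If every coordinate is constant across the
#'   collection, returns 0 with attribute `degenerate = TRUE`.
#' @export
effective_dimension <- function(irs, threshold = 0.9) {
  if (length(irs) < 2L) stop("need at least 2 impulse responses")
  Theta <- do.call(rbind, lapply(irs, function(ir) ir$theta))
  sds <- apply(Theta, 2L, stats::sd)
  scale_ref <- max(mean(abs(Theta)), 1e-300)
  keep <- sds > 1e-10 * scale_ref
  if (!any(keep)) {
    out <- 0L
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  C <- stats::cor(Theta[, keep, drop = FALSE])
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cs <- cumsum(ev)
  tot <- sum(ev)
  m <- which(cs >= threshold * tot - 1e-8 * tot)[1L]
  as.integer(m)
}

#' Summarise circulation percentiles across a population
#'
#' Mean and standard error of the circulation-time percentiles, computed
#' across individually fitted impulse responses.
#'
#' @inheritParams effective_dimension
#' @param probs Percentile levels.
#' @param ref_time Reference time (seconds).
#' @return A data frame with one row per percentile: `prob`, `mean`, `se`,
#'   `n`.
#' @export
percentile_summary <- function(irs, probs = c(0.25, 0.5, 0.95),
                               ref_time = 5) {
  qs <- vapply(irs, function(ir)
    as.numeric(ir_percentiles(normalize_ir(ir), probs, ref_time)),
    numeric(length(probs)))
  qs <- matrix(qs, nrow = length(probs))  # rows: probs, cols: curves
  data.frame(prob = probs,
             mean = rowMeans(qs),
             se = apply(qs, 1L, stats::sd) / sqrt(ncol(qs)),
             n = ncol(qs))
}
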