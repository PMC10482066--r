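#' Contamination specification for simulated blood-pool data
#'
#' The simulated ROI concentration is a weighted sum of the true AIF, a
#' dispersed copy of it, and a spillover pattern:
#' `C_T = (1 - p_d) C_p + p_d E_{phi_d} * C_p + p_b S_bar`, with `S_bar`
#' the cumulative integral of the AIF scaled to 1 at the end of the study.
#'
#' @param p_d Dispersed fraction, in `[0, 1)`.
#' @param p_b Spillover amplitude, `>= 0`.
#' @param phi_d Dispersion time constant (seconds), `> 0`.
#' @return An object of class `contamination_spec`.
#' @export
contamination_spec <- function(p_d, p_b, phi_d) {
  if (!is.finite(p_d) || p_d < 0 || p_d >= 1) stop("p_d must lie in [0, 1)")
  if (!is.finite(p_b) || p_b < 0) stop("p_b must be non-negative")
  if (!is.finite(phi_d) || phi_d <= 0) stop("phi_d must be positive")
  structure(list(p_d = p_d, p_b = p_b, phi_d = phi_d),
            class = "contamination_spec")
}

#' The standard six-level contamination ladder
#'
#' `(p_d, p_b)` pairs ranging from nearly contamination-free to heavy
#' dispersion plus dominant spillover:
#' (0.1, 0.125), (0.2, 0.25), (0.3, 0.5), (0.4, 0.75), (0.5, 1), (0.6, 2).
#'
#' @param phi_d Dispersion time constant (seconds) shared by all levels.
#' @return List of six [contamination_spec()] objects.
#' @export
contamination_levels <- function(phi_d) {
  pd <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  pb <- c(0.125, 0.25, 0.5, 0.75, 1, 2)
  lapply(seq_along(pd), function(i) contamination_spec(pd[i], pb[i], phi_d))
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# ---- exponential-mixture impulse-response generator -----------------------

# The ground-truth generator uses a mixture of decaying exponentials
# R(t) = sum_m a_m exp(-t / b_m), a >= 0 summing to 1, which is monotone
# non-increasing and deliberately outside the span of the piecewise-linear
# fitting basis.
mix_eval <- function(a, b, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  for (m in seq_along(a)) out[pos] <- out[pos] + a[m] * exp(-t[pos] / b[m])
  out
}

# closed-form convolution with a unit-height square of duration d (times h)
mix_conv_square <- function(a, b, h, d, t) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  lo <- pmax(0, tp - d)
  for (m in seq_along(a))
    out[pos] <- out[pos] +
      a[m] * b[m] * (exp(-lo / b[m]) - exp(-tp / b[m]))
  h * out
}

# survival-style percentile of the mixture past ref (dense bisection)
mix_percentile <- function(a, b, prob, ref = 5) {
  r0 <- mix_eval(a, b, ref)
  target <- (1 - prob) * r0
  f <- function(t) mix_eval(a, b, t) - target
  hi <- ref + max(b) * 20
  stats::uniroot(f, c(ref, hi), tol = 1e-8)$root
}

#' Built-in tracer archetypes
#'
#' Two synthetic study designs spanning the extremes of tracer circulation
#' behaviour. The water-like archetype uses a 5 s bolus-style square
#' injection, a short fine-grained frame schedule and a fast impulse
#' response (circulation half-life about 9.5 s past a 5 s reference); the
#' FDG-like archetype uses a 60 s infusion, a 90-minute schedule and a slow
#' response (half-life about 79 s) with a heavy late tail. Decay constants
#' are those of O-15 (122.2 s half-life) and F-18 (109.77 min).
#'
#' @return Named list of `tracer_archetype` objects with fields `name`,
#'   `injection`, `schedule`, `ir_a`, `ir_b` (mixture weights and time
#'   constants), `decay_constant`, `sample_time` (scaling sample, seconds),
#'   `phi_d` (contamination dispersion constant, half-life matched to the
#'   archetype's circulation half-life), `arterial_times` (sampling times
#'   for prior-building arterial curves) and `K`, `first_knot` (knot
#'   design).
#' @export
builtin_archetypes <- function() {
  h2o_end <- 435
  h2o <- structure(list(
    name = "H2O-like",
    injection = injection_profile("square", duration = 5),
    schedule = frame_schedule_blocks(
      c(5L, 10L, 12L, 8L, 6L), c(3, 6, 10, 15, 20),
      decay_constant = log(2) / 122.24),
    ir_a = c(0.87, 0.10, 0.03), ir_b = c(5.2, 14, 110),
    amplitude = 45,
    decay_constant = log(2) / 122.24,
    sample_time = 120,
    phi_d = 9.5 / log(2),
    arterial_times = c(seq(2, 120, by = 4), seq(130, h2o_end, by = 15)),
    K = 12L, first_knot = 3),
    class = "tracer_archetype")
  fdg_end <- 5340
  fdg <- structure(list(
    name = "FDG-like",
    injection = injection_profile("square", duration = 60),
    schedule = frame_schedule_blocks(
      c(4L, 4L, 4L, 4L, 14L), c(15, 30, 60, 180, 300),
      decay_constant = log(2) / 6586.2),
    ir_a = c(0.30, 0.45, 0.25), ir_b = c(28, 95, 1600),
    amplitude = 35,
    decay_constant = log(2) / 6586.2,
    sample_time = 600,
    phi_d = 79 / log(2),
    arterial_times = c(seq(5, 180, by = 7.5), seq(200, 600, by = 25),
                       seq(660, fdg_end, by = 120)),
    K = 12L, first_knot = 5),
    class = "tracer_archetype")
  list(h2o = h2o, fdg = fdg)
}

#' @export
print.tracer_archetype <- function(x, ...) {
  cat(sprintf("tracer archetype '%s': %d frames to %.0f s, injection %s\n",
              x$name, length(x$schedule$mid),
              max(x$schedule$frame_end),
              if (x$injection$kind == "square")
                sprintf("square %.0f s", x$injection$duration)
              else x$injection$kind))
  invisible(x)
}

#' Generate a ground-truth AIF from an archetype
#'
#' Draws a subject-specific impulse response by log-normal jitter
#' (coefficient of variation `jitter_cv`) of the archetype's mixture
#' parameters, then convolves it with the archetype's injection profile
#' and scales by the archetype's `amplitude` so the curve is in realistic
#' decay-corrected activity units (kBq/ml). The absolute scale matters for
#' the contamination model: its spillover pattern is normalised to 1 at
#' the study end, so `p_b` is a small fraction of late-time blood activity
#' at the light contamination levels and dominates it at the heavy ones.
#' The convolution is evaluated in closed form.
#'
#' @param arch A `tracer_archetype`.
#' @param seed Integer seed; the same seed reproduces the same subject.
#' @param jitter_cv Log-normal coefficient of variation of the mixture
#'   parameters (default 0.2, i.e. 20% subject-to-subject variation). Use 0
#'   for the archetype's nominal curve.
#' @return List with `curve` (the AIF as a [sampled_curve()] covering the
#'   study), `aif_fun` (vectorised closed-form `C_p(t)`), `ir_fun`
#'   (the generating `R(t)`), and `a`, `b` (the jittered mixture
#'   parameters).
#' @export
make_true_aif <- function(arch, seed, jitter_cv = 0.2) {
  stopifnot(inherits(arch, "tracer_archetype"))
  ab <- with_seed(seed, {
    if (jitter_cv > 0) {
      sdlog <- sqrt(log(1 + jitter_cv^2))
      b <- arch$ir_b * exp(stats::rnorm(length(arch$ir_b), 0, sdlog))
      a <- arch$ir_a * exp(stats::rnorm(length(arch$ir_a), 0, sdlog))
      list(a = a / sum(a), b = b)
    } else list(a = arch$ir_a, b = arch$ir_b)
  })
  inj <- arch$injection
  amp <- if (is.null(arch$amplitude)) 1 else arch$amplitude
  aif_fun <- if (inj$kind == "square") {
    function(t) amp * mix_conv_square(ab$a, ab$b, inj$height, inj$duration, t)
  } else if (inj$kind == "bolus") {
    function(t) amp * inj$mass * mix_eval(ab$a, ab$b, t)
  } else stop("archetype injections must be square or bolus")
  grid <- default_grid(max(arch$schedule$frame_end))
  list(curve = sampled_curve(grid, aif_fun(grid)), aif_fun = aif_fun,
       ir_fun = function(t) mix_eval(ab$a, ab$b, t),
       a = ab$a, b = ab$b)
}

#' Contaminate a true AIF with dispersion and spillover
#'
#' @param cp A [sampled_curve()], the true AIF `C_p` on a grid covering the
#'   study.
#' @param spec A [contamination_spec()].
#' @param schedule The [frame_schedule()]; the spillover pattern is
#'   normalised to 1 at the end of the last frame.
#' @return The contaminated concentration `C_T` as a [sampled_curve()].
#' @export
contaminate <- function(cp, spec, schedule) {
  stopifnot(inherits(cp, "sampled_curve"),
            inherits(spec, "contamination_spec"),
            inherits(schedule, "frame_schedule"))
  end <- max(schedule$frame_end)
  s <- curve_cumint(cp)
  s_end <- curve_value(s, end)
  if (s_end <= 0) stop("AIF has zero integral over the study")
  v <- (1 - spec$p_d) * cp$values
  if (spec$p_d > 0)
    v <- v + spec$p_d * exp_kernel_filter(cp$values, cp$dt, spec$phi_d)
  v <- v + spec$p_b * s$values / s_end
  sampled_curve(cp$grid, v)
}

#' Simulate noisy ROI frame data
#'
#' Frame activities follow the decay-corrected PET noise model:
#' `z_i = C_T(t_i) + sigma_i eps_i` with
#' `sigma_i^2 = noise_scale^2 * C_T(t_i) * exp(tau t_i) / dur_i` and
#' `eps_i` iid standard normal. Negative draws are kept; the weights, not
#' truncation, handle low-count frames. By default `noise_scale` is
#' calibrated so the coefficient of variation at the peak frame is
#' `cv_peak` (2%), a low noise level typical of large blood-pool ROIs.
#'
#' @param ct The contaminated concentration [sampled_curve()].
#' @param schedule A [frame_schedule()] (its `decay_constant` is `tau`).
#' @param seed Integer seed.
#' @param noise_scale Noise multiplier; `0` gives noise-free frames.
#' @param cv_peak Target peak coefficient of variation used when
#'   `noise_scale` is `NULL`.
#' @return An [roi_timecourse()] with [default_weights()] attached.
#' @export
simulate_roi <- function(ct, schedule, seed, noise_scale = NULL,
                         cv_peak = 0.02) {
  stopifnot(inherits(ct, "sampled_curve"), inherits(schedule, "frame_schedule"))
  mu <- curve_value(ct, schedule$mid)
  tau <- schedule$decay_constant
  if (is.null(noise_scale)) noise_scale <- noise_scale_for_cv(ct, schedule,
                                                              cv_peak)
  sd_i <- noise_scale * sqrt(pmax(mu, 0) * exp(tau * schedule$mid) /
                               schedule$dur)
  z <- with_seed(seed, mu + sd_i * stats::rnorm(length(mu)))
  roi_timecourse(schedule, z)
}

#' Noise multiplier achieving a target peak coefficient of variation
#'
#' @inheritParams simulate_roi
#' @param cv_peak Target coefficient of variation at the peak frame.
#' @return The `noise_scale` value.
#' @export
noise_scale_for_cv <- function(ct, schedule, cv_peak = 0.02) {
  mu <- curve_value(ct, schedule$mid)
  i <- which.max(mu)
  if (mu[i] <= 0) return(0)
  cv_peak * sqrt(mu[i] * schedule$dur[i] *
                   exp(-schedule$decay_constant * schedule$mid[i]))
}

#' Root mean integrated squared error between two curves
#'
#' `sqrt( int_0^horizon (estimate - truth)^2 dt )`, the AIF error metric.
#'
#' @param estimate,truth [sampled_curve()] objects (interpolated onto the
#'   truth's grid).
#' @param horizon Upper integration limit (seconds); default the end of the
#'   truth grid.
#' @return Non-negative scalar.
#' @export
rmise <- function(estimate, truth, horizon = NULL) {
  stopifnot(inherits(estimate, "sampled_curve"), inherits(truth, "sampled_curve"))
  if (is.null(horizon)) horizon <- truth$grid[length(truth$grid)]
  g <- truth$grid[truth$grid <= horizon]
  d <- curve_value(estimate, g) - curve_value(truth, g)
  sqrt(trapz_integral(g, d * d))
}

#' Percent RMISE improvement of one estimate over another
#'
#' `100 * (rmise_direct - rmise_reg) / rmise_direct`: positive when the
#' regularised extraction beats the direct use of the ROI curve.
#'
#' @param rmise_reg,rmise_direct RMISE values.
#' @return Percent improvement.
#' @export
percent_improvement <- function(rmise_reg, rmise_direct) {
  100 * (rmise_direct - rmise_reg) / rmise_direct
}

#' Build a population prior for an archetype from simulated arterial fits
#'
#' Simulates `n_curves` subjects from the archetype's generator, samples
#' each AIF at the archetype's arterial sampling times, fits each in
#' arterial mode (no constraints, `pi = 0`, `alpha3 = 0`), and summarises
#' the normalised impulse responses into an [aif_prior()].
#'
#' @param arch A `tracer_archetype`.
#' @param seed Integer seed.
#' @param n_curves Number of simulated arterial curves (default 20).
#' @param jitter_cv Subject variation, see [make_true_aif()].
#' @return List with `prior` (an [aif_prior()]), `knots` and `irs` (the
#'   fitted normalised impulse responses).
#' @export
archetype_prior <- function(arch, seed, n_curves = 20L, jitter_cv = 0.2) {
  stopifnot(inherits(arch, "tracer_archetype"))
  end <- max(arch$schedule$frame_end)
  knots <- make_knots(end, K = arch$K, first_knot = arch$first_knot)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_curves))
  irs <- vector("list", n_curves)
  for (j in seq_len(n_curves)) {
    truth <- make_true_aif(arch, seeds[j], jitter_cv = jitter_cv)
    samples <- cbind(arch$arterial_times, truth$aif_fun(arch$arterial_times))
    fit <- fit_arterial_curve(samples, arch$injection, knots,
                              delta_bounds = c(-10, 10))
    # keep the activity scale: the prior regularises ROI fits on this scale
    irs[[j]] <- fit_ir(fit)
  }
  list(prior = build_prior(irs), knots = knots, irs = irs)
}

#' Run the contamination simulation experiment
#'
#' For each archetype and contamination level, simulates `reps` independent
#' subjects, extracts the AIF two ways, and scores both against the known
#' truth by RMISE over the study duration:
#' \describe{
#'   \item{direct}{the raw ROI frame curve, linearly interpolated and
#'     rescaled through a single simulated measurement of the true AIF at
#'     the archetype's sample time;}
#'   \item{regularised}{the constrained, Mahalanobis-penalised
#'     impulse-response extraction, with identifiability constraints and
#'     the penalty taken from a prior built once per archetype from
#'     `n_prior` simulated arterial fits, the spillover column from the
#'     prior-mean AIF, `lambda` chosen by GCV, and the same single-sample
#'     rescaling.}
#' }
#'
#' @param archetypes List of `tracer_archetype` objects
#'   (default [builtin_archetypes()]).
#' @param levels List of [contamination_spec()] objects, or `NULL` to use
#'   [contamination_levels()] with each archetype's `phi_d`.
#' @param reps Replicates per (archetype, level).
#' @param seed Master integer seed; all randomness derives from it.
#' @param n_prior Arterial curves behind each archetype prior.
#' @param cv_peak Peak coefficient of variation of the frame noise.
#' @param n_lambda Length of the GCV grid used per replicate.
#' @param control Optimiser knobs passed to the fits.
#' @return Data frame with one row per successful replicate: `archetype`,
#'   `level`, `p_d`, `p_b`, `rep`, `rmise_direct`, `rmise_reg`,
#'   `improvement` (percent), `lambda`. Failed replicates are dropped;
#'   their count is in attribute `n_failed`.
#' @export
run_experiment <- function(archetypes = builtin_archetypes(), levels = NULL,
                           reps = 10L, seed = 1L, n_prior = 20L,
                           cv_peak = 0.02, n_lambda = 7L,
                           control = list(n_pi = 3L, n_phi = 3L,
                                          n_delta = 4L, maxit = 15L)) {
  rows <- list()
  n_failed <- 0L
  for (ai in seq_along(archetypes)) {
    arch <- archetypes[[ai]]
    pr <- archetype_prior(arch, seed = seed + 7919L * ai, n_curves = n_prior)
    knots <- pr$knots
    prior <- pr$prior
    spec <- constraints_from_prior(prior)
    levs <- if (is.null(levels)) contamination_levels(arch$phi_d) else levels
    n_frames <- length(arch$schedule$mid)
    scale_lams <- n_frames / sum(diag(prior_precision(prior)))
    lam_grid <- scale_lams * 10^seq(-4, 4, length.out = n_lambda)
    rep_seeds <- with_seed(seed + 104729L * ai,
                           sample.int(.Machine$integer.max - 1L,
                                      reps * length(levs)))
    si <- 0L
    for (li in seq_along(levs)) {
      for (r in seq_len(reps)) {
        si <- si + 1L
        res <- tryCatch(
          run_one_rep(arch, levs[[li]], rep_seeds[si], knots, prior, spec,
                      lam_grid, cv_peak, control),
          error = function(e) NULL)
        if (is.null(res)) { n_failed <- n_failed + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          archetype = arch$name, level = li, p_d = levs[[li]]$p_d,
          p_b = levs[[li]]$p_b, rep = r,
          rmise_direct = res$rmise_direct, rmise_reg = res$rmise_reg,
          improvement = res$improvement, lambda = res$lambda)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}

run_one_rep <- function(arch, lev, rep_seed, knots, prior, spec, lam_grid,
                        cv_peak, control) {
  truth <- make_true_aif(arch, rep_seed)
  ct <- contaminate(truth$curve, lev, arch$schedule)
  roi <- simulate_roi(ct, arch$schedule, seed = rep_seed + 1L,
                      cv_peak = cv_peak)
  horizon <- max(arch$schedule$frame_end)
  ts <- arch$sample_time
  cp_sample <- truth$aif_fun(ts)

  # direct: interpolate the frame curve, rescale through the blood sample
  direct <- sampled_curve(truth$curve$grid,
                          stats::approx(c(0, roi$schedule$mid),
                                        c(0, roi$z),
                                        xout = truth$curve$grid,
                                        rule = 2)$y)
  dv <- curve_value(direct, ts)
  if (dv <= 0) stop("direct curve non-positive at the sample time")
  direct <- sampled_curve(direct$grid, direct$values * cp_sample / dv)
  r_direct <- rmise(direct, truth$curve, horizon)

  # regularised constrained extraction with GCV-chosen lambda
  sel <- gcv_select(roi, arch$injection, knots, spec, prior,
                    lambda_grid = lam_grid, background = "prior_aif",
                    control = control)
  est <- aif_curve(sel$fit, grid = truth$curve$grid)
  sc <- scale_blood_sample(est, ts, cp_sample)
  r_reg <- rmise(sc$curve, truth$curve, horizon)

  list(rmise_direct = r_direct, rmise_reg = r_reg,
       improvement = percent_improvement(r_reg, r_direct),
       lambda = sel$lambda)
}

#' Summarise an experiment by archetype and level
#'
#' @param results Data frame from [run_experiment()].
#' @return Data frame with mean RMISEs and mean percent improvement per
#'   (archetype, level).
#' @export
summarize_experiment <- function(results) {
  agg <- stats::aggregate(
    cbind(rmise_direct, rmise_reg, improvement) ~ archetype + level + p_d + p_b,
    data = results, FUN = mean)
  agg[order(agg$archetype, agg$level), ]
}
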