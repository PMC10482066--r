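#' Identifiability constraint specification
#'
#' With dispersion or spillover present, the normalised impulse response is
#' not identifiable from blood-pool ROI data alone. Identifiability is
#' restored by pinning two functionals of the normalised response: its mean
#' residence time `mu1` and a contrast ratio `mu2 = R(Tb)/R(Ta)` between a
#' late and an early time. Both are implemented as linear equality
#' constraints on the basis coefficients.
#'
#' @param mu1 Target mean residence time (seconds), `> 0`.
#' @param mu2 Target contrast ratio in `(0, 1]`.
#' @param Ta,Tb Contrast evaluation times (seconds), `Ta < Tb`.
#' @param enabled Logical vector `c(mrt = , contrast = )` switching each
#'   constraint on or off.
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(mu1, mu2, Ta, Tb,
                            enabled = c(mrt = TRUE, contrast = TRUE)) {
  if (!is.finite(mu1) || mu1 <= 0) stop("mu1 must be a positive time")
  if (!is.finite(mu2) || mu2 <= 0 || mu2 > 1) stop("mu2 must lie in (0, 1]")
  if (!(Ta < Tb)) stop("Ta must be smaller than Tb")
  if (!all(c("mrt", "contrast") %in% names(enabled)))
    stop("enabled must have elements named 'mrt' and 'contrast'")
  structure(list(mu1 = mu1, mu2 = mu2, Ta = Ta, Tb = Tb,
                 enabled = enabled), class = "constraint_spec")
}

#' Constraints derived from a population prior
#'
#' @param prior An [aif_prior()].
#' @return A [constraint_spec()] using the prior's `mu1`, `mu2`, `Ta`, `Tb`.
#' @export
constraints_from_prior <- function(prior) {
  stopifnot(inherits(prior, "aif_prior"))
  constraint_spec(prior$mu1, prior$mu2, prior$Ta, prior$Tb)
}

#' Build the linear equality constraint matrix
#'
#' Column 1 encodes the mean-residence-time identity
#' `sum_k theta_k int (mu1 - t) B_k(t) dt = 0`; column 2 the contrast-ratio
#' identity `sum_k theta_k (mu2 B_k(Ta) - B_k(Tb)) = 0`. A final row of
#' zeros leaves the spillover coefficient unconstrained.
#'
#' @param knots A [knot_vector()].
#' @param spec A [constraint_spec()].
#' @return Matrix of dimension `(K + 1) x m` where `m` is the number of
#'   enabled constraints (possibly 0 columns).
#' @export
build_constraints <- function(knots, spec) {
  stopifnot(inherits(knots, "knot_vector"), inherits(spec, "constraint_spec"))
  K <- knots$K
  cols <- list()
  if (isTRUE(spec$enabled[["mrt"]])) {
    a1 <- vapply(seq_len(K), function(k)
      spec$mu1 * basis_integral(knots, k) - basis_t_moment(knots, k),
      numeric(1))
    cols$mrt <- c(a1, 0)
  }
  if (isTRUE(spec$enabled[["contrast"]])) {
    tK <- knots$knots[length(knots$knots)]
    if (spec$Ta >= tK || spec$Tb >= tK)
      stop("contrast times Ta, Tb must lie before the last knot ",
           "(the ratio constraint is vacuous beyond it)")
    a2 <- vapply(seq_len(K), function(k)
      spec$mu2 * basis_eval(knots, k, spec$Ta) -
        basis_eval(knots, k, spec$Tb), numeric(1))
    cols$contrast <- c(a2, 0)
  }
  if (length(cols) == 0L) return(matrix(numeric(0), nrow = K + 1L, ncol = 0L))
  do.call(cbind, cols)
}

#' Background spillover pattern
#'
#' Constructs the background time-course `S_t` entering the spillover term.
#' Modes: `"patlak"` takes the cumulative integral of the (shifted)
#' injection profile, the generic pattern of irreversible tissue uptake;
#' `"prior_aif"` takes the cumulative integral of the prior-mean AIF
#' (normalised to 1 at the end of the grid), the pattern appropriate when
#' the surrounding tissue tracks the blood curve's integral; `"measured"`
#' interpolates a supplied background TAC.
#'
#' @param injection An [injection_profile()] (patlak mode).
#' @param delta Time shift applied to the pattern (seconds).
#' @param mode One of `"patlak"`, `"prior_aif"`, `"measured"`.
#' @param grid Evaluation grid (seconds), e.g. [default_grid()].
#' @param prior An [aif_prior()] (prior_aif mode).
#' @param background_tac An [roi_timecourse()] (measured mode).
#' @return A non-negative [sampled_curve()]; non-decreasing for the patlak
#'   and prior_aif modes.
#' @export
build_background <- function(injection, delta = 0,
                             mode = c("patlak", "prior_aif", "measured"),
                             grid, prior = NULL, background_tac = NULL) {
  mode <- match.arg(mode)
  base <- background_base(injection, mode, grid, prior, background_tac)
  if (mode == "measured" || delta == 0) return(base)
  shift_curve(base, delta)
}

# un-shifted background pattern on the grid
background_base <- function(injection, mode, grid, prior = NULL,
                            background_tac = NULL) {
  if (mode == "patlak") {
    stopifnot(inherits(injection, "injection_profile"))
    v <- switch(injection$kind,
      square = injection$height *
        pmin(pmax(grid, 0), injection$duration),
      bolus = injection$mass * as.numeric(grid >= 0),
      measured = curve_cumint(
        sampled_curve(grid, injection_eval(injection, grid)))$values)
    sampled_curve(grid, v)
  } else if (mode == "prior_aif") {
    if (is.null(prior)) stop("prior_aif background mode requires a prior")
    mu_ir <- impulse_response(prior$knots, prior$mu_theta)
    aif <- convolve_with_injection(mu_ir, injection, grid)
    s <- curve_cumint(sampled_curve(grid, aif))
    tot <- s$values[length(s$values)]
    if (tot <= 0) stop("prior-mean AIF has zero integral")
    sampled_curve(grid, s$values / tot)
  } else {
    if (is.null(background_tac)) stop("measured background mode requires a background TAC")
    stopifnot(inherits(background_tac, "roi_tac"))
    # constant extension on both sides: the pattern is only known from the
    # first frame onward, and a zero cliff there would be an artefact
    v <- stats::approx(background_tac$schedule$mid, background_tac$z,
                       xout = grid, rule = 2)$y
    sampled_curve(grid, v)
  }
}

#' Weighted residual sum of squares
#'
#' `sum_i w_i (z_i - X_i' theta)^2`, the data-fit criterion.
#'
#' @param theta Coefficient vector (length `ncol(X)`).
#' @param X Design matrix.
#' @param z Observed activities.
#' @param w Positive weights.
#' @return Scalar WRSS, `>= 0`.
#' @export
wrss <- function(theta, X, z, w) {
  r <- z - as.numeric(X %*% theta)
  sum(w * r * r)
}

#' Non-negative equality-constrained weighted least squares
#'
#' Solves `min_theta sum_i w_i (z_i - X_i' theta)^2 [+ lambda (theta - mu)'
#' Sinv (theta - mu)]` subject to `theta >= 0` and `A' theta = 0`, by dual
#' quadratic programming (Goldfarb-Idnani via `quadprog::solve.QP`). The
#' zero vector is always feasible, so the feasible set is never empty. A
#' tiny ridge proportional to the diagonal scale is added if the quadratic
#' term is numerically rank-deficient; this selects a minimum-norm solution
#' and is reported via a warning.
#'
#' @param X Design matrix `n x p`.
#' @param z Observations, length `n`.
#' @param w Positive weights, length `n`.
#' @param A Equality constraint matrix `p x m` (`A' theta = 0`), or `NULL`.
#' @param penalty Optional list with `lambda` (>= 0), `mu` (prior mean,
#'   length `K <= p`) and `Sinv` (inverse prior covariance, `K x K`); the
#'   penalty applies to the first `K` coordinates only, leaving any
#'   spillover coefficient unpenalised.
#' @return Numeric coefficient vector of length `p` (non-negative,
#'   satisfying the equality constraints to solver tolerance).
#' @export
qp_solve <- function(X, z, w, A = NULL, penalty = NULL) {
  p <- ncol(X)
  sw <- sqrt(w)
  Xw <- X * sw
  Dmat <- crossprod(Xw)
  dvec <- crossprod(Xw, sw * z)
  if (!is.null(penalty) && penalty$lambda > 0) {
    K <- length(penalty$mu)
    idx <- seq_len(K)
    Dmat[idx, idx] <- Dmat[idx, idx] + penalty$lambda * penalty$Sinv
    dvec[idx] <- dvec[idx] +
      penalty$lambda * as.numeric(penalty$Sinv %*% penalty$mu)
  }
  m <- if (is.null(A)) 0L else ncol(A)
  Amat <- cbind(if (m > 0L) A, diag(p))
  bvec <- numeric(m + p)
  # normalise the quadratic form's overall scale: the minimiser is invariant
  # and the dual solver is much more stable under heavy penalties
  sc <- mean(diag(Dmat))
  if (sc <= 0) sc <- 1
  Dmat <- Dmat / sc
  dvec <- dvec / sc
  base_ridge <- 1e-12
  ridge <- 0
  for (attempt in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat + diag(ridge, p), as.numeric(dvec),
                         Amat, bvec, meq = m),
      error = function(e) e)
    if (!inherits(sol, "error")) break
    # theta = 0 satisfies A'theta = 0, theta >= 0, so the feasible set is
    # never empty: "inconsistent constraints" here is a conditioning
    # failure and is retried with a larger ridge like rank deficiency
    ridge <- if (ridge == 0) base_ridge else ridge * 100
  }
  if (inherits(sol, "error"))
    stop("quadratic program failed: ", conditionMessage(sol))
  if (ridge > base_ridge)
    warning("ill-conditioned system; ridge of ", signif(ridge, 3),
            " applied (minimum-norm convention)")
  pmax(sol$solution, 0)
}

# ---- fitting context ------------------------------------------------------

# Precomputes everything that does not depend on (pi, phi, delta):
# the basis-injection convolutions on the fine grid and at arbitrary times,
# and the un-shifted background pattern. Dispersed design columns are cached
# per phi value.
make_fit_context <- function(t_obs, z, w, injection, knots,
                             background = NULL, prior = NULL,
                             background_tac = NULL, delta_max = 0,
                             grid = NULL) {
  K <- knots$K
  if (is.null(grid))
    grid <- default_grid(max(t_obs) + max(0, -delta_max) + 1)
  if (injection$kind == "measured") {
    BI_grid <- vapply(seq_len(K), function(k)
      convolve_with_injection(knots, injection, grid, k = k),
      numeric(length(grid)))
    und_eval <- function(times) {
      out <- interp_cols(grid, BI_grid, times)
      out[times < 0, ] <- 0
      out
    }
  } else {
    t0 <- knots$knots[seq_len(K)]
    h <- knots$knots[-1L] - t0
    # antiderivative of B_k, all columns at once (closed form)
    anti <- function(x) {
      x <- pmax(x, 0)
      U <- pmin(pmax(outer(x, t0, "-"), 0),
                matrix(h, length(x), K, byrow = TRUE))
      outer(x, t0, pmin) + U - U^2 / matrix(2 * h, length(x), K, byrow = TRUE)
    }
    und_eval <- if (injection$kind == "square") {
      function(times) {
        out <- injection$height *
          (anti(times) - anti(times - injection$duration))
        out[times < 0, ] <- 0
        out
      }
    } else {  # bolus: B_k itself times the mass
      function(times) {
        U <- pmin(pmax(outer(pmax(times, 0), t0, "-"), 0),
                  matrix(h, length(times), K, byrow = TRUE))
        out <- injection$mass *
          (1 - U / matrix(h, length(times), K, byrow = TRUE))
        out[times < 0, ] <- 0
        out
      }
    }
    BI_grid <- und_eval(grid)
  }
  bg0 <- if (!is.null(background))
    background_base(injection, background, grid, prior, background_tac)
  ctx <- list(t_obs = t_obs, z = z, w = w, injection = injection,
              knots = knots, K = K, grid = grid, dt = grid[2L] - grid[1L],
              BI_grid = BI_grid, und_eval = und_eval,
              background = background, bg0 = bg0,
              disp_cache = new.env(parent = emptyenv()))
  ctx
}

# dispersed basis-injection convolutions on the grid, cached per phi
dispersed_grid <- function(ctx, phi) {
  key <- sprintf("phi%.10e", phi)
  hit <- ctx$disp_cache[[key]]
  if (!is.null(hit)) return(hit)
  D <- exp_kernel_filter(ctx$BI_grid, dt = ctx$dt, phi = phi)
  # phi repeats across the multi-start grid but varies continuously during
  # refinement; bound the cache so refinement does not accumulate memory
  if (length(ctx$disp_cache) < 50L) ctx$disp_cache[[key]] <- D
  D
}

# design matrix at (pi, phi, delta): columns 1..K mix the direct and
# dispersed basis responses, column K+1 (if a background is present) is the
# background pattern at the frame times.
design_matrix <- function(ctx, pi, phi, delta) {
  tshift <- ctx$t_obs - delta
  X <- ctx$und_eval(tshift)
  if (pi > 0) {
    Xd <- interp_cols(ctx$grid, dispersed_grid(ctx, phi), tshift)
    X <- (1 - pi) * X + pi * Xd
  }
  if (!is.null(ctx$bg0)) {
    s_t <- if (identical(ctx$background, "measured")) ctx$t_obs else tshift
    X <- cbind(X, interp_cols(ctx$grid,
                              matrix(ctx$bg0$values, ncol = 1L), s_t))
  }
  unname(X)
}

# reduced objective: the QP solution profile over theta at fixed nuisance
# parameters; returns the (optionally penalised) objective value and theta
reduced_objective <- function(ctx, pi, phi, delta, A, penalty) {
  X <- design_matrix(ctx, pi, phi, delta)
  th <- qp_solve(X, ctx$z, ctx$w, A = A, penalty = penalty)
  obj <- wrss(th, X, ctx$z, ctx$w)
  if (!is.null(penalty) && penalty$lambda > 0) {
    d <- th[seq_along(penalty$mu)] - penalty$mu
    obj <- obj + penalty$lambda * sum(d * (penalty$Sinv %*% d))
  }
  list(obj = obj, theta = th, X = X)
}

#' Default bounds for the nonlinear nuisance parameters
#'
#' @return List with elements `pi` (mixing fraction), `phi` (dispersion time
#'   constant, seconds) and `delta` (time shift, seconds), each a
#'   `c(lower, upper)` pair.
#' @export
default_nl_bounds <- function() {
  list(pi = c(0, 1), phi = c(0.5, 120), delta = c(-30, 120))
}

#' Fit the blood-pool ROI measurement model
#'
#' Estimates the impulse-response coefficients `theta`, spillover
#' coefficient `alpha3`, dispersion mixing fraction `pi`, dispersion time
#' constant `phi` and time shift `delta` from an ROI time-activity curve.
#' For fixed `(pi, phi, delta)` the coefficients solve a non-negative,
#' equality-constrained weighted least-squares problem by quadratic
#' programming; the reduced objective is then minimised over
#' `(pi, phi, delta)` by a coarse multi-start grid followed by bounded
#' quasi-Newton (`L-BFGS-B`) refinement. The direct-signal coefficient is
#' fixed at 1, so `theta` is unnormalised and `pi` is the dispersed fraction
#' of the blood signal.
#'
#' `mode = "arterial"` is for directly sampled arterial curves: dispersion
#' (`pi = 0`) and spillover (`alpha3 = 0`) are fixed and only `delta` is
#' optimised; constraints default to none.
#'
#' @param roi An [roi_timecourse()].
#' @param injection An [injection_profile()].
#' @param knots A [knot_vector()] whose last knot is beyond the study end.
#' @param spec A [constraint_spec()] or `NULL` for an unconstrained fit.
#' @param background Background mode for the spillover column:
#'   `"patlak"`, `"prior_aif"`, `"measured"`, or `NULL` to omit the
#'   spillover term.
#' @param prior An [aif_prior()]; required for `background = "prior_aif"`
#'   and for `lambda > 0`.
#' @param background_tac [roi_timecourse()] for `background = "measured"`.
#' @param lambda Regularisation weight (`>= 0`); `0` gives the unpenalised
#'   fit, positive values add the Mahalanobis penalty
#'   `lambda * (theta - mu_theta)' Sigma_theta^{-1} (theta - mu_theta)`.
#' @param mode `"roi"` (full model) or `"arterial"` (delta-only).
#' @param nl_bounds Bounds list as from [default_nl_bounds()].
#' @param control List of optimiser knobs: `n_pi`, `n_phi`, `n_delta`
#'   (multi-start grid sizes), `refine` (logical, run L-BFGS-B), `maxit`.
#' @return An object of class `aif_fit` with elements `theta`, `alpha3`,
#'   `pi`, `phi`, `delta`, `wrss`, `penalty`, `objective`, `lambda`,
#'   `active_set`, `sigma2` (filled by [sigma2_ratio()]), plus the design
#'   matrix `X`, background values `S`, data and metadata needed by the
#'   downstream pooling and scaling operations.
#' @export
fit_roi <- function(roi, injection, knots, spec = NULL,
                    background = "patlak", prior = NULL,
                    background_tac = NULL, lambda = 0,
                    mode = c("roi", "arterial"),
                    nl_bounds = default_nl_bounds(), control = list()) {
  stopifnot(inherits(roi, "roi_tac"))
  mode <- match.arg(mode)
  fit_tac(roi$schedule$mid, roi$z, roi$w, injection, knots, spec = spec,
          background = if (mode == "roi") background else NULL,
          prior = prior, background_tac = background_tac, lambda = lambda,
          mode = mode, nl_bounds = nl_bounds, control = control)
}

# core fitter on raw (t, z, w) observations
fit_tac <- function(t_obs, z, w, injection, knots, spec = NULL,
                    background = "patlak", prior = NULL,
                    background_tac = NULL, lambda = 0,
                    mode = c("roi", "arterial"),
                    nl_bounds = default_nl_bounds(), control = list()) {
  mode <- match.arg(mode)
  ctrl <- utils::modifyList(
    list(n_pi = 4L, n_phi = 4L, n_delta = 5L, refine = TRUE, maxit = 60L,
         factr = 1e9),
    control)
  if (all(z == 0)) {
    warning("all-zero ROI activities; returning a zero fit")
    K <- knots$K
    return(finish_fit(theta_aug = numeric(K + (mode == "roi" &&
             !is.null(background))), pi = 0, phi = nl_bounds$phi[1L],
           delta = 0, ctx = make_fit_context(t_obs, z, w, injection, knots,
             background = if (mode == "roi") background else NULL,
             prior = prior, background_tac = background_tac,
             delta_max = nl_bounds$delta[1L]),
           A = NULL, penalty = NULL, lambda = lambda, mode = mode,
           convergence = 0L))
  }
  penalty <- NULL
  if (lambda > 0) {
    if (is.null(prior)) stop("a prior is required when lambda > 0")
    if (!isTRUE(all.equal(prior$knots$knots, knots$knots)))
      stop("prior knots do not match the fitting knots")
    penalty <- list(lambda = lambda, mu = prior$mu_theta,
                    Sinv = prior_precision(prior))
  }
  A <- if (!is.null(spec)) {
    Afull <- build_constraints(knots, spec)
    if (ncol(Afull) == 0L) NULL else Afull
  }
  ctx <- make_fit_context(t_obs, z, w, injection, knots,
                          background = if (mode == "roi") background else NULL,
                          prior = prior, background_tac = background_tac,
                          delta_max = nl_bounds$delta[1L])
  # without a background column the design is only K wide: drop A's
  # spillover row
  A_use <- A
  if (is.null(ctx$bg0) && !is.null(A_use) && nrow(A_use) == knots$K + 1L)
    A_use <- A_use[seq_len(knots$K), , drop = FALSE]

  obj_fun <- function(pi, phi, delta)
    reduced_objective(ctx, pi, phi, delta, A_use, penalty)$obj

  if (mode == "arterial") {
    dgrid <- seq(nl_bounds$delta[1L], nl_bounds$delta[2L],
                 length.out = max(ctrl$n_delta, 5L))
    vals <- vapply(dgrid, function(d) obj_fun(0, nl_bounds$phi[1L], d),
                   numeric(1))
    i <- which.min(vals)
    lo <- dgrid[max(1L, i - 1L)]; hi <- dgrid[min(length(dgrid), i + 1L)]
    op <- stats::optimize(function(d) obj_fun(0, nl_bounds$phi[1L], d),
                          lower = lo, upper = hi, tol = 1e-3)
    best <- list(pi = 0, phi = nl_bounds$phi[1L], delta = op$minimum)
    conv <- 0L
  } else {
    pis <- seq(nl_bounds$pi[1L], nl_bounds$pi[2L], length.out = ctrl$n_pi)
    phis <- exp(seq(log(nl_bounds$phi[1L]), log(nl_bounds$phi[2L]),
                    length.out = ctrl$n_phi))
    deltas <- seq(nl_bounds$delta[1L], nl_bounds$delta[2L],
                  length.out = ctrl$n_delta)
    starts <- if (!is.null(ctrl$start)) list(ctrl$start) else list()
    if (!(isTRUE(ctrl$skip_grid) && length(starts) > 0L)) {
      gridpts <- expand.grid(pi = pis, phi = phis, delta = deltas)
      gv <- mapply(obj_fun, gridpts$pi, gridpts$phi, gridpts$delta)
      i <- which.min(gv)
      starts <- c(starts, list(list(pi = gridpts$pi[i], phi = gridpts$phi[i],
                                    delta = gridpts$delta[i])))
    }
    best <- NULL; best_val <- Inf; conv <- 1L
    for (s in starts) {
      if (isTRUE(ctrl$refine)) {
        op <- tryCatch(stats::optim(
          c(s$pi, log(s$phi), s$delta),
          function(p) obj_fun(min(max(p[1L], 0), 1), exp(p[2L]), p[3L]),
          method = "L-BFGS-B",
          lower = c(nl_bounds$pi[1L], log(nl_bounds$phi[1L]),
                    nl_bounds$delta[1L]),
          upper = c(nl_bounds$pi[2L], log(nl_bounds$phi[2L]),
                    nl_bounds$delta[2L]),
          control = list(maxit = ctrl$maxit, factr = ctrl$factr)),
          error = function(e) NULL)
      } else op <- NULL
      if (is.null(op)) {
        val <- obj_fun(s$pi, s$phi, s$delta)
        cand <- list(pi = s$pi, phi = s$phi, delta = s$delta); cc <- 1L
      } else {
        val <- op$value
        cand <- list(pi = op$par[1L], phi = exp(op$par[2L]),
                     delta = op$par[3L])
        cc <- op$convergence
      }
      if (val < best_val) { best_val <- val; best <- cand; conv <- cc }
    }
  }
  final <- reduced_objective(ctx, best$pi, best$phi, best$delta, A_use, penalty)
  finish_fit(final$theta, best$pi, best$phi, best$delta, ctx, A_use, penalty,
             lambda, mode, conv, X = final$X)
}

# prior precision with a small diagonal ridge: the number of basis
# coefficients can exceed the number of arterial curves behind the prior,
# so the raw sample covariance may be singular
prior_precision <- function(prior, eps = 1e-6) {
  S <- prior$sigma_theta
  S <- S + diag(eps * mean(diag(S)), nrow(S))
  solve(S)
}

finish_fit <- function(theta_aug, pi, phi, delta, ctx, A, penalty, lambda,
                       mode, convergence, X = NULL) {
  K <- ctx$K
  if (length(theta_aug) == 0L) theta_aug <- numeric(K + !is.null(ctx$bg0))
  if (is.null(X)) X <- design_matrix(ctx, pi, phi, delta)
  has_bg <- !is.null(ctx$bg0)
  theta <- theta_aug[seq_len(K)]
  alpha3 <- if (has_bg) theta_aug[K + 1L] else 0
  w_rss <- wrss(theta_aug, X, ctx$z, ctx$w)
  pen_val <- if (!is.null(penalty) && penalty$lambda > 0) {
    d <- theta - penalty$mu
    penalty$lambda * sum(d * (penalty$Sinv %*% d))
  } else 0
  scale_th <- max(abs(theta_aug), 1e-12)
  structure(list(
    theta = theta, alpha3 = alpha3, pi = pi, phi = phi, delta = delta,
    wrss = w_rss, penalty = pen_val, objective = w_rss + pen_val,
    lambda = lambda, sigma2 = NA_real_,
    active_set = which(theta_aug <= 1e-9 * scale_th),
    knots = ctx$knots, injection = ctx$injection, mode = mode,
    X = X, S = if (has_bg) X[, K + 1L] else rep(0, length(ctx$z)),
    z = ctx$z, w = ctx$w, t_obs = ctx$t_obs,
    convergence = convergence,
    ctx = ctx, A = A, penalty_spec = penalty),
    class = "aif_fit")
}

#' @export
print.aif_fit <- function(x, ...) {
  cat(sprintf(
    "AIF fit (%s mode): WRSS = %.6g, pi = %.3f, phi = %.2f s, delta = %.2f s, alpha3 = %.4g, lambda = %.3g\n",
    x$mode, x$wrss, x$pi, x$phi, x$delta, x$alpha3, x$lambda))
  invisible(x)
}

#' Fitted impulse response of a fit
#'
#' @param fit An `aif_fit`.
#' @param normalized Normalise to unit integral?
#' @return An [impulse_response()].
#' @export
fit_ir <- function(fit, normalized = FALSE) {
  stopifnot(inherits(fit, "aif_fit"))
  ir <- impulse_response(fit$knots, fit$theta)
  if (normalized) normalize_ir(ir) else ir
}

#' Fitted (unscaled) AIF of a fit
#'
#' The extracted AIF is the fitted impulse response convolved with the
#' injection profile. Its scale is arbitrary whenever dispersion or
#' spillover are present; see the scaling operations.
#'
#' @param fit An `aif_fit`.
#' @param grid Evaluation grid; defaults to the fit's internal grid.
#' @return A [sampled_curve()].
#' @export
aif_curve <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "aif_fit"))
  if (is.null(grid)) grid <- fit$ctx$grid
  ir <- impulse_response(fit$knots, fit$theta)
  sampled_curve(grid, convolve_with_injection(ir, fit$injection, grid))
}

#' Model-predicted frame values of a fit
#'
#' @param object An `aif_fit`.
#' @param ... Unused.
#' @return Fitted values at the frame times.
#' @export
fitted.aif_fit <- function(object, ...) {
  as.numeric(object$X %*% c(object$theta,
                            if (ncol(object$X) > length(object$theta))
                              object$alpha3))
}
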