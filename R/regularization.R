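#' Mahalanobis-penalised AIF fit
#'
#' Minimises the regularised criterion
#' `WRSS(theta, pi, phi, delta) + lambda (theta - mu_theta)'
#' Sigma_theta^{-1} (theta - mu_theta)` subject to `theta >= 0` and the
#' equality constraints, where `(mu_theta, Sigma_theta)` summarise a
#' population of impulse responses fitted to directly sampled arterial
#' curves. With `lambda = 0` this is the unpenalised fit; as
#' `lambda -> Inf` the coefficient estimate shrinks to the population mean.
#' The spillover coefficient is never penalised (the population carries no
#' information about ROI-specific spillover).
#'
#' @inheritParams fit_roi
#' @param prior An [aif_prior()] supplying `mu_theta` and `Sigma_theta`.
#'   The prior covariance is ridged by `1e-6 * mean(diag)` before inversion
#'   since the basis dimension may exceed the number of arterial curves.
#' @param lambda Penalty weight, `>= 0`.
#' @return An `aif_fit`; see [fit_roi()].
#' @export
penalized_fit <- function(roi, injection, knots, spec, prior, lambda,
                          background = "patlak", background_tac = NULL,
                          nl_bounds = default_nl_bounds(), control = list()) {
  if (lambda < 0) stop("lambda must be non-negative")
  fit_roi(roi, injection, knots, spec = spec, background = background,
          prior = prior, background_tac = background_tac, lambda = lambda,
          nl_bounds = nl_bounds, control = control)
}

# Effective degrees of freedom of the fit as a linear smoother in z,
# restricted to the converged active set: coordinates held at the zero
# bound are dropped, the equality constraints are absorbed by a null-space
# basis Z, and
#   tr(H) = tr( (Z'(M + lambda P)Z)^{-1} Z' M Z ),  M = X'WX on free coords.
hat_trace <- function(fit) {
  p <- ncol(fit$X)
  theta_aug <- c(fit$theta, if (p > length(fit$theta)) fit$alpha3)
  free <- which(theta_aug > 1e-9 * max(abs(theta_aug), 1e-12))
  if (length(free) == 0L) return(0)
  Xf <- fit$X[, free, drop = FALSE]
  M <- crossprod(Xf * sqrt(fit$w))
  P <- matrix(0, p, p)
  if (!is.null(fit$penalty_spec) && fit$penalty_spec$lambda > 0) {
    K <- length(fit$penalty_spec$mu)
    P[seq_len(K), seq_len(K)] <- fit$penalty_spec$lambda * fit$penalty_spec$Sinv
  }
  Pf <- P[free, free, drop = FALSE]
  Z <- if (is.null(fit$A)) diag(length(free)) else {
    Af <- fit$A[free, , drop = FALSE]
    sv <- svd(Af, nu = nrow(Af))
    r <- sum(sv$d > 1e-10 * max(sv$d, 1e-300))
    if (r >= nrow(Af)) return(0)
    sv$u[, (r + 1L):nrow(Af), drop = FALSE]
  }
  G <- crossprod(Z, (M + Pf) %*% Z)
  N <- crossprod(Z, M %*% Z)
  sum(diag(solve(G, N)))
}

#' Select the regularisation weight by generalised cross-validation
#'
#' Fits the penalised model along a grid of `lambda` values, re-optimising
#' the nuisance parameters `(pi, phi, delta)` at each (warm-started from the
#' previous value), and selects the minimiser of the GCV score
#' `GCV(lambda) = (WRSS/n) / (1 - tr(H_lambda)/n)^2`, where `H_lambda` is
#' the hat matrix of the equality-constrained penalised smoother restricted
#' to the converged active set. Values of `lambda` whose effective degrees
#' of freedom reach `n` are excluded. Ties are broken toward the larger
#' (smoother) `lambda`.
#'
#' @inheritParams penalized_fit
#' @param lambda_grid Positive, increasing grid of penalty weights. Default:
#'   25 log-spaced points spanning `1e-4` to `1e4` times the natural scale
#'   `n / tr(Sigma_theta^{-1})`.
#' @return List with `lambda` (selected weight), `fit` (the fit at that
#'   weight), and `table` (a data frame with columns `lambda`, `wrss`,
#'   `penalty`, `edf`, `gcv`).
#' @export
gcv_select <- function(roi, injection, knots, spec, prior,
                       lambda_grid = NULL, background = "patlak",
                       background_tac = NULL,
                       nl_bounds = default_nl_bounds(), control = list()) {
  stopifnot(inherits(roi, "roi_tac"), inherits(prior, "aif_prior"))
  n <- length(roi$z)
  if (is.null(lambda_grid)) {
    scale <- n / sum(diag(prior_precision(prior)))
    lambda_grid <- scale * 10^seq(-4, 4, length.out = 25L)
  }
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive")
  lambda_grid <- sort(lambda_grid)
  fits <- vector("list", length(lambda_grid))
  tab <- data.frame(lambda = lambda_grid, wrss = NA_real_,
                    penalty = NA_real_, edf = NA_real_, gcv = NA_real_)
  ctrl <- control
  for (i in seq_along(lambda_grid)) {
    f <- penalized_fit(roi, injection, knots, spec, prior,
                       lambda = lambda_grid[i], background = background,
                       background_tac = background_tac,
                       nl_bounds = nl_bounds, control = ctrl)
    fits[[i]] <- f
    tr_h <- hat_trace(f)
    tab$wrss[i] <- f$wrss
    tab$penalty[i] <- f$penalty
    tab$edf[i] <- tr_h
    if (tr_h >= n) {
      warning("lambda = ", signif(lambda_grid[i], 3),
              " excluded: effective degrees of freedom reach n")
      tab$gcv[i] <- Inf
    } else {
      tab$gcv[i] <- (f$wrss / n) / (1 - tr_h / n)^2
    }
    # warm start the next lambda from this optimum and skip the grid stage;
    # warm-started refinements need fewer quasi-Newton iterations
    ctrl <- utils::modifyList(control, list(
      start = list(pi = f$pi, phi = f$phi, delta = f$delta),
      skip_grid = TRUE,
      maxit = max(10L, ceiling((if (is.null(control$maxit)) 60L
                                else control$maxit) / 2))))
  }
  ok <- is.finite(tab$gcv)
  if (!any(ok)) stop("GCV failed for every lambda on the grid")
  gmin <- min(tab$gcv[ok])
  best <- max(which(ok & tab$gcv <= gmin * (1 + 1e-10)))
  list(lambda = lambda_grid[best], fit = fits[[best]], table = tab)
}
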