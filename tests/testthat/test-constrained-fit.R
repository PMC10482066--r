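test_that("patlak background is the cumulative integral of the shifted injection", {
  g <- default_grid(300)
  inj <- injection_profile("square", duration = 60, height = 1)
  s <- build_background(inj, delta = 0, mode = "patlak", grid = g)
  expect_equal(curve_value(s, c(10, 30, 60)), c(10, 30, 60), tolerance = 1e-9)
  expect_equal(curve_value(s, c(100, 250)), c(60, 60), tolerance = 1e-9)
  expect_true(all(diff(s$values) >= 0))
  shifted <- build_background(inj, delta = 25, mode = "patlak", grid = g)
  expect_true(all(curve_value(shifted, c(0, 10, 24.9)) == 0))
  expect_equal(curve_value(shifted, 85), 60, tolerance = 1e-6)
})

test_that("prior-mean background is normalised, non-decreasing and requires a prior", {
  kn <- test_knots(300, K = 5)
  inj <- injection_profile("square", duration = 30)
  mu <- normalize_ir(impulse_response(kn, c(0.5, 0.3, 0.1, 0.05, 0.02)))$theta
  pr <- aif_prior(kn, mu, diag(5) * 1e-4, mu1 = 30, mu2 = 0.2,
                  Ta = 8, Tb = 100)
  g <- default_grid(300)
  s <- build_background(inj, mode = "prior_aif", grid = g, prior = pr)
  expect_true(all(diff(s$values) >= -1e-12))
  expect_equal(s$values[length(s$values)], 1, tolerance = 1e-9)
  expect_error(build_background(inj, mode = "prior_aif", grid = g), "prior")
  expect_error(build_background(inj, mode = "measured", grid = g),
               "background TAC")
})

test_that("constraint matrix encodes the residence-time and ratio identities", {
  kn <- knot_vector(c(0, 10, 30))
  spec <- constraint_spec(mu1 = 15, mu2 = 0.5, Ta = 5, Tb = 25)
  A <- build_constraints(kn, spec)
  expect_equal(dim(A), c(3L, 2L))
  expect_equal(A[3, ], c(mrt = 0, contrast = 0))
  # column 1 against quadrature of (mu1 - t) B_k(t)
  for (k in 1:2) {
    quad <- stats::integrate(function(t) (15 - t) * basis_eval(kn, k, t),
                             0, 30, rel.tol = 1e-11)$value
    expect_equal(A[k, 1], quad, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # column 2 from the basis values directly
  expect_equal(A[1, 2], 0.5 * basis_eval(kn, 1, 5) - basis_eval(kn, 1, 25),
               ignore_attr = TRUE)

  # an IR whose residence time is exactly mu1 satisfies the identity
  kn2 <- test_knots(400, K = 6)
  th <- random_theta(kn2, 11)
  ir <- impulse_response(kn2, th)
  spec2 <- constraint_spec(mu1 = ir_mrt(ir), mu2 = 0.5, Ta = 5, Tb = 100)
  A2 <- build_constraints(kn2, spec2)
  expect_equal(sum(A2[1:6, 1] * th), 0, tolerance = 1e-8 * max(abs(th)))

  # basis elements supported before Ta contribute nothing to the ratio row
  kn3 <- knot_vector(c(0, 5, 10, 200))
  spec3 <- constraint_spec(mu1 = 20, mu2 = 0.5, Ta = 50, Tb = 150)
  A3 <- build_constraints(kn3, spec3)
  expect_equal(A3[1, 2], 0, ignore_attr = TRUE)
  expect_equal(A3[2, 2], 0, ignore_attr = TRUE)

  # vacuous ratio times are rejected
  expect_error(build_constraints(kn3, constraint_spec(20, 0.5, 50, 250)),
               "last knot")
})

test_that("design matrix mixes direct and dispersed responses convexly", {
  sch <- simple_schedule(n = 12, dur = 30)
  kn <- test_knots(360, K = 5)
  inj <- injection_profile("square", duration = 30)
  ctx <- aifx:::make_fit_context(sch$mid, rep(1, 12), rep(1, 12), inj, kn,
                                 background = "patlak")
  X0 <- aifx:::design_matrix(ctx, 0, 10, 4)
  X1 <- aifx:::design_matrix(ctx, 1, 10, 4)
  Xm <- aifx:::design_matrix(ctx, 0.3, 10, 4)
  expect_equal(Xm[, 1:5], 0.7 * X0[, 1:5] + 0.3 * X1[, 1:5],
               tolerance = 1e-12)
  # pi = 0 columns equal the undispersed convolution at shifted times
  direct <- vapply(1:5, function(k)
    convolve_with_injection(kn, inj, pmax(sch$mid - 4, 0), k = k),
    numeric(12))
  expect_equal(X0[, 1:5], unname(direct), tolerance = 1e-9)
})

test_that("wrss matches a naive loop and has its defining special cases", {
  with_seed(5, {
    X <- matrix(stats::rnorm(60), 12, 5)
    z <- stats::rnorm(12)
    w <- stats::runif(12, 0.5, 2)
    th <- stats::rnorm(5)
  })
  loop <- 0
  for (i in 1:12) loop <- loop + w[i] * (z[i] - sum(X[i, ] * th))^2
  expect_equal(wrss(th, X, z, w), loop, tolerance = 1e-12)
  expect_equal(wrss(rep(0, 5), X, z, w), sum(w * z^2))
  th_fit <- qp_solve(X, as.numeric(X %*% abs(th)), w)
  expect_equal(wrss(th_fit, X, as.numeric(X %*% abs(th)), w), 0,
               tolerance = 1e-10)
})

test_that("qp_solve equals weighted least squares when constraints are slack", {
  with_seed(8, {
    X <- matrix(stats::runif(80, 0.1, 1), 16, 5)
    th_true <- stats::runif(5, 0.5, 2)
    z <- as.numeric(X %*% th_true) + stats::rnorm(16, 0, 0.01)
    w <- stats::runif(16, 0.5, 2)
  })
  th <- qp_solve(X, z, w)
  ols <- solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), sqrt(w) * z))
  # interior solution: non-negativity inactive
  expect_true(all(ols > 0))
  expect_equal(th, as.numeric(ols), tolerance = 1e-7)
})

test_that("qp_solve recovers noise-free feasible coefficients and satisfies KKT", {
  kn <- test_knots(300, K = 6)
  sch <- simple_schedule(n = 20, dur = 15)
  inj <- injection_profile("square", duration = 15)
  th_true <- c(0.6, 0.25, 0.12, 0.06, 0.02, 0.01)
  ir <- impulse_response(kn, th_true)
  spec <- constraint_spec(mu1 = ir_mrt(ir),
                          mu2 = ir_eval(ir, 100) / ir_eval(ir, 10),
                          Ta = 10, Tb = 100)
  A <- build_constraints(kn, spec)[1:6, , drop = FALSE]
  X <- vapply(1:6, function(k)
    convolve_with_injection(kn, inj, sch$mid, k = k), numeric(20))
  z <- as.numeric(X %*% th_true)
  w <- rep(1, 20)
  th <- qp_solve(X, z, w, A = A)
  expect_equal(th, th_true, tolerance = 1e-6)
  expect_true(all(th >= -1e-10))
  expect_lt(max(abs(t(A) %*% th)), 1e-8 * max(th))
})

test_that("qp_solve beats every feasible probe on the constrained simplex", {
  obj <- function(th, X, z, w) wrss(th, X, z, w)
  for (seed in 1:20) {
    with_seed(seed, {
      X <- matrix(stats::runif(30, 0, 1), 10, 3)
      z <- stats::rnorm(10, mean = 0.3)
      w <- stats::runif(10, 0.5, 2)
    })
    th <- qp_solve(X, z, w)
    val <- obj(th, X, z, w)
    # exhaustive grid over the non-negative box (oracle)
    gr <- seq(0, 2, by = 0.05)
    best <- Inf
    for (a in gr) for (b in gr) {
      cand <- obj(c(a, b, 0), X, z, w)
      if (cand < best) best <- cand
      cand <- obj(c(a, 0, b), X, z, w)
      if (cand < best) best <- cand
      cand <- obj(c(0, a, b), X, z, w)
      if (cand < best) best <- cand
    }
    expect_lte(val, best + 1e-8)
    # random feasible probes never beat the QP
    probes <- with_seed(seed + 100,
                        matrix(stats::rexp(30), 10, 3))
    for (i in 1:10) expect_lte(val, obj(probes[i, ], X, z, w) + 1e-10)
  }
})

test_that("noise-free roi fit recovers the generating curve", {
  kn <- test_knots(435, K = 8, first = 3)
  arch <- builtin_archetypes()$h2o
  th_true <- normalize_ir(impulse_response(
    kn, exp(-kn$knots[-1] / 25)))$theta
  ir <- impulse_response(kn, th_true)
  g <- default_grid(435)
  cp <- sampled_curve(g, convolve_with_injection(ir, arch$injection, g))
  pi_true <- 0.35; phi_true <- 12; a3_true <- 0.4
  cd <- disperse(cp, phi_true)
  s <- build_background(arch$injection, mode = "patlak", grid = g)
  s <- sampled_curve(g, s$values / max(s$values))
  ct <- sampled_curve(g, (1 - pi_true) * cp$values + pi_true * cd$values +
                        a3_true * s$values)
  roi <- roi_timecourse(arch$schedule, curve_value(ct, arch$schedule$mid))
  # with contamination present the shape is identifiable only under the
  # residence-time and contrast-ratio constraints (supplied from truth)
  spec <- constraint_spec(mu1 = ir_mrt(ir),
                          mu2 = ir_eval(ir, kn$knots[7]) /
                            ir_eval(ir, kn$knots[3]),
                          Ta = kn$knots[3], Tb = kn$knots[7])
  fit <- fit_roi(roi, arch$injection, kn, spec = spec,
                 background = "measured",
                 background_tac = roi_timecourse(
                   arch$schedule, curve_value(s, arch$schedule$mid)),
                 control = list(n_pi = 4L, n_phi = 4L, n_delta = 3L,
                                factr = 10, maxit = 300L,
                                start = list(pi = 0.3, phi = 11,
                                             delta = 0.5)))
  est <- aif_curve(fit, grid = g)
  # identifiable up to scale: compare peak-normalised shapes; the
  # time-averaged RMS error must be below 1% of the peak
  shape_est <- est$values / max(est$values)
  shape_tru <- cp$values / max(cp$values)
  rms <- sqrt(aifx:::trapz_integral(g, (shape_est - shape_tru)^2) / 435)
  expect_lt(rms, 0.01 * max(shape_tru))
})

test_that("arterial mode fixes dispersion and spillover and recovers the shift", {
  kn <- test_knots(435, K = 8, first = 3)
  inj <- injection_profile("square", duration = 5)
  th_true <- exp(-kn$knots[-1] / 30) / 10
  ir <- impulse_response(kn, th_true)
  times <- seq(2, 420, by = 6)
  delta_true <- 4.5
  z <- convolve_with_injection(ir, inj, pmax(times - delta_true, 0))
  fit <- fit_arterial_curve(cbind(times, z), inj, kn,
                            delta_bounds = c(-10, 20))
  expect_identical(fit$pi, 0)
  expect_identical(fit$alpha3, 0)
  expect_equal(fit$delta, delta_true, tolerance = 0.1)
  expect_equal(fit$theta, th_true, tolerance = 1e-3)
})

test_that("fits satisfy enabled constraints to high relative accuracy", {
  arch <- builtin_archetypes()$h2o
  kn <- test_knots(435, K = 8, first = 3)
  inj <- arch$injection
  # constraint values consistent with the generating population
  a <- arch$ir_a / sum(arch$ir_a); b <- arch$ir_b
  mu1 <- sum(a * b^2) / sum(a * b)
  Ta <- kn$knots[3]; Tb <- kn$knots[8]
  mu2 <- aifx:::mix_eval(a, b, Tb) / aifx:::mix_eval(a, b, Ta)
  spec <- constraint_spec(mu1 = mu1, mu2 = mu2, Ta = Ta, Tb = Tb)
  n_checked <- 0L
  for (seed in 1:5) {
    truth <- make_true_aif(arch, seed)
    ct <- contaminate(truth$curve, contamination_spec(0.3, 0.5, arch$phi_d),
                      arch$schedule)
    roi <- simulate_roi(ct, arch$schedule, seed = seed + 50)
    fit <- fit_roi(roi, inj, kn, spec = spec, background = "patlak",
                   control = list(n_pi = 2L, n_phi = 2L, n_delta = 3L,
                                  maxit = 15L))
    ir <- fit_ir(fit)
    if (ir_integral(ir) > 1e-6 * max(roi$z)) {
      n_checked <- n_checked + 1L
      expect_equal(ir_mrt(ir), mu1, tolerance = 1e-6)
      ra <- ir_eval(ir, Ta)
      if (ra > 1e-8)
        expect_equal(ir_eval(ir, Tb) / ra, mu2, tolerance = 1e-6)
    }
  }
  expect_gte(n_checked, 3L)
})

test_that("degenerate all-zero data yields a zero fit with a warning", {
  sch <- simple_schedule(n = 8, dur = 30)
  kn <- test_knots(240, K = 4)
  inj <- injection_profile("square", duration = 30)
  expect_warning(fit <- fit_roi(roi_timecourse(sch, rep(0, 8)), inj, kn,
                                spec = NULL),
                 "all-zero")
  expect_equal(fit$theta, rep(0, 4))
})
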