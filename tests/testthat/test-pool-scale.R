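# quick constrained-free fit on synthetic data for pooling tests
make_pool_fit <- function(seed, a3 = 0.3) {
  kn <- test_knots(360, K = 5)
  sch <- simple_schedule(n = 12, dur = 30)
  inj <- injection_profile("square", duration = 30)
  th <- c(0.5, 0.3, 0.12, 0.05, 0.02)
  ir <- impulse_response(kn, th)
  g <- default_grid(360)
  s <- build_background(inj, mode = "patlak", grid = g)
  z <- convolve_with_injection(ir, inj, sch$mid) +
    a3 * curve_value(s, sch$mid) +
    with_seed(seed, stats::rnorm(12, 0, 0.02))
  fit_roi(roi_timecourse(sch, z), inj, kn, spec = NULL,
          background = "patlak",
          control = list(n_pi = 2L, n_phi = 2L, n_delta = 3L, maxit = 10L))
}

test_that("sigma2 ratio matches the loop oracle and its special cases", {
  fit <- make_pool_fit(1)
  fit <- sigma2_ratio(fit)
  num <- 0; den <- 0
  pred <- fitted(fit)
  for (i in seq_along(fit$z)) {
    num <- num + fit$w[i] * (fit$z[i] - pred[i])^2
    den <- den + fit$w[i] * (fit$z[i] - fit$alpha3 * fit$S[i])^2
  }
  expect_equal(fit$sigma2, num / den, tolerance = 1e-12)
  expect_gte(fit$sigma2, 0)
  # a perfect fit gives zero; theta = alpha3 = 0 gives one
  perfect <- fit
  perfect$wrss <- 0
  expect_equal(sigma2_ratio(perfect)$sigma2, 0)
  null <- fit
  null$theta <- rep(0, length(null$theta)); null$alpha3 <- 0
  null$wrss <- sum(null$w * null$z^2)
  expect_equal(sigma2_ratio(null)$sigma2, 1)
})

test_that("pooling is an inverse-variance convex combination", {
  f1 <- sigma2_ratio(make_pool_fit(1))
  f2 <- sigma2_ratio(make_pool_fit(2))
  f3 <- sigma2_ratio(make_pool_fit(3))
  # single fit: identity with weight one
  p1 <- pool_fits(list(f1))
  expect_equal(p1$theta, f1$theta)
  expect_equal(unname(p1$weights), 1)
  # equal variances: arithmetic mean
  f2b <- f2; f2b$sigma2 <- f1$sigma2
  pe <- pool_fits(list(f1, f2b))
  expect_equal(pe$theta, (f1$theta + f2b$theta) / 2, tolerance = 1e-12)
  # general: weights sum to one, pooled inside the envelope
  p <- pool_fits(list(f1, f2, f3))
  expect_equal(sum(p$weights), 1)
  Theta <- rbind(f1$theta, f2$theta, f3$theta)
  expect_true(all(p$theta >= apply(Theta, 2, min) - 1e-12))
  expect_true(all(p$theta <= apply(Theta, 2, max) + 1e-12))
  expect_equal(p$theta, as.numeric(crossprod(Theta, p$weights)))
  # idempotence on identical fits
  pi2 <- pool_fits(list(f1, f1, f1))
  expect_equal(pi2$theta, f1$theta, tolerance = 1e-12)
})

test_that("blood-sample scaling passes through the measurement exactly", {
  g <- default_grid(300)
  aif <- sampled_curve(g, g * exp(-g / 40))
  sc <- scale_blood_sample(aif, t_B = 120, d_B = 7.5)
  expect_equal(curve_value(sc$curve, 120), 7.5, tolerance = 1e-12)
  # factor 1 when the measurement already agrees
  v <- curve_value(aif, 120)
  expect_equal(scale_blood_sample(aif, 120, v)$factor, 1)
  # doubling the measurement doubles the whole curve
  sc2 <- scale_blood_sample(aif, 120, 15)
  expect_equal(sc2$curve$values, 2 * sc$curve$values, tolerance = 1e-12)
  # shape is unchanged: peak-normalised curves identical
  expect_equal(sc$curve$values / max(sc$curve$values),
               aif$values / max(aif$values), tolerance = 1e-12)
  zero <- sampled_curve(g, rep(0, length(g)))
  expect_error(scale_blood_sample(zero, 120, 1), "later")
})

test_that("physiologic scaling recovers a constructed amplitude factor", {
  kn <- test_knots(400, K = 6, first = 4)
  g <- default_grid(400)
  inj <- injection_profile("square", duration = 30)
  aif_ir <- impulse_response(kn, c(0.4, 0.25, 0.12, 0.05, 0.02, 0.01))
  aif <- sampled_curve(g, convolve_with_injection(aif_ir, inj, g))
  # vascular residue with unit integral
  res_kn <- test_knots(400, K = 5, first = 2)
  residue <- normalize_ir(impulse_response(res_kn, c(1, 0.4, 0.1, 0.02, 0)))
  sch <- simple_schedule(n = 13, dur = 30)
  for (c_amp in c(1, 2.5)) {
    inj_aif <- injection_profile("measured", samples = cbind(g, aif$values))
    vz <- c_amp * convolve_with_injection(residue, inj_aif, sch$mid)
    vroi <- roi_timecourse(sch, vz)
    out <- scale_physiologic(aif, vroi, res_kn, delta_bounds = c(0, 5))
    expect_equal(out$factor, c_amp, tolerance = 0.01)
  }
  # correctly scaled AIF with a unit-integral residue gives factor ~ 1
  # (covered by c_amp = 1 above); linearity covered by c_amp = 2.5
})

test_that("Nadler blood volume follows the published formula", {
  expect_equal(nadler_bv(1.80, 80, "M"),
               0.3669 * 1.80^3 + 0.03219 * 80 + 0.6041, tolerance = 1e-12)
  expect_equal(nadler_bv(1.80, 80, "M"), 5.31876, tolerance = 1e-4)
  # monotone in height and weight; female below male at equal body size
  expect_gt(nadler_bv(1.9, 80, "M"), nadler_bv(1.8, 80, "M"))
  expect_gt(nadler_bv(1.8, 90, "M"), nadler_bv(1.8, 80, "M"))
  expect_lt(nadler_bv(1.8, 80, "F"), nadler_bv(1.8, 80, "M"))
  expect_error(nadler_bv(3.1, 80, "M"), "height")
  expect_error(nadler_bv(1.8, 500, "M"), "weight")
})

test_that("dose-per-blood-volume scaling hits its target exactly", {
  g <- default_grid(600)
  aif <- sampled_curve(g, 5 * exp(-g / 200))
  out <- scale_dose_bv(aif, V_I = 8, tau_act = 50, bv = 5, beta_hat = 0.9,
                       T_E = 500)
  expect_equal(curve_value(out$curve, 500), 0.9 * 50 * 8 / 5,
               tolerance = 1e-9)
  # halving the blood volume doubles the factor
  out2 <- scale_dose_bv(aif, 8, 50, 2.5, 0.9, 500)
  expect_equal(out2$factor, 2 * out$factor, tolerance = 1e-12)
  # factor 1 when the target equals the current value
  v <- curve_value(aif, 500)
  out3 <- scale_dose_bv(aif, 8, 50, 5, v * 5 / (50 * 8), 500)
  expect_equal(out3$factor, 1, tolerance = 1e-12)
})

test_that("beta estimation is the no-intercept WLS slope", {
  x <- c(2, 4, 6, 8)
  expect_equal(estimate_beta(0.7 * x, x), 0.7, tolerance = 1e-12)
  # single repeated predictor: mean(y) / x
  y <- c(1.1, 0.9, 1.05)
  expect_equal(estimate_beta(y, rep(2, 3)), mean(y) / 2, tolerance = 1e-12)
  # symmetric noise keeps the estimate near truth (seeded)
  with_seed(99, {
    xx <- stats::runif(40, 1, 10)
    yy <- 1.3 * xx + stats::rnorm(40, 0, 0.1)
  })
  b <- estimate_beta(yy, xx)
  expect_lt(abs(b - 1.3), 0.03)
  expect_error(estimate_beta(c(1, 2), c(0, 0)), "degenerate")
})
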