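test_that("geometric knot construction covers the study with K elements", {
  kn <- make_knots(5400, K = 12, first_knot = 5)
  expect_length(kn$knots, 13)
  expect_identical(kn$knots[1], 0)
  expect_equal(kn$knots[13], 6480)
  expect_true(all(diff(kn$knots) > 0))
  expect_error(make_knots(100, K = 12, first_knot = 200), "first_knot")
  expect_error(make_knots(100, K = 2), "at least 3")
})

test_that("basis elements have plateau, linear ramp and compact support", {
  kn <- knot_vector(c(0, 10, 30, 90))
  # k = 2: plateau on [0, 10), ramp to 0 at 30
  expect_equal(basis_eval(kn, 2, 0), 1)
  expect_equal(basis_eval(kn, 2, 9.99), 1)
  expect_equal(basis_eval(kn, 2, 20), 0.5)
  expect_equal(basis_eval(kn, 2, 30), 0)
  expect_equal(basis_eval(kn, 2, 1000), 0)
  expect_equal(basis_eval(kn, 2, -5), 0)
})

test_that("closed-form basis integrals match numeric quadrature", {
  kn <- knot_vector(c(0, 7, 22, 61, 140))
  for (k in 1:4) {
    quad <- stats::integrate(function(t) basis_eval(kn, k, t), 0,
                             140, rel.tol = 1e-11, subdivisions = 1000L)$value
    expect_equal(aifx:::basis_integral(kn, k),
                 (kn$knots[k] + kn$knots[k + 1]) / 2)
    expect_equal(aifx:::basis_integral(kn, k), quad, tolerance = 1e-8)
    quad_t <- stats::integrate(function(t) t * basis_eval(kn, k, t), 0,
                               140, rel.tol = 1e-11,
                               subdivisions = 1000L)$value
    expect_equal(aifx:::basis_t_moment(kn, k), quad_t, tolerance = 1e-8)
  }
})

test_that("impulse responses are non-negative and non-increasing", {
  kn <- test_knots(300, K = 6)
  for (seed in 1:5) {
    ir <- impulse_response(kn, random_theta(kn, seed))
    t <- sort(with_seed(seed, stats::runif(80, 0, 400)))
    v <- ir_eval(ir, t)
    expect_true(all(v >= 0))
    expect_true(all(diff(v) <= 1e-12))
  }
  # single basis element reproduction and the zero response
  e1 <- rep(0, 6); e1[1] <- 1
  ir1 <- impulse_response(kn, e1)
  tt <- seq(0, 100, by = 0.5)
  expect_equal(ir_eval(ir1, tt), basis_eval(kn, 1, tt))
  expect_equal(ir_eval(impulse_response(kn, rep(0, 6)), tt), rep(0, length(tt)))
})

test_that("normalisation yields unit integral, is idempotent, matches quadrature", {
  kn <- test_knots(400, K = 7)
  for (seed in 1:10) {
    ir <- normalize_ir(impulse_response(kn, random_theta(kn, seed)))
    expect_equal(ir_integral(ir), 1, tolerance = 1e-10)
    expect_equal(ir_quad_integral(ir), 1, tolerance = 1e-6)
    again <- normalize_ir(ir)
    expect_equal(again$theta, ir$theta, tolerance = 1e-12)
  }
  expect_error(normalize_ir(impulse_response(kn, rep(0, 7))), "zero")
})

test_that("square-wave convolution matches adaptive quadrature at random times", {
  kn <- knot_vector(c(0, 5, 18, 60, 200))
  inj <- injection_profile("square", duration = 60)
  times <- with_seed(7, sort(stats::runif(50, 0, 250)))
  for (k in 1:4) {
    closed <- convolve_with_injection(kn, inj, times, k = k)
    oracle <- vapply(times, function(tt)
      stats::integrate(function(s) basis_eval(kn, k, tt - s) *
                         injection_eval(inj, s),
                       0, tt, rel.tol = 1e-10,
                       subdivisions = 2000L)$value, numeric(1))
    expect_equal(closed, oracle, tolerance = 1e-5)
  }
})

test_that("convolution limits: zero at t = 0, bolus identity, total mass", {
  kn <- knot_vector(c(0, 5, 18, 60, 200))
  sq <- injection_profile("square", duration = 10, height = 1)
  bol <- injection_profile("bolus")
  expect_equal(convolve_with_injection(kn, sq, 0, k = 2), 0)
  # a Dirac bolus reproduces the basis element itself
  tt <- seq(0, 120, by = 1)
  expect_equal(convolve_with_injection(kn, bol, tt, k = 3),
               basis_eval(kn, 3, tt))
  # Fubini: integral of B_k * square = d * height * integral of B_k
  for (k in 1:4) {
    grid <- seq(0, 300, by = 0.02)
    vals <- convolve_with_injection(kn, sq, grid, k = k)
    tot <- aifx:::trapz_integral(grid, vals)
    expect_equal(tot, 10 * (kn$knots[k] + kn$knots[k + 1]) / 2,
                 tolerance = 1e-4)
  }
})

test_that("convolution is linear in the coefficients", {
  kn <- test_knots(200, K = 5)
  inj <- injection_profile("square", duration = 20)
  th <- random_theta(kn, 3)
  ir <- impulse_response(kn, th)
  tt <- seq(0, 240, by = 3)
  whole <- convolve_with_injection(ir, inj, tt)
  parts <- Reduce(`+`, lapply(1:5, function(k)
    th[k] * convolve_with_injection(kn, inj, tt, k = k)))
  expect_equal(whole, parts, tolerance = 1e-10)
})

test_that("measured injection profiles convolve consistently with the square closed form", {
  kn <- knot_vector(c(0, 5, 18, 60, 200))
  d <- 20
  ts <- seq(-1, 30, by = 0.05)
  meas <- injection_profile("measured",
                            samples = cbind(ts, ifelse(ts >= 0 & ts < d,
                                                       1 / d, 0)))
  sq <- injection_profile("square", duration = d)
  tt <- seq(5, 150, by = 7)
  a <- convolve_with_injection(kn, meas, tt, k = 3)
  b <- convolve_with_injection(kn, sq, tt, k = 3)
  expect_equal(a, b, tolerance = 5e-3)
})

test_that("dispersion reproduces the closed-form step response and preserves mass", {
  g <- seq(0, 400, by = 0.05)
  step <- sampled_curve(g, rep(1, length(g)))
  for (phi in c(2, 13.7, 50)) {
    out <- disperse(step, phi)
    expect_equal(out$values, 1 - exp(-g / phi), tolerance = 1e-9)
  }
  # phi -> 0 is the identity on the grid scale (away from t = 0, where the
  # causal convolution is exactly zero)
  pulse <- sampled_curve(g, exp(-g / 10))
  tiny <- disperse(pulse, 1e-6)
  expect_lt(max(abs(tiny$values[-1] - pulse$values[-1])), 1e-3)
  # kernel integrates to one: total mass preserved for a compact input
  hump <- sampled_curve(g, exp(-((g - 30) / 8)^2))
  disp <- disperse(hump, 12)
  expect_equal(curve_integral(disp), curve_integral(hump), tolerance = 5e-3)
  expect_error(disperse(hump, 0), "positive")
})

test_that("time shifts compose and interpolate", {
  g <- seq(0, 100, by = 0.5)
  x <- sampled_curve(g, pmax(0, 1 - abs(g - 20) / 10))
  expect_equal(shift_curve(x, 0)$values, x$values)
  one <- shift_curve(x, 0.5)
  expect_equal(one$values[-1], x$values[-length(x$values)])
  # composition within interpolation tolerance (non-integer steps)
  ab <- shift_curve(shift_curve(x, 3.3), 4.4)
  once <- shift_curve(x, 7.7)
  expect_equal(ab$values, once$values, tolerance = 5e-3)
  # values before the shifted origin are zero
  expect_true(all(shift_curve(x, 15)$values[g < 15 - 10] == 0))
})
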