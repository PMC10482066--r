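# Shared fixtures, generated in code.

# small uniform schedule: n frames of `dur` seconds
simple_schedule <- function(n = 10, dur = 60, tau = 0) {
  frame_schedule(seq(0, by = dur, length.out = n),
                 seq(dur, by = dur, length.out = n), decay_constant = tau)
}

# short knot design for fast fits
test_knots <- function(study_end = 435, K = 8, first = 3) {
  make_knots(study_end, K = K, first_knot = first)
}

# deterministic non-negative theta on a knot vector
random_theta <- function(knots, seed = 1) {
  with_seed(seed, stats::rexp(knots$K, rate = seq_len(knots$K)))
}

# numeric quadrature of an impulse response (oracle for closed forms);
# integrates between knots so the integrand is smooth on each panel
ir_quad_integral <- function(ir) {
  kk <- ir$knots$knots
  sum(vapply(seq_len(length(kk) - 1L), function(i)
    stats::integrate(function(t) ir_eval(ir, t), kk[i], kk[i + 1L],
                     rel.tol = 1e-10)$value, numeric(1)))
}

# write a TAC CSV and return the path
write_tac_csv <- function(df, unit = NULL) {
  path <- tempfile(fileext = ".csv")
  con <- file(path, "w")
  if (!is.null(unit)) writeLines(paste0("# time_unit: ", unit), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}
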