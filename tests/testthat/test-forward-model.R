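# Closed-form point-source model: unit conversions, limiting cases, scaling
# laws, and equivalence with an independent finite-difference PDE solution.

test_that("effective diffusion follows lambda^2 = D / D*", {
  expect_equal(effective_diffusion(6.9e-6, 1.0), 6.9e-6)
  expect_equal(effective_diffusion(6.9e-6, 1.54), 6.9e-6 / 1.54^2)
  expect_equal(effective_diffusion(6.9e-6, 1.39), 6.9e-6 / 1.39^2)
  expect_error(effective_diffusion(-1e-6, 1.5), "free_D")
  expect_error(effective_diffusion(6.9e-6, 0), "lambda")
})

test_that("source strength converts current to mol/s and is linear", {
  src <- ionto_source(transport_number = 0.3, free_D = 1.24e-5)
  expect_equal(source_strength(src, 0), 0)
  expect_equal(source_strength(src, 180), 0.3 * 180e-9 / 96485,
               tolerance = 1e-12)
  expect_equal(source_strength(src, 360), 2 * source_strength(src, 180))
  src2 <- ionto_source(transport_number = 0.6, free_D = 1.24e-5)
  expect_equal(source_strength(src2, 180), 2 * source_strength(src, 180))
})

test_that("point-source solution has the right limits and scalings", {
  src <- default_source()
  ecs <- ecs_params(0.2, 1.5, 0.004)
  # nothing released yet
  expect_equal(point_source_concentration(120, 0, src, ecs), 0)
  # uptake-free free-medium limit collapses to the textbook solution
  free <- free_medium()
  t <- c(0.5, 2, 10, 24)
  D <- src$free_D * 1e8
  Q <- source_strength(src, src$step_current) * 1e21
  ref <- Q / (4 * pi * D * 100) * pracma::erfc(100 / (2 * sqrt(D * t)))
  expect_equal(point_source_concentration(100, t, src, free), ref,
               tolerance = 1e-12)
  # linear in step current, inverse in alpha
  src2x <- default_source(step_current = 360)
  expect_equal(point_source_concentration(120, t, src2x, ecs),
               2 * point_source_concentration(120, t, src, ecs))
  half_alpha <- ecs_params(0.1, 1.5, 0.004)
  expect_equal(point_source_concentration(120, t, src, half_alpha),
               2 * point_source_concentration(120, t, src, ecs))
  # domain errors
  expect_error(point_source_concentration(0, 1, src, ecs), "r must")
  expect_error(point_source_concentration(120, -1, src, ecs), "t must")
})

test_that("superposition keeps the curve continuous at the pulse end", {
  src <- default_source()
  ecs <- ecs_params(0.2, 1.5, 0.004)
  eps <- 1e-8
  before <- point_source_concentration(120, src$pulse_duration - eps, src, ecs)
  after <- point_source_concentration(120, src$pulse_duration + eps, src, ecs)
  expect_lt(abs(after - before), 1e-4 * before)
})

test_that("increasing tortuosity lowers early concentration far from source", {
  src <- default_source()
  lams <- c(1.2, 1.5, 1.8, 2.2)
  for (t in c(2, 5)) {
    c_vals <- vapply(lams, function(l)
      point_source_concentration(150, t, src, ecs_params(0.2, l, 0.004)), 0)
    expect_true(all(diff(c_vals) < 0))
  }
})

test_that("bias steady state matches the long-time limit and 1/r decay", {
  ecs <- ecs_params(0.2, 1.5, 0.004)
  src0 <- default_source(bias_current = 0)
  expect_equal(bias_steady_state(120, src0, ecs), 0)
  ecs_k0 <- ecs_params(0.2, 1.5, 0)
  src <- default_source(bias_current = 20)
  expect_equal(bias_steady_state(200, src, ecs_k0),
               bias_steady_state(100, src, ecs_k0) / 2)
  # continuous release approaches the steady state (uptake sets the timescale)
  long <- default_source(bias_current = 20, step_current = 20,
                         pulse_duration = 2e4)
  expect_equal(point_source_concentration(120, 1e4, long, ecs),
               bias_steady_state(120, long, ecs), tolerance = 1e-3)
})

test_that("generated curves rise during the pulse and decay after it", {
  src <- default_source()
  ecs <- ecs_params(0.2, 1.5, 0.004)
  tt <- seq(0, 72, by = 0.1)
  cv <- generate_curve(src, ecs, 120, tt)
  expect_s3_class(cv, "diffusion_curve")
  expect_equal(generate_curve(src, ecs, 120, 0)$concentration, 0)
  expect_true(all(cv$concentration >= 0))
  # the sensor sits 120 um away, so the peak lags the pulse end by a short
  # diffusion delay (a few seconds at most for these parameters)
  peak_t <- tt[which.max(cv$concentration)]
  expect_gte(peak_t, src$pulse_duration)
  expect_lt(peak_t, src$pulse_duration + 5)
  rising <- tt > 0.5 & tt <= src$pulse_duration
  falling <- tt > peak_t + 0.5
  expect_true(all(diff(cv$concentration[rising]) > 0))
  expect_true(all(diff(cv$concentration[falling]) < 0))
})

test_that("closed form agrees with an independent finite-difference solution", {
  src <- default_source()
  ecs <- ecs_params(0.2, 1.5, 0.004)
  oracle <- fd_reference_solution(src, ecs)
  peak <- point_source_concentration(50, src$pulse_duration, src, ecs)
  for (r in c(50, 100, 150, 200)) {
    for (t in c(1, 10, 24, 40, 60)) {
      ref <- point_source_concentration(r, t, src, ecs)
      got <- oracle(r, t)
      # 1% relative, with a small absolute floor for the deep far-field tail
      # (values there are ~1e-9 of the peak and below FD resolution)
      expect_lt(abs(got - ref), 0.01 * ref + 1e-5 * peak)
    }
  }
})
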