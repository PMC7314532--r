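# Dopamine reaction-diffusion solver: waveforms, conservation, linear-uptake
# equivalence with the closed form, monotonicity, and the field integrals.

quick_grid <- function() {
  simulation_grid(r_max_report = 60, t_max = 1.5, r_pad = 200,
                  dr_fine = 0.25, out_times = seq(0, 1.5, by = 0.1),
                  out_r = seq(2, 60, by = 2))
}

test_that("release waveforms implement tonic and burst regimes", {
  tonic <- release_protocol("tonic")
  expect_equal(release_waveform(tonic, 0.5), 100)
  expect_equal(release_waveform(tonic, 2), 0)
  ph <- release_protocol("phasic")
  tt <- seq(0, 0.999999, by = 1e-4)
  on <- release_waveform(ph, tt) > 0
  expect_equal(sum(on) * 1e-4, 20 * 0.004, tolerance = 1e-2)  # 20 bursts, 80 ms
  # charge normalisation: equal integrals of the two waveforms
  dt <- 1e-5
  tt <- seq(0, 1.2, by = dt)
  q_tonic <- sum(release_waveform(tonic, tt)) * dt
  q_phasic <- sum(release_waveform(ph, tt)) * dt
  expect_equal(q_phasic, q_tonic, tolerance = 1e-3)
  # amplitude mode keeps the burst height at the nominal current
  amp <- release_protocol("phasic", normalize = "amplitude")
  expect_equal(max(release_waveform(amp, tt)), 100)
  expect_error(release_protocol("phasic", burst_width = 0.06,
                                burst_frequency = 20), "burst_width")
})

test_that("without uptake the released moles are conserved in the ECS", {
  f <- solve_dopamine(ecs_geometry_control(), uptake_kinetics(0, 0.15),
                      release_protocol("tonic"), quick_grid())
  post <- f$t > 1
  expect_lt(max(abs(f$mass_ecs[post] - f$released[post]) / f$released[post]),
            0.01)
  # and the ECS mass stays constant after the release ends
  expect_lt(diff(range(f$mass_ecs[post])) / max(f$mass_ecs[post]), 0.01)
  # with uptake the mass strictly decreases after release
  fu <- solve_dopamine(ecs_geometry_control(), uptake_kinetics(0.2, 0.15),
                       release_protocol("tonic"), quick_grid())
  expect_true(all(diff(fu$mass_ecs[fu$t > 1]) < 0))
})

test_that("linearised Michaelis-Menten matches the closed-form solution", {
  kp <- 0.2 / 0.15                       # Vm/Km held fixed while Km -> Inf
  Kbig <- 1e9
  prot <- release_protocol("tonic", source_radius = 0.25)
  grid <- simulation_grid(dr_fine = 0.125, fine_to = 60, dr_coarse = 1,
                          out_times = c(0, 0.3, 1, 2.5, 3),
                          out_r = c(20, 50))
  f <- solve_dopamine(ecs_geometry_control(), uptake_kinetics(kp * Kbig, Kbig),
                      prot, grid, rtol = 1e-10, atol = 1e-8)
  src <- ionto_source(bias_current = 0, step_current = 100,
                      pulse_duration = 1, transport_number = 1,
                      free_D = 6.9e-6)
  ecs <- suppressWarnings(ecs_params(0.20, 1.54, kp))
  for (r in c(20, 50)) {
    ref <- point_source_concentration(r, c(1, 2.5), src, ecs)
    got <- f$C[match(c(1, 2.5), f$t), match(r, f$r)]
    expect_lt(max(abs(got - ref) / ref), 0.01)
  }
})

test_that("field differences are signed and antisymmetric", {
  kin <- uptake_kinetics()
  fc <- solve_dopamine(ecs_geometry_control(), kin,
                       release_protocol("tonic"), quick_grid())
  fe <- solve_dopamine(ecs_geometry_etoh(), kin,
                       release_protocol("tonic"), quick_grid())
  zero <- field_difference(fc, fc)
  expect_true(all(zero$C == 0))
  d1 <- field_difference(fe, fc)
  d2 <- field_difference(fc, fe)
  expect_equal(d1$C, -d2$C)
  expect_true(any(d1$C > 0) && any(d1$C < 0))
  bad <- fe; bad$r <- bad$r + 1
  expect_error(field_difference(bad, fc), "grids")
})

test_that("spatial and temporal integrals match analytic test fields", {
  # synthetic field: C(r, t) = (c0 + c1 r) * t on the reported grid
  r <- seq(1, 50, by = 0.5); tt <- seq(0, 2, by = 0.1)
  c0 <- 3; c1 <- 0.2
  fake <- structure(list(
    r = r, t = tt, C = outer(tt, c0 + c1 * r),
    geometry = ecs_geometry(0.2, 1.5)), class = "concentration_field")
  # zero field -> zero series
  zero <- fake; zero$C[] <- 0
  expect_true(all(integrate_space(zero, "volume")$M == 0))
  expect_true(all(integrate_time(zero)$S == 0))
  # trapezoid vs analytic integral of (c0 + c1 r) 4 pi r^2 over [1, 50]
  analytic <- 4 * pi * (c0 * diff(range(r)^3) / 3 + c1 * diff(range(r)^4) / 4)
  M <- integrate_space(fake, "shell")$M
  expect_equal(M, tt * analytic, tolerance = 1e-3)
  expect_equal(integrate_space(fake, "volume")$M, 0.2 * tt * analytic,
               tolerance = 1e-3)
  # time integral of linear-in-t field: S(r) = C(r, 1) * t_max^2 / 2
  S <- integrate_time(fake)$S
  expect_equal(S, (c0 + c1 * r) * 2^2 / 2, tolerance = 1e-12)
})

test_that("stronger uptake can only lower the field", {
  base <- uptake_kinetics(0.2, 0.15)
  sc <- vm_scan(ecs_geometry_control(), base, release_protocol("tonic"),
                quick_grid(), multipliers = c(-0.6, 0.6))
  lo <- sc[["-60%"]]$C
  hi <- sc[["+60%"]]$C
  expect_true(all(hi <= lo + 1e-6 * max(lo)))
  expect_error(vm_scan(ecs_geometry_control(), base,
                       release_protocol("tonic"), quick_grid(),
                       multipliers = -1.5), "negative Vm")
})

test_that("cumulative exposure decreases with distance from the source", {
  f <- solve_dopamine(ecs_geometry_control(), uptake_kinetics(),
                      release_protocol("tonic"), quick_grid())
  S <- integrate_time(f)
  beyond <- S$r >= f$protocol$source_radius
  expect_true(all(diff(S$S[beyond]) <= 0))
})
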