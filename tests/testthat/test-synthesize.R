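# Synthetic-data generators: determinism, noise calibration, cohort layout,
# and file round trips.

test_that("synthetic curves are deterministic and noise-calibrated", {
  src <- default_source()
  truth <- ecs_params(0.2, 1.5, 0.004)
  # zero noise reproduces the forward model
  a <- make_curve(truth, src, 120, noise_fraction = 0, seed = 1)
  clean <- generate_curve(src, truth, 120, rti_times())
  expect_equal(a$curve$concentration, clean$concentration)
  # fixed seed -> identical reruns
  b1 <- make_curve(truth, src, 120, noise_fraction = 0.02, seed = 99)
  b2 <- make_curve(truth, src, 120, noise_fraction = 0.02, seed = 99)
  expect_identical(b1$curve$concentration, b2$curve$concentration)
  # empirical noise SD within 5% of nominal over 1e4 samples
  tt <- seq(0, 72, length.out = 10000)
  big <- make_curve(truth, src, 120, noise_fraction = 0.02, seed = 3,
                    times = tt)
  ref <- generate_curve(src, truth, 120, tt)
  sd_emp <- stats::sd(big$curve$concentration - ref$concentration)
  nominal <- 0.02 * max(ref$concentration)
  expect_lt(abs(sd_emp - nominal) / nominal, 0.05)
})

test_that("cohorts have the specified layout and are seed-stable", {
  spec <- cohort_spec(n_animals = 2L, depths = c(400, 600, 800),
                      repeats = 3L, seed = 17L)
  coh <- make_cohort(spec, default_source())
  expect_length(coh$curves, 2 * 2 * 3 * 3)   # groups x animals x depths x reps
  expect_equal(nrow(coh$truth), 4)
  spacings <- coh$truth$spacing
  expect_true(all(spacings >= 100 & spacings <= 150))
  coh2 <- make_cohort(spec, default_source())
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$curves[[10]]$concentration,
                   coh2$curves[[10]]$concentration)
  # between-animal SD of zero collapses all animals onto the group truth
  spec0 <- cohort_spec(n_animals = 3L, depths = 400, repeats = 1L,
                       between_sd = c(alpha = 0, lambda = 0, kprime = 0),
                       noise_fraction = 0, seed = 2L)
  coh0 <- make_cohort(spec0, default_source())
  expect_equal(unique(coh0$truth$alpha[coh0$truth$group == "control"]), 0.196)
  expect_equal(unique(coh0$truth$lambda[coh0$truth$group == "etoh"]), 1.403)
})

test_that("truth tables survive a CSV round trip", {
  coh <- make_cohort(cohort_spec(n_animals = 2L, depths = 400, repeats = 1L,
                                 seed = 8L), default_source())
  path <- tempfile(fileext = ".csv")
  utils::write.csv(coh$truth, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$alpha, coh$truth$alpha, tolerance = 1e-12)
  expect_equal(back$lambda, coh$truth$lambda, tolerance = 1e-12)
  expect_identical(back$animal_id, coh$truth$animal_id)
})

test_that("synthetic calibration tables follow the log-linear model", {
  tab <- make_calibration(slope = 58, offset = -5, noise_mV = 0)
  expect_length(tab$concentrations, 7)     # the standard 0.25-16 mM series
  expect_equal(tab$voltages, -5 + 58 * log10(tab$concentrations))
  expect_error(make_calibration(slope = -3), "slope")
})

test_that("random microglia trees are consistent with their summaries", {
  trees <- make_microglia_trees(12, seed = 21)
  expect_length(trees, 12)
  for (tr in trees) {
    # brute-force traversal of the stored branch table
    expect_equal(tr$summary$n_terminals, sum(tr$tree$terminal))
    expect_equal(sort(tr$summary$terminal_orders),
                 sort(tr$tree$order[tr$tree$terminal]))
    expect_equal(tr$summary$total_length, sum(tr$tree$length))
    expect_equal(tr$summary$n_primary, sum(tr$tree$order == 1))
  }
  # seeded determinism
  again <- make_microglia_trees(12, seed = 21)
  expect_identical(trees[[5]]$tree, again[[5]]$tree)
})

test_that("curve and calibration CSV files round-trip", {
  src <- default_source()
  cv <- generate_curve(src, ecs_params(0.2, 1.5, 0.004), 120,
                       rti_times(), depth = 800, medium = "tissue",
                       animal_id = "control_01", group = "control")
  p <- tempfile(fileext = ".csv")
  write_curve_csv(cv, p)
  back <- read_curve_csv(p)
  expect_equal(back$concentration, cv$concentration, tolerance = 1e-9)
  expect_equal(back$distance, 120)
  expect_equal(back$depth, 800)
  expect_identical(back$animal_id, "control_01")
  tab <- make_calibration(noise_mV = 0.5, seed = 2)
  p2 <- tempfile(fileext = ".csv")
  write_calibration_csv(tab, p2)
  tab2 <- read_calibration_csv(p2)
  expect_equal(tab2$voltages, tab$voltages, tolerance = 1e-9)
})
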