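# Seeded synthetic-data generators: noisy TMA+ diffusion curves with known
# ground truth (single curves and full two-group cohorts), electrode
# calibration tables, and random microglial skeletons for the morphometry
# index. Every routine takes an explicit seed; cohort-internal seeds are
# derived from the master seed by fixed offsets so a cohort is reproducible
# curve-by-curve.

derive_seed <- function(master, ...) {
  offs <- c(...)
  as.integer((master + sum(offs * seq(17, by = 30, length.out = length(offs)))) %%
               2147483647)
}

rtrunc_norm <- function(mean, sd, lo, hi, max_tries = 1000L) {
  if (sd == 0) {
    if (mean < lo || mean > hi) stop("degenerate draw outside bounds")
    return(mean)
  }
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection exceeded ", max_tries, " tries")
}

#' Synthetic noisy diffusion curve with known truth
#'
#' Samples the forward model and adds Gaussian noise with standard deviation
#' `noise_fraction` times the clean curve's peak (additive, concentration
#' domain).
#'
#' @inheritParams generate_curve
#' @param true_params Generating [ecs_params()].
#' @param noise_fraction Noise SD as a fraction of the clean peak (>= 0).
#' @param seed Integer seed.
#' @return List with `curve` (the noisy [diffusion_curve()]) and `truth`
#'   (one-row data.frame of generating parameters and geometry).
#' @export
make_curve <- function(true_params, source, r, noise_fraction = 0.02,
                       seed = 1L, times = rti_times(source$pulse_duration),
                       depth = NA_real_, medium = "tissue",
                       animal_id = NA_character_, group = NA_character_) {
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  clean <- generate_curve(source, true_params, r, times, depth = depth,
                          medium = medium, animal_id = animal_id,
                          group = group)
  conc <- clean$concentration
  if (noise_fraction > 0) {
    set.seed(seed)
    conc <- conc + stats::rnorm(length(conc), 0,
                                noise_fraction * max(clean$concentration))
  }
  curve <- clean
  curve$concentration <- conc
  list(curve = curve,
       truth = data.frame(animal_id = animal_id, group = group, depth = depth,
                          distance = r, alpha = true_params$alpha,
                          lambda = true_params$lambda,
                          kprime = true_params$kprime,
                          noise_fraction = noise_fraction, seed = seed,
                          stringsAsFactors = FALSE))
}

#' Cohort specification for synthetic RTI experiments
#'
#' Defines the study design of a synthetic two-group cohort. Defaults mirror
#' the in-vivo protocol: recordings at depths 400-2000 um in 200-um steps,
#' three repeats per depth, electrode spacing drawn uniformly from 100-150 um
#' per animal, 2% peak-proportional noise, six animals per group, and group
#' truths set to the reported cortical estimates (control alpha 0.196 /
#' lambda 1.503; EtOH alpha 0.176 / lambda 1.403). Between-animal SDs default
#' to sqrt(6) times the reported group standard errors (0.007 for alpha,
#' 0.015 for lambda) so the simulated cohort's SE matches the reported one at
#' n = 6 per group.
#'
#' @param groups Named list of generating [ecs_params()] per group.
#' @param n_animals Animals per group.
#' @param depths Recording depths, um.
#' @param repeats Curves per depth.
#' @param between_sd Named numeric: between-animal SD of alpha, lambda,
#'   kprime.
#' @param noise_fraction Curve noise SD as a fraction of peak.
#' @param spacing_range Electrode spacing bounds, um.
#' @param seed Master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          control = ecs_params(0.196, 1.503, 0.004),
                          etoh = ecs_params(0.176, 1.403, 0.004)),
                        n_animals = 6L,
                        depths = seq(400, 2000, by = 200),
                        repeats = 3L,
                        between_sd = c(alpha = 0.007 * sqrt(6),
                                       lambda = 0.015 * sqrt(6),
                                       kprime = 0.001),
                        noise_fraction = 0.02,
                        spacing_range = c(100, 150),
                        seed = 1L) {
  if (repeats < 1L) stop("repeats must be >= 1")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  if (spacing_range[1] < 100 || spacing_range[2] > 150)
    stop("electrode spacing must stay within 100-150 um")
  stopifnot(all(c("alpha", "lambda", "kprime") %in% names(between_sd)))
  structure(list(groups = groups, n_animals = as.integer(n_animals),
                 depths = depths, repeats = as.integer(repeats),
                 between_sd = between_sd, noise_fraction = noise_fraction,
                 spacing_range = spacing_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-animal true parameters from truncated normals around each group's
#' truth (truncation at the physical bounds alpha in (0.01, 1], lambda in
#' \[1, 3\], k' in \[0, 0.1\]), then synthesises `repeats` noisy curves at
#' every depth. Fully deterministic given the spec's master seed.
#'
#' @param spec A [cohort_spec()].
#' @param source An [ionto_source()]; its transport number and free D are the
#'   generating values (in analysis they would come from the agar fit).
#' @return List with `curves` (flat list of [diffusion_curve()]), `truth`
#'   (per-animal data.frame of generating parameters), and `spec`.
#' @export
make_cohort <- function(spec, source = ionto_source()) {
  stopifnot(inherits(spec, "cohort_spec"))
  curves <- list()
  truth <- list()
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    gtruth <- spec$groups[[gi]]
    for (ai in seq_len(spec$n_animals)) {
      set.seed(derive_seed(spec$seed, gi * 1000L, ai))
      a <- rtrunc_norm(gtruth$alpha, spec$between_sd[["alpha"]], 0.01, 1)
      l <- rtrunc_norm(gtruth$lambda, spec$between_sd[["lambda"]], 1, 3)
      k <- rtrunc_norm(gtruth$kprime, spec$between_sd[["kprime"]], 0, 0.1)
      spacing <- stats::runif(1, spec$spacing_range[1], spec$spacing_range[2])
      animal <- sprintf("%s_%02d", gname, ai)
      truth[[animal]] <- data.frame(
        animal_id = animal, group = gname, alpha = a, lambda = l, kprime = k,
        spacing = spacing, stringsAsFactors = FALSE)
      pars <- ecs_params(a, l, k)
      for (di in seq_along(spec$depths)) {
        for (ri in seq_len(spec$repeats)) {
          cs <- derive_seed(spec$seed, gi * 100000L, ai * 1000L, di * 10L, ri)
          mk <- make_curve(pars, source, spacing,
                           noise_fraction = spec$noise_fraction, seed = cs,
                           depth = spec$depths[di], medium = "tissue",
                           animal_id = animal, group = gname)
          curves[[length(curves) + 1L]] <- mk$curve
        }
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(curves = curves, truth = truth, spec = spec)
}

#' Synthetic electrode calibration table
#'
#' Log-linear (Nernstian) voltages over the standard fixed-interference
#' concentration series, with optional Gaussian voltage noise.
#'
#' @param slope mV per decade (default 58, near-Nernstian at body
#'   temperature).
#' @param offset mV.
#' @param noise_mV Voltage noise SD, mV.
#' @param seed Integer seed (used when `noise_mV > 0`).
#' @param concentrations Concentration series, mM.
#' @return A [calibration_table()].
#' @export
make_calibration <- function(slope = 58, offset = 0, noise_mV = 0, seed = 1L,
                             concentrations = c(0.25, 0.5, 1, 2, 4, 8, 16)) {
  if (slope <= 0) stop("slope must be > 0")
  v <- offset + slope * log10(concentrations)
  if (noise_mV > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_mV)
  }
  calibration_table(concentrations, v)
}

# Recursively grow one branch; returns a data.frame of branch records.
grow_branch <- function(order, max_order, branch_prob, length_range) {
  len <- stats::runif(1, length_range[1], length_range[2])
  if (order < max_order && stats::runif(1) < branch_prob) {
    kids <- do.call(rbind, lapply(1:2, function(i)
      grow_branch(order + 1L, max_order, branch_prob, length_range)))
    rbind(data.frame(order = order, length = len, terminal = FALSE), kids)
  } else {
    data.frame(order = order, length = len, terminal = TRUE)
  }
}

#' Random microglial skeletons with exact summaries
#'
#' Grows random rooted binary branching trees (each process leaving the soma
#' is an order-1 primary branch; children increment the order) and computes
#' the [skeleton_summary()] exactly from the generated branches.
#'
#' @param n Number of cells.
#' @param n_primary_range Integer range of primary processes per cell.
#' @param branch_prob Probability that a branch below `max_order` bifurcates.
#' @param max_order Maximum branch order.
#' @param length_range Branch length bounds, um.
#' @param seed Integer seed.
#' @return List of length `n`; each element has `tree` (data.frame of branch
#'   order/length/terminal) and `summary` (a [skeleton_summary()]).
#' @export
make_microglia_trees <- function(n, n_primary_range = c(2L, 6L),
                                 branch_prob = 0.5, max_order = 5L,
                                 length_range = c(5, 40), seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    n_primary <- sample(seq(n_primary_range[1], n_primary_range[2]), 1L)
    tree <- do.call(rbind, lapply(seq_len(n_primary), function(p)
      grow_branch(1L, max_order, branch_prob, length_range)))
    rownames(tree) <- NULL
    summ <- skeleton_summary(
      terminal_orders = tree$order[tree$terminal],
      total_length = sum(tree$length),
      n_primary = n_primary)
    list(tree = tree, summary = summ)
  })
}
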