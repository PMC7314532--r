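# Closed-form point-source diffusion model for an inert tracer (TMA+) in brain
# extracellular space with first-order nonspecific uptake.
#
# Internal unit conventions used throughout the package:
#   length um, time s, concentration uM, current nA.
#   Diffusion coefficients are accepted in cm^2/s at the API and converted
#   (1 cm^2/s = 1e8 um^2/s).

FARADAY <- 96485          # C/mol
CM2_TO_UM2 <- 1e8         # cm^2/s -> um^2/s
MOL_TO_UM3_UM <- 1e21     # mol -> uM * um^3  (1 mol = 1e6 umol = 1e21 uM um^3)

#' ECS diffusion parameters
#'
#' Container for the triplet describing extracellular-space (ECS) geometry and
#' nonspecific tracer loss: volume fraction `alpha` (ECS volume / total tissue
#' volume), tortuosity `lambda` (`lambda^2 = D / ADC`, the hindrance relative
#' to free diffusion) and the first-order nonspecific uptake rate `kprime`.
#'
#' @param alpha ECS volume fraction, dimensionless, in (0, 1].
#' @param lambda Tortuosity, dimensionless, >= 0.9 (values in \[0.9, 1) are
#'   permitted as slack for noisy fits and flagged with a warning; the physical
#'   range is lambda >= 1).
#' @param kprime Nonspecific uptake rate constant, 1/s, >= 0.
#' @return An object of class `ecs_params`.
#' @export
ecs_params <- function(alpha, lambda, kprime = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(lambda), length(lambda) == 1L,
            is.numeric(kprime), length(kprime) == 1L)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (lambda < 0.9) stop("lambda must be >= 0.9")
  if (lambda < 1) warning("lambda < 1 is unphysical; allowed as fit slack only")
  if (kprime < 0) stop("kprime must be >= 0")
  structure(list(alpha = alpha, lambda = lambda, kprime = kprime),
            class = "ecs_params")
}

#' @export
print.ecs_params <- function(x, ...) {
  cat(sprintf("ECS parameters: alpha = %.4g, lambda = %.4g, k' = %.4g /s\n",
              x$alpha, x$lambda, x$kprime))
  invisible(x)
}

#' Iontophoretic source description
#'
#' Current protocol and electrode properties defining the tracer source of a
#' real-time iontophoresis (RTI) experiment: a continuously applied bias
#' current (keeping the electrode transport number constant) plus a rectangular
#' current step that generates the diffusion curve.
#'
#' @param bias_current Bias current, nA (default 20).
#' @param step_current Main current step, nA (default 180).
#' @param pulse_duration Duration of the current step, s (default 24).
#' @param transport_number Fraction of the current carried by the tracer ion,
#'   in (0, 1].
#' @param free_D Free-medium diffusion coefficient of the tracer, cm^2/s.
#' @param valence Ion charge number (1 for TMA+).
#' @return An object of class `ionto_source`.
#' @export
ionto_source <- function(bias_current = 20, step_current = 180,
                         pulse_duration = 24, transport_number = 0.3,
                         free_D = 1.24e-5, valence = 1L) {
  if (step_current <= 0) stop("step_current must be > 0")
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (!(transport_number > 0 && transport_number <= 1))
    stop("transport_number must lie in (0, 1]")
  if (free_D <= 0) stop("free_D must be > 0")
  if (bias_current < 0) stop("bias_current must be >= 0")
  structure(list(bias_current = bias_current, step_current = step_current,
                 pulse_duration = pulse_duration,
                 transport_number = transport_number,
                 free_D = free_D, valence = as.integer(valence)),
            class = "ionto_source")
}

#' Effective diffusion coefficient in tissue
#'
#' Tortuosity relates free and effective diffusion by `lambda^2 = D / D*`,
#' so the apparent (effective) coefficient is `D* = D / lambda^2`.
#'
#' @param free_D Free diffusion coefficient, cm^2/s.
#' @param lambda Tortuosity, dimensionless.
#' @return Effective diffusion coefficient, cm^2/s.
#' @export
effective_diffusion <- function(free_D, lambda) {
  if (any(free_D <= 0)) stop("free_D must be > 0")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  free_D / lambda^2
}

#' Molar release rate of an iontophoretic current
#'
#' Converts an iontophoretic current into a molar release rate,
#' `Q = I * n_t / (z * F)` with Faraday's constant F = 96485 C/mol.
#'
#' @param source An [ionto_source()].
#' @param current Current, nA; defaults to the source's step current.
#' @return Release rate, mol/s.
#' @export
source_strength <- function(source, current = source$step_current) {
  stopifnot(inherits(source, "ionto_source"))
  if (any(current < 0)) stop("current must be >= 0")
  current * 1e-9 * source$transport_number / (source$valence * FARADAY)
}

# Scaled complementary error function exp(x^2) * erfc(x) for x >= 0.
# pracma::erfcx underflows to NaN beyond ~26.5; the divergent asymptotic series
# 1/(x sqrt(pi)) * (1 - 1/(2x^2) + 3/(4x^4) - ...) is accurate to < 1e-12
# relative for x > 20, so switch there.
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  lo <- x < 20
  if (any(lo)) out[lo] <- pracma::erfcx(x[lo])
  if (any(!lo)) {
    xi2 <- 1 / (2 * x[!lo]^2)
    out[!lo] <- (1 - xi2 + 3 * xi2^2 - 15 * xi2^3 + 105 * xi2^4) /
      (x[!lo] * sqrt(pi))
  }
  out
}

# exp(-(u^2 + s^2)) * [erfcx(u + s) + erfcx(u - s)] for u, s >= 0, evaluated
# without overflow. Equals e^{2us} erfc(u+s) + e^{-2us} erfc(u-s), the two-term
# kernel of the point-source solution with uptake (2us = r sqrt(k'/D*)).
uptake_kernel <- function(u, s) {
  e_common <- exp(-(u^2 + s^2))
  term1 <- e_common * erfcx_safe(u + s)
  d <- u - s
  term2 <- ifelse(d >= 0,
                  e_common * erfcx_safe(pmax(d, 0)),
                  2 * exp(-2 * u * s) - e_common * erfcx_safe(pmax(-d, 0)))
  term1 + term2
}

# Concentration response to a current switched on at t = 0 and held on,
# at distance r (um), times t (s). Returns uM.
step_on_concentration <- function(r, t, source, ecs, current) {
  Dstar <- effective_diffusion(source$free_D, ecs$lambda) * CM2_TO_UM2  # um^2/s
  Q <- source_strength(source, current) * MOL_TO_UM3_UM                 # uM um^3/s
  pref <- Q / (8 * pi * Dstar * ecs$alpha * r)
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    u <- r / (2 * sqrt(Dstar * t[pos]))
    s <- sqrt(ecs$kprime * t[pos])
    out[pos] <- pref * uptake_kernel(u, s)
  }
  out
}

#' Point-source concentration for a rectangular current step
#'
#' Closed-form solution of the diffusion equation with first-order uptake for
#' a point source in a homogeneous isotropic ECS. During the current step the
#' concentration at distance `r` is
#' \deqn{C(r,t) = \frac{Q}{8\pi D^* \alpha r}\left[e^{r\gamma}\,
#'   \mathrm{erfc}\!\left(\frac{r}{2\sqrt{D^* t}} + \sqrt{k' t}\right) +
#'   e^{-r\gamma}\,\mathrm{erfc}\!\left(\frac{r}{2\sqrt{D^* t}} -
#'   \sqrt{k' t}\right)\right],}
#' with \eqn{\gamma = \sqrt{k'/D^*}}, \eqn{D^* = D/\lambda^2} and
#' \eqn{Q = I n_t / (zF)}; after the step ends the response is the linear
#' superposition \eqn{C_{on}(r,t) - C_{on}(r, t - t_{pulse})}. The exp*erfc
#' products are evaluated through the scaled complementary error function so
#' large \eqn{r\gamma} cannot overflow.
#'
#' The returned value is the increment above the bias-current steady state
#' (the quantity RTI analysis fits); see [bias_steady_state()] for the
#' baseline itself.
#'
#' @param r Source-sensor distance, um (> 0, scalar).
#' @param t Time since step onset, s (>= 0, vectorised).
#' @param source An [ionto_source()].
#' @param ecs An [ecs_params()].
#' @return Concentration increment, uM, same length as `t`.
#' @export
point_source_concentration <- function(r, t, source, ecs) {
  stopifnot(inherits(source, "ionto_source"), inherits(ecs, "ecs_params"))
  if (length(r) != 1L || r <= 0) stop("r must be a single positive distance")
  if (any(t < 0)) stop("t must be >= 0")
  on <- step_on_concentration(r, t, source, ecs, source$step_current)
  after <- t > source$pulse_duration
  if (any(after)) {
    on[after] <- on[after] -
      step_on_concentration(r, t[after] - source$pulse_duration, source, ecs,
                            source$step_current)
  }
  on
}

#' Steady-state baseline from the bias current
#'
#' The continuously applied bias current builds a steady-state concentration
#' `C_b(r) = Q_b / (4 pi D* alpha r) * exp(-r sqrt(k'/D*))`, the t -> Inf
#' limit of the point-source solution. With `kprime = 0` it decays as 1/r.
#'
#' @inheritParams point_source_concentration
#' @return Baseline concentration, uM.
#' @export
bias_steady_state <- function(r, source, ecs) {
  stopifnot(inherits(source, "ionto_source"), inherits(ecs, "ecs_params"))
  if (any(r <= 0)) stop("r must be > 0")
  Dstar <- effective_diffusion(source$free_D, ecs$lambda) * CM2_TO_UM2
  Q <- source_strength(source, source$bias_current) * MOL_TO_UM3_UM
  Q / (4 * pi * Dstar * ecs$alpha * r) * exp(-r * sqrt(ecs$kprime / Dstar))
}

#' Diffusion curve container
#'
#' One concentration-time record at a known source-sensor separation and
#' cortical depth. Concentrations are stored as increments over the
#' bias-current baseline unless noted otherwise by the producer.
#'
#' @param times Strictly increasing sampling times, s, `times[1] >= 0`.
#' @param concentration Concentrations, uM, same length as `times`.
#' @param distance Source-sensor separation, um.
#' @param depth Cortical depth, um (NA for agar).
#' @param medium `"agar"` or `"tissue"`.
#' @param animal_id,group Optional cohort metadata.
#' @return An object of class `diffusion_curve`.
#' @export
diffusion_curve <- function(times, concentration, distance, depth = NA_real_,
                            medium = c("tissue", "agar"),
                            animal_id = NA_character_, group = NA_character_) {
  medium <- match.arg(medium)
  if (length(times) != length(concentration))
    stop("times and concentration must have equal length")
  if (length(times) < 1L || times[1] < 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at >= 0")
  if (distance <= 0) stop("distance must be > 0")
  structure(list(times = as.numeric(times),
                 concentration = as.numeric(concentration),
                 distance = as.numeric(distance), depth = as.numeric(depth),
                 medium = medium, animal_id = animal_id, group = group),
            class = "diffusion_curve")
}

#' @export
print.diffusion_curve <- function(x, ...) {
  cat(sprintf(
    "Diffusion curve (%s): %d samples over %.3g s, r = %.0f um, peak %.3g uM\n",
    x$medium, length(x$times), max(x$times), x$distance,
    max(x$concentration)))
  invisible(x)
}

#' Sample the forward model into a diffusion curve
#'
#' Evaluates the point-source solution on a time grid, producing a noiseless
#' `diffusion_curve`. With `baseline = "absolute"` the bias steady state is
#' added so the record mimics a raw (non-subtracted) measurement.
#'
#' @inheritParams point_source_concentration
#' @param times Sampling times, s, strictly increasing.
#' @param depth,medium,animal_id,group Metadata passed to [diffusion_curve()].
#' @param baseline `"subtracted"` (default; step increment only) or
#'   `"absolute"`.
#' @return A [diffusion_curve()].
#' @export
generate_curve <- function(source, ecs, r, times, depth = NA_real_,
                           medium = c("tissue", "agar"),
                           animal_id = NA_character_, group = NA_character_,
                           baseline = c("subtracted", "absolute")) {
  baseline <- match.arg(baseline)
  conc <- point_source_concentration(r, times, source, ecs)
  if (baseline == "absolute") conc <- conc + bias_steady_state(r, source, ecs)
  diffusion_curve(times, conc, distance = r, depth = depth,
                  medium = match.arg(medium), animal_id = animal_id,
                  group = group)
}

#' Default RTI sampling grid
#'
#' Time base used for fitting and synthesis: the 24-s current step plus twice
#' that in decay, sampled at 5 Hz.
#'
#' @param pulse_duration Step duration, s.
#' @param decay Extra recording time after the step, s.
#' @param rate Sampling rate, Hz.
#' @return Numeric vector of times, s.
#' @export
rti_times <- function(pulse_duration = 24, decay = 2 * pulse_duration,
                      rate = 5) {
  seq(0, pulse_duration + decay, by = 1 / rate)
}
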