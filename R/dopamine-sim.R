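# Numerical solution of the spherically symmetric dopamine reaction-diffusion
# equation with Michaelis-Menten uptake,
#
#   dC/dt = D* (d2C/dr2 + (2/r) dC/dr) - Vm C / (Km + C),   D* = D_free/lambda^2,
#
# for control vs alcohol-exposed ECS geometries and tonic vs phasic release.
# Discretisation: conservative finite volumes on a stretched radial grid
# (method of lines), dopamine injected as a flux through the source-sphere
# surface r = a, Dirichlet C = 0 at a far outer boundary; stiff time
# integration by deSolve::lsoda with a banded Jacobian. The conservative form
# makes the ECS mass balance exact up to integrator tolerance, which the
# conservation checks rely on.

#' ECS geometry for the dopamine simulation
#'
#' @param alpha ECS volume fraction in (0, 1].
#' @param lambda Tortuosity >= 1.
#' @return An object of class `ecs_geometry`.
#' @export
ecs_geometry <- function(alpha, lambda) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (lambda < 1) stop("lambda must be >= 1")
  structure(list(alpha = alpha, lambda = lambda), class = "ecs_geometry")
}

#' @rdname ecs_geometry
#' @details `ecs_geometry_control()` and `ecs_geometry_etoh()` return the two
#'   substrates measured by RTI in cortex: control alpha = 0.20,
#'   lambda = 1.54; EtOH alpha = 0.19, lambda = 1.39.
#' @export
ecs_geometry_control <- function() ecs_geometry(0.20, 1.54)

#' @rdname ecs_geometry
#' @export
ecs_geometry_etoh <- function() ecs_geometry(0.19, 1.39)

#' Michaelis-Menten uptake kinetics
#'
#' Transporter-mediated dopamine clearance `Vm * C / (Km + C)`. Defaults are
#' the baseline DAT kinetics Vm = 0.2 uM/s, Km = 0.15 uM.
#'
#' @param Vm Maximum uptake velocity, uM/s, >= 0.
#' @param Km Michaelis constant, uM, > 0.
#' @return An object of class `uptake_kinetics`.
#' @export
uptake_kinetics <- function(Vm = 0.2, Km = 0.15) {
  if (Vm < 0) stop("Vm must be >= 0")
  if (Km <= 0) stop("Km must be > 0")
  structure(list(Vm = Vm, Km = Km), class = "uptake_kinetics")
}

#' Dopamine release protocol
#'
#' Tonic release holds the source current constant over the release period;
#' phasic release switches it on in short bursts (default 4 ms at 20 Hz).
#' With `normalize = "charge"` (default) the phasic burst amplitude is scaled
#' so both regimes deliver the same total charge, hence the same moles.
#'
#' @param pattern `"tonic"` or `"phasic"`.
#' @param total_duration Release period, s (default 1).
#' @param current Source current, nA (default 100; for tonic, the on-current;
#'   for phasic, the tonic-equivalent current being normalised).
#' @param burst_width Burst duration, s (phasic only).
#' @param burst_frequency Burst rate, Hz (phasic only).
#' @param source_radius Source sphere radius, um (default 2).
#' @param transport_number Fraction of current converted to dopamine flux
#'   (default 1: the stated source current is treated as fully converted).
#' @param normalize `"charge"` (equal delivered charge to tonic) or
#'   `"amplitude"` (bursts at `current`).
#' @return An object of class `release_protocol`.
#' @export
release_protocol <- function(pattern = c("tonic", "phasic"),
                             total_duration = 1, current = 100,
                             burst_width = 0.004, burst_frequency = 20,
                             source_radius = 2, transport_number = 1,
                             normalize = c("charge", "amplitude")) {
  pattern <- match.arg(pattern)
  normalize <- match.arg(normalize)
  if (source_radius <= 0) stop("source_radius must be > 0")
  if (total_duration <= 0) stop("total_duration must be > 0")
  if (pattern == "phasic" && burst_width * burst_frequency > 1)
    stop("burst_width * burst_frequency must be <= 1")
  structure(list(pattern = pattern, total_duration = total_duration,
                 current = current, burst_width = burst_width,
                 burst_frequency = burst_frequency,
                 source_radius = source_radius,
                 transport_number = transport_number, normalize = normalize),
            class = "release_protocol")
}

n_bursts <- function(protocol) {
  floor(protocol$total_duration * protocol$burst_frequency + 1e-9)
}

phasic_amplitude <- function(protocol) {
  if (protocol$normalize == "charge") {
    protocol$current * protocol$total_duration /
      (n_bursts(protocol) * protocol$burst_width)
  } else {
    protocol$current
  }
}

#' Source current waveform
#'
#' @param protocol A [release_protocol()].
#' @param t Times, s (>= 0, vectorised).
#' @return Current, nA, at each `t`.
#' @export
release_waveform <- function(protocol, t) {
  stopifnot(inherits(protocol, "release_protocol"))
  if (any(t < 0)) stop("t must be >= 0")
  if (protocol$pattern == "tonic")
    return(ifelse(t < protocol$total_duration, protocol$current, 0))
  k <- floor(t * protocol$burst_frequency + 1e-12)
  phase <- t - k / protocol$burst_frequency
  on <- k < n_bursts(protocol) & phase < protocol$burst_width &
    t < protocol$total_duration
  ifelse(on, phasic_amplitude(protocol), 0)
}

# Times at which the waveform switches on/off, clipped to [0, t_max].
waveform_segments <- function(protocol, t_max) {
  if (protocol$pattern == "tonic") {
    b <- c(0, protocol$total_duration, t_max)
  } else {
    k <- seq_len(n_bursts(protocol)) - 1
    starts <- k / protocol$burst_frequency
    b <- c(0, starts, starts + protocol$burst_width,
           protocol$total_duration, t_max)
  }
  sort(unique(pmin(pmax(b, 0), t_max)))
}

#' Radial/time grid for the dopamine solver
#'
#' The solver domain extends well beyond the reported window so the far
#' Dirichlet boundary cannot contaminate it; spacing is fine near the source
#' and geometrically stretched outward.
#'
#' @param r_max_report Outer radius of the reported field, um (default 100).
#' @param t_max Reported time horizon, s (default 3).
#' @param r_pad Solver domain radius, um (>= 2 * `r_max_report`).
#' @param dr_fine Spacing near the source, um (<= 1).
#' @param fine_to Radius up to which `dr_fine` is used, um.
#' @param dr_coarse Cap on the stretched spacing, um.
#' @param stretch Geometric growth factor of the spacing.
#' @param out_times Reported time samples, s.
#' @param out_r Reported radial samples, um.
#' @return An object of class `simulation_grid`.
#' @export
simulation_grid <- function(r_max_report = 100, t_max = 3, r_pad = 300,
                            dr_fine = 0.25, fine_to = 10, dr_coarse = 2,
                            stretch = 1.05,
                            out_times = seq(0, t_max, by = 0.05),
                            out_r = seq(1, r_max_report, by = 1)) {
  if (r_pad < 2 * r_max_report) stop("r_pad must be >= 2 * r_max_report")
  if (dr_fine > 1) stop("dr_fine must be <= 1 um near the source")
  structure(list(r_max_report = r_max_report, t_max = t_max, r_pad = r_pad,
                 dr_fine = dr_fine, fine_to = fine_to, dr_coarse = dr_coarse,
                 stretch = stretch, out_times = out_times, out_r = out_r),
            class = "simulation_grid")
}

#' Refined copy of a simulation grid (for convergence checks)
#'
#' Halves both spacing parameters and softens the stretch, leaving the
#' reported window untouched.
#'
#' @param grid A [simulation_grid()].
#' @param factor Refinement factor (default 2).
#' @return A [simulation_grid()].
#' @export
refine_grid <- function(grid, factor = 2) {
  simulation_grid(r_max_report = grid$r_max_report, t_max = grid$t_max,
                  r_pad = grid$r_pad, dr_fine = grid$dr_fine / factor,
                  fine_to = grid$fine_to, dr_coarse = grid$dr_coarse / factor,
                  stretch = 1 + (grid$stretch - 1) / factor,
                  out_times = grid$out_times, out_r = grid$out_r)
}

# Node radii from the source surface a to r_pad (last node sits inside; the
# Dirichlet boundary is the face at r_pad).
build_radii <- function(a, grid) {
  r <- seq(a, min(grid$fine_to, grid$r_pad), by = grid$dr_fine)
  dr <- grid$dr_fine
  while (r[length(r)] < grid$r_pad) {
    dr <- min(dr * grid$stretch, grid$dr_coarse)
    r <- c(r, r[length(r)] + dr)
  }
  r[length(r)] <- grid$r_pad
  r
}

#' Solve the dopamine reaction-diffusion equation
#'
#' Method-of-lines finite-volume solution of the spherically symmetric
#' diffusion equation with Michaelis-Menten uptake. Dopamine enters through
#' the source-sphere surface as the flux `Q(t) / (4 pi a^2 alpha)` with
#' `Q(t) = I(t) n_t / F`; the outer boundary holds C = 0 at `r_pad` and is
#' enlarged automatically (up to `max_pad_doublings` doublings) if the
#' boundary-adjacent concentration exceeds 1e-6 of the field maximum.
#'
#' @param geometry An [ecs_geometry()].
#' @param kinetics An [uptake_kinetics()].
#' @param protocol A [release_protocol()].
#' @param grid A [simulation_grid()].
#' @param D_free Free dopamine diffusion coefficient, cm^2/s (default
#'   6.9e-6).
#' @param rtol,atol Integrator tolerances (atol in uM).
#' @param max_pad_doublings Outer-boundary enlargement attempts.
#' @return An object of class `concentration_field`: `r` (um), `t` (s), `C`
#'   (uM matrix, time x radius, reported window), `mass_ecs` and `released`
#'   (uM um^3 series on `t`, computed on the solver grid), provenance
#'   (`geometry`, `kinetics`, `protocol`, `grid`, `D_free`), and
#'   `boundary_ratio` (max boundary-adjacent C over field max).
#' @export
solve_dopamine <- function(geometry, kinetics, protocol,
                           grid = simulation_grid(), D_free = 6.9e-6,
                           rtol = 1e-8, atol = 1e-4, max_pad_doublings = 3L) {
  stopifnot(inherits(geometry, "ecs_geometry"),
            inherits(kinetics, "uptake_kinetics"),
            inherits(protocol, "release_protocol"))
  Dstar <- effective_diffusion(D_free, geometry$lambda) * CM2_TO_UM2  # um^2/s
  a <- protocol$source_radius
  g <- grid
  for (attempt in seq_len(max_pad_doublings + 1L)) {
    sol <- solve_on_grid(geometry, kinetics, protocol, g, Dstar,
                         rtol, atol)
    if (sol$boundary_ratio <= 1e-6) break
    if (attempt > max_pad_doublings)
      stop("outer boundary still active after ", max_pad_doublings,
           " domain doublings (boundary ratio ", sol$boundary_ratio, ")")
    g <- simulation_grid(r_max_report = g$r_max_report, t_max = g$t_max,
                         r_pad = 2 * g$r_pad, dr_fine = g$dr_fine,
                         fine_to = g$fine_to, dr_coarse = g$dr_coarse,
                         stretch = g$stretch, out_times = g$out_times,
                         out_r = g$out_r)
  }
  cmax <- max(sol$C_nodes)
  if (any(sol$C_nodes < -1e-6 * cmax))
    stop("solver produced negative concentrations beyond tolerance (min ",
         min(sol$C_nodes), " uM)")
  sol$C_nodes[sol$C_nodes < 0] <- 0
  # report on the fixed output grid (linear interpolation in r)
  C_out <- t(apply(sol$C_nodes, 1, function(row)
    stats::approx(sol$radii, row, xout = g$out_r, rule = 2)$y))
  structure(list(r = g$out_r, t = g$out_times, C = C_out,
                 mass_ecs = sol$mass_ecs, released = sol$released,
                 geometry = geometry, kinetics = kinetics,
                 protocol = protocol, grid = g, D_free = D_free,
                 boundary_ratio = sol$boundary_ratio),
            class = "concentration_field")
}

# One solve on a concrete grid. Returns node-level results.
solve_on_grid <- function(geometry, kinetics, protocol, grid, Dstar,
                          rtol, atol) {
  a <- protocol$source_radius
  radii <- build_radii(a, grid)
  n <- length(radii) - 1L               # last node is the Dirichlet boundary
  faces <- c(a, (radii[-1] + radii[-length(radii)]) / 2)  # n + 1 faces
  faces[n + 1L] <- grid$r_pad
  vol <- 4 * pi / 3 * diff(faces^3)     # control volumes of nodes 1..n
  area <- 4 * pi * faces^2
  dr_node <- diff(radii)                # distance node i -> i+1 (length n)
  # conductance of interior faces 2..n+1 (face between node i and i+1)
  cond <- area[-1] * Dstar / dr_node
  Vm <- kinetics$Vm; Km <- kinetics$Km
  rhs <- function(t, C, parms) {
    Cb <- c(C, 0)                          # Dirichlet ghost at r_pad
    f <- cond * (Cb[-1] - Cb[-(n + 1L)])   # inflow through upper face of node i
    # net inflow of node i: upper-face inflow minus what leaves via the lower
    # face (node 1's lower face carries the source influx instead)
    net <- f - c(-parms$influx, f[seq_len(n - 1L)])
    dC <- net / vol - Vm * C / (Km + C)
    list(dC)
  }
  segs <- waveform_segments(protocol, grid$t_max)
  mid <- (segs[-1] + segs[-length(segs)]) / 2
  seg_current <- release_waveform(protocol, mid)
  # molar inflow into the ECS concentration field, uM um^3 / s
  seg_influx <- seg_current * 1e-9 * protocol$transport_number / FARADAY *
    MOL_TO_UM3_UM / geometry$alpha
  out_t <- grid$out_times
  C <- numeric(n)
  C_store <- matrix(0, nrow = length(out_t), ncol = n)
  if (out_t[1] == 0) C_store[1, ] <- 0
  released <- numeric(length(out_t))
  cum_rel <- 0
  for (si in seq_along(mid)) {
    t0 <- segs[si]; t1 <- segs[si + 1L]
    if (t1 <= t0) next
    inner <- out_t[out_t - t0 > 1e-9 & t1 - out_t > 1e-9]
    tt <- sort(c(t0, inner, t1))
    tt <- tt[c(TRUE, diff(tt) > 1e-9)]
    res <- deSolve::lsoda(C, tt, rhs, parms = list(influx = seg_influx[si]),
                          rtol = rtol, atol = atol, jactype = "bandint",
                          bandup = 1, banddown = 1)
    if (attr(res, "istate")[1] < 0)
      stop("lsoda failed in segment [", t0, ", ", t1, "] s")
    for (ti in seq_along(tt)) {
      hit <- which(abs(out_t - tt[ti]) < 1e-9)
      if (length(hit)) {
        C_store[hit, ] <- res[ti, -1]
        released[hit] <- cum_rel +
          seg_influx[si] * geometry$alpha * (tt[ti] - t0)
      }
    }
    C <- res[nrow(res), -1]
    cum_rel <- cum_rel + seg_influx[si] * geometry$alpha * (t1 - t0)
  }
  mass <- geometry$alpha * as.numeric(C_store %*% vol)
  list(radii = radii[seq_len(n)], C_nodes = C_store, mass_ecs = mass,
       released = released,
       boundary_ratio = if (max(C_store) > 0)
         max(C_store[, n]) / max(C_store) else 0)
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "Concentration field: r in [%g, %g] um (%d), t in [%g, %g] s (%d), peak %.4g uM\n",
    min(x$r), max(x$r), length(x$r), min(x$t), max(x$t), length(x$t),
    max(x$C)))
  cat(sprintf("  alpha = %.3g, lambda = %.3g, Vm = %.3g uM/s, Km = %.3g uM, %s release\n",
              x$geometry$alpha, x$geometry$lambda, x$kinetics$Vm,
              x$kinetics$Km, x$protocol$pattern))
  invisible(x)
}

#' Signed difference of two concentration fields
#'
#' Elementwise `f_a - f_b` on identical reported grids (e.g. EtOH minus
#' control); the sign map is retained.
#'
#' @param f_a,f_b [solve_dopamine()] results on the same grid.
#' @return A `concentration_field`-like object whose `C` holds the signed
#'   difference.
#' @export
field_difference <- function(f_a, f_b) {
  stopifnot(inherits(f_a, "concentration_field"),
            inherits(f_b, "concentration_field"))
  if (!isTRUE(all.equal(f_a$r, f_b$r)) || !isTRUE(all.equal(f_a$t, f_b$t)))
    stop("fields are on different reported grids")
  out <- f_a
  out$C <- f_a$C - f_b$C
  out$mass_ecs <- out$released <- NULL
  class(out) <- c("concentration_field_difference", "concentration_field")
  out
}

#' Integrate a field over space
#'
#' Spatial integrals of the reported window, one value per output time:
#' * `"volume"`: `M(t) = integral of C(r,t) alpha 4 pi r^2 dr` - moles of
#'   dopamine in the ECS (default);
#' * `"shell"`: the same without the alpha weight - the tissue-volume
#'   integral of the ECS concentration, i.e. moles / alpha; this is the
#'   quantity that separates two geometries holding equal moles;
#' * `"plain"`: `integral of C(r,t) dr`.
#'
#' @param field A [solve_dopamine()] result (or field difference).
#' @param weighting `"volume"`, `"shell"` or `"plain"`.
#' @return data.frame with `t` (s) and `M` (uM um^3 for volume/shell,
#'   uM um for plain).
#' @export
integrate_space <- function(field, weighting = c("volume", "shell", "plain")) {
  weighting <- match.arg(weighting)
  w <- switch(weighting,
              volume = field$geometry$alpha * 4 * pi * field$r^2,
              shell = 4 * pi * field$r^2,
              plain = rep(1, length(field$r)))
  M <- apply(field$C, 1, function(row) pracma::trapz(field$r, row * w))
  data.frame(t = field$t, M = as.numeric(M))
}

#' Integrate a field over time
#'
#' `S(r) = integral of C(r,t) dt` over the reported horizon, one value per
#' radius (uM s): the cumulative dopamine exposure at each distance.
#'
#' @param field A [solve_dopamine()] result (or field difference).
#' @return data.frame with `r` (um) and `S` (uM s).
#' @export
integrate_time <- function(field) {
  S <- apply(field$C, 2, function(col) pracma::trapz(field$t, col))
  data.frame(r = field$r, S = as.numeric(S))
}

#' Scan the uptake maximum velocity
#'
#' Re-solves the field over a set of relative Vm perturbations (default
#' -60%, -30%, +30%, +60% around the baseline), as used to probe robustness
#' of the geometry contrast against reported alcohol effects on DAT kinetics.
#'
#' @param geometry,protocol,grid,D_free As in [solve_dopamine()].
#' @param base Baseline [uptake_kinetics()].
#' @param multipliers Relative changes of Vm (e.g. -0.6 for -60%).
#' @param ... Passed to [solve_dopamine()].
#' @return Named list of `concentration_field`s, one per multiplier.
#' @export
vm_scan <- function(geometry, base, protocol, grid = simulation_grid(),
                    multipliers = c(-0.6, -0.3, 0.3, 0.6), D_free = 6.9e-6,
                    ...) {
  vm <- base$Vm * (1 + multipliers)
  if (any(vm < 0)) stop("multiplier yields negative Vm")
  out <- lapply(seq_along(multipliers), function(i)
    solve_dopamine(geometry, uptake_kinetics(vm[i], base$Km), protocol,
                   grid, D_free = D_free, ...))
  names(out) <- sprintf("%+.0f%%", 100 * multipliers)
  out
}
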