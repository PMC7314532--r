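# Inverse problem of the RTI experiment: ion-selective electrode calibration,
# agar reference fit (transport number + free D), and tissue fit (alpha,
# lambda, k') by bounded Levenberg-Marquardt least squares with multi-start.

#' Electrode calibration table
#'
#' @param concentrations TMA+ concentrations, mM, strictly positive and
#'   increasing. Default is the usual fixed-interference series.
#' @param voltages Measured electrode voltages, mV.
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(concentrations = c(0.25, 0.5, 1, 2, 4, 8, 16),
                              voltages) {
  if (length(concentrations) != length(voltages))
    stop("concentrations and voltages must have equal length")
  if (any(concentrations <= 0) || any(diff(concentrations) <= 0))
    stop("concentrations must be strictly positive and increasing")
  structure(list(concentrations = as.numeric(concentrations),
                 voltages = as.numeric(voltages)),
            class = "calibration_table")
}

#' Calibrate an ion-selective microelectrode
#'
#' Fits the Nikolsky/Nernst log-linear response `V = offset + slope *
#' log10(C)` by ordinary least squares and exposes the inverse map used to
#' convert recorded voltages to concentrations.
#'
#' @param table A [calibration_table()] with at least 3 points.
#' @return An object of class `electrode_calibration`: `slope` (mV/decade),
#'   `offset` (mV), `rms` residual (mV), logical `monotone`, and the function
#'   `voltage_to_concentration(V)` returning mM.
#' @export
calibrate_electrode <- function(table) {
  stopifnot(inherits(table, "calibration_table"))
  if (length(table$concentrations) < 3L)
    stop("electrode calibration needs at least 3 points")
  monotone <- all(diff(table$voltages) > 0)
  if (!monotone)
    warning("calibration voltages are not monotone increasing")
  fit <- stats::lm(table$voltages ~ log10(table$concentrations))
  offset <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) warning("non-positive calibration slope")
  structure(list(
    slope = slope, offset = offset,
    rms = sqrt(mean(stats::resid(fit)^2)),
    monotone = monotone,
    voltage_to_concentration = function(V) 10^((V - offset) / slope)),
    class = "electrode_calibration")
}

# Shared bounded LM driver: residuals between a curve and the forward model
# under a parameter mapping. Returns the nls.lm result augmented with ssr.
lm_fit_curve <- function(curve, make_model, start, lower, upper) {
  resid_fun <- function(p) {
    make_model(p) - curve$concentration
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-10))
  fit$ssr <- sum(fit$fvec^2)
  # info 1-3: ftol/ptol met; 4: gradient orthogonality met (e.g. an exact
  # zero-residual start) - all count as converged
  fit$ok <- fit$info %in% 1:4
  fit
}

#' Fit the free-diffusion reference curve recorded in agar
#'
#' In dilute agar diffusion is free: alpha = 1, lambda = 1, k' = 0 by
#' definition, leaving the electrode transport number and the free diffusion
#' coefficient as the only unknowns of the forward model. Both are recovered
#' by bounded nonlinear least squares and subsequently held fixed in tissue
#' fits.
#'
#' @param curve A [diffusion_curve()] with `medium == "agar"`.
#' @param source An [ionto_source()] giving the current protocol; its
#'   `transport_number` and `free_D` entries are used as one of the starts.
#' @return An object of class `agar_fit`: `transport_number`, `free_D`
#'   (cm^2/s), `ssr` (uM^2), `converged`.
#' @export
fit_agar <- function(curve, source) {
  stopifnot(inherits(curve, "diffusion_curve"), inherits(source, "ionto_source"))
  if (curve$medium != "agar") stop("fit_agar expects an agar curve")
  free <- ecs_params(1, 1, 0)
  if (max(curve$concentration) <= 0) {
    return(structure(list(transport_number = NA_real_, free_D = NA_real_,
                          ssr = sum(curve$concentration^2), converged = FALSE),
                     class = "agar_fit"))
  }
  model <- function(p) {
    src <- source
    src$transport_number <- p[["nt"]]
    src$free_D <- p[["D"]]
    point_source_concentration(curve$distance, curve$times, src, free)
  }
  starts <- list(
    c(nt = source$transport_number, D = source$free_D),
    c(nt = 0.15, D = 0.6e-5),
    c(nt = 0.6, D = 2e-5))
  best <- NULL
  for (st in starts) {
    fit <- lm_fit_curve(curve, model, st,
                        lower = c(nt = 0.01, D = 1e-6),
                        upper = c(nt = 1, D = 1e-4))
    if (is.null(best) || fit$ssr < best$ssr) best <- fit
  }
  structure(list(transport_number = unname(best$par[["nt"]]),
                 free_D = unname(best$par[["D"]]),
                 ssr = best$ssr, converged = best$ok),
            class = "agar_fit")
}

# Default multi-start grid for the tissue fit.
tissue_starts <- function() {
  g <- expand.grid(alpha = c(0.1, 0.2, 0.3), lambda = c(1.2, 1.5, 1.8),
                   kprime = c(0, 0.005))
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ]))
}

#' Fit the ECS diffusion parameters to a tissue curve
#'
#' With the transport number and free diffusion coefficient known from the
#' agar reference, the tissue curve determines (alpha, lambda, k') by bounded
#' Levenberg-Marquardt least squares. A multi-start grid guards against local
#' minima; the lowest-SSR solution wins (ties broken by iteration count).
#'
#' Bounds: alpha in (0.01, 1], lambda in \[0.9, 3\] (the sub-1 slack absorbs
#' noise in near-free media), k' in \[0, 0.1\] /s.
#'
#' @param curve A [diffusion_curve()] with `medium == "tissue"` (the agar
#'   identity check may pass an agar-conditions curve relabelled as tissue).
#' @param agar An [agar_fit()] (must have converged), or a list with
#'   `transport_number` and `free_D`.
#' @param source An [ionto_source()] giving the current protocol.
#' @param starts List of named start vectors; defaults to the 3 x 3 x 2 grid.
#' @return An object of class `tissue_fit`: `params` ([ecs_params()]), `ssr`,
#'   `converged`, `at_bound` (named logical), `n_starts_used`.
#' @export
fit_tissue <- function(curve, agar, source, starts = tissue_starts()) {
  stopifnot(inherits(curve, "diffusion_curve"))
  if (inherits(agar, "agar_fit") && !agar$converged)
    stop("agar reference fit did not converge")
  src <- source
  src$transport_number <- agar$transport_number
  src$free_D <- agar$free_D
  lower <- c(alpha = 0.01, lambda = 0.9, kprime = 0)
  upper <- c(alpha = 1, lambda = 3, kprime = 0.1)
  model <- function(p) {
    ecs <- structure(list(alpha = p[["alpha"]], lambda = p[["lambda"]],
                          kprime = p[["kprime"]]), class = "ecs_params")
    point_source_concentration(curve$distance, curve$times, src, ecs)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(lm_fit_curve(curve, model, st, lower, upper),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$ssr < best$ssr - 1e-12 ||
        (abs(fit$ssr - best$ssr) <= 1e-12 && fit$niter < best$niter))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, ssr = Inf, converged = FALSE,
                          at_bound = NULL, n_starts_used = length(starts)),
                     class = "tissue_fit"))
  }
  p <- best$par
  at_bound <- abs(p - lower) < 1e-8 | abs(p - upper) < 1e-8
  params <- suppressWarnings(ecs_params(p[["alpha"]], p[["lambda"]],
                                        p[["kprime"]]))
  structure(list(params = params, ssr = best$ssr, converged = best$ok,
                 at_bound = at_bound, n_starts_used = length(starts)),
            class = "tissue_fit")
}

#' @export
print.tissue_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("Tissue fit: failed (no usable start)\n")
  } else {
    cat(sprintf(
      "Tissue fit: alpha = %.4g, lambda = %.4g, k' = %.4g /s (SSR %.3g, %s)\n",
      x$params$alpha, x$params$lambda, x$params$kprime, x$ssr,
      if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Average repeated fits at one depth
#'
#' The protocol records several diffusion curves at each depth; the fitted
#' parameters of the converged repeats are averaged arithmetically to one
#' representative triplet.
#'
#' @param fits List of [fit_tissue()] results at a single depth.
#' @return An [ecs_params()] of the component-wise means.
#' @export
average_repeats <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged) && !is.null(f$params), fits)
  if (length(ok) == 0L) stop("no converged fits to average")
  suppressWarnings(ecs_params(
    mean(vapply(ok, function(f) f$params$alpha, 0)),
    mean(vapply(ok, function(f) f$params$lambda, 0)),
    mean(vapply(ok, function(f) f$params$kprime, 0))))
}

#' Map a recording depth to its cortical layer
#'
#' Recording depths (400-2000 um below the pial surface, 200-um steps) map to
#' cortical layers: 400 and 600 um, layer III; 800 um, layer IV; 1000-1400 um,
#' layer V; 1600 and 1800 um, layer VI; 2000 um, white matter.
#'
#' @param depth Depth in um; must be one of the sampled depths.
#' @return Character layer label in `{"III","IV","V","VI","WM"}` (vectorised).
#' @export
assign_layer <- function(depth) {
  map <- c(`400` = "III", `600` = "III", `800` = "IV", `1000` = "V",
           `1200` = "V", `1400` = "V", `1600` = "VI", `1800` = "VI",
           `2000` = "WM")
  key <- as.character(depth)
  if (any(!key %in% names(map)))
    stop("depth must be one of 400, 600, ..., 2000 um")
  unname(map[key])
}
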