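---
title: "Modelling diffusion in the brain extracellular space: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diffusion in the brain extracellular space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsdiff)
```

# Scope

`ecsdiff` implements two connected computations. First, the real-time
iontophoresis (RTI) analysis: an inert tracer (TMA⁺) is released from a
point source by a current step and its concentration transient at a nearby
ion-selective microelectrode is fitted with a diffusion model to estimate
the extracellular space (ECS) volume fraction α, tortuosity λ, and
nonspecific uptake rate k′. Second, a forward simulation asking what a
measured change in (α, λ) — here, the contrast between a control and an
alcohol-exposed cortical geometry — does to the spread of an
extrasynaptically released transmitter (dopamine) governed by
Michaelis–Menten transporter uptake. A seeded synthetic-data generator
supplies every input with known ground truth, so the whole inverse pipeline
can be validated by parameter recovery.

# The forward model and its assumptions

The tracer model treats the tissue as a homogeneous, isotropic porous
medium. Diffusion is slowed by tortuosity (effective coefficient
D\* = D/λ²), dilution is governed by the volume fraction (a source term
scaled by 1/α), and loss across cell membranes is a first-order sink k′.
For a constant current *I* starting at *t* = 0, the concentration at
distance *r* is the classic two-term erfc expression implemented in
`point_source_concentration()`; a finite pulse is the superposition of an
on-step and a delayed negative on-step. Assumptions worth keeping in mind:

* **Point source, infinite medium.** Electrode geometry, tissue boundaries
  and the ~1 µm source tip are not represented. At the 100–150 µm tip
  separations used in vivo this is standard practice.
* **Constant transport number.** The bias current is assumed to keep
  n~t~ stable; the model fits the increment above the bias steady state
  (`bias_steady_state()` gives the baseline itself, and
  `generate_curve(baseline = "absolute")` can retain it).
* **Linear uptake.** k′ lumps all nonspecific loss; it is fitted but, like
  the in vivo literature, not interpreted as a group-level readout by
  default.

One property deserves a note because it is often mis-stated: the curve's
peak does *not* occur at the end of the current pulse. At a sensor 120 µm
away the response keeps rising for ≈1–2 s after switch-off, because the
subtracted "image" step has not yet reached the sensor. The tests assert
this corrected property.

Internally all lengths are µm, times s, concentrations µM; diffusion
coefficients are accepted in cm²/s and converted (1 cm²/s = 10⁸ µm²/s).
The exp·erfc products are evaluated through the scaled complementary error
function (with an asymptotic-series tail beyond where `pracma::erfcx`
underflows), so large *r*√(k′/D\*) cannot overflow.

# The inverse problem

`fit_agar()` fixes α = 1, λ = 1, k′ = 0 (free diffusion by definition) and
estimates (n~t~, D) from the agar reference curve; `fit_tissue()` then
holds (n~t~, D) and estimates (α, λ, k′). Both use bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`) on the full
record: the 24-s rise plus 48 s of decay sampled at 5 Hz, both phases
weighted equally (the decay tail is what separates k′ from λ, so we keep
it at full weight). The tissue fit multi-starts from the 3 × 3 × 2 grid
α ∈ {0.1, 0.2, 0.3} × λ ∈ {1.2, 1.5, 1.8} × k′ ∈ {0, 0.005} within bounds
α ∈ (0.01, 1], λ ∈ [0.9, 3], k′ ∈ [0, 0.1] s⁻¹, keeping the lowest-SSR
solution (ties: fewest iterations). λ values in [0.9, 1) are allowed purely
as noise slack for near-free media and are flagged with a warning by the
parameter constructor. Stopping codes 1–4 of the optimizer count as
converged (code 4 is the gradient-orthogonality rule, returned for
example when a start already sits at an exact zero-residual minimum);
non-converged curves are reported rather than raised, and
`average_repeats()` drops them, so cohort pipelines degrade gracefully.

Noiseless self-consistency (fit ∘ generate = identity to 10⁻³ relative)
holds across the whole start grid, and a free-diffusion curve fitted with
all three parameters free returns α = 1, λ = 1, k′ = 0 — the agar identity
that anchors the method.

`calibrate_electrode()` fits the Nikolsky/Nernst log-linear response over
the standard 0.25–16 mM fixed-interference series and exposes the inverse
map; it is kept separate from the diffusion fits because in practice
calibration happens per electrode, before the experiment.

# Cohort analysis

Per animal and depth, the three repeat fits are averaged; depths map to
cortical layers (400/600 µm → III, 800 → IV, 1000–1400 → V, 1600/1800 → VI,
2000 → white matter). `compare_groups()` runs the two-way fixed-effects
ANOVA (group × layer, layers III–VI, per-animal-per-layer means) for α and
λ separately and applies the pooling rule: if neither the layer main
effect nor the interaction reaches 0.05, layers are pooled and a
two-sample Welch comparison of per-animal means is reported as the pooled
group contrast. The Welch test is our interpretation of "pooled
comparison" — the convention in the field leaves the pooled test
unspecified — and it is labelled as such in the output. The two parameters
are tested without multiplicity correction, matching how such experiments
are conventionally reported; k′ can be added explicitly. Animal nesting is
deliberately not modelled with mixed effects: the per-animal averaging
step keeps the ANOVA's exchangeability assumption honest at the cost of
some power, which mirrors the source experiments.

# The synthetic cohort generator

`make_cohort()` emulates the in vivo design: two groups of 6 animals
(total n = 12 split evenly — the split is configurable), depths 400–2000 µm
in 200-µm steps, 3 curves per depth, electrode spacing drawn once per
animal from U(100, 150) µm. Group truths default to the cortical
estimates the RTI experiment produced (control α = 0.196, λ = 1.503; EtOH
α = 0.176, λ = 1.403); k′ truth is set to 0.004 s⁻¹, a typical cortical
value, since no group-level k′ estimate is reported. Per-animal truths are
truncated-normal draws around the group truth with between-animal SDs
chosen as √6 × the reported group SEs (0.007 for α, 0.015 for λ), so a
6-animal cohort reproduces the reported standard errors — a calibration of
the generator, not a measured quantity. Curve noise is additive Gaussian
with SD = 2% of the clean peak (no noise magnitude is reported for the
real recordings; 2% is our stated assumption, configurable, and can be
moved to the voltage domain before calibration inversion). Master-seed
determinism is curve-level: every draw uses a seed derived from the master
seed by fixed offsets.

What the generator does *not* emulate: electrode drift, depth-dependent
tissue heterogeneity, anesthesia effects, non-Gaussian artefacts, and any
within-animal correlation beyond the shared true parameters. Passing
recovery tests therefore demonstrates that the *pipeline* is unbiased and
correctly seeded under the stated noise model — not that real recordings
meet that model.

A corollary worth stating explicitly: a recovery check of the form "cohort
mean within one generating SE of the group truth" is itself a stochastic
event. The recovered mean tracks the *realized* mean of the six animal
draws to ≲10⁻³ (the fits contribute almost nothing), so the check's
outcome at any fixed seed is essentially the luck of those six draws and
passes ≈68% of seeds per parameter by construction. The analysis drivers
therefore always print the realized truth next to the recovered value.

# The dopamine solver

`solve_dopamine()` integrates the spherically symmetric reaction–diffusion
equation with Michaelis–Menten uptake by conservative finite volumes on a
stretched radial grid (0.25 µm cells near the source, geometric stretch
capped at 2 µm), method of lines in time with `deSolve::lsoda` and a
banded Jacobian. Design choices:

* **Source.** Dopamine enters as a flux Q(t)/(4πa²α) through the surface
  of an a = 2 µm sphere, Q = I·n~t~/F. The release transport number
  defaults to 1 (the stated 100 nA source current is treated as fully
  converted flux); it is configurable. The 1/α in the flux is the same
  dilution physics as in the tracer model.
* **Waveforms.** Tonic: constant current for 1 s. Phasic: 4-ms bursts at
  20 Hz (exactly 20 bursts in 1 s, 80 ms total on-time); by default the
  burst amplitude is scaled (×12.5) so both regimes deliver identical
  charge, hence identical moles — the equal-amplitude alternative is
  selectable. The integrator is restarted at every waveform discontinuity,
  with the source constant within each segment.
* **Boundaries and grid.** Dirichlet C = 0 at r_pad = 300 µm (≥3× the
  100-µm reported window); if the boundary-adjacent concentration ever
  exceeds 10⁻⁶ of the field maximum the domain is doubled and re-solved,
  so the far boundary adapts to the effective diffusion coefficient. The
  field is reported on a fixed output grid (1-µm radial, 50-ms temporal
  steps over r ≤ 100 µm, t ≤ 3 s) by linear interpolation, which makes
  fields from different geometries and resolutions directly comparable.
  Negative excursions below solver tolerance are clipped to zero; anything
  beyond 10⁻⁶ of the field maximum is an error.
* **Verification.** The conservative discretisation makes the ECS mass
  balance exact up to integrator tolerance: with Vm = 0 the stored
  `mass_ecs` series equals cumulative release to ~10⁻¹¹ relative. With
  Km → ∞ at fixed Vm/Km the solver reproduces the closed-form linear
  uptake solution at nine (r, t) probes to <0.3% — for that oracle the
  source radius is shrunk to 0.125 µm, because a 2-µm sphere genuinely
  differs from an ideal point source by 1–3% at early-time far-field
  probes (an O(a²) physical effect, not solver error). Halving the grid
  spacing moves the reported field by ~0.1% in max-norm (<0.5% required).

# Field summaries and the geometry contrast

`integrate_space()` offers three weightings. The α-weighted volume
integral ∫C·α·4πr²dr is the moles of dopamine in the ECS — the right
quantity for mass bookkeeping, and the default. But it is by construction
almost blind to the geometry contrast during release: both geometries
receive the same moles and uptake removes five orders of magnitude less
than is released, so the two mass curves coincide. The quantity that
carries the biological claim — how concentrated the transmitter is in the
fluid that receptors actually face — is the *tissue-volume* integral
∫C·4πr²dr = moles/α (weighting `"shell"`): equal moles confined to a
smaller fluid fraction mean proportionally higher ECS concentration. Under
the alcohol-exposed geometry this integral runs ≈5% above control
throughout the release phase, and the sign survives Vm perturbations of
±30% and ±60% (the scan set we adopt; the published range statement is
internally inconsistent and we read it as the symmetric four-point set,
configurable in `vm_scan()`). The plain line integral ∫C dr is provided
for completeness; note it orders the geometries the *other* way (it scales
like 1/(D\*α)), which is a useful reminder that "integrated concentration"
claims are meaningless without stating the weight. The signed difference
map (`field_difference()`) contains both signs for the production
parameter sets: the faster-diffusing EtOH geometry is lower very near the
source and during the immediate post-release collapse, higher almost
everywhere else.

`integrate_time()` gives the cumulative exposure S(r) = ∫C dt, which
decreases monotonically with distance for the production parameters and is
the natural axis for "spatial reach" statements.

# Morphometry

`ramification_index()` implements the dendritic-density score
(Σ terminal orders + number of terminals) × (total length / number of
primary processes) on per-cell skeleton summaries; image processing is out
of scope. Terminal order is counted from 1 at the primary process (the
published formula does not fix the origin; starting at 1 makes the minimal
unbranched cell score 2L, which we document as the convention).
`make_microglia_trees()` grows random binary branching trees and returns
both the branch table and the exact summary, so the index can be checked
against brute-force traversal.

# Problem sizes and runtime

The shipped configuration runs on a single CPU: the full synthetic cohort
(324 curves, 18-start fits each) completes in about a minute; a production
dopamine solve takes ~0.1 s (tonic) to ~1 s (phasic) on the default grid,
and the fine-grid solver oracle a few seconds. These sizes were chosen to
make the complete analysis, test suite and reproduction script comfortably
re-runnable; all of them scale up by ordinary arguments to the grid and
cohort constructors.

# Known limitations

* Homogeneous isotropic media only; no anisotropy, no depth gradients, no
  DAT density gradients, no reuptake pharmacology beyond the Vm scan.
* The RTI fit assumes the agar-derived (n~t~, D) transfer unchanged into
  tissue, as the method requires; electrode polarization and temperature
  effects are not modelled.
* The generator's noise model is a stated assumption (see above); recovery
  results quantify pipeline behaviour under that model only.
* The pooled group contrast after a negative layer test is an
  interpretation; users wanting the strict two-way ANOVA group effect can
  read it directly from the returned table.
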