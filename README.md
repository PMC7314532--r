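# ecsdiff

Diffusion analysis of the brain **extracellular space (ECS)** for
real-time-iontophoresis (RTI) experiments and dopamine volume-transmission
modelling, with a seeded synthetic-data generator for parameter-recovery
studies. Built for experimenters and modellers who work with TMA⁺ diffusion
curves and want a tested, scriptable replacement for legacy point-source
curve-fitting programs, plus a reaction–diffusion solver to ask what a
measured change in ECS geometry does to extrasynaptic signalling.

## The models

**Forward model (RTI).** An iontophoretic microelectrode releases the inert
cation TMA⁺ at rate *Q = I·n<sub>t</sub>/(zF)* into the ECS. With volume
fraction α (ECS/total tissue volume), tortuosity λ (λ² = D/D\*), and
first-order nonspecific uptake k′, the concentration at distance *r* from a
point source driven by a rectangular current step is

```
C(r,t) = Q/(8π D* α r) · [ e^{rγ} erfc( r/(2√(D*t)) + √(k′t) )
                         + e^{-rγ} erfc( r/(2√(D*t)) − √(k′t) ) ],
γ = √(k′/D*),  D* = D/λ²,
```

during the step, and the superposition `C(t) − C(t − t_pulse)` after it.
Calibration in dilute agar (α = 1, λ = 1, k′ = 0 by definition) yields the
electrode transport number *n<sub>t</sub>* and free diffusion coefficient
*D*; the tissue curve then determines (α, λ, k′) by bounded multi-start
Levenberg–Marquardt least squares. Cohorts are compared with a two-way
ANOVA (group × cortical layer) and the layer-pooling rule used in the RTI
literature.

**Dopamine simulation.** The spherically symmetric reaction–diffusion
equation with Michaelis–Menten transporter uptake,

```
∂C/∂t = D* ( ∂²C/∂r² + (2/r) ∂C/∂r ) − Vm·C/(Km + C),
```

is solved by conservative finite volumes (method of lines, stiff `lsoda`
integration) with dopamine injected as a flux through a 2-µm source sphere,
for a control geometry (α = 0.20, λ = 1.54) and an alcohol-exposed one
(α = 0.19, λ = 1.39), under tonic (constant, 1 s) or phasic (4-ms bursts at
20 Hz, charge-normalized) release.

**Morphometry.** The microglial ramification ("dendritic density") index
`(Σ terminal orders + #terminals) × (total length / #primary processes)` on
pre-extracted skeleton summaries.

## Worked example

```r
library(ecsdiff)

src  <- ionto_source()                       # 20 nA bias, +180 nA for 24 s
truth <- ecs_params(alpha = 0.2, lambda = 1.5, kprime = 0.004)
noisy <- make_curve(truth, src, r = 120, noise_fraction = 0.02, seed = 7)

agar <- list(transport_number = src$transport_number,
             free_D = src$free_D, converged = TRUE)
fit_tissue(noisy$curve, agar, src)
#> Tissue fit: alpha = 0.1989, lambda = 1.498, k' = 0.004097 /s (SSR 3.34e+05, converged)
```

The fit recovers the generating geometry of the 2%-noise curve to well
under the between-animal spread seen in vivo: α to 0.6%, λ to 0.2%. At
cohort level (`analysis/02_fit_cohort.R`, 324 curves), the pipeline
reproduces each group's realized mean α and λ to within 7×10⁻⁴ and flags
the group difference in λ at `F(1, 40) = 30.7, p = 2.1e-06` with layers
pooled, while α shows no significant group effect at this cohort size.

For the dopamine contrast (`analysis/03_dopamine_fields.R`): the
EtOH − control difference field carries both signs (62% of the reported
grid positive, 36% negative for tonic release), and the tissue-integrated
ECS dopamine concentration during release is 4.7–5.2% higher under the
alcohol-exposed geometry — a preserved contrast across a ±60% scan of the
uptake Vm (`analysis/04_vm_scan.R`).

## The analysis workflow

Numbered drivers under `analysis/` (each writes its tables to `results/`):

1. `01_simulate_cohort.R` — synthetic two-group RTI cohort with known truth.
2. `02_fit_cohort.R` — fit every curve, average repeats, group ANOVA.
3. `03_dopamine_fields.R` — control/EtOH × tonic/phasic dopamine fields,
   difference maps, space/time integrals.
4. `04_vm_scan.R` — robustness of the geometry contrast to DAT Vm.
5. `05_morphometry.R` — ramification index on synthetic skeletons.

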