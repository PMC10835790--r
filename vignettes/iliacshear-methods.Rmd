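---
title: "Reduced-order hemodynamics of iliac vein compression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order hemodynamics of iliac vein compression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iliacshear)
```

## The problem

Iliac vein compression syndrome (IVCS, May-Thurner syndrome) is an
anatomical narrowing of the left common iliac vein (LCIV), typically by
the overlying right common iliac artery. Compression accelerates blood
through the stenosis and raises the local shear rate
$\dot\gamma$ — a scalar measure of fluid deformation and an index of
mechanical platelet activation. Because shear combines information from
both flow and lumen area, the patient-level **LCIV/RCIV shear-rate
ratio** — the mean shear in the compressed LCIV divided by that in the
contralateral right common iliac vein (RCIV), which acts as an internal
control — is an attractive, largely self-normalizing stratification
metric.

`iliacshear` implements, at desk scale, the full comparative analysis
around that metric: a synthetic cohort generator, a reduced-order
non-Newtonian venous flow model, control-volume shear metrics, a
calibration loop against ultrasound-like measurements, and the
case-control statistics layer. A fixture of published per-patient
metrics from a reference cohort (four IVCS subjects, four controls) is
bundled so that the statistics layer can be validated independently of
the flow model.

## Rheology

Blood is shear thinning. We use the Carreau–Yasuda law

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \bigl[1 + (\lambda\dot\gamma)^a\bigr]^{(n-1)/a},$$

with whole-blood constants $\mu_\infty = 0.0035$ Pa s (infinite-shear
plateau), $\mu_0 = 0.16$ Pa s (zero-shear plateau), $n = 0.2128$,
$a = 0.64$ and $\lambda = 8.2$ s. At venous shear rates of tens of
1/s the fluid sits mid-transition, so the non-Newtonian treatment
matters most in the *uncompressed* vessels; the stenotic jet region is
close to the infinite-shear plateau.

The scalar shear rate is
$\dot\gamma = \sqrt{2\,D\!:\!D}$ with
$D = (\nabla u + \nabla u^{T})/2$: zero for rigid rotation, equal to the
velocity-gradient magnitude $k$ in simple shear. `shear_rate_scalar()`
implements the tensor contraction; `shear_rate_field()` applies it to a
gridded velocity field using second-order central differences in the
interior and first-order one-sided stencils at boundaries. For the
constitutive container we verify at construction that
$\tau(\dot\gamma) = \mu(\dot\gamma)\dot\gamma$ is strictly increasing
(for $0 < n \le 1$ this holds analytically; the numerical scan guards
against future parameter extensions).

## The reduced-order flow model

The reference analysis rests on full 3D finite-element CFD. This package
deliberately replaces it with a quasi-steady, fully developed,
axisymmetric **generalized-Poiseuille** model solved independently at
every arclength station and stored time point:

* in fully developed tube flow the stress profile is exactly
  $\tau(r) = G r / 2$ with $G = -dp/dz$;
* the local shear rate inverts the constitutive law,
  $\dot\gamma(r) = \tau^{-1}(G r/2)$ (safeguarded bisection, relative
  tolerance $10^{-10}$);
* no-slip integration gives
  $u(r) = \int_r^R \dot\gamma(s)\,ds$ and
  $Q = 2\pi\int_0^R r u\,dr$;
* the outer solve finds $G$ so that the *discrete* flow (Simpson
  quadrature on 129 radial nodes, the same rule used for the returned
  profile) equals the requested $Q$, so mass closure holds to the solver
  tolerance and the Newtonian limit is exact to round-off.

This is defensible at venous Womersley and Reynolds numbers (slow,
respiration-paced flow) and is the only desk-scale option, but it is
also the headline modeling simplification: it omits secondary flows,
flow separation and above all the **post-stenotic jet**, which in 3D
simulations dominates shear amplification downstream of a compression.
Consequences are quantified under *Limitations*.

Flows are routed by conservation through the fixed topology
REIV+RIIV→RCIV, LEIV+LIIV→LCIV, RCIV+LCIV→IVC. The outflow is a
three-element (RCR) Windkessel at the infrarenal IVC,
$C\,dP_c/dt = Q - (P_c - P_{ref})/R_d$, $P = R_p Q + P_c$, integrated
with fixed-step RK4 (`deSolve`), the compliance state initialized at its
steady value and the first cycle discarded. Resistances are tuned so
the mean IVC pressure is 10 mmHg: $R_{tot} = (P_{target} -
P_{ref})/\bar Q$ with a 5% proximal share — the split implied by the
published subject-average (0.00187/0.0355) and control-average
(0.00237/0.0451) resistances, which are reproduced to within 2% by this
rule. $P_{ref} = 0$ (gauge venous reference); the reference pressure
and split rule are not stated in the source protocol and are our
reconstruction.

Numerical defaults: time step 0.01 s for the lumped model (the 1e-4 s
of the reference FEM runs is a stability choice irrelevant here), four
respiratory cycles with the last stored at 32 samples, stations every
1 mm, 129 radial nodes (wall shear changes by far less than 0.1% on
doubling). Warm-started secant continuation across time steps keeps a
full patient solve at a few seconds on one core.

## Control volumes and metrics

The stenotic LCIV control volume is the region where the lumen area is
smaller than 90% of the uncompressed proximal and distal luminal areas.
We operationalize "uncompressed luminal area" as the **maximum** area
over a 5 mm flank window immediately outside the candidate region,
iterated to a fixed point, and take the smaller of the two flank
references (conservative both-sided rule). With a smooth compression
profile the *mean* over the flank window would still include partially
compressed stations, biasing the cutoff downward and shrinking the
detected extent; the maximum reading makes the detected bounds agree
with the analytic 90% crossings of the area profile, which is the
defining property of the rule. Exact bounds are interpolated between
stations; disjoint sub-threshold runs raise an explicit ambiguity error.

The RCIV control volume starts at the same distance from the iliac
confluence and encloses an identical volume (monotone root-finding on
the cumulative volume). For controls, both vessels use the mean start
distance and mean volume of the subject LCIV control volumes.

Within a control volume, shear values are pooled over all stations and
radial nodes with annular volume weights $2\pi r\,\Delta r\,\Delta z$
(weights close to the control volume to well under 0.5%). Per stored
time we compute the volume-weighted mean and the weighted quartiles
(linear interpolation on the weighted empirical CDF); the reported
mean/Q1/Q3 are time averages over the final respiratory cycle. The
**mean-peak** shear rate is the maximum over the cycle of the
volume-weighted spatial mean, averaged across stored cycles — not the
spatial mean of nodal temporal peaks; the source description is
ambiguous on this point, so the spatial weighting is switchable
(`weighting = "count"`) and the peak definition is documented here. In
steady Newtonian tube flow the chain reproduces the closed forms
mean $= \tfrac23\dot\gamma_w$, Q1 $= \tfrac12\dot\gamma_w$,
Q3 $= \tfrac{\sqrt3}{2}\dot\gamma_w$ (weighted CDF
$F(\gamma) = (\gamma/\dot\gamma_w)^2$) to 1% at default resolution.

The ratio series is the pointwise-in-time ratio of the two
volume-weighted mean shears over one normalized cycle; its time mean is
the patient-level LCIV/RCIV shear-rate ratio.

## Synthetic cohorts

No patient data are shipped or downloadable; every downstream stage is
exercised on virtual patients. A patient is a seven-segment tree with
constant-area vessels except the LCIV, which carries a single-parameter
cosine-bump stenosis
$A(z) = A_0\left[1 - s\,(1 + \cos(2\pi(z - z_c)/L))/2\right]$ — smooth,
continuous, with throat area exactly $(1-s)A_0$. Inflows are
single-harmonic waveforms $Q(t) = \bar Q[1 + \phi\cos(2\pi t/T)]$.
Ultrasound-like records (mean velocity and area, with multiplicative
noise floored at 5% of the true value) are taken at the stenosis throat
for the LCIV and mid-vessel elsewhere.

Generator defaults are the study conditions: subject leg flows
1.46/0.73 L/min and control 0.82/0.91 L/min (group averages),
respiratory periods sampled in 3.0–3.75 s, LCIV baseline 131.8 mm²,
RCIV 196.3 mm² (subjects) / 138.5 mm² (controls), compliances 22.4 and
12.6 mm³/Pa, severity sampled in 0.4–0.8 for subjects and fixed at 0
for controls. Quantities the source never reports received one-time
realistic stand-ins, flagged here and in the configuration docs: a
30:70 internal:external iliac split (internal iliac flow fractions are
rarely measured; 20–40% is the physiological range), waveform phasicity
0.3 (respiratory modulation of venous return in supine subjects),
5% measurement noise (Doppler repeatability scale), external/internal
iliac areas 110/60 mm², IVC area 280 mm², and segment lengths
(IVC 100 mm, common iliacs 60 mm, external 80 mm, internal 60 mm).
What the generator does **not** emulate: real lumen eccentricity and
tapering, collateral pathways, waveform shape variability, and any
imaging physics — so passing synthetic tests demonstrates correctness
of the analysis chain, not clinical fidelity of absolute outputs.

## Calibration

Each patient is calibrated against its own measurements, mirroring the
published three-criterion protocol: common-iliac mean flows within 2%,
mean IVC pressure 10 mmHg (within 2%), slice velocities within 10%.
The loop order is flows → pressure → areas: because routing is linear,
one multiplicative correction per leg matches the measured flows
exactly; the Windkessel is retuned at the corrected total flow; and
only if a velocity residual still exceeds tolerance is that vessel's
CT/US area blend weight $w$ adjusted, solving
$Q/\bigl[w A_{CT}(z_s) + (1 - w) A_{US}\bigr] = v_{meas}$ by monotone
1D search (velocity at fixed flow is strictly monotone in slice area).
The blend preserves the CT *shape*: the profile is rescaled so its
slice value equals the blended area, rather than flattened toward a
constant — blending the magnitude, not the geometry. Convergence is
declared only when all three criteria hold on a fresh simulation, and
reported residuals are always recomputed from the final state. A
noise-free self-consistent patient is a fixed point (zero iterations);
contradictory measurements (e.g. a directly measured flow inconsistent
with velocity × area) leave `converged = FALSE` with the offending
residual reported. Per-inlet `frozen_inlets` flags exclude individual
inflows from rescaling, mimicking the reference cohort's one untuned
internal iliac boundary.

## Statistics and the bundled fixture

Within-group comparisons (RCIV vs LCIV) use two-sided paired Student t
tests; between-group comparisons (subject vs control, same vessel) use
two-sided homoscedastic (pooled-variance) t tests. p-values come from
the exact t CDF — required to resolve $p \approx 8\times10^{-5}$ at six
degrees of freedom. Degenerate conventions (ours; the reference data
never hit them): all-zero paired differences give $p = 1$; zero pooled
variance gives $p = 1$ for equal means and $p = 0$ with a degeneracy
flag otherwise.

`reproduce_reference_statistics()` regenerates every group mean,
standard deviation and p-value derivable from the bundled per-patient
values and compares each to its printed counterpart at printed
precision (tolerance: one unit in the last printed digit). A handful of
printed cells cannot be matched exactly because the original authors
computed them from unrounded per-patient data — most visibly the
between-group LCIV flow and RCIV area p-values, which differ in the
fourth decimal when recomputed from the printed three-decimal flows.
These carry documented wider tolerances in the bundled target table
rather than silently loosened global tolerances.

```{r stats, eval = FALSE}
rep <- reproduce_reference_statistics()
all(rep$pass)
```

## Worked example

```{r pipeline, eval = FALSE}
subjects <- make_cohort(subject_template(), 4, master_seed = 101)
controls <- make_cohort(control_template(), 4, master_seed = 202)
res <- run_case_control_analysis(subjects, controls)
print(res)
severity_ratio_sweep(c(0.4, 0.5, 0.6, 0.7, 0.8), seed = 7)
```

(Chunks are not evaluated at build time; the cohort run takes a few
minutes. The README shows the printed output of this exact example.)

## Limitations

* **Shear-ratio compression.** The quasi-steady axisymmetric model
  preserves the *direction* and *monotonicity* of all effects — the
  subject ratio exceeds the control ratio, grows monotonically with
  severity, and control vessels never trigger the stenosis detector —
  but it compresses the magnitude of the LCIV/RCIV ratio. With
  group-average conditions the synthetic subject cohort reaches mean
  ratios of roughly 1.5–3 across severities 0.4–0.8, versus 6.56
  reported from 3D CFD; the missing post-stenotic jet (and, secondarily,
  lumen eccentricity) accounts for the gap. Even the reference protocol
  notes that it *underestimates* the subject-group ratio. Absolute
  per-patient shear magnitudes (e.g. 571 1/s) are not reproducible
  without the original imaging and are exercised exclusively through
  the bundled fixture layer.
* Rigid walls, no collaterals, no thrombus-cycle dynamics.
* The calibration scheme (loop order, stopping logic, blend form) is a
  reconstruction; only its three tolerance criteria are published.
* Quartile weighting and the mean-peak definition are one documented
  reading of an ambiguous description (both switchable).
* Problem sizes used in the shipped tests and acceptance script —
  4+4-patient cohorts, 32 stored time samples, 1 mm stations, 129
  radial nodes, a 5-point severity sweep — are the package's chosen
  desk-scale defaults; they keep a full cohort analysis in the
  minutes range on a single core.
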