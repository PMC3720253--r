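---
title: "Methods: the cerebral venous outflow model in cvoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cerebral venous outflow model in cvoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvoflow)
```

## What the package models

Cerebral venous return leaves the head through two main routes — the
internal jugular veins (IJVs), measured at the consensus segments J3
(mandibular angle), J2 (thyroid level) and J1 (brachio-cephalic
confluence), and the vertebral veins (VVs) — plus a web of cervical
collaterals. The package treats the neck as a purely volumetric
network: arterial inflow on one side, venous outflow on the other, and
five collateral flows that close the books. There is no pressure or
resistance modelling; every quantity is a flow in ml/min, and the model
is exactly as good as the Doppler flow estimates feeding it.

Three assumptions matter. First, arteries are circular (CSA from the
B-mode diameter) while veins are elliptical and respire (CSA as the
mean of the minimum and maximum traced area over one respiratory
cycle). Second, the peak-envelope velocity TAV_p relates to the spatial
mean through a single velocity factor η determined by the Womersley
number of the site. Third, flows are stationary over the acquisition,
so one TAV per site suffices.

## The velocity factor

For the fundamental harmonic of oscillatory pipe flow the axial
velocity profile is $u(y) = 1 - J_0(\Lambda y)/J_0(\Lambda)$ with
$\Lambda = i^{3/2}\alpha$ and $\alpha = r\sqrt{\omega/\nu}$. We define

$$\eta(\alpha) = \frac{|u(0)|}{\left|\,2\int_0^1 u(y)\,y\,dy\,\right|},$$

the modulus ratio of the axis velocity — where the operator parks the
sample volume, because that is where the time-averaged velocity is
highest — to the cross-sectional mean. This satisfies every property a
velocity factor needs: $\eta(0) = 2$ exactly (Poiseuille), monotone
non-increasing decay, and $\eta \to 1$ in the plug-flow limit
($\eta(100) \approx 1.014$). We deliberately do *not* use the spatial
maximum of $|u|$: beyond $\alpha \approx 5.5$ the Womersley profile
overshoots near the wall (the annular effect) and the max-to-mean ratio
plateaus around 1.09 instead of reaching the plug-flow limit; on the
physiological range of this application ($\alpha \lesssim 5$ for the
carotids at rest, $\lesssim 3$ for the veins at respiratory frequency)
the axis *is* the spatial maximum and the two definitions coincide.

Numerically, $J_0$ and $J_1$ of complex argument are evaluated from
their integral representations by 400-node Gauss–Legendre quadrature —
accurate to ~12 digits over the range used, and only ratios of the
(exponentially large) values enter η, so the growth cancels. Because
the closed form is O(1) per evaluation we compute η directly rather
than caching a grid with interpolation, which would only add error. For
$\alpha < 10^{-3}$, η is set to its limit 2 to avoid cancellation in
$1 - 1/J_0(\Lambda)$. The test suite cross-checks η against a
brute-force radial integration of the profile built on series-expansion
Bessel functions (an independent algorithm) to <1% over
$\alpha \in [0, 30]$.

Fluid and pulsation constants are configuration, never hard-coded:
kinematic viscosity 0.035 cm²/s (whole blood at body temperature),
heart rate 70 bpm for arteries, respiratory rate 15/min for veins (the
venous envelope is respiration-modulated). A per-vessel-class
`eta_override` lets users substitute their own calibration curve.

## The five-point profile fallback

When J1 flow is turbulent or nearly absent, a single peak sample is
unreliable and operators record five velocities across the lumen
chord. The spatial mean is computed by completing the chord with
zero-velocity no-slip nodes at both walls — seven equally spaced nodes
— and applying the composite trapezoid rule. A constant profile $v$
therefore yields $5v/6$, and a parabola sampled at the five interior
nodes comes within 3% of the analytic chord mean $2V/3$. We considered
area-weighting the samples as elliptical annuli (which would target the
disc mean $V/2$ for a paraboloid) and rejected it: the five samples lie
along a chord, not along a radius, and pretending otherwise assumes an
axisymmetry that a septum-bearing J1 segment specifically lacks.
Negative samples are kept signed — reversed flow is information, not an
error.

## Uncertainty model

The dominant controllable error is insonation-angle placement:
$\delta TAV = TAV\,(\cos\theta/\cos(\theta+\epsilon) - 1)$, with
$\epsilon$ defaulting to 5° (a repeat-placement standard deviation
typical of jugular insonation) and $\delta Q = \delta TAV \times CSA$.
The error is zero iff $\epsilon = 0$ and grows with both angle and
error — at $\theta = 60°$ it is an 18% effect on flow, which is the
quantitative reason steep insonation angles at J1 are the weak point of
the whole chain. The domain guard $\theta + \epsilon < 90°$ is
enforced: past it the cosine changes sign and the formula is
meaningless.

## Network bookkeeping and signs

Aggregates use side-summed flows; the jugular re-entry flows
$Q_{23} = Q_{J2} - Q_{J3}$ and $Q_{12} = Q_{J1} - Q_{J2}$ are computed
per side (they are per-jugular statements) and side-summed only inside
the continuity check and the indexes. The continuity relation
$(Q_{C\text{-}D} + Q_{FN}) - (\Sigma Q_{23} + \Sigma Q_{12} +
Q_{C\text{-}P}) = 0$ is an algebraic identity of the definitions, so
the solver stores its residual and the tests fuzz it to
$|r| < 10^{-9} \times HBinF$: any violation is an implementation bug,
not a data problem. Negative flows are reported, never clipped —
$Q_{23} < 0$ means the jugular feeds the collaterals on that side, and
a negative aggregate $Q_{C\text{-}P}$ on cohort-mean inputs flags the
well-known J1 overestimation (turbulence near the valve inflates TAV).

Sites with absent flow enter as flow state `absent` with zero velocity
— an observed state contributing $Q = 0$ to the aggregates, not a
missing value. A subject missing any of the 16 model sites is named
site by site by `validate_subject()`, and the network solver refuses to
run on an incomplete subject (the collateral equations need J2/J3, not
only the aggregate sites).

## Indexes: per-subject, not ratio-of-means

Cohort index values are computed per subject and then averaged.
Ratio-then-average and average-then-ratio differ materially here
because per-site flow dispersion is large (sd comparable to the mean);
only the per-subject path is consistent with small per-subject
collateral fractions coexisting with large aggregate J1 flows. The
aggregate path is still provided (`aggregate_indexes()`) and every
result carries a `computation_path` attribute so reports can label
which was used.

DCVO needs both postures. By default each posture uses its own
measured arterial denominator (`denominator = "matched"`); datasets
without upright arterial measurements can force the supine HBinF on
both terms (`"supine"`). Neither choice is claimed to be canonical —
the definition is ambiguous when only one inflow value exists — so
both are explicit options, and a missing posture leaves DCVO undefined
(`NA`), never zero.

## Two-cohort comparison

The Wilcoxon–Mann–Whitney U test is implemented with midranks for
ties. For combined $n \le 20$ the two-sided p comes from full
enumeration of the $\binom{n}{n_a}$ group assignments (tail defined by
$|W - \mu|$, with a $10^{-9}$ slack against floating-point midranks),
so a 10-vs-10 study is always exact, ties included; the null
distribution is cached per tie pattern, which makes repeated testing
(e.g. 2000-replicate size checks) cheap. Beyond 20 the tie-corrected
normal approximation with continuity correction is used. Both p-values
are always reported; identical pooled values yield a degenerate flag
and p = 1. No multiplicity or demographic adjustment is applied — the
comparisons are deliberately marginal, mirroring how such pilot
cohorts are analysed.

## The synthetic cohort generator

The generator exists so every pipeline stage is testable against known
truth. Per subject it draws arterial per-vessel flows from lognormal
distributions moment-matched to the published cohort means and sds
(lognormal because flows are positive and the printed sds are large
relative to the means — Gaussian noise at those sds would produce
negative flows). The venous side is built top-down: a baseline
collateral-to-caval fraction (1 ± 3% across subjects, the healthy CFI
distribution), a vertebral-vein share of the main-route outflow (7–10%
supine, 15% upright), segmental re-entry fractions placing 37/55% of
the eventual jugular flow at J3/J2 for controls (26/59% of the
unobstructed flow for patients, whose observed rates are depressed by
the obstruction), and — for the CCSVI phenotype — a J1 obstruction
multiplier drawn with mean 0.65, sd 0.29, clipped to [0, 1], so the
per-subject collateral fraction lands near the published 61 ± 27%. The
flow blocked at J1 is rerouted to the collateral-proximal channel, so
continuity holds in truth exactly as in the estimates. Posture is a
subject-level shift of the collateral fraction (+5 points upright for
controls, −42 for patients, the published postural index values) plus
the upright vein-geometry collapse.

Each latent site flow is then decomposed into what an operator records:
the peak-envelope velocity through the same velocity factor the
quantifier uses, min/max lumen areas around the reference geometry with
±30% respiratory variation, a diameter for arteries, and a uniform
45–60° insonation angle with a Normal(0, 2.5°) placement error (making
the configured 5° uncertainty a ~2σ statement). One lognormal factor
per site (default sd 0.10) governs the flow-level measurement noise;
the geometry jitter is compensated inside the decomposed velocity so
that the realized per-site flow noise equals the documented `noise_sd`
rather than compounding. With zero noise and zero angle error the
quantification pipeline recovers the latent flows to machine precision
— the inverse-then-forward identity that anchors the test suite.

What the generator does **not** emulate: intraluminal septum/valve
mechanics (obstruction is a scalar multiplier), turbulence-induced TAV
bias at J1, within-subject left/right correlation (a correlation
parameter exists, default 0, as the published data report none), and
operator drift across a session. Passing recovery tests on synthetic
cohorts therefore demonstrates that the estimator chain is unbiased and
correctly propagates the modelled error sources — not that real J1
turbulence is handled, which no velocity-factor correction can fix.

All randomness flows from one master seed: per-subject child seeds are
drawn once from a `sample.int(2^31 - 1)` stream seeded with the master,
so cohorts are reproducible from `(phenotype, n, seed)` and
sub-sampling a cohort never shifts another subject's draws.

## Problem sizes and numerical tolerances in the tests

The suite runs cohorts of 10 subjects (the scale the phenotypes
describe): 100 seeded replicates for the collateral-index recovery
check (cohort-mean CFI within ±6 points of the latent truth in ≥90% of
replicates at 10% noise; the measured error sd is ≈2.4 points), 60
replicates for the HC-vs-CCSVI separation check (CFI rejected at
p < 0.05 in ≥95%), and 2000 null replicates for the exact test's size
(empirical type-I error within [0.03, 0.07] at α = 0.05). Continuity is
fuzzed over 500 random subjects spanning four orders of magnitude of
flow. Exact-vs-oracle Mann–Whitney equality is checked exhaustively
over all group-size splits with combined n ≤ 6 with forced ties.

## Known limitations

- The velocity factor assumes a single-harmonic Womersley profile;
  real arterial waveforms carry several harmonics, and the venous
  "pulsation" is respiratory modulation, not oscillation. η is best
  read as a principled bridge between peak and mean velocity, not an
  exact profile model, which is why a per-class override is exposed.
- J1 turbulence biases TAV upward; the model reports the resulting
  negative aggregate collateral flows rather than correcting them.
- The network has no C1-C2 site: flow inversion in the upper
  collaterals shows up only implicitly in the signs of Q_23/Q_12.
- Acquisition duration bookkeeping (nominally one respiratory cycle
  for veins within a 4-second trace) is stored but unused; slow
  breathers may undersample the respiratory CSA variation.
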