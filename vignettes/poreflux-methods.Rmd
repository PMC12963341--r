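---
title: "Methods: ion permeation and single-channel analysis with poreflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion permeation and single-channel analysis with poreflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreflux)
```

## Scope

`poreflux` characterizes ion conduction through a narrow membrane
nanopore from two complementary directions:

1. **Trajectory side** — counting complete, directional ion translocations
   in particle trajectories and converting them to ionic current and
   conductance, together with dwell-time analysis of a charged constriction
   and Kabsch-superposed RMSD series. Because raw all-atom trajectories of
   this kind are rarely shareable, the package includes an overdamped
   Brownian-dynamics surrogate that generates statistically realistic
   trajectories under controlled, known conditions.
2. **Recording side** — idealization of single-channel planar-bilayer
   current recordings into classified open events
   (step-like / multi-level / erratic) with duration and conductance
   statistics, validated against a ground-truth-labelled trace generator
   that emulates the acquisition chain.

A small statistical kernel (Brunner–Munzel rank test, median/IQR,
mean ± SD/SEM) is implemented in the package itself because these are the
procedures both analysis arms report.

## The counting model

The trajectory-side current estimator is deliberately literal. With $N_K$
the number of K$^+$ ions completing a passage in the $+Z$ direction and
$N_{Cl}$ the number of Cl$^-$ ions completing a passage in $-Z$ over a
window $\Delta t$,

$$I = \frac{(N_K + N_{Cl})\, e}{\Delta t}, \qquad G = \frac{I}{V},$$

with $e = 1.602\times10^{-19}$ C. Both identities are enforced to machine
precision (`compute_current()`, `compute_conductance()`), and replicate
runs aggregate as mean ± sample SD (`aggregate_replicates()`).
Counter-productive crossings (K$^+$ in $-Z$, Cl$^-$ in $+Z$) are tallied
and reported but never subtracted: the equation above counts productive
passages only, and we follow it literally rather than invent a net-flux
variant. At strong positive voltage, counter-productive crossings are rare,
so the distinction matters mostly at low or zero bias.

**What is a crossing?** The definition must be robust to an ion dithering
at a boundary. `detect_crossings()` uses two-plane hysteresis: the counter
arms when the ion leaves a reservoir through the first plane and fires only
when it reaches the opposite reservoir beyond the second plane. In a
periodic box this is implemented by tracking which *reservoir image* the
ion occupies along its unwrapped coordinate; the crossing count is the
sequence of image increments. This makes the counter exact under periodic
recycling (an ion recycled through the box boundary is never miscounted)
and automatically counts recrossings after completion as new events. The
unwrapping itself is minimal-image (`unwrap_z()`); a single-frame jump of
exactly half a box is treated as no wrap. The counting planes default to
the membrane slab faces; the exact planes are configurable because
published analyses rarely state them.

The implementation is verified against an independent brute-force
finite-state walk on randomly generated paths (1,000 paths, exact
agreement), and is invariant under rigid z-translation, ion relabelling,
and time reversal (with direction labels negated).

## The Brownian-dynamics surrogate

`simulate_ions()` propagates point ions by Euler–Maruyama overdamped
Langevin steps: per axis a drift $(D/kT)F\,\delta t$ plus a Gaussian
displacement of variance $2D\,\delta t$. Geometry and conditions follow the
emulated study: a 6×6×12 nm periodic box, a 4 nm membrane slab pierced by a
cylindrical pore, 1.0 M KCl (ion counts from concentration × volume,
charge-neutral), 298.15 K, +150 mV across the slab, 500 ns per replicate in
triplicate. The axial electric force acts only inside the slab
(field = V / slab thickness) and is oriented so that positive voltage
drives K$^+$ toward $+Z$ and Cl$^-$ toward $-Z$ — the productive
directions of the counting equation. We adopt this sign convention from
the reported crossing directions; the alternative field-vector wording
that sometimes accompanies such setups is electrostatically inconsistent
with those directions and is not used.

Defaults not fixed by the emulated conditions are standard values:
$D_K = 1.96$, $D_{Cl} = 2.03$ nm²/ns (infinite-dilution diffusion
coefficients), time step 1 ps, frames saved every 10 ps, pore radius
0.45 nm (narrow-pore regime). Walls are hard: radial reflection at the
pore wall, axial reflection at the membrane faces; all axes are periodic,
so the reservoirs recycle. A configuration whose single-step RMS
displacement reaches the pore radius is rejected. All randomness flows
from one recorded seed; identical seeds give bitwise identical
trajectories.

**Validation limit.** For the unobstructed pore the package provides the
Nernst–Einstein closed form
$G = (e^2/kT)(c_K D_K + c_{Cl} D_{Cl})\,\pi r^2/L$
(`nernst_einstein_reference()`). This neglects access resistance and
concentration polarization at the pore mouths, so the simulated
conductance sits somewhat below it; at the default geometry the measured
ratio is ≈ 0.85–0.90, comfortably within the 25% validation band we
require, and the gap shrinks as the pore narrows relative to the slab.
Zero-voltage runs give a net current statistically indistinguishable from
zero, and the current is odd in voltage.

**The constriction surrogate.** The emulated pore has a charged
constriction (two arginine rings) that transiently traps anions and lowers
conductance; the double-glycine mutant abolishes both effects. We model
the constriction as a Gaussian potential well in $z$ (default depth 4 kT,
σ = 0.3 nm, mid-slab, acting on Cl$^-$) *plus single-occupancy exclusion*:
while a well-bound ion resides in the constriction window, the window is
closed to all other ions. The exclusion term is essential, not cosmetic:
for non-interacting particles a purely attractive well adds no
steady-state resistance (in the 1-D Smoluchowski picture the resistance
integral weights $e^{+U/kT}$, so wells contribute nothing), and without it
the trap prolongs individual residences but leaves conductance unchanged —
contradicting the phenomenon being modelled. Occlusion by the bound anion
is also the physical mechanism proposed for the real constriction. The
mutant surrogate is simply the trap switched off.

Measured behaviour (30–100 ns runs, 8–10 seeds): total conductance falls
monotonically with well depth (≈ 2.17 → 1.27 nS over 0–6 kT at default
geometry), the mean Cl$^-$ dwell time in the window rises monotonically
(≈ 0.04 → 0.13 ns), and in paired seeds the unobstructed pore conducts
more and traps less in ≥ 9/10 comparisons. One known limitation: the
conduction loss manifests almost entirely as co-ion (K$^+$) starvation —
the Cl$^-$ crossing *count* stays roughly flat with depth, because each
bound anion is eventually carried through by the drift and the site
processes anions serially at close to their free supply rate. The
surrogate therefore reproduces the observable contrast (conductance and
dwell) but should not be read as a per-species flux model of the real
constriction.

## Dwell analysis

`dwell_events()` extracts maximal runs of frames with $z$ inside a window
(default: the constriction window), with half-open durations
((exit frame − entry frame) × save interval), an optional merge of runs
separated by at most `gap_frames`, and a minimum-duration filter. With
zero gap and zero minimum the events exactly partition the inside-window
frames (checked against a brute-force frame scan), and event counts are
monotone non-increasing in both filters. Because the emulated study
reports trapping qualitatively, no numeric dwell target exists; the
package reports count, mean, median, max and total occupancy per species,
and `compare_conditions()` assembles the two-condition contrast (with an
optional Brunner–Munzel test on dwell durations).

## RMSD

`kabsch_rmsd()` implements least-squares rigid-body superposition through
the SVD with the determinant correction that enforces a proper rotation,
and `rmsd_series()` maps it over a trajectory against a chosen reference
frame. The implementation is cross-checked against the independent
reference implementation in bio3d. When reading structured trajectories,
backbone atoms are the conventional selection for stability analysis; the
package reads ion records and coordinates via bio3d (PDB topology plus
multi-model PDB or DCD coordinates, unit cell read per frame when
present).

## The recording generator

`trace_protocol()` fixes the acquisition chain at the emulated values:
+150 mV, 20 kHz sampling, 4 kHz low-pass (4-pole Bessel-type — the
patch-clamp convention; built from the standard magnitude-normalized
4th-order Bessel analog poles with a prewarped bilinear transform, unit DC
gain). `render_trace()` produces baseline + $G \cdot V$ piecewise-constant
ideal current, adds white Gaussian noise (default SD 1 pA before
filtering, a realistic RMS for this bandwidth), filters, and samples.

**Step-conductance law.** The emulated cohort is summarized as median
(IQR) = 0.17 (0.12–0.32) nS. A single log-normal cannot match all three
numbers — the log-quartile offsets are asymmetric (0.348 vs 0.632) — so
the generator uses a two-piece log-normal: equal-mass halves with separate
log-scales below and above the median (σ_lo = 0.516, σ_hi = 0.937). Its
median and both quartiles equal the requested values exactly
(`qcond_step()`), which makes recovery tests well-posed.

**Event classes.** Step-like events have one stable level; multi-level
events have 2–3 stacked levels (each an additional conductance draw, each
dwelling ≥ 100 ms — the stacking mimics additional insertions); erratic
events are ≥ 5 open flickers of 5–40 ms separated by closed gaps of
5–40 ms. The class mixture defaults to 55/25/20%. Every class draws its
*total* duration from the same log-normal duration law, parameterized so
that ≈ 54% of all events exceed 1 s (matching the reported 63/116);
control mode generates only short single-level fusion-like transients with
a law putting ≈ 85% under 1 s. Short erratic and multi-level draws are
truncated up to the minimum length their structure needs (0.45 s and
0.25–0.5 s respectively); the truncation affects only sub-second draws and
leaves the > 1 s fraction unchanged.

## The idealization pipeline

`analyze_trace()` chains: robust baseline (mode of a kernel-smoothed
histogram, lower mode on bimodal ambiguity, MAD-based noise scale);
threshold detection (|deviation| > 5 noise SDs, absolute floor 0.5 pA for
noiseless input; 50 ms debounce merge so flickering stays one event;
10 ms minimum duration); binary-segmentation change-point splitting of
each event window (within-segment variance objective, stiff
penalty 40 σ² log n because the filtered noise is correlated, 1.5 ms
minimum segment, adjacent segments re-merged when their means differ by
< 4 σ); stability flags (within-segment SD ≤ 1.5 σ and dwell ≥ 50 ms);
and the three-way classification: step-like iff the stable open levels
form exactly one conductance group and unstable time is ≤ 10% of the
event, multi-level iff ≥ 2 distinct stable groups, erratic otherwise.
These thresholds are declared defaults exposed as arguments — commercial
analysis software keeps its equivalents unstated, so no claim is made that
they reproduce any particular software's settings.

Event boundaries are refined to the half-amplitude crossing of the
adjacent open level and compensated for the acquisition filter's DC group
delay (2.1139/ω_c for the 4-pole Bessel, ≈ 1.7 samples at the default
settings). On noise-free traces the full pipeline recovers every boundary
within 2 samples, every class exactly, and step conductances within 1%;
at recording-like SNR it detects ≥ 95% of true events ≥ 10 ms and assigns
≥ 90% of classes correctly. Detection counts are monotone in the
threshold and the minimum duration, and classification is invariant to
baseline shifts and time reversal.

Open current for a step-like event is the dwell-weighted mean of its
stable segment(s) (edge-trimmed, so edge transients are excluded), and
conductance is the baseline-subtracted open current over the voltage.
`event_conductances()` summarizes step-like conductances as median/IQR
through the same `median_iqr()` code path used everywhere else, plus a
0.05 nS-binned histogram. `duration_analysis()` reports per-group
fractions beyond a 1 s cutoff (the criterion separating genuine openings
from transient liposome-fusion events) and the Brunner–Munzel comparison.

## Statistical kernel

`brunner_munzel()` implements the rank formulation with midrank tie
handling, the studentized statistic, Satterthwaite degrees of freedom and
a t reference distribution; degenerate inputs (zero rank variance) are
flagged with the documented limit behaviour. Fixed small-sample cases
agree with an independent reference evaluation to 1e-6, the test keeps
its nominal size under the null (type-I error within [0.04, 0.06] at
α = 0.05, n = m = 30, 10,000 replicates), the relative effect mirrors
under group swap and is invariant under strictly monotone transforms.
`median_iqr()` fixes the linear-interpolation quantile convention (type
7); the source analyses do not state a convention, and this is the most
common default. Mean ± SD uses the n−1 denominator; a single replicate
reports SD 0 and is flagged.

## Problem sizes and reproducibility

The validation suite runs at desk scale by design: 20–100 ns
Brownian-dynamics runs with 6–10 seeds (the counting statistics converge
like √N, and 40 ns already yields ~100 productive crossings at default
geometry), 2–20 min synthetic recordings with ~50–220 events, 1,000-sample
conductance cohorts, and 10,000-replicate Monte-Carlo calibrations. The
500 ns triplicate defaults remain the generator's study conditions; the
shorter validation runs simply trade statistical precision, not physics.
Every stochastic function takes an explicit seed, `report()` writes a
manifest with the seed and a configuration hash, and rerunning any
pipeline with the same configuration and seed reproduces its outputs byte
for byte.

## What the synthetic data do and do not show

The generators emulate the *statistical structure* of the study's data —
event mixtures, conductance and duration laws, acquisition filtering,
trapping phenomenology — under known ground truth, which is exactly what
is needed to validate the analysis code. They do not emulate protein
flexibility, explicit solvent, ion–ion electrostatics beyond mean-field
neutrality and single-file exclusion, electroosmotic flow, capacitive
transients, or 50/60 Hz interference. Passing the validation suite
therefore certifies the analysis pipeline, not the microscopic fidelity
of the surrogate: conclusions about a real pore still require real
trajectories or recordings, which the readers (`read_trajectory_table()`,
`read_md_trajectory()`, `read_trace()`) accept in standard formats.
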