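# poreflux

Ion permeation and single-channel current analysis for membrane nanopores.

Narrow β-barrel nanopores are characterized from two directions that rarely
share code: molecular simulation, where conductance is estimated by counting
complete ion translocations, and planar-lipid-bilayer electrophysiology,
where noisy current recordings are idealized into open events and
summarized. `poreflux` implements both analysis arms as one tested R
package, for people who run (or referee) nanopore characterization studies:

* **Trajectory arm** — periodic-boundary-aware detection of complete
  directional K⁺/Cl⁻ translocations along the pore axis, conversion to
  current and conductance, triplicate aggregation, dwell-time analysis of a
  charged constriction, and Kabsch-superposed RMSD series. A fast
  overdamped Brownian-dynamics simulator (Rcpp) generates surrogate
  trajectories with known ground truth, including an anion-binding
  constriction model and its "mutant" (constriction removed).
* **Recording arm** — a ground-truth-labelled generator of bilayer current
  traces (+150 mV, 20 kHz sampling, 4 kHz Bessel-type low-pass), and an
  idealization pipeline: robust baseline, threshold detection with
  debounce, change-point sub-level segmentation, three-way classification
  (step-like / multi-level / erratic), conductance histograms and duration
  statistics.
* **Statistics** — Brunner–Munzel rank test (midrank ties, Satterthwaite
  df), median/IQR and mean ± SD/SEM, implemented once and used by both
  arms.

## The model in brief

The trajectory-side estimator counts productive passages: with `N_K` the
K⁺ ions completing a crossing in +Z and `N_Cl` the Cl⁻ ions completing one
in −Z over a window Δt,

    I = (N_K + N_Cl) · e / Δt        G = I / V

with e = 1.602×10⁻¹⁹ C. Crossings are counted with two-plane hysteresis on
unwrapped coordinates (arm at the first plane, fire at the second), so
boundary dithering never double-counts and periodic recycling is handled
exactly. The recording-side pipeline classifies each detected event from
its segmented sub-levels: one stable conductance level → step-like; two or
more distinct stable levels → multi-level; otherwise → erratic. Step-like
conductances are summarized as median (IQR). See the methods vignette
(`vignettes/poreflux-methods.Rmd`) for the full model, parameter defaults
and limitations.

## Worked example

```r
library(poreflux)

# trajectory arm: constricted pore, triplicate 20-ns surrogate runs
cfg <- sim_config(duration_ns = 20, trap = trap_config(depth_kT = 4))
trajs <- make_replicates(cfg, seeds = 1:3)
aggregate_replicates(lapply(trajs, estimate_conductance))
#> conductance estimate (aggregate of 3 replicates)
#>   I = 250.98 +/- 37.85 pA,  G = 1.67 +/- 0.252 nS at +150 mV

# recording arm: synthesize a labelled 240-s recording, then idealize it
p <- trace_protocol(duration_s = 240, seed = 42)
events <- analyze_trace(render_trace(generate_events(p), p))
event_conductances(events)
#> step-like conductance: median (IQR) = 0.30 (0.16-0.37) nS, n = 24
table(events$class)
#>     erratic multi_level   step_like
#>           6           5          24

# duration criterion vs a fusion-transient control recording
ctrl <- trace_protocol(duration_s = 120, control = TRUE, seed = 43)
ev_c <- analyze_trace(render_trace(generate_events(ctrl), ctrl))
duration_analysis(events$duration_s, ev_c$duration_s,
                  labels = c("channel", "control"))
#> event durations vs 1.0 s cutoff
#>   channel: 21/35 events (60%) longer than cutoff
#>   control: 3/23 events (13%) longer than cutoff
#>   Brunner-Munzel: W = -6.032, p = 1.968e-07
```

The aggregate current is the literal counting-equation value for the three
runs; the channel-vs-control comparison shows the long-lived channel
openings separating cleanly (p ≪ 0.01) from short fusion transients; and
the step-like median/IQR here scatters around the generator's 0.17
(0.12–0.32) nS law at this small event count (n = 24) — the conductance
recovery tests use larger cohorts.

`report()` chains either arm end-to-end (simulate → analyze → summarize)
and writes JSON/TSV outputs plus a seed-and-hash manifest; re-running with
the same configuration and seed reproduces the payloads byte for byte.

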