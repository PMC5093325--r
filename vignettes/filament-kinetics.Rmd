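---
title: "Modelling single-filament growth kinetics with filakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-filament growth kinetics with filakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(filakin)
library(dplyr)
```

## The model

Short peptides such as diphenylalanine (FF) self-assemble into crystalline
nanotubes whose axial growth can be watched one filament at a time when the
assembly is held in a microfluidic channel under a continuous flow of
monomer solution. `filakin` implements the quantitative machinery for this
kind of experiment.

The core is a linear growth law. A filament end gains length by monomer
attachment at rate $k_{\mathrm{on}} c$ — proportional to the local
free-monomer concentration $c$ — and loses length by detachment at a
concentration-independent rate $k_{\mathrm{off}}$. The net growth rate is

$$R(c) = k_{\mathrm{on}}\, c - k_{\mathrm{off}},$$

with $k_{\mathrm{on}}$ in µm·min⁻¹·mM⁻¹ and $k_{\mathrm{off}}$ in µm·min⁻¹.
$R$ crosses zero at the *critical concentration*
$c_s = k_{\mathrm{off}}/k_{\mathrm{on}}$: above $c_s$ filaments elongate,
below it they shorten, and under sustained subcritical flow they dissolve
completely, because the flow carries detached monomer away instead of
letting it re-equilibrate. The law describes the *maturation* (elongation)
of preformed structures only; nucleation is a separate statistical process
that the package deliberately does not model.

Two stylised parameterisations ship as presets. `ff_filament()` is the
strong-asymmetry limit of the FF nanotube: the fitted law
($k_{\mathrm{on}} = 3.36$, $k_{\mathrm{off}} = 7.4$, hence
$c_s \approx 2.2$ mM in water) is carried entirely by the fast O
(carboxylate-exposed) face while the N (amino-exposed) face is silent,
which reproduces unidirectional growth and shortening.
`cycloff_filament()` is the symmetric counterpart for cyclo-(Phe-Phe) in
DMSO ($k_{\mathrm{on}} = 0.15$, $k_{\mathrm{off}} = 1.2$, $c_s = 8.0$ mM
as the ratio of those rounded rates): the law is split equally between the
faces, so both termini move and their rates are indistinguishable within
error. Length measurements constrain only the *summed* two-end law, so the
per-face split is a modelling choice, clearly labelled and overridable —
whether a "silent" face has strictly zero rates or merely reduced ones is
not decidable from length data alone.

## The stochastic simulator

`simulate_filament()` runs an exact Gillespie (kinetic Monte Carlo)
simulation of a two-ended filament. Length is quantised in layers of
`layer_um` µm; per uncapped end the event propensities per minute are

* attach: $k_{\mathrm{on}} c / \delta L$,
* detach: $k_{\mathrm{off}} / \delta L$ (impossible at zero length),
* cap: `cap_rate` (a Poisson process modelling irreversible growth arrest;
  default 0).

Waiting times are exponential in the total propensity and events are chosen
proportionally, so the trajectory is a statistically exact realisation of
the continuous-time Markov jump process. The layer size $\delta L$ is a
pure discretisation knob, not a physical parameter: the default 0.01 µm is
small against the µm-scale measurements while keeping event counts
tractable, and the test suite checks that halving it leaves ensemble rates
unchanged within Monte Carlo error.

Two bath modes bracket the experimental situations:

* **open** — constant $c$, emulating continuous flow; the system never
  equilibrates, and the ensemble mean net rate equals $R(c)$ of the summed
  law (a law-of-large-numbers identity the tests verify at 100 seeds per
  concentration).
* **closed** — a finite monomer reservoir: every attach/detach event moves
  the free concentration by $\mp\gamma$ (`gamma_mM`, default $10^{-4}$ mM),
  so $c(t) + \gamma \cdot (\text{net layers added}) = c_0$ holds *exactly*
  at every event. With a persistent filament the pool relaxes to the fixed
  point where attach and detach propensities balance — exactly $c_s$ —
  independent of the supercritical starting concentration and of how the
  rates are split across faces (faces with equal $k_{\mathrm{off}}/k_{\mathrm{on}}$
  but 10-fold different magnitudes share the fixed point, while showing
  10-fold different binding *turnover*; `turnover_summary()` resolves
  this). $\gamma$ is the single coarse-graining parameter of the closed
  system; it sets the concentration fluctuation scale around equilibrium.

Determinism: each simulation seeds R's Mersenne–Twister stream locally (the
C++ core draws through R's RNG), so the same configuration and seed give a
bit-identical trace, and the global RNG state is untouched.

```{r sim-example}
tr <- simulate_filament(ff_filament(), bath_config("open", c0_mM = 3.2,
                                                   t_max_min = 5), seed = 1)
autoplot(tr)
```

Degenerate inputs are handled conservatively: a filament of zero length can
grow (detachment is simply impossible) but a detach event that *reaches*
zero length terminates the trace as full dissolution; the initial length is
snapped to a whole number of layers so dissolution hits exactly zero and
closed-mode mass conservation is exact in floating point; in closed mode
the attach propensity is clamped to zero when less than one depletion
quantum of monomer remains.

## The measurement model

The synthetic observation layer emulates the manual image-analysis
protocol: frames at a fixed interval, and each end position measured five
times and averaged per time point. `observe_trace()` samples the event
trace by zero-order hold (positions are constant between events; a frame
exactly on an event time reports the post-event position) and adds the
mean of `n_repeats` iid Gaussian reads of SD `sigma_um`. The default
`sigma_um = 0.25` µm is a package choice — the measurement error of the
original protocol was never quantified — picked so that 5-replicate
averaging leaves ~0.11 µm SD, small against the 5–10 µm structures; it is
surfaced in every design. Frame intervals in the real experiments varied
by condition (tens of seconds for FF, minutes for cycloFF), so
`frame_interval_min` is a free design field rather than a constant.

What the generator does *not* emulate: spatially varying flow and mass
transfer to the two ends (neglected in the kinetic analysis as well),
radial growth (the nanotube width is treated as constant), image artefacts,
and operator selection of which tubes to measure. Passing tests therefore
certify the estimation machinery under the stated noise model, not
robustness to those real-world effects.

## Estimation and classification

`estimate_terminus_rate()` fits position against time by OLS over the whole
trace — the minimum-variance linear estimator for a constant-rate segment,
and the reason the package reports one rate per terminus per condition
rather than frame-to-frame differences. Orientation is the outward-positive
convention: terminus A sits at the lower coordinate (orientation −1),
terminus B at the higher (+1), so growth is positive at either end and the
two rates are directly comparable. Traces with a capped or stalled tail
can be truncated by the caller before fitting; automatic changepoint
detection is deliberately out of scope.

Because length is $x_B - x_A$, the *sum* of the two outward terminus rates
is the tube's net elongation rate $dL/dt$ — the quantity the growth law
describes. `tube_rates()` forms that sum, `condition_rates()` averages it
over the tubes of each concentration (unweighted, with the SE over tubes),
and `fit_growth_law()` fits $R$ on $c$, by default weighting each condition
point by its inverse squared SE. Averaging raw per-terminus rates instead
would halve $k_{\mathrm{on}}$ for a unidirectional filament, so the
summed-per-tube reading is the one under which both presets return their
generating parameters; the unweighted fit remains available
(`run_recovery(..., weighted = FALSE)`).

`critical_concentration()` of a fit is $\hat k_{\mathrm{off}}/\hat
k_{\mathrm{on}}$, with a first-order (delta-method) interval from the fit's
parameter covariance, using the fit's residual $t$ distribution since the
covariance rests on few degrees of freedom. The interval is symmetric and
approximate; when $\hat k_{\mathrm{on}}$ is within 2 SE of zero it is
flagged as unreliable.

`classify_directionality()` formalises "grows at one end only": a terminus
is *active* when $|\hat r| > z_{1-\alpha/2}\,\mathrm{se}(\hat r)$ (an SE of
zero is treated as exact), and a tube is unidirectional, bidirectional or
stalled according to whether one, two or zero termini are active, with the
two-sample $z$ for rate equality reported alongside. The activity test is
the simplest formalisation of "distinguishable from zero within
experimental error" — it is a package decision, not something the
experiments prescribe. The single-comparison default is $\alpha = 0.05$;
`run_recovery()` instead uses $\alpha = 0.01$ per end, because an
experiment tests two termini on each of ~50 tubes and a 5% false-activity
rate would flag about five truly silent termini per experiment, which
would misrepresent a categorically unidirectional dataset. Non-finite
inputs yield `indeterminate` with a warning rather than an error.

## Concentration programming

The microfluidic part of the workflow is bookkeeping, but bookkeeping that
is easy to get wrong, so it is explicit. `to_millimolar()` /
`to_mass_concentration()` convert through the compound's molar mass
(built-ins: FF 312.4 g/mol, cycloFF 294.3 g/mol) and are exact inverses;
rounding (half away from zero, two decimals for concentrations) happens
only at reporting boundaries via `round_half_up()`. `mixed_concentration()`
is the flow-weighted mean over inlet streams — justified by the complete
diffusive mixing the devices achieve in the mixing channel — and refuses
to mix mg/ml with mM silently, because both units are in routine use for
the same solutions. `flow_rates_for_target()` solves the inverse problem
of holding a filament at a target (e.g. critical) concentration:

```{r mixing}
mixing_spec(conc = c(0.5, 4.0), flow_ul_h = c(1.9, 2.1), unit = "mg/ml") |>
  mixed_concentration() |>
  mutate(conc_reported = round_half_up(conc, 2))

flow_rates_for_target(1.60, 3.20, c_target = 2.43, q_total = 3.9)
```

## The recovery experiment

`run_recovery()` chains the whole pipeline — generate, estimate, average,
fit, classify — deterministically under one master seed (per-tube sub-seeds
come from a fixed Lehmer-style mixing of the master seed and the condition
and tube indices, so the dataset does not depend on iteration order):

```{r recovery}
design <- experiment_design(seed = 1)
design
report <- run_recovery(design)
tidy(report)
report$tally
autoplot(report)
```

The default design mirrors the study shape: 5 concentrations spanning
subcritical to supercritical around $c_s$, 10 tubes per concentration,
10 min of observation at 2 frames/min, default measurement noise. The
concentration grid avoids sitting exactly on $c_s$, where a tube is
genuinely stalled and directionality is undefined. For cycloFF-style
designs the slower kinetics call for longer horizons (the test suite uses
60 min at 4 min/frame, concentrations bracketing $c_s = 8$ mM).

Validation problem sizes, chosen to give clear statistical verdicts at
desk scale: ensemble-law checks use 100 seeds per concentration (3-SEM
bands); closed-pool equilibration uses $\gamma = 5\times10^{-4}$ mM over
60–90 min horizons so the relaxation time ($\tau = \delta L/(\gamma
k_{\mathrm{on}})\approx 6$ min) fits comfortably; CI calibration uses 200
full pipeline replicates, in which the generating $(k_{\mathrm{on}},
k_{\mathrm{off}})$ fall inside their joint 95% intervals in well over 90%
of runs.

## Known limitations

* One-dimensional, two-ended filaments only: no radial growth, no
  branching, no filament–filament interaction.
* No nucleation and no automatic detection of capping changepoints; capped
  behaviour is simulated (Poisson capping) but detection is left to the
  analyst.
* The closed pool is a conceptual coarse-graining — one filament against a
  well-mixed reservoir with a fixed depletion quantum — not a model of a
  quiescent droplet with many competing nuclei.
* Delta-method intervals for $c_s$ are first-order; with very few
  concentration points or a weakly identified slope they should be read as
  indicative.
* The flow-weighted mixing mean presumes complete mixing; no
  Péclet/diffusion calculation is attempted.
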