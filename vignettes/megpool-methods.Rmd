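---
title: "Methods: multi-subject MEG source estimation in megpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-subject MEG source estimation in megpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megpool)
```

This vignette documents the statistical model behind `megpool`, the
assumptions it makes, every parameter with its unit, and the numerical
design choices, so that results can be interpreted and reproduced
without reading the source.

# The problem

$S$ subjects view the same visual stimulus while MEG is recorded. For
each subject $s$ we observe sensor data $Y^s \in \mathbb{R}^{n}$
(one measurement per sensor at a chosen latency) generated by

$$Y^s = L^s X^s + E^s,$$

where $L^s \in \mathbb{R}^{n \times p}$ is the subject's leadfield on a
*common template source space* of $p$ candidate source locations,
$X^s$ is the unknown source amplitude vector (A·m), and $E^s$ is noise.
The scientific question is how estimates of the *group-typical* source
configuration improve as more subjects are pooled, given that each
subject's true sources sit at slightly different template locations
(inter-subject variability of early visual areas is on the order of
1 cm even after surface-based morphing).

# Source space, sensors and forward model

**Template source space** (`build_template_space`): two disjoint
icosahedral spheres ("hemispheres") of radius 35 mm whose centres are
72 mm apart, each subdivided `subdivisions` times (default 2, giving
162 vertices per hemisphere, $p = 324$; `build_icosphere(4)` gives the
familiar 2562-vertex ico4 hemisphere). Distances between sources are
*geodesic* distances along mesh edges (`geodesic_distances`, Dijkstra
via `igraph`); the minimum edge length at the default resolution is
9.66 mm, which sets the attainable localization precision.

**Sensors** (`make_sensor_array`): 64 radial magnetometers on a helmet
sphere of radius 120 mm covering the top and sides of the head
(`sensor_z_min = -60` mm).

**Leadfields** (`build_leadfield`): the analytic Sarvas formula for a
current dipole in a spherical conductor, with tangential dipole
orientations (radial dipoles are magnetically silent in a sphere).
Units: fields in T per A·m of dipole moment.

**Inter-subject variability** (`jitter_subject`): each subject's
leadfield is recomputed after (i) jittering every source position by
independent Gaussian offsets with `position_jitter_mm = 3` mm per axis
(anatomy/coregistration error) and (ii) scaling each sensor's gain by
$1 + \mathcal{N}(0, 0.1^2)$ (`gain_jitter_fraction`). In addition each
subject's true *target* vertices are scattered on the template by
`target_jitter_mm = 10` mm geodesically (functional variability).

# Synthetic multifocal retinotopy

`make_stimulus_layout()` defines 24 stimulus regions: 3 eccentricity
rings × 8 polar wedges. Wedges touching the vertical meridian are
flagged `bilateral` and activate one target per hemisphere; the rest
activate the hemisphere contralateral to their hemifield.
`place_targets()` positions targets by geodesic distance from a
per-hemisphere pole anchor: rings at 10, 20, 30 mm
(`ecc_geodesic_mm`), mirroring between hemispheres.

Evoked responses (`simulate_evoked`) are Gaussian pulses in time with
peak latency 83 ms (per-subject SD 5 ms, per-region SD 5 ms), temporal
width `sigma_ms = 10` ms, base amplitude `1e-8` A·m scaled by ring
(1, 0.8, 0.6) and a 30 % relative per-subject amplitude jitter; an
optional spatial `spread` (default 0.3) leaks amplitude to neighbouring
vertices. Sensor noise is white Gaussian scaled so the *whitened RMS
amplitude SNR* at the peak equals `snr_target = 2`; the averaging basis
is 258 stimulus flashes per run × 7 runs = 1806 presentations per
region, recorded in the experiment metadata. All randomness descends
from one `master_seed` via per-subject derived seeds, so any subject
can be regenerated independently.

# Method 1: eLORETA + source-space averaging

`elora_weights` computes the eLORETA diagonal weight matrix by the
fixed-point iteration

$$d_i \leftarrow \sqrt{l_i^\top \left(L D^{-1} L^\top +
  \lambda^2 \Sigma\right)^{+} l_i},$$

normalized by its first element each sweep, and
`elora_inverse_operator` forms
$W = D^{-1} L^\top (L D^{-1} L^\top + \lambda^2 \Sigma)^{+}$. This
weighting provably yields *exact* (zero-error) localization of
noiseless point sources, which the test suite verifies for all 324
columns of a leadfield and end to end on simulated subjects.

Regularization is tied to the measured SNR:
`regularization_from_snr(snr)` returns $\lambda^2 = 1/\mathrm{SNR}^2$
(0.25 at the default SNR of 2), with `estimate_snr` computing the
whitened-RMS amplitude SNR from pre-stimulus samples.

A scale note: the weights $d$ are *invariant* under a global leadfield
rescaling $L \to cL$ (substituting into the fixed point forces the
proportionality constant to 1), while the operator scales as $1/c$ so
that $\hat X$ correctly scales as $1/c$. This is checked explicitly in
the tests.

Pooling is plain averaging of the per-subject source-magnitude
estimates on the template (`average_estimates`), the strategy usually
available in standard MEG toolchains.

# Method 2: minimum Wasserstein estimates

All subjects are solved jointly:

$$\min_{X^1..X^S,\,\bar X}\;
  \frac{1}{2n}\sum_s \lVert Y^s - L^s X^s \rVert_2^2
  + \lambda \sum_s \lVert X^s \rVert_{1/2}^{1/2}
  + \frac{\mu}{S} \sum_s \widetilde W(X^s, \bar X),$$

where $\lVert x \rVert_{1/2}^{1/2} = \sum_i \sqrt{|x_i|}$ promotes
hard sparsity without the amplitude shrinkage of the ℓ₁ norm, and
$\widetilde W$ is an *unbalanced entropic optimal-transport* divergence
that lets each subject's sources sit near — not exactly at — the group
barycenter $\bar X$.

**Transport details** (`transport_ground_metric`,
`unbalanced_wasserstein`, `wasserstein_barycenter`):

* Ground cost: squared geodesic distance, normalized to $[0,1]$ per
  hemisphere (the normalization scale in mm² is recorded as
  `metric$scale_mm2`).
* Hemisphere blocking: mass never moves between hemispheres (they are
  anatomically disconnected); transport is computed per hemisphere
  block.
* Signed amplitudes: positive and negative parts are transported
  separately and may not cancel across signs; opposite-sign mass can
  only be created/destroyed at the marginal-relaxation price $\gamma$.
* Entropic regularization $\varepsilon = 5/(3p)$; marginal relaxation
  $\gamma = 1$; solved by Sinkhorn-like scaling iterations implemented
  in C++ (`src/uot.cpp`). In the limit $\varepsilon \to 0$,
  $\gamma \to \infty$ the cost matches an exact transport linear
  program (verified in the tests against `scipy.optimize.linprog`
  within 1 %).

**Optimization** (`solve_mwe`): block coordinate descent alternating
(i) per-subject proximal coordinate sweeps using the closed-form ℓ½
half-thresholding prox (`prox_lq_half`, validated against dense 1-D
numerical minimization), and (ii) barycenter updates. The objective
trace is monitored and guaranteed non-increasing: any candidate update
that would raise the objective is rejected.

Because the ℓ½ + transport objective is nonconvex with *spatially
clustered* local minima (a "ghost" source one mesh edge from the true
vertex can trap a pure descent method), the solver adds deterministic
escape proposals: dominant-vertex drop-and-refit restarts at several
mask radii (including a single-vertex swap move, needed when the ghost
is adjacent to the truth), hemisphere-local refits, and composed
two-hemisphere moves that pass through an intermediate state. Every
proposal is polished by unrestricted descent sweeps and accepted only
if it strictly lowers the objective, preserving monotonicity. A
penalty-only lower bound (the transport term is nonnegative) prunes
proposals cheaply before the transport cost is evaluated.

**Scaling convention**: the ℓ½ penalty is *not* invariant under
rescaling of the problem, so the solver internally rescales each
leadfield by its median column norm and the data by its maximum
absolute amplitude; the λ fraction is defined on this rescaled problem,
and `sol$amp_unit` maps internal amplitudes back to A·m. λ = 1
corresponds to the analytic
$\lambda_{\max} = \max_s \lVert {L^s}^\top Y^s \rVert_\infty / n$
(`compute_lambda_max`) above which the all-zero solution is stationary;
the tests verify both the hand-computed value and the null solution at
λ = 1.

**Single subject**: with $S = 1$ the barycenter term degenerates (an
entropic self-coupling cost would bias the solution), so the solver
sets $\mu = 0$ internally and reports the barycenter from the single
estimate afterwards.

# Hyperparameter calibration

Hyperparameters are set by modified binary searches against the known
expected source count (3 active vertices for unilateral regions, 6 for
bilateral, given a point target plus symmetric spread):

* `find_lambda` bisects the λ fraction on $[0,1]$ with
  $\mu = 0$, accepting when the active count is within 1 of the target
  and checking that the count decreases (weakly) in λ; a non-monotone
  response aborts with the probe trace attached.
* `find_mu_max` finds the coupling at which the solution stops being
  sparse: geometric bracket expansion followed by bisection on
  $\log \mu$; the working value is $\mu = \mu_{\max}/2$.
* `calibrate_mwe` runs both searches (on at most 3 subjects in the
  pipeline, with loosened solver tolerances) and re-checks λ at the
  chosen μ, re-searching once if the active count drifted by more
  than 1.

"Active" means amplitude above `rel_threshold = 1e-6` of the maximum
(`count_active`). Both searches are validated on stub solvers with
planted transitions.

# Group analysis and evaluation

* Groups are *nested prefixes* of a fixed random subject ordering
  (`subject_ordering`, `build_groups`): the 5-subject group contains
  the 1-subject group, as in a sequential recruitment design.
* The single-subject condition uses the *representative* subject
  (`select_representative`): the subject whose median localization
  error is closest to the group median, lower index breaking ties.
* Peak latency (`find_peak_time`): the global-field-power peak within
  60–100 ms, flagged if it lies on the search boundary; the group uses
  the median across non-flagged subjects.
* Localization error (`peak_target_distance`): geodesic distance from
  the estimated peak vertex to the true target, per hemisphere for
  bilateral regions. A peak in the wrong hemisphere has no defined
  geodesic distance and is recorded as an outlier.
* Summaries (`winsorized_stats`): distances above 80 mm and outliers
  are Winsorized before medians/means, following standard practice for
  heavy-tailed localization errors.

`run_pipeline` ties everything together and `write_evaluation` writes
`rows.csv`, `summary.csv` and a JSON manifest (including the calibrated
hyperparameters); plain-text outputs keep results diffable and
dependency-free.

# Design decisions and open questions

* **Hemisphere-blocked transport.** Allowing cross-hemisphere mass
  transfer would let the barycenter "explain" a bilateral pair with one
  midline blob; blocking matches anatomy and keeps bilateral regions
  honest.
* **One latency, not a window.** The inverse problems are solved at a
  single latency (the evoked peak). Extending MWE to a time window
  would multiply the transport cost per iteration by the number of
  samples without changing the localization question studied here.
* **eLORETA scale law.** Under $L \to cL$ the weights are invariant
  and the operator scales as $1/c$; a published description stating
  that the weights themselves scale does not satisfy the fixed-point
  equation, so the package implements (and tests) the invariant form.
* **λ as a fraction of λ_max on the rescaled problem.** Since the ℓ½
  penalty is not scale-invariant, a λ fraction is meaningful only once
  the problem's units are fixed; the internal rescaling makes the
  fraction comparable across subjects and experiments.
* **Deterministic escape proposals instead of random restarts.** The
  local minima observed in practice are spatially structured (ghost
  vertices adjacent to the truth, paired cross-hemisphere traps);
  targeted drop/refit and composed moves find the global basin in a
  handful of proposals and keep the solver fully reproducible.
* **Text outputs.** CSV + JSON replace binary scientific containers so
  the package has no system-level storage dependency and results
  remain inspectable with standard tools.

# Reproducing the headline results

```{r, eval = FALSE}
# Noiseless closure: every method localizes exactly (0 mm).
cfg0 <- list(noise = FALSE, position_jitter_mm = 0,
             gain_jitter_fraction = 0, target_jitter_mm = 0,
             amplitude_jitter = 0, peak_time_subject_sd = 0,
             peak_time_region_sd = 0)
tab0 <- run_pipeline(n_subjects = 3, master_seed = 1,
                     group_sizes = c(1, 3), regions = c(1, 2),
                     config = cfg0)
max(tab0$rows$distance_mm)  # 0

# Pooling benefit: 10 subjects vs 1, 20 seeds.
tpl <- build_experiment_template()
sapply(1:20, function(seed) {
  s <- run_pipeline(n_subjects = 10, master_seed = seed,
                    group_sizes = c(1, 10), methods = "elora_avg",
                    template = tpl)$summary
  s$median_mm[s$group_size == 10] < s$median_mm[s$group_size == 1]
})
```
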