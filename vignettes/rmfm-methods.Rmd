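---
title: "Whole-brain relaxed mean-field modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain relaxed mean-field modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmfm)
```

## The model

`rmfm` implements a whole-brain *relaxed mean-field model* (rMFM): each of
the N regions of a parcellated brain carries an average synaptic gating
variable $S_i \in [0, 1]$, the fraction of open synaptic channels, driven by

$$\dot S_i = -\frac{S_i}{\tau_s} + r\,(1 - S_i)\,H(x_i) + \sigma v_i(t),$$

where $v_i(t)$ is uncorrelated standard Gaussian noise and the population
firing rate is the familiar sigmoidal-linear transfer

$$H(x) = \frac{a x - b}{1 - e^{-d (a x - b)}},$$

continuous at $a x = b$ with value $1/d$. The total input current combines
recurrent self-excitation, structurally routed long-range input, and a
constant subcortical drive:

$$x_i = w_i J S_i + G J \sum_j C_{ij} S_j + I_i.$$

$C$ is the structural connectome (symmetric, nonnegative, zero diagonal).
The *relaxation* of the model is that the recurrent strength $w_i$ and the
subcortical input $I_i$ are per-region parameters, while the coupling scale
$G$ and the noise amplitude $\sigma$ stay global. The kinetic constants are
fixed at the standard values $r = 0.641$, $\tau_s = 0.1$ s, $a = 270$ /nA,
$b = 108$ Hz, $d = 0.154$ s, $J = 0.2609$ nA
(see `synaptic_constants()`).

Gating activity drives the Balloon–Windkessel hemodynamic cascade —
vasodilatory signal $z_i$, inflow $f_i$, venous volume $v_i$,
deoxyhemoglobin content $q_i$ — and the BOLD observation equation
$\mathrm{BOLD}_i = V_0 [k_1 (1 - q_i) + k_2 (1 - q_i / v_i) +
k_3 (1 - v_i)]$ with $k_1 = 4.3\,\vartheta_0 \rho \mathrm{TE}$,
$k_2 = \varepsilon r_0 \rho \mathrm{TE}$, $k_3 = 1 - \varepsilon$ and
$\vartheta_0 = 28.265\,B_0$ (always derived, never stored). All
hemodynamic constants are fixed (`hemodynamic_constants()`); the resting
state $(z, f, v, q) = (0, 1, 1, 1)$ is an exact fixed point and the BOLD
signal is exactly zero there.

Functional connectivity (FC) is the Pearson correlation matrix of the
regional BOLD series, and the objective of every fit is the *FC
similarity*: the Pearson correlation between the strictly-upper-triangle
entries of the simulated and the empirical FC. The diagonal is excluded —
it is identically one and would only inflate the score. No Fisher
transformation is applied anywhere.

## Numerical choices

* **Integration.** Euler–Maruyama for the gating stochastic differential
  equation and explicit Euler for the hemodynamics, both at `dt = 10 ms`
  by default; a finer hemodynamic substep is exposed (`substeps`). The
  convergence tests verify first-order behaviour by step halving.
* **Gating clamp.** Under noise the Euler step can leave $[0, 1]$; the
  gating is clamped back and a counter records how often. With
  $\sigma = 0$ and interior starts the clamp never activates.
* **Initial condition and burn-in.** $S(0) = 0.1$ uniformly. The
  hemodynamics are driven by the *full* gating trajectory and the burn-in
  is discarded from the BOLD output, so the neural and the (much slower)
  hemodynamic transients are dropped together; discarding the gating
  trajectory first would leave a large shared hemodynamic onset in every
  region and push all correlations toward one.
* **Noise convention.** One global $\sigma$ scales
  $\sqrt{dt}\,\mathcal N(0,1)$ per region, uncorrelated across regions and
  steps. The compiled integration loop draws its normals from R's RNG in
  the same order as the pure-R reference loop, so both produce
  bit-identical trajectories from the same seed (this is tested).
* **Units.** The transfer gain is read as 270 per nA of input current so
  that $a x$ is in Hz, dimensionally consistent with $b = 108$ Hz.

## Fitting

`fit_subject()` estimates $\theta = (w_1..w_N, I_1..I_N, G, \sigma)$ by a
damped Gauss–Newton iteration on the upper-triangle FC residual:

1. The whole fit runs under **common random numbers**: one noise seed is
   fixed and reused by every forward simulation, making the objective a
   deterministic function of $\theta$. Without this, finite-difference
   derivatives are swamped by realization noise and the optimizer chases
   noise patterns — in the worst case inflating $\sigma$ to amplify the
   very noise realization it is matching.
2. A forward-difference Jacobian of the simulated FC vector with respect
   to $\theta$ (absolute step `fd_step`) feeds damped normal equations
   with Levenberg scaling; steps are halved on non-improvement and the
   damping relaxes or grows with acceptance. A long rejection streak
   resets the damping.
3. A Gaussian **prior centred on the initialization**
   (`prior_weight`, scalar or per-parameter) augments the least-squares
   objective. The FC objective is nearly flat along directions that trade
   a region's recurrent strength against its subcortical input (both act
   through the region's total drive), and the prior resolves that
   degeneracy toward the smallest parameter deviation — the same role the
   shrinkage priors play in the expectation–maximization schemes used for
   this model family. The update algebra here is deliberately our own,
   fully specified design; fidelity is to the objective and the
   best-of-trace selection rule, not to any particular published
   implementation.
4. Per-iteration similarities are recorded and the returned parameters
   are always the **best-of-trace** iterate (earliest on exact ties),
   never a later, worse one. The default budget is 500 iterations;
   every test and example in this package uses much smaller budgets.
5. Between full Jacobian rebuilds (`jacobian_every`) the Jacobian is
   carried forward with rank-one Broyden updates. Because the objective
   is deterministic under common random numbers, subjects fitted from the
   same initialization on a shared connectome have *identical* first
   evaluations and Jacobians; `precompute_jacobian()` computes them once
   per cohort and `fit_cohort()`/`run_fit()` reuse them. With one shared
   fitting seed across a cohort, the realization-specific component of
   the fitting error is common mode and cancels in group contrasts.

Parameters are clipped to $[10^{-4}, 10]$ throughout, which keeps the
forward model in its valid regime.

## Initial-parameter sensitivity

`init_grid()` reproduces the initialization-sensitivity design: both
per-region parameter families start uniform at $(w_0, I_0)$, every
combination on a grid over $[0.1, 0.9]$ in steps of 0.1 (81 cells) is
fitted, and the best similarity per cell is recorded, optionally averaged
over seeded replicates — repeated runs smooth the jitter that the noise
parameter induces in any single surface. `refine_grid()` re-grids the
bounding box of the best cells at finer spacing (the refined step is not
pinned by any reference value; 0.05 is the default). In the
weakly-coupled regime the network is silent for small subcortical input
and saturates for large input, so mid-range $I_0$ initializations
(roughly 0.3–0.5) achieve visibly better similarity than extreme ones —
the package asserts this as an ordering, not as specific surface values.

## Cohort statistics

`compare_groups()` runs a per-region two-sample t-test between the young
(age < 20) and old (age > 60) groups; boundary ages fall into the middle
group, which is used only for trend fitting. Welch's unequal-variance
test is the default (group spreads genuinely differ; a pooled-variance
option exists), and Benjamini–Hochberg FDR correction is applied across
regions, by default separately within the $w$ and $I$ families since the
two parameters are reported as separate analyses (a single-family mode is
exposed). A region is flagged when its corrected p falls below 0.05.

`fit_trends()` fits first- and second-order polynomials of a parameter on
age by ordinary least squares and `classify_trend()` labels the
trajectory: *inverted-U* requires negative curvature, a vertex inside the
10th–90th percentile band of observed ages, and a partial F-test (at
0.05) showing the quadratic genuinely improves on the line; otherwise a
significant slope gives *linear-decline*/*linear-incline*, and *flat*
remains. The percentile band, the slope threshold, and the F-test level
are package choices — the shapes themselves are only ever described
verbally in the aging literature this mirrors.

## The synthetic cohort generator

Because the cohort data this analysis was designed for are not
redistributable, the package ships a generator that emulates their
statistical structure with known ground truth:

* **Connectome.** `generate_sc()` builds a modular weighted graph:
  within-module edges 1.5× as probable as the target density,
  between-module 0.5×, log-normal weights (meanlog −0.5, sdlog 0.45 — a
  deliberately light tail so that the overall coupling strength, after
  normalizing the maximum entry to one, is comparable across seeds rather
  than hostage to a single extreme weight), maximum entry normalized to 1.
* **Ground-truth trajectories.** `trend_spec()` /
  `default_trend_spec()` give every region and parameter an age
  trajectory: linear decline, inverted-U (peak at 45 y by default), or
  flat. Age-affected regions sit at 0.6 in mid-life and decline at
  0.0075/yr, losing ≈ 0.45 of recurrent strength between 10 and 70 years
  — the separation scale of the most strongly aging frontal-pole regions
  in lifespan cohorts, whose young/old group means differ by ≈ 0.4–0.55.
  Between-subject spreads are 0.05 for $w$ and 0.03 for $I$; the narrower
  $I$ spread mirrors the reported pattern of strong $w$ contrasts and
  null $I$ contrasts. $G = 0.5$ and $\sigma = 0.01$ are fixed globals.
* **Two independent noise layers.** Subject-level parameter noise and
  FC measurement noise (upper-triangle jitter, re-symmetrized, clipped,
  unit diagonal restored; default sd 0.02) are separately configurable,
  so failures can be attributed to the fitting stage or the statistics
  stage.
* **Ages.** Uniform over 4–85 years by default (a lifespan sample's
  range); `age_sampler_bimodal()` provides the young/old two-band design
  used in group-comparison experiments.

`write_dataset()` materializes a cohort in exactly the delimited-text
layout the file pipeline reads back, so the pipeline cannot distinguish
synthetic from real input.

### The dynamic regime, and what it implies

The default study conditions put the baseline network in the *low-activity*
state near the firing threshold ($x \approx 0.33$ nA against the threshold
0.4): this is where FC is sensitive to the regional parameters. Two
consequences, established empirically during design and verified by the
test suite:

* **Coupling scale matters.** In this regime the drive $I_i$ has far more
  leverage on FC than $w_i$ (the recurrent term is scaled by the small
  gating level), and the sensitivity of FC to *any* parameter collapses
  if the connectome's total coupling is weak. This motivated the
  light-tailed weight distribution above.
* **Per-region $w$/$I$ separation is weak from a single scan.** The two
  parameters act on FC almost collinearly (through the region's total
  drive), so individual-level recovery of $w$ against heterogeneous $I$
  is structurally limited. The parameter-recovery validation therefore
  runs in the strongly-coupled regime ($G = 1.3$), where the gating level
  is high and the recurrent term carries weight comparable to the drive,
  with broad $w$ heterogeneity (sd 0.15) against narrow $I$ heterogeneity
  (sd 0.015) — the identifiable version of the question, matching the
  empirical pattern that $w$ varies much more than $I$. Recovery is
  assessed under matched noise realizations ("noiseless" in the sense
  that the target FC is produced by the same generative simulator the
  optimizer evaluates, with no extra measurement noise), so the optimum
  is exact and the experiment isolates the estimator.

## Problem sizes used by the tests

The validation suite runs desk-scale versions of the full design, as a
matter of the package's own test design: connectomes of 4–20 regions,
cohorts of 40 subjects, simulated scans of 4 minutes (10 ms step, BOLD
sampled every 0.5 s), fitting budgets of 1–30 iterations, 10 cohort
replications for the planted-signal experiment, and 50 seeds for the
trend-classification rates. The full-scale analysis (188 regions, 196
subjects, 500 iterations) is reachable through the same functions and the
configuration object; nothing in the code is specialized to the reduced
sizes.

## What passing tests do and do not show

The synthetic cohorts share one connectome, have Gaussian parameter and
measurement noise, stationary dynamics, and no head motion,
physiological confounds, parcellation error, or site effects. Passing the
end-to-end recovery experiments shows the estimation and statistics
machinery is sound — planted effects of the magnitude reported for
strongly aging regions are recovered, null cohorts stay clean, trend
shapes classify correctly. It does not show that fitted parameters from
real scans have the same effect sizes or error structure; in particular,
per-subject fits against a single empirical FC realization carry
substantial noise (visible here as fitted spreads larger than the planted
subject spreads), which is consistent with the modest corrected p-values
such analyses report on real cohorts.

## Known limitations

* The w/I collinearity above: single-scan estimates of $w_i$ should be
  interpreted at the group level, not subject by subject.
* The optimizer is a local scheme; the initialization grid exists
  precisely because the objective surface depends on the starting point.
* Scan length and TR of the reference dataset are not public in the
  source material; the defaults (240 s simulated, TR 2 s at the user
  level, 0.5 s in the reduced tests) are declared assumptions, exposed in
  `sim_config()`.
* The file pipeline's YAML configuration replaces a TOML design sketch;
  YAML is what the installed toolchain parses natively, and the contract
  (defaults equal to reference settings, effective-config snapshots next
  to outputs) is unchanged.
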