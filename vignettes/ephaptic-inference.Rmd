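---
title: "Methods: detecting ephaptic coupling in engram-bearing recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting ephaptic coupling in engram-bearing recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(engramfield)
```

This vignette documents the modelling and inference choices behind
`engramfield`: the generative field model, the bidomain forward solution,
the evidence-based model comparison, the directed-interaction and
representational analyses, and the mode-reduced stability theory. It is
written for a reader who wants to know *why* each stage is built the way it
is, including the places where a naive construction fails.

## 1. The neural field model and its ephaptic variant

Delay-period activity on a one-dimensional cortical patch is modelled as a
stochastic neural field: the membrane potential profile $V(x, t)$ obeys

$$\dot V = -V/\tau + K * f(V) + U,$$

with leak time constant $\tau$, connectivity kernel $K$, logistic transfer
function $f$, and input $U$ (cue-locked drive plus white noise). The
*ephaptic* variant replaces $f(V)$ with $f(V + V_{0e})$, where $V_{0e}$ is
the extracellular potential evaluated at the sheet: the field the population
generates feeds back into its own excitability. `step_field()` is the
literal Euler–Maruyama update; `simulate_recording()` integrates trials of a
cue-conditioned task and refuses linearly unstable parameterizations, naming
the offending eigenvalue of $-I/\tau + f'(0)K$.

## 2. The bidomain forward model

The extracellular potential above the active sheet is computed as an exact
spectral filter: each spatial frequency $k$ of the membrane potential is
scaled by a transfer kernel built from modified Bessel functions of the
sheet geometry (fiber radius $a$, recording height $y$, intra- and
extracellular conductivities). Two numerical points matter:

- the kernel is evaluated with **exponentially scaled** Bessel functions, so
  it remains finite at wavenumbers where the unscaled products overflow;
- the $k = 0$ component is removed — a spatially constant membrane profile
  produces no extracellular field, which makes the operator well defined on
  the circle.

`bidomain_operator()` materializes the filter as a channel-space matrix;
`field_estimate()` applies it to a recording over a grid of depths. For
distant (far-field) observation points, `multipole_coefficient()` evaluates
the multipole series of the potential; at unit geometry its value is the
exact rational number $223/240$, which the tests pin down.

## 3. From field dynamics to a Gaussian linear model

Subtracting the across-trial condition mean and projecting the dynamics onto
**spatial-derivative principal axes** $H_j = D^j \bar V$ (successive
derivative-matrix applications to the mean profile) turns the linearized
field equation into a Gaussian linear model for the temporal derivative of
each trial's deviation: the regression weights $w_j$ are *global kernel
moments* — one coefficient per derivative order, shared across all channels.
The ephaptic model adds the corresponding axes of the boundary field, so the
two hypotheses differ only in their regressor sets and can be compared on
identical data.

Sharing $w$ across channels is not a convenience but part of the model: a
translation-invariant kernel has one moment expansion, not one per
electrode. Fitting per-channel weights would multiply the complexity penalty
by the channel count and bias the comparison toward the smaller model.

## 4. Model evidence and ReML

Model comparison uses the log evidence of the Gaussian linear model with a
unit-variance Gaussian prior on the weights,

$$F = -\tfrac12\left[\|Y - Hw\|^2/s^2 + w^\top w
      + (n - p)\log s^2 + \log\lvert\Pi\rvert\right],
\qquad \Pi = s^2 I + H^\top H,$$

which at the posterior mean $w = \Pi^{-1} H^\top Y$ equals
$\log \mathcal N(Y;\, 0,\, s^2 I + H H^\top)$ exactly. The determinant term
enters with a *positive* sign inside the bracket, i.e. it **penalizes**
model complexity; an evidence whose Occam term rewards extra regressors
inverts every comparison on null data, and the test suite guards this
direction explicitly (adding a useless regressor must lower $F$).

`reml_fit()` maximizes $F$ by coordinate ascent: the $w$-step is the exact
posterior-mean ridge solve $(s^2 I + H^\top H)^{-1} H^\top Y$, and the
$s^2$-step is a one-dimensional optimization over $\log s^2$. Both steps
maximize $F$ in their coordinate, so the trace of $F$ is provably
non-decreasing — a property the tests check on a hundred random problems.

`compare_models()` fits both models on a training half of the trials per cue
condition and evaluates held-out evidence on the remaining trials; the
reported statistic is the log Bayes factor
$\mathrm{BF} = F_{\text{non-ephaptic}} - F_{\text{ephaptic}}$, so positive
values favour the non-ephaptic model and $|\mathrm{BF}| > 3$ is treated as
decisive (`bf_winner()`).

## 5. Validation regime for model recovery

Recovery studies (and the defaults of the acceptance runs) use the
*diffusive local kernel* `local_kernel()`, $K = a_0 I + a_2 D^2$, rather
than a broad Gaussian kernel, and a moderate ephaptic coupling (0.3). Both
choices are about validity, not convenience:

- A broad Gaussian kernel is **not** in the span of the order-4 derivative
  regressors. Its truncation residual is spatially smooth, and the smoother
  ephaptic regressor absorbs it, producing a systematic bias toward the
  ephaptic model even on non-ephaptic data. The local kernel lies exactly in
  the regressor span, so the comparison measures the ephaptic effect and not
  the truncation error.
- At unit coupling the materialized bidomain operator (norm $\approx 4.8$)
  destabilizes the linearized field; simulations either saturate or are
  refused. Coupling 0.3 keeps the generator in the small-effect regime the
  inference is designed for.

With this regime the confusion study recovers the generating model in 50/50
datasets per cell with margins of tens of nats.

## 6. Snapshot ("spatial") Granger causality

Field–activity interactions are effectively instantaneous in time, so
directed analyses regress over *space* within single time-point snapshots:
the target profile on its own $p$ spatial lags (restricted) versus adding
the source profile's lags (full), with strength
$\ln(\mathrm{RSS}_r/\mathrm{RSS}_f)$ and an exact nested-model F-test on
$(p,\, n_{\text{obs}} - 2p - 1)$ degrees of freedom. Under the null the
p-values are uniform (KS-checked) with nominal type-I error; under genuine
coupling the strength is larger in the coupled direction in $\ge 95\%$ of
snapshots. The coefficient of variation of the strengths across snapshots
summarizes temporal stability of the directed interaction.

## 7. Representational similarity analysis

The pattern for one cue condition is the across-trial mean of the vectorized
upper triangle of the channels-by-channels correlation matrix of delay
activity; dissimilarity between conditions is one minus the Pearson
correlation of patterns. RDM correspondence between areas is tested by a
randomization test whose null relabels the conditions of one RDM (one joint
row-and-column permutation per relabeling), with
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n)$. With six conditions
the permutation space has $720$ elements, which bounds the attainable
resolution; the test warns below four conditions.

## 8. Mode reduction, slaving, and the two-area engram condition

Projecting field and activity onto circular Fourier modes yields a small
coupled ODE system: field modes relax at $1/\tau_{EP}$ driven by
$Z n^2 \psi_n$, activity modes at $1/\tau_{NA}$ driven through the
transformed kernel. When activity is much faster than the field, the
activity modes *slave* to the instantaneous boundary field; the quasi-steady
solution solves $(I - cK)\psi = cK\xi_0$ with $c = \delta\,\tau_{NA}$.
`adiabatic_tracking_error()` quantifies the approximation: the relative
tracking error falls monotonically with the timescale ratio and is below 5%
at a ratio of 100. Its defaults keep the feedback coefficient $Z$ and the
noise small so the *configured* timescale ratio is the realized one.

The two-area linearized system (`build_two_area_blocks()`) is an $8\times8$
block matrix $M = [A\, B; C\, D]$ with feedforward coupling entering only
the activity rows of area 2. `engram_condition()` verifies the Schur
determinant identity and its three-factor feedforward form, and evaluates
the implication they support: a solvable coupled system with field–activity
coupling in one area forces it in the other — shared field coupling is a
structural property of the pair, not of a single area.

## 9. The pipeline and its known confound

`run_pipeline()` executes simulation, field estimation, model comparison,
GC, RSA, and the stability condition from a single seeded configuration;
every stage's seed derives from `master_seed`, failures are recorded with
their messages, and dependent stages are skipped rather than crashed.

One honest caveat: with feedforward strength `w_ff` at its default (0.2),
area 2 receives drive from area 1 that neither candidate model represents.
The evidence comparison absorbs that unmodeled input into the simpler
non-ephaptic model, so area 2 is typically labelled non-ephaptic even when
simulated ephaptically (at `w_ff` 0.05 the label flips back). Within-area
conclusions should therefore come from area 1 or from disconnected runs,
and between-area claims from the GC and RSA stages, which remain directional
and calibrated under feedforward drive.

## Limitations

- The patch is one-dimensional with a circular spectral treatment; real
  laminar geometry is three-dimensional.
- The inference linearizes around the condition mean; strongly nonlinear
  regimes (near saturation) violate the Gaussian linear reformulation.
- The derivative expansion of the kernel is truncated (order 4 by default);
  kernels far outside its span reintroduce the bias of Section 5.
- Snapshot GC assumes an arbitrary but fixed spatial orientation; the
  `orientation = "both"` option averages out the choice.
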