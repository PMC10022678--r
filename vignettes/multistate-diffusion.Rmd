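---
title: "Multistate lateral diffusion: models, estimators and the mosaic field simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate lateral diffusion: models, estimators and the mosaic field simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptfield)
```

## The measurement model

`sptfield` analyses 2-D single-molecule trajectories sampled at a fixed
frame interval $\Delta t$ (default $1/30$ s; the camera in a typical
TIRFM setup runs at 30 frames/s, and pixel-to-µm conversion happens at
import). Three observables drive everything downstream:

* the per-step displacement magnitude $\Delta r$,
* the mean square displacement $\mathrm{MSD}(n\Delta t)$, averaged over
  all start times within each trajectory and over trajectories,
* the sequence of $\Delta r$ along each track, which carries the
  state-switching information.

For free 2-D diffusion with coefficient $D$ and i.i.d. Gaussian
localization error of per-coordinate s.d. $\varepsilon$,

$$\mathrm{MSD}(t) = 4 D t + 4 \varepsilon^2 ,$$

so the slope of an ordinary least-squares line through the MSD curve
(default lags 1–15) estimates $D$ and the intercept estimates
$\varepsilon$. Localization noise shifts the intercept, never the slope —
a property the test suite checks directly. Negative fitted intercepts
(possible on clean data by chance) are reported as $\varepsilon = 0$ with
a flag; negative slopes are clamped with a flag and a warning.

Within one mobility state the step length is Rayleigh,

$$f(\Delta r \mid D) = \frac{\Delta r}{2 D \Delta t}
  \exp\!\left(-\frac{\Delta r^2}{4 D \Delta t}\right),$$

and a molecule that switches between $N$ states produces a weighted
mixture of such densities. Localization error is deliberately **absent**
from this density and from the HMM emission below: the error is itself
state dependent (fast-moving molecules blur during the exposure), so it
cannot be identified at this stage; the mixture/HMM coefficients are
*apparent* coefficients, $D_{\text{app}} = D + \varepsilon^2/\Delta t$,
and the true $D$ and $\varepsilon$ per state are recovered afterwards
from per-state MSD fits on the segmented trajectories. Including the
error in the emission is known not to work in practice, and we follow
that two-stage contract.

## Choosing the number of states

Mixtures with $N = 1 \dots 4$ are fitted by maximum likelihood using EM
with closed-form M-steps
($D_n = \sum_j r_{jn}\Delta r_j^2 / (4\Delta t \sum_j r_{jn})$), 10
seeded random restarts, a relative log-likelihood tolerance of $10^{-8}$
and at most 2000 iterations. The state count minimizes
$\mathrm{AIC}_N = -2\log L + 2 k_N$ with $k_N = 2N - 1$ free parameters
($N$ coefficients, $N-1$ weights); ties break toward the smaller $N$.
`relative_likelihood()` exposes the usual
$\exp((\mathrm{AIC}_a - \mathrm{AIC}_b)/2)$ comparison. Zero step lengths
(possible in synthetic data) are floored at machine-epsilon scale to keep
the log-density finite.

## Segmenting trajectories

The HMM has Rayleigh emissions per state, a shared initial distribution
and a row-stochastic transition matrix. Fitting uses multi-sequence
Baum-Welch with scaled forward–backward recursions, relative tolerance
$10^{-6}$, at most 500 iterations and 5 seeded restarts keeping the best
log-likelihood. Initialization follows the field's practice: the
diffusion coefficients start at the k-means centres of the per-step
coefficients $\Delta r^2 / 4\Delta t$, while $p_0$ and $A$ start random.
Worth knowing: k-means on these right-skewed values tends to split the
fast component's exponential tail rather than isolate the slow state, so
the initial centres are only order-of-magnitude correct — which is all
EM needs, and is why restarts matter. States are labelled
fast/middle/slow by decreasing fitted $D$ after convergence; Viterbi ties
break deterministically toward the faster state.

The forward–backward implementation is validated against brute-force
enumeration of all state paths on short two-state instances (agreement to
$10^{-10}$), and the EM monotonicity of the log-likelihood is asserted on
every tracked run.

Per-state summaries come from three estimators:

* **$D_S$, $\varepsilon_S$** — contiguous same-state Viterbi segments are
  pooled per state and passed through the MSD fit. Caveat (measured, and
  worth stating): because Viterbi conditions on the observed step sizes,
  segments of the *short-lived* fast state are a biased sample — at a
  mean fast dwell of ~1.4 frames the fast-state $D_S$ can be off by tens
  of percent while middle and slow recover within a few percent. The
  slowly-switching states are where this estimator is trustworthy.
* **$p_S$** — posterior state probabilities averaged over all steps and
  tracks (a Viterbi-fraction variant is available via
  `occupancy(..., method = "viterbi")`).
* **$\tau$** — dwell durations of maximal same-state runs, fitted by
  unweighted least squares of $C e^{-\lambda t}$ to the survival
  histogram $N(\ge t)$ (bin width one frame, bins with $\ge 5$ counts),
  $\tau = 1/\lambda$. Runs truncated by track ends are included by
  default (no censoring correction, matching the analysis this package
  reimplements); a strict mode excludes them. With short tracks this
  biases $\tau$ low by roughly $\tau/L_{\text{track}}$ — the tests use
  tracks much longer than the dwell when asserting the
  $\tau = \Delta t/(1 - A_{kk})$ law.

Transition "rate constants" are reported as the off-diagonal per-frame
probabilities divided by $\Delta t$ (a first-order reading; the diagonal
is not a rate).

## Membrane viscosity models

Two hydrodynamic laws relate a protein's in-membrane radius $R$ to its
diffusion coefficient. Saffman–Delbrück:

$$D = \frac{k_B T}{4\pi \mu_m h}\left(\ln\frac{\mu_m h}{\mu_s R} - \gamma\right),$$

valid when $\mu_m h/(\mu_s R) > e^{\gamma}$, and a Stokes–Einstein-like
alternative in which $D \propto 1/(\mu_m R)$. For the latter we use

$$D = \frac{k_B T \lambda}{4\pi \mu_m h R},$$

with the characteristic length $\lambda$ a configuration constant
(default: the membrane thickness $h$) rather than a fitted parameter —
the discriminating feature between the models is the $\ln R$ versus $1/R$
dependence, which this choice preserves; any other fixed $\lambda$ only
rescales the fitted $\mu_m$ of the second model. Defaults: $T = 294$ K,
$\mu_s = 9.6\times10^{-4}$ Pa·s, $h = 3.8\times10^{-9}$ m. The membrane
viscosity is estimated by bounded scalar least squares on
$\log_{10}\mu_m \in [-2, 4]$; on noiseless synthetic grids the inversion
is exact to $10^{-6}$ relative, and data generated under one law are
preferred (lower residual) over the other in ≥95% of noisy replicates.
Radii are user-supplied inputs (proteins with the same number of
transmembrane helices may share one radius); estimating radii from
structures is out of scope.

## The mosaic field simulator

The field model asks whether *spatial heterogeneity in viscosity alone*
can produce multistate free diffusion. A square patch (default
10 µm × 10 µm, about one cell footprint; 5 µm is common for display) is
rasterized at 10 nm and tiled with fast and slow square clumps (50 and
250 nm under control-like settings) on a middle background, placed
uniformly at random without overlap. Fast and slow clumps must not
adjoin — decoded trajectories show almost no direct fast↔slow transitions
— which we enforce as a 50 nm buffer between clumps of opposite kind;
"spaced apart" is not otherwise quantified. Equal-area circular clumps
are available (`shape = "circle"`), and simulations confirm that shape
does not matter at fixed area.

Particle dynamics per frame: look up the region at the step's **start**
(no sub-stepping across boundaries — this matches the published
algorithm, and at these step sizes boundary-crossing steps are a small
minority), draw $\Delta r$ from the region's Rayleigh law and a uniform
direction, move. Particles leaving the field reflect specularly, and the
trajectory is broken at the reflected frame (the continuation gets a new
id, as if a new molecule flowed in). The first 100 frames are discarded
as burn-in: starting uniform, particles accumulate in slow regions until
the position distribution reaches its steady state, which is exactly the
mechanism that enriches slow-state occupancy beyond the slow area
fraction. State-dependent Gaussian localization error (88/12/10 nm
fast/middle/slow under control-like settings) is added per frame
afterwards, and ground-truth region labels ride along for validation.

Tracking interruptions are reproduced by cutting trajectories at random
internal junctions, never where the new start would sit in the slow state
(slow molecules are rarely the ones whose tracking breaks; the slow cut
count is fixed at zero). `match_interruption_counts()` solves the
count-ratio equations
$p_0 = (F + f,\; M + m,\; S)/(F + M + S + f + m)$ in closed form for the
cut allocation that reproduces measured initial-state probabilities.

Calibration against measured data proceeds in two steps, mirroring how
the field parameters are identified: clump sizes from the monotone
lifetime-versus-size curve (`lifetime_vs_size()`), then a grid search
over the two occupancy percentages minimizing a weighted mean relative
error against measured $D_M$, $p_S$ and $\tau$ (`calibrate_field()`).
The closed loop — simulate a known field, measure, calibrate — recovers
the occupancies within one grid step in the test suite.

## Synthetic-data conditions and what passing tests mean

The simulators double as the package's data generators, and their
defaults are the study conditions: 5000 trajectories × 100 frames at
$\Delta t = 1/30$ s, $D = 0.10/0.03/0.008$ µm²/s,
$\varepsilon = 88/12/10$ nm, control-like field occupancies 5% fast /
30% slow, ~80,000 pooled displacements per condition for the AIC stage.
For the pure-HMM validation generator the transition diagonals are
$(0.3, 0.95, 0.93)$ — fast dwell ≈ 0.05 s, slow dwell ≈ 0.5 s — with
near-zero direct fast↔slow exchange and the stationary distribution as
$p_0$; given those pinned diagonals the stationary state mix is
essentially determined (≈ 3/75/22%), since the middle state's 5% outflow
budget cannot feed both a larger fast and a larger slow pool.

Unit tests run the same machinery at smaller problem sizes (hundreds of
tracks, 40–80 frames, 2–5 restarts) chosen so the whole suite stays
quick while every estimator is still exercised in its informative
regime; the full study scale is reserved for the dedicated acceptance
checks and `scripts/acceptance.R`.

What the synthetic generators do *not* emulate: anomalous or confined
diffusion, photophysics (blinking), detection/linking errors other than
clean track termination, inter-particle interactions, binding–unbinding
state switching (an alternative mechanism that the spatial field
deliberately excludes), and domain motion or turnover. Passing tests
therefore demonstrate estimator correctness under the stated model, not
that real membranes satisfy the model.

## Numerical choices

* All randomness flows through explicit seeds; seeded runs are
  bit-reproducible, and package functions restore the caller's RNG
  state.
* Forward–backward uses per-cell emission shifting plus per-step scaling,
  so likelihoods stay finite even when one state's density underflows.
* $\Delta r = 0$ is floored at machine-epsilon scale before taking logs.
* Empty k-means clusters trigger re-initialization with a fresh derived
  seed (bounded retries).
* AIC ties break toward fewer states; Viterbi ties toward the faster
  state; both deterministic.
* The viscosity fit brackets $\log_{10}\mu_m$ in $[-2, 4]$ and warns if
  the optimum lands on the bracket edge.

## Known limitations

* Fast-state $D_S$/$\varepsilon_S$ from Viterbi segments are biased when
  the fast dwell approaches one frame (selection effect described
  above); treat them as qualitative for short-lived states.
* Consecutive observed displacements share localization noise at the
  common frame, so they are negatively correlated; the HMM emission
  ignores this, which slightly distorts apparent-$D$ estimates for
  noise-dominated states.
* The exponential lifetime fit has no censoring correction; with track
  durations comparable to a dwell time, $\tau$ is biased low.
* The field simulator checks the region only at step starts; steps that
  jump a boundary are attributed entirely to the start region.
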