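---
title: "Modelling the surface tension of organic acids with a small perceptron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the surface tension of organic acids with a small perceptron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surftens)
library(dplyr)
```

## The model

Surface tension decreases with temperature and must vanish at the critical
point, so the reduced temperature $T_r = T/T_c$ is an obligatory input for
any model of $\sigma(T)$. `surftens` models

$$\sigma = f(T_r,\, T_b,\, \omega)$$

with a feed-forward perceptron: an input layer of fluid descriptors, one
hidden layer of $H$ logistic-sigmoid neurons
$s(x) = 1/(1 + e^{-x})$, and a single linear output neuron. All inputs and
the target are min–max normalised to $[0,1]$ before entering the network,
which keeps the hidden layer away from saturation regardless of the raw
units (kelvin versus dimensionless). The parameter count is
$H(n_{in}+1) + H + 1$; the reference three-input, 41-neuron configuration
has 206 coefficients, small relative to a corpus of about two thousand
points.

Two deliberate activation choices are worth spelling out:

* **Output neuron is linear.** A sigmoid output would compress residuals
  near the target range's edges — exactly where the near-critical data live.
  Linear output is the standard choice for regression; a sigmoid output
  remains available via `mlp_control(output_activation = "sigmoid")` for
  sensitivity checks.
* **Two sigmoid variants.** The increasing form $1/(1+e^{-x})$ is the
  default. The mirrored, decreasing form $1/(1+e^{x})$ is selectable
  (`sigmoid_form = "printed"`); the two differ only by a sign flip that the
  hidden weights absorb, so trained models are equivalent families.

### Deviation statistics

For datum $i$, the signed percent deviation is
$PD_i = 100\,(\sigma(T_i) - \sigma_i)/\sigma_i$; a data set is summarised by
$AAD = \tfrac1N \sum_i |PD_i|$, $PD_m = \max_i |PD_i|$,
$RMSE = \sqrt{\tfrac1N\sum_i(\sigma_i - \sigma_i^{calc})^2}$ (in N/m), and
$R^2 = 1 - SS_{res}/SS_{tot}$ where $SS_{tot}$ is taken about each
subset's own mean. Because $\sigma \to 0$ at the critical point, $PD$
diverges there: data below a configurable floor (`sigma_floor`, default
$10^{-6}$ N/m) are excluded from the percent-based statistics with a
warning, while RMSE and $R^2$ always use every point. Duplicate
(fluid, $T$) rows from different sources are retained verbatim and scored
per row — one model value cannot match two conflicting measurements, and
that disagreement should appear in the deviations rather than be averaged
away.

## Training procedure

The corpus is split **by datum, not by fluid**, into training (75%), test
(15%) and prediction (10%) subsets; subset sizes follow the deterministic
rounding rule $n_{tr} = \lfloor 0.75N + 0.5\rfloor$,
$n_{te} = \lfloor 0.15N + 0.5\rfloor$, remainder to prediction, so they
always sum to $N$ (for $N = 2051$: 1538/308/205). Splitting by datum means
most fluids contribute to all three subsets; the prediction subset
therefore measures interpolation to unseen state points, not transfer to
unseen chemistry.

Weights are fitted by a Levenberg–Marquardt loop on the normalised
residuals with RMSE as the target function:

* analytic Jacobian of the network output with respect to all parameters
  (verified against central finite differences in the tests);
* damping $\lambda$ starts at $10^{-3}$, is multiplied by 10 when a trial
  step fails to reduce the training RMSE and divided by 10 when it
  succeeds; accepted steps are therefore monotone in training RMSE by
  construction;
* a restart is abandoned if $\lambda$ exceeds $10^{10}$ without an
  acceptable step (singular normal equations or a hard local minimum);
* stopping: 1000 accepted steps (default), or relative RMSE improvement
  below $10^{-9}$ for 10 consecutive accepted steps;
* **early stopping**: the test-subset RMSE is tracked at every accepted
  step and the returned weights are those at its minimum, which is what
  keeps the selected model from overfitting the training subset;
* initial weights are uniform on $[-0.5, 0.5]$, seeded per restart as
  `seed + restart`, and the best of `restarts` (default 30) runs is kept —
  lowest test RMSE, ties broken by training RMSE, then restart index.

Everything above is reproducible: the same data, seed and control give
bit-identical weights, and saved model files contain no timestamps so
re-runs are byte-identical.

### Input ranking and architecture selection

Nine candidate inputs are scored by an *effect factor*: the coefficient of
each candidate in a joint multilinear least-squares fit of normalised
$\sigma$ on all normalised candidates. This is a transparent surrogate for
proprietary factor-analysis tools; its absolute values are not comparable
to theirs, but the sign (direction of influence) and the ranking by
magnitude are the decision-relevant output, and those are what the tests
assert on generated data with known structure. Collinear candidates (e.g.
$T_c$ appears inside $T_r$) trigger a warning but are retained — dropping
them silently would hide the collinearity from the user.

The hidden-layer size is chosen by sweeping a range (classically 2–50) with
a fixed split and multi-restart training per size, then selecting the size
with the lowest **test-subset** AAD (ties go to the smaller network; the
prediction subset is never consulted). Each (size, restart) cell is seeded
as `seed + 1000*size + restart`, so any cell is reproducible in isolation.
A per-size re-randomised split (`resplit = TRUE`) is offered for protocols
that re-draw subsets every run; the fixed split is the default because it
makes sizes comparable on identical data.

## Corresponding-states baselines

Four classical CSP correlations are implemented for benchmarking, each with
a $(1 - T_r)$-power factor so that $\sigma \to 0$ at $T_c$:

| id | inputs | native form |
|---|---|---|
| `brock_bird` | $P_c, T_c, T_b$ | $P_c^{2/3} T_c^{1/3} Q (1-T_r)^{11/9}$, $Q = 0.1196[1 + T_{br}\ln(P_c/1.01325)/(1-T_{br})] - 0.279$ |
| `sastri_rao` | $P_c, T_b, T_c$ | $0.125\, P_c^{0.5} T_b^{-1.5} T_c^{1.85} [(1-T_r)/(1-T_{br})]^{11/9}$ (acid parameter set) |
| `pitzer` | $P_c, T_c, \omega$ | $P_c^{2/3} T_c^{1/3} \frac{1.86 + 1.18\omega}{19.05} \big[\frac{3.75+0.91\omega}{0.291-0.08\omega}\big]^{2/3}(1-T_r)^{11/9}$ |
| `gharagheizi` | $T_c, T, \omega, M_w$ | **surrogate**, see below |

(mN/m with $P_c$ in bar and temperatures in K; converted to N/m.) The
Brock–Bird, Sastri–Rao and Pitzer forms are the standard reference
transcriptions and are pinned by hand-evaluated fixtures in the tests. For
the molecular-weight-based correlation the original coefficients were not
available when this package was written, so `gharagheizi` is an explicitly
labelled surrogate with the published input signature,
$1.2305\, T_c^{2/3} M_w^{-1/12} (1 + 0.0523\,\omega)(1-T_r)^{11/9}$ mN/m,
anchored once to typical organic-acid magnitudes. Its qualitative behaviour
(shape, limits, input requirements) is right; treat its absolute deviations
as indicative only.

The benchmark reports, per model: the number of fluids with AAD < 10%
(strict inequality), the per-fluid max/min AAD, and the data-count-weighted
overall AAD. Fluids missing a model's required constants are skipped with a
notice rather than failing the run.

## The synthetic corpus generator

Real acid corpora cannot be redistributed, so every stage is exercised on
generated data whose *statistical* structure mirrors compiled collections:

* per-fluid constants drawn from realistic ranges ($T_c \in [550, 900]$ K,
  $T_{br} \in [0.55, 0.75]$, $\omega \in [0.3, 1.1]$, $P_c \in [10, 60]$
  bar, $M_w \in [46, 350]$ g/mol, plus radius of gyration, liquid molar
  volume and dipole moment so the full nine-candidate ranking runs);
* per-fluid ground truth $\sigma(T) = \sigma_0 (1 - T_r)^p$ with the
  classical critical exponent $p = 11/9$ jittered by $\pm 0.1$ per fluid.
  The jitter is what keeps the learning task honest: without it, three
  inputs reproduce the truth exactly and every architecture looks perfect.
  With it, part of the variance is *not* a function of $(T_r, T_b, \omega)$
  — as in real corpora — so the fitted network retains a small irreducible
  deviation concentrated near $T_c$;
* amplitude $\sigma_0 = 10^{-3}(12 + 0.09\,T_b - 14\,\omega)$ N/m, chosen
  increasing in $T_b$ and decreasing in $\omega$ so the effect-factor signs
  have a known ground truth to assert against;
* point counts per fluid drawn log-uniformly on $[4, 165]$ (strongly
  right-skewed, geometric mean ≈ 26, as in compiled corpora where a few
  well-studied fluids dominate); reduced temperatures uniform on
  $[0.25, 0.92]$;
* 1% multiplicative Gaussian noise, and with probability 0.15 a duplicated
  temperature under a second source tag with independent noise (pair
  scatter $\sqrt{2}\times$ the noise sd, checked by Monte Carlo);
* alternative teachers — a CSP model or a frozen random network — for
  closed-loop benchmark checks and parameter-recovery experiments.

All randomness flows from one seed through per-fluid derived streams, so
any fluid's draw is reproducible in isolation.

What passing on this generator does **not** show: accuracy for real acids
(the truth curves are idealised, measurement error is not 1% i.i.d., and
real sources disagree systematically, not randomly), behaviour under
fluid-wise extrapolation (the split is by datum), and the exact deviation
figures of any published corpus.

## Numerical choices and degenerate inputs

* Normalisation bounds are fitted on the **full** dataset passed to
  `mlp_fit()` (configurable to training-only via `norm_scope`). Full-set
  bounds guarantee the test and prediction subsets map inside $[0,1]$;
  training-only bounds are the stricter choice when leakage through two
  scalar bounds matters. The bounds travel inside the model file and
  prediction-time inputs outside them set an `extrapolated` flag with a
  warning — extrapolation is surfaced, not forbidden.
* A constant input column cannot be normalised and raises a degenerate-range
  error rather than silently producing NaNs.
* Percent deviations require $\sigma > 0$; the `sigma_floor` exclusion
  (default $10^{-6}$ N/m) is logged whenever it bites.
* Model JSON stores weights at full printed double precision
  (~15 significant digits); reloaded predictions agree to well below any
  physically meaningful tolerance.

## Problem sizes used in the test suite

The suite favours small, fast cases: metrics and Jacobian properties run on
hundreds of points and (3, 5, 1)-scale networks; the recovery experiment
trains a (3, 5, 1) student on a frozen same-size teacher over ~2000 points
(noise-free AAD must come in under 0.5%, 1%-noise AAD under 2%); the sweep
check uses hidden sizes {2, 4, 8, 16} with 5 restarts on a 4-neuron-teacher
corpus of 500 points. The acceptance script scales the reference fit to 6
restarts × 400 accepted steps on a 98-fluid corpus. These sizes were chosen
so the whole pipeline, including the sweep, runs routinely on a laptop; the
full-scale protocol (2–50 neurons, 30 restarts, 1000 steps) is available
through the same functions.

## Known limitations

* Single hidden layer, single output; no minibatching, no GPU — deliberate,
  since the method's point is a *small* network trained by second-order
  least squares.
* The effect-factor surrogate is linear; a strongly non-monotone influence
  would be under-ranked. It is a screening tool, not an importance proof.
* The `gharagheizi` baseline is a surrogate (above).
* Splitting by datum means reported "prediction" accuracy is
  interpolation; per-fluid transfer requires a fluid-wise split the package
  does not currently implement.
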