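---
title: "Testing additional predictive value: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing additional predictive value: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offsetboost)
```

## The testing problem

Clinical covariates (age, sex, stage, ...) are cheap, validated and few; a
molecular block (expression, methylation, ...) is expensive and
high-dimensional, with p often orders of magnitude above n. The question
`offsetboost` answers is not "does X predict Y?" but "does X predict Y
*given that Z is already in the model*?" — a global null over all p
molecular coefficients at once. Three properties drive the design:

* it is a **hypothesis test**, not a prediction pipeline: the output is a
  p-value with a guaranteed null distribution, not a signature;
* the molecular model is built **around** the clinical model: the clinical
  linear predictor enters boosting as a fixed offset, so molecular
  features redundant with Z cannot look informative;
* both adjustment scenarios are supported: a clinical model estimated from
  the data at hand, or a fixed published risk score (any monotone score —
  logit-transformed if on the probability scale — including scores that
  never came from a logistic model).

## Two-stage fit

**Stage 1.** `fit_logistic_offset()` computes the logistic MLE of Y on Z
by IRLS (`stats::glm.fit`) and freezes the linear predictor
η̂ᵢ = β̂₀ + Σⱼ β̂ⱼ zᵢⱼ. The coefficients are never updated afterwards;
the `offset_model` object is treated as immutable input to stage 2.
Assumptions here are the usual ones of a low-dimensional GLM: n
appreciably larger than q, no separation. Separation is a *hard error* by
default (flagged at IRLS non-convergence or any |coefficient| > 15): if
the clinical model alone is degenerate, "additional value beyond it" has
no meaning. `allow_nonconverged = TRUE` downgrades this to a warning for
exploratory use.

**Stage 2.** `boost_fit()` runs functional gradient descent on the
binomial log-likelihood loss with componentwise linear least squares as
base procedure, starting at f⁽⁰⁾ = η̂. Iteration m:

1. negative gradient uᵢ = 1(yᵢ = +1) − expit(fᵢ⁽ᵐ⁻¹⁾);
2. for every column j, OLS of u on (1, Xⱼ); keep the column j* with the
   smallest RSS (equivalently the largest (Xⱼᶜ′u)²/‖Xⱼᶜ‖², which is how
   the kernel computes it in O(np) per iteration);
3. f⁽ᵐ⁾ = f⁽ᵐ⁻¹⁾ + ν·(â + b̂·X_{j*}), with â, b̂ accumulated into an
   explicit intercept and sparse coefficient vector, so the final linear
   predictor is reproducible as β̂₀* + Xβ̂* + η̂ (verified to 1e-10 in
   the tests).

The training loss is provably non-increasing for ν ≤ 1: the base fit is a
projection of the gradient, and the binomial loss has curvature at most
1/4, so each step decreases the loss by at least ν(1 − ν/8)‖ĝ‖²/n ≥ 0.
The test suite asserts this per iteration on every fixture.

### Logit convention

The package works on the full logit scale: probabilities expit(f),
gradient y′ − π with y′ ∈ {0, 1}. The classical boosting literature often
writes the same algorithm on a half-logit scale (f equal to half the
log-odds, with the loss written on Y ∈ {−1, 1}); the two differ by an
exact factor-2 reparameterization of f, which only rescales the effective
step length. Full logit is used here because it makes the stage-1 GLM
linear predictor the offset *verbatim* — at m_stop = 0 the boosting loss
equals the GLM's maximized average negative log-likelihood to machine
precision, an identity the tests pin down exactly — and because the
permutation comparison is unaffected by the convention.

## Parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `nu` | 0.1 | (0, 1] | standard boosting shrinkage; small values make m_stop the only effective tuner |
| `mstop` | `"aic"` | iterations | the method's single real parameter; fixed values 100–1000 behave similarly in simulations |
| `mmax` | 1000 | iterations | AIC search cap; besides CPU time there is little harm in a generous cap |
| `B` | 200 | permutations | p-value resolution is 1/(B+1); set as high as affordable |
| `center` | `TRUE` | flag | numerically symmetric columns; fitted probabilities are invariant to it (the per-iteration intercept absorbs shifts), only the reported intercept moves |
| `standardize` | `FALSE` | flag | selection *is* scale-sensitive; off by default so variance information is kept, on for features on incommensurate scales |
| `eps` | 1e-10 | probability | clipping before logs keeps permutation statistics finite when boosting saturates |

Coefficients are reported on the working (centered/scaled) scale with the
transformation stored in the fit; `predict()` applies it, so round trips
are exact.

## AIC stopping

`select_mstop_aic()` treats the boosting path as a sequence of linear
smoothers on the gradient scale and accumulates the hat operator
B_m = B_{m−1} + ν·H_{j*_m}(I − B_{m−1}), H_j the rank-2 hat matrix of the
univariate fit on (1, Xⱼ). The effective degrees of freedom df(m) =
tr(B_m) start at 0, increase by 2ν at the first step, never decrease, and
are bounded by n; AIC(m) = −2·loglik(m) + 2·df(m) is minimized over
1..mmax with ties to the smallest m. This linear-smoother df is the
classical approximation for boosting with L2 base learners; it is an
approximation for the binomial loss, which is acceptable here because
only the *relative* AIC across m matters. The fixed clinical parameters
contribute no df — they are offsets, not estimates. The classical (not
small-sample-corrected) AIC form is used.

Two honest caveats. The operator is a dense n × n matrix, so selection is
guarded above n = 5000 (use fixed m_stop there). And under permutation
the selection is *re-run on every permuted dataset* by default: the null
distribution must be generated by the identical procedure applied to
exchangeable data, m_stop selection included. `aic_once = TRUE` reuses
the original selection when the B-fold cost matters; this slightly breaks
procedural symmetry and is therefore not the default.

## Permutation scheme

A single random permutation σ_b is applied jointly to the rows of X;
Z and y stay fixed, so the clinical offset is computed once and reused
(it depends only on Z and y). Permutations are drawn with replacement
from the permutation group, the identity not excluded — for n in the
dozens, collisions are negligible and excluding the identity would bias
the null. All B permutations are drawn up front from the master seed, so
the result is bit-identical for any `threads` value. The p-value uses the
add-one convention (1 + #{ℓ_b ≤ ℓ})/(B + 1): strictly positive, exactly
discrete-uniform under the null, with ties counted conservatively.

## What the generator emulates — and what it does not

`simulate_dataset()` reproduces a Gaussian two-group shift design:
Y a fair coin; informative molecular columns N(μ_X, 1) in the Y = +1
group against N(0, 1); clinical columns shifted by μ_Z the same way; all
columns independent. The named settings span "few strong" (p* = 5,
μ_X = 0.5 or 0.8) to "very many weak" (p* = 200, μ_X = 0.3) signals, plus
the additional-value contrast pair: `f1` (clinical and molecular blocks
both informative but independent) and `f2` (the informative molecular
columns are *exact copies* of the clinical columns — the molecular block
is fully redundant and a correct method must not reject).

Real molecular data are not Gaussian, not independent across features,
not variance-1, and their informative features are not axis-aligned mean
shifts. Passing the simulation suite therefore demonstrates calibration
and power *under this design*, not under arbitrary correlation
structures; the only dependence structure exercised is the extreme
duplication case. The test itself makes no distributional assumption
about X — its validity rests on row exchangeability of X under the null —
but its *power* figures are design-specific.

## Study sizes used by the tests and acceptance script

Chosen once as the package's own desk-scale conditions: calibration and
power studies run at n = 50, p = 200, q = 5, B = 99, m_stop = 100 with
200 (null) or 50 (power) replicates; the `f1`/`f2` contrast and the
m_stop-robustness study run at the benchmark sample size n = 100 with the
same p, B and replicate counts — at n = 50 a clinical model with five
covariates each shifted by a full standard deviation quasi-separates in a
non-trivial fraction of replicates (correctly raising the separation
error), and the strong-sparse setting sits on the 0.05 boundary, which is
not the regime the robustness claim is about. The full benchmark scale
(n = 100, p = 1000, B = 200, 100 replicates) is available via
`study_profile("paper")` for overnight runs.

## Numerical choices and degenerate inputs

* Outcome coding: two-level input mapped by sorted level order (lower
  level → −1), so results are invariant to row order; degenerate
  (one-class) outcomes are errors.
* Ties in the componentwise argmin: smallest column index, deterministic.
* Zero-variance molecular columns: retained, never selectable (gain 0);
  if *all* columns are constant the base fit degenerates to the intercept
  with a warning.
* Probability clipping at `eps = 1e-10` before logs; configurable.
* GLM convergence: tolerance 1e-8, 100 IRLS iterations — stated as
  package defaults, not field constants.
* Serialization: doubles written with 17 significant digits, so a
  write/load round trip reproduces p-values bit-identically.

## Limitations

* Binary outcomes and the binomial log-likelihood only; no survival,
  multiclass, or asymmetric-cost losses.
* Linear base learners only: the test is geared toward linear additional
  signal. Nonlinear molecular effects that are orthogonal to every single
  feature can escape it.
* A single global hypothesis: no per-feature follow-up tests and no
  multiplicity machinery.
* The statistic is a training-sample quantity; it is meaningful only
  inside the permutation comparison and is not an out-of-sample error
  estimate.
* The AIC df is a linear-smoother approximation; at extreme saturation
  the AIC curve can keep decreasing up to `mmax`, in which case the
  selected m_stop is effectively `mmax` (harmless for the test, per the
  robustness study).
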