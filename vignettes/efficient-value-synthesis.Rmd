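---
title: "Efficient value synthesis: model, plasticity rule, and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient value synthesis: model, plasticity rule, and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valsyn)
library(dplyr)
```

## The model

`valsyn` models how a decision maker values a 50/50 gamble that offers a
prospective gain $G$ and a prospective loss $L$ (both entered as positive
magnitudes). Value is *synthesized* — constructed from attribute inputs —
rather than received: each attribute feeds a dedicated sublayer of $n_x$
bounded units,

$$x(i,j) = f\big(u(i);\, \mu(i,j), \sigma(i,j)\big), \qquad
  f(u;\mu,\sigma) = \frac{1}{1 + e^{(\mu - u)/\sigma}},$$

whose outputs are mixed through a connectivity matrix $C$ into $n_z$
integration units $z(k) = f(v(k);\, \mu_z(k), \sigma_z(k))$ with
$v(k) = \sum_{i,j} C(i,j,k)\, x(i,j)$, and the gamble's value is a linear
population readout $V = \sum_k w(k)\, z(k)$. Choices follow
$p(\text{accept}) = \operatorname{logit}^{-1}(b + V)$ with unit slope; any
behavioral temperature is absorbed by the scale of $w$, and the decision
bias $b$ plays the role of the logistic intercept (the value chain itself
has no intercept).

The bounded (sigmoidal) activation is the load-bearing assumption: real
neurons cannot fire above a physiological ceiling. When the inputs $v(k)$
drift into the saturating tails of $f$, different gambles produce nearly
identical responses and information about value is lost to any downstream
noise.

## The plasticity rule

At the small-noise limit, the information lost between noisy and noiseless
integration responses decomposes (up to constants) into the negative entropy
of the integration inputs plus the mean log-steepness of the activation
functions; `information_loss()` reports both terms, approximating the
entropy as Gaussian, $\tfrac12 \ln\det(C^\top S C)$ with $S$ the attribute
output covariance. Descending this loss with respect to each connection —
keeping only the local part of the gradient, since the entropy gradient
couples every connection to every other and is biologically implausible —
and estimating the across-trial expectation with an exponentially weighted
moving average yields the rule implemented by `plasticity_step()` and the
C++ engine behind `adapt_sequence()`:

$$\Delta C_t(i,j,k) = \alpha(1-\beta)\,\Delta C_{t-1}(i,j,k)
  + \alpha\beta\,\frac{1 - 2 z_t(k)}{\sigma_z(k)}\, x_t(i,j).$$

The innovation is the exact gradient of $\ln |\partial f_z/\partial v(k)|$
with respect to $C(i,j,k)$ (the unit tests verify this against central
finite differences to $10^{-6}$ relative error). Note the *division* by
$\sigma_z(k)$: with $f' = f(1-f)/\sigma$, the chain rule forces it, and we
follow the derivation. The rule is self-organized (no teaching signal),
local (each connection sees only its own pre- and post-synaptic outputs) and
anti-Hebbian: a connection from a firing input unit weakens exactly while
the receiving unit is above half-maximum. Setting $\alpha = 0$ or
$\beta = 0$ recovers *static* value synthesis exactly.

A genuine steady state of the local rule alone is the collapse $v \to
\mu_z$: the dropped entropy term is what would oppose it asymptotically.
All analyses therefore concern the quasi-settled state reached within a
256-trial session, where connectivity changes have shrunk by an order of
magnitude but outputs retain contrast.

## Parameters and defaults

| parameter | default | units / meaning |
|---|---|---|
| `money_unit` | 40 (dollar designs), 1 (unit domain) | affine money normalization; $40 is the largest amount either study design can present |
| `n_x`, `n_z` | 8 per attribute, 16 | layer sizes; results are insensitive to the exact counts |
| attribute $\mu, \sigma$ | tile $[0,1]$, $\sigma = 1/(2 n_x)$ | fixed population code over the canonical input domain |
| integration $\mu_z, \sigma_z$ | 0, 1 | adaptation of $C$ relocates and rescales $v$, so these stay canonical |
| `c_scale` | 6 | initial $C$ entries are $\mathcal N(0, (c/\sqrt{2 n_x})^2)$ |
| `alpha`, `beta` | 0.05, 0.2 (simulations); agents draw $\alpha \sim U[0.01, 0.04]$, $\beta \sim U[0.1, 0.3]$ | plasticity magnitude and moving-average rate |

Two of these deserve their rationale spelled out.

**Initial connectivity scale.** The adaptation account presumes that a
random, untrained network drives a sizable share of integration inputs into
the saturating range. At `c_scale = 6` roughly a quarter of initial inputs
sit beyond $\pm 2\sigma_z$, the EV readout is still learnable
($R^2 > 0.95$), and adapted networks choose more consistently than static
ones under response noise. At much smaller scales almost all inputs start
responsive, leaving adaptation nothing to improve — the premise of the
theory is simply not instantiated.

**Plasticity magnitude.** $\alpha$ is on this rule's own scale: with
$\sigma_z = 1$ a single-trial innovation is $O(x) \approx O(1)$, so usable
magnitudes are small. At $\alpha = 0.05$, $\beta = 0.2$ a 256-trial session
settles (late connectivity changes are several-fold smaller than early
ones) without collapsing unit outputs to $0.5$; an order of magnitude more
drives every $z$ to its threshold response and erases the very contrasts
the simulations measure. Cohort agents use somewhat smaller magnitudes
($\alpha \le 0.04$) because on the dollar designs — whose inputs are
bounded away from zero, giving every always-active attribute unit a
constant anti-Hebbian pressure — larger magnitudes distort the value
landscape so strongly that simulated choices become degenerate
(acceptance rates near 1, undefined loss aversion).

## The Monte-Carlo protocol

`run_condition()` implements one simulated study cell: draw a random
connectivity, train the readout to expected value $EV = (G - L)/2$ on the
condition's $16 \times 16$ factorial grid (`train_readout_to_ev()`,
minimum-norm least squares), freeze it, then let the network self-organize
through a freshly shuffled 256-trial series. The settled network is
evaluated once on the unshuffled grid; all summaries (EV-binned unit
curves, RDM-based encoding strengths, behavioral sensitivities) are taken
there rather than during the transient, because the range-adaptation claims
concern the settled state. "Narrow" and "wide" ranges are $[0, 0.5]$ and
$[0, 1]$ on the unit domain; the range-grid sweeps vary the upper bounds
over $\{0.25, 0.5, 0.75, 1\}$ with a common lower bound of 0.

Two estimator details matter. EV-binned unit curves pool units by the sign
of their correlation with EV, using 9 equal-width bins within each
condition's realized EV range. And the per-condition loss-aversion ratio is
the ratio of *run-averaged* sensitivities, not the average of per-run
ratios: a ratio of noisy quantities is upward-biased, and the summary-level
ratio is the one whose diagonal neutrality the theory predicts.

## Behavioral analyses

`fit_choice_logistic()` is the within-subject model-free benchmark,
$p = \operatorname{logit}^{-1}(w_0 + w_G G - w_L L)$ (losses as positive
magnitudes), fitted by IRLS with trial-wise exclusion of missing responses.
Perfect separation — routine in 16-trial windows — triggers a MAP refit
under zero-mean Gaussian priors (sd 10) and a flag. The loss-aversion index
$\lambda = \log(w_L / w_G)$ is invariant to behavioral temperature. The
sliding-window analysis refits in consecutive non-overlapping 16-trial
windows; window estimates are noisy (the per-window standard error of
$\lambda$ is several times the group effects of interest), so drift
detection is a group-level question: the package's validation asks whether
the *cohort-mean* window trend is positive, not whether each subject's is.
Group comparisons use the pooled-variance one-way F test, identical to the
squared two-sample t.

## Fitting networks to choices

`fit_ann_to_choices()` computes a MAP estimate of the sequential model:
bias, readout weights, two per-attribute input gains, and (plastic variant)
logit-transformed $\alpha, \beta$. The initial connectivity is *not*
fitted; it is a fixed draw from a subject-specific seed, which keeps the
problem identifiable while the input gains and readout supply the flexible
value landscape. Priors are zero-mean Gaussians on bias and readout and a
logit-normal centered at $\operatorname{logit}(0.1)$ on the plasticity
parameters. Optimization is multi-start BFGS with numerical gradients; the
first start initializes the readout at the EV-trained solution, and plastic
starts tile the $(\alpha, \beta)$ plane because the likelihood is ridged
along $\alpha\beta$ — the product, which sets the effective per-trial
learning rate, is the well-identified quantity, while $\alpha$ and $\beta$
separately trade off. Recovery harnesses therefore either pin $\beta$
(`fix_beta`) or accept that $\hat\alpha$ carries that ridge's noise.

Counterfactual prediction (`counterfactual_predict()`) resets the
plasticity state to the fitted initial condition and runs the model on the
other context's trial series without re-adjustment. Static variants are
context-invariant for any shared gamble by construction; plastic variants
re-adapt, which is exactly the signature separating the accounts: on
twin-paired synthetic cohorts the plastic models predict *less* gambling in
the wide (favorable) context within the common EV range, static models
predict more, and the plastic models' absolute out-of-sample error is
lower.

## RSA

`compute_rdm()` measures trial-pair dissimilarity as one minus the Pearson
correlation of activity patterns, which is invariant to affine
transformations of individual patterns. Confounds are removed in the order
session projection (per-unit within-session demeaning of the pattern
matrix), then RDM computation, then per-delay demeaning
(`delay_detrend()`); delay is defined on the concatenated trial index.
Encoding strengths regress the vectorized lower triangle on absolute
attribute differences — gain and loss jointly, EV separately to avoid
collinearity — and their standard errors are nominal, since trial pairs
are not independent. Binned RDMs average trial-pair dissimilarities within
level pairs (robust to unequal bin counts). Model-vs-data comparison is
the Pearson correlation of lower triangles, Fisher-transformed, with
one-sample t group inference.

## The synthetic-data generator

`gen_group_design()` reproduces the two study designs: 16 gain levels
crossed with 16 loss levels, each combination once, shuffled, in four
contiguous 64-trial sessions; narrow has $G, L \in \{5, \dots, 20\}$
dollars, wide doubles the gain levels to $\{10, 12, \dots, 40\}$ (ranges
are stated for the original studies; the $2\times$ level spacing is the
faithful reading of "gains double the losses"). `value_agent()` turns a
network into a ground-truth participant — readout trained to EV over its
own design then frozen, seeded connectivity, plasticity, decision bias —
and `simulate_choices()` draws Bernoulli choices, emitting the four-level
response vocabulary with strong/weak split at $|p - 0.5| \ge 0.25$.
`gen_voxel_patterns()` stands in for ROI trial patterns: a seeded random
linear mixture of integration outputs plus per-session offsets and AR(1)
trial noise scaled per voxel to a requested signal-to-noise ratio.

What the generator deliberately does not emulate: hemodynamics and
HRF-convolved time series (only trial-wise patterns), heterogeneous unit
slopes, trait loss aversion (agents start as EV maximizers, so cohort
$\lambda$ starts near 0 rather than the mildly positive values real
cohorts show), non-response trials, and any within-trial dynamics. Passing
tests on these cohorts show that the pipeline detects the phenomena the
model generates — not that real populations match the generator.

## Numerical choices and degenerate inputs

* Rank-deficient readout features fall back to the minimum-norm solution
  (SVD pseudoinverse) with a warning; near-singular input covariances in
  `information_loss()` get a relative ridge of $10^{-8} \cdot
  \text{trace}/\text{dim}$ and a flag.
* Constant trial patterns yield flagged missing RDM entries that propagate
  through pairwise-dropping estimators; constant units are excluded from
  binned curves (variance floor $10^{-8}$) and left unclassified by
  `classify_value_cells()`.
* Attribute slopes under the alternative adaptation scenario are floored at
  $10^{-3}$ with a warning.
* Money outside $[0, \texttt{money\_unit}]$ errors rather than
  extrapolating, which also guards counterfactual transplantation across
  incompatible designs.
* All stochastic entry points take explicit seeds and are bit-reproducible.

## The alternative attribute-coding scenario

`adapt_attributes_sequence()` implements the competing account — the same
infomax principle applied to each attribute unit's own threshold and
log-slope, with the connectivity untouched:
$\Delta\mu = \text{rate}\,(2x - 1)/\sigma$,
$\Delta\ln\sigma = \text{rate}\,((\mu - u)(1 - 2x)/\sigma - 1)$. These
equations are this package's derivation; the original account's
supplementary equations are not available, so only qualitative contrasts
can be attempted. One published contrast does not reproduce under our
re-derivation: the claim that attribute-level adaptation makes the
integration layer's gain-encoding strength *increase* with the gain range.
The per-unit infomax objective has a unique fixed point (thresholds at the
input median, slope proportional to the spanned range), so the adapted
attribute code is range-normalizing; correlation-distance RDMs over the
integration layer are then invariant in rank space and the per-dollar
encoding slope scales as one over the range — a decrease, at every step
size we explored. The corresponding check in the test suite is stated as
the published contrast and records this as a failure by design rather than
asserting something the implementation does not do.

## Problem sizes

Monte-Carlo properties are validated at 100 runs per condition (the
headline protocol uses 1000; both are configurable), recovery benchmarks at
100 logistic seeds, 10 replicate drift cohorts of 54 subjects, one
20-subject plasticity-recovery cohort, and two twin-paired cohorts fitted
with both variants: a default-strength 6 + 6 cohort for the signed
counterfactual contrast and a strong-adaptation 10 + 10 cohort for the
out-of-sample error ordering (at default magnitudes the true context
effect is smaller than the plastic fit's estimation noise, so the ordering
is only detectable where the generative adaptation is strong). The
acceptance script (`scripts/acceptance.R`) re-runs all of these from
scratch at the same sizes plus a study-sized (54 + 54) cohort for the
model-free group statistics.

## Known limitations

* $\hat\alpha$ and $\hat\beta$ are only jointly identified through their
  product at realistic trial counts; per-subject $\hat\alpha$ carries
  substantial noise, and truth-estimate correlations near 0.7 over 20
  subjects are at the edge of what 256 binary choices support.
* The local rule's long-run fixed point is output collapse; conclusions
  hold for session-length exposures, not asymptotically.
* Choice-level loss aversion in wide-range contexts mixes slope changes
  with an adaptation-induced value drift that the logistic intercept only
  partly absorbs; group contrasts are reliable, single-subject landscape
  summaries less so.
* The attribute-coding contrast above is unresolved against the original's
  unprinted equations.
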