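---
title: "Methods: stereotypy metrics and the mushroom-body network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereotypy metrics and the mushroom-body network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbstereo)
```

This vignette documents the models, metrics, parameters and numerical
choices behind `mbstereo`, in the spirit of a methods section: what is
computed, under which assumptions, and where the design was genuinely open.

## The stereotypy metrics

A *response table* is an individuals × odors matrix of trial-averaged scalar
responses (spike counts, ΔF/F, or model output — the metrics are unit-free).

**PRED.** For odors (1, 2) and individuals (A, B) with responses
$a_1, a_2, b_1, b_2$, the same-odor and cross-odor squared distances are
$D_1 = (a_1-b_1)^2 + (a_2-b_2)^2$ and $D_2 = (a_1-b_2)^2 + (a_2-b_1)^2$, and

$$\mathrm{PRED} = \frac{D_2 - D_1}{D_2 + D_1} \in [-1, 1].$$

Useful identities (all verified in the test suite): $D_2 - D_1 =
2(a_1-a_2)(b_1-b_2)$, so the sign of PRED is the sign of the product of the
two individuals' odor-response differences; PRED is invariant to adding a
common constant to all four responses and to scaling all four by any
non-zero constant; swapping individuals leaves it unchanged, and swapping
one individual's odor labels flips its sign. When $D_1 + D_2 = 0$ (all four
responses equal) PRED is defined as 0. Numerically, the ratio is zeroed
whenever $D_1 + D_2 \le 10^{-12}\max(a_1^2, a_2^2, b_1^2, b_2^2)$ so that
floating-point ties never produce 0/0. For larger tables, one PRED value is
computed for every unordered individual pair × odor pair and averaged.

**Correlation.** The Pearson correlation between the two individuals'
odor-indexed response vectors, averaged over individual pairs. A constant
vector makes the correlation undefined; such pairs are *excluded and
counted*, never coerced to 0. With only two odors, defined correlations are
forced to ±1 — one reason PRED is the default metric in the simulations.

**Significance.** Stereotypy means are compared against the chance level 0
with a two-tailed one-sample t-test (`one_sample_t()`); zero-variance input
raises an error pointing to the permutation test. `permutation_null()`
builds a null by independently permuting each individual's odor labels and
recomputing the mean PRED; the one-sided p-value uses the
$(1 + k)/(n + 1)$ small-sample correction. The exact resampling scheme is
our choice — independent within-individual label permutations are the
natural null for "responses unrelated to odor identity" — since no single
canonical scheme exists for this statistic.

## The network model

Each simulated *individual* is a three-layer feedforward network:

| parameter | default | meaning |
|---|---|---|
| `n_pns` | 50 | projection neurons (input layer; one per glomerulus) |
| `pn_response_prob` | 0.5 | probability a PN responds to a given odor |
| `spike_low`, `spike_high` | 10, 30 | responder spike counts, uniform **integers** (mean 20) |
| `n_kcs` | 2000 | Kenyon cells (expansion layer) |
| `pn_kc_prob` | 0.14 | i.i.d. Bernoulli PN–KC connection probability (mean in-degree 7) |
| `kc_threshold` | 119 | rectifier threshold `t` in `f(k) = max(0, k − t)` |
| `kc_mbon_prob` | 0.5 | fraction of KCs read by the MBON |
| `randomness_fraction` | 1 | fraction of PN–KC entries redrawn per further individual |
| `noise_sd` | 0 | s.d. of Gaussian noise added to each KC's summed input |

PN response vectors vary with the odor but not the individual; PN–KC
matrices vary with the individual but not the odor. The default threshold
119 leaves roughly 10% of KCs responsive per odor, matching the observed
sparseness of KC codes. Spike counts are inclusive uniform integers because
that gives the stated mean of 20. Connectivity is i.i.d. Bernoulli per
entry, not fixed in-degree: the in-degree of 7 holds in expectation.

The MBON sums the rectified responses of its connected KCs with threshold 0
(a plain sum). Whether the biological readout applies its own threshold is
unknown; threshold 0 is the choice that makes the MBON equal the total KC
response exactly at full convergence, which is also the behaviour the model
exhibits at `kc_mbon_prob = 1` and which anchors the convergence analysis.
At the defaults the mask is the leading half of the KCs (any fixed shared
subset is statistically equivalent); Bernoulli masks, shared across
individuals, are used in convergence sweeps.

**Noise.** Where noise is enabled it is additive Gaussian on each KC's
summed input, independent per KC, odor and individual, truncated at 0. The
placement (input rather than output) is a documented choice; the magnitude
is a free parameter with no canonical value, so no default other than 0 is
shipped.

**Seeding.** Every experiment takes one master seed; per-iteration child
seeds are drawn once up front with `sample.int()`, so any single iteration
can be reproduced in isolation and a report is bit-identical across runs
with the same seed.

## The experiments

* `run_simulation()` — fresh odor panel, fresh connectivity per iteration;
  stereotypy (both metrics) of the MBON response, total KC response, total
  KC input and individual KCs (the latter restricted to KCs responsive to
  at least one odor in *both* individuals, pooled across iterations).
  Controls: `identical_connectivity` (positive — stereotypy is perfect by
  construction) and `nonstereotypic_pns` (negative — PN panels drawn
  independently per individual, which abolishes readout stereotypy).
  `normalize_mbon_weights` mean-subtracts the KC–MBON weight vector before
  the sum, the normalization used in piriform-cortex models; it collapses
  readout stereotypy, which is why those models needed learning to recover
  it.
* `run_learning()` — per individual, a random half of the odors is learned
  sequentially; each event connects or disconnects (probability 0.5 each) a
  fraction `learning_rate` of the KCs activated by that odor and currently
  unconnected/connected to the MBON. Eligible counts are rounded to the
  nearest integer and activation is evaluated against the current
  connectivity (events compound). Learning diversifies the readout across
  individuals, so MBON stereotypy decreases with the learning rate.
* `run_fixed_drive()` — the total PN spike count is fixed (500 = mean rate ×
  half the PNs) and distributed among the active PNs, eliminating the
  total-drive cue. The constrained partition draws part $j$ uniformly from
  $[\max(lo, rem - (n-j)\,hi),\ \min(hi, rem - (n-j)\,lo)]$ and then
  permutes the parts; this is always feasible when $lo \cdot n \le total
  \le hi \cdot n$ and needs no rejection loop. In the base condition the
  active-PN count is fixed at half the PNs for *both* odors: with the
  drive, the count and the spike range all matched, no stereotypy remains —
  an odor-varying count would itself be a stereotypy-generating cue and
  belongs to the `nactive_*` variants instead. Variants manipulate the
  spike range or active count for one or both odors, shuffle PN labels for
  the second odor, or use the linear transfer $y_i = m x_i - t$ with $m$
  calibrated per iteration so the grand-mean total linear response matches
  the rectified model on the same inputs ($m = (\bar{R} + N_{KC}\,t) /
  \bar{K}$). The linear runs lose the stereotypy that the range and count
  differences otherwise create, isolating the role of the rectifier.
* `run_parameter_sweep()` — sweeps PN mean rate (spike range = mean ± 10),
  KC count, connection probability, KC threshold, PN count or response
  probability, on two-odor panels, tracking stereotypy together with the
  mean active-KC count and mean active-KC rate. Stereotypy rises with the
  number of active KCs however it is achieved, and the active rate matters
  little — the sparseness/stereotypy trade-off.
* `run_convergence_randomness_grid()` — KC–MBON connection probability
  (convergence $c$) × fraction of PN–KC entries redrawn in the second
  individual (randomness $f$), both on a 21-point log grid over
  [0.01, 1]. Within an iteration the grid shares its random draws across
  points (nested redraw subsets over $f$, nested masks over $c$): every
  point remains a valid sample of its condition with unbiased means, at a
  fraction of the cost of independent runs. `fit_hill()` fits
  $S = r^a/(b + r^a)$ to the 441 (ratio, mean PRED) points by nonlinear
  least squares (start $a = b = 1$, bounds $a \in (0, 10]$, $b \in
  (0, 100]$, `nls` port algorithm with a Levenberg–Marquardt fallback);
  same-ratio points are fitted as-is, not pre-averaged. Degenerate
  (constant) input is flagged with $R^2 = 0$ rather than fitted.

## The analytical binary model

`binary_model_params()` describes the reduced network: binary PN patterns
(each PN active with probability $q$ per odor), binary i.i.d. connectivity
(probability $p$), and a KC that fires when at least $\theta$ of its
connected PNs are active; the population response is the count of firing
KCs. The default $\theta$ is the smallest integer keeping the expected
active fraction at or below 12%, computed from the binomial mixture
$\sum_s \binom{n}{s} q^s (1-q)^{n-s}\, P(\mathrm{Bin}(s, p) \ge \theta)$.

`expected_pred_enumeration()` computes $E[\mathrm{PRED}]$ exactly: the two
odor patterns reduce to overlap classes $(n_{11}, n_{10}, n_{01})$ with
multinomial (or, in shuffled mode, hypergeometric) weights; each KC's joint
firing probabilities for the two odors follow by conditioning on its
connections to the shared PNs; the joint pmf of the two population counts
is built by iterated 2-D convolution; and PRED is averaged over the two
individuals' independent count pairs. The cost grows as
$O(n_{kcs}^4)$ per class, so enumeration is restricted to $n_{pns} \le 12$,
$n_{kcs} \le 60$; larger instances are directed to
`expected_pred_monte_carlo()`, which samples patterns and full connectivity
matrices by brute force (the estimator the enumeration is tested against).
Shuffled patterns give expectation 0 by symmetry, for any network size —
the same lower-bound statement the simulations make: odors must differ in
total drive, active count or rate range for stereotypy to exist.

## What the generator emulates — and what it does not

The synthetic odor panels emulate trial-averaged PN firing-rate vectors
with odor-specific identity and rate, stereotyped across individuals. They
do **not** model spike timing, oscillatory synchrony, lateral inhibition
(its effects are folded into the PN rates and the KC threshold), receptor
noise, trial-to-trial variability (responses are already trial-averaged),
or experience-dependent plasticity upstream of the KC–MBON synapse. Passing
tests therefore certify the population-arithmetic account of stereotypy —
convergence over random wiring plus response nonlinearity — not a
biophysical reproduction of any recording. Measured stereotypy in real
data is expected to be lower than the noiseless model's; adding input noise
(`noise_sd > 0`) moves the model's distribution toward experimental ranges.

## Numerical choices and degenerate inputs

* All-equal PRED rule thresholded at $10^{-12}$ relative to the largest
  squared response (exact ties in integer-valued simulations hit the rule
  exactly).
* Identical-connectivity controls can produce occasional exact integer ties
  between two odors' totals; by the all-equal rule these pairs score 0, so
  a per-iteration mean can sit marginally below 1 while every distinct pair
  scores exactly 1.
* Undefined correlations (constant vectors) are excluded and counted; a
  report whose pairs are all undefined carries `NA`, never a silent 0.
* Hill fits refuse fewer than 3 points or non-positive ratios, flag
  constant responses as degenerate, and report non-convergence with the
  starting point and residual norm.
* Infeasible spike partitions are rejected before any sampling.
* CSV output uses 10 significant digits so byte-identical reruns are a
  meaningful determinism contract.

## Problem sizes

The unit tests run the model at reduced sizes (typically 20 PNs × 200 KCs,
10–20 odors, 10–60 iterations) chosen so each directional effect clearly
exceeds its Monte-Carlo noise; the reference checks and
`scripts/acceptance.R` run the full configuration (50 × 2000, 100 odors,
100 iterations, and the full 21 × 21 grid at 100 iterations per point),
which completes in a few minutes on one CPU.

## Known limitations

* The Hill-fit summary of the convergence × randomness grid is sensitive to
  exactly how randomness is injected (per-entry vs per-KC, one- vs
  two-sided) and how the readout mask is drawn; under this package's
  design (shared mask, one-sided per-entry redraw) the ratio explains the
  grid almost completely, and the fitted $(a, b, R^2)$ should be compared
  across configurations of *this* model rather than against other
  implementations of the same idea.
* The analytical enumeration is exact but deliberately capped at small
  instances; at realistic sizes only the Monte-Carlo estimate (with its
  standard error) is available.
* `n_individuals > 2` is supported (all pairs are averaged), but the
  experiments follow the two-individual design throughout.
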