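---
title: "Models and methods behind the tojlab pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tojlab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tojlab)
```

This vignette is the package's own account of the statistics it implements:
the models, the conventions, the tunable parameters, and the choices made
where the design was genuinely open. Nothing here states an empirical result
that the test suite does not itself compute.

## The experimental design the package assumes

A temporal-order judgment (TOJ) trial presents two simultaneous motion
displays, left and right, each of which reverses direction once; the
reversal on one side is offset from the other by a signed asynchrony
$X \in \{-200, -133, -67, 0, +67, +133, +200\}$ ms (negative: the left side
lags). The observer reports which side changed first. The factorial design
crosses two motion types (radial, rotational) with two initial-direction
conditions (same, opposite) and the seven asynchronies, 20 analysis repeats
per cell: 560 analysis trials per participant, preceded by one practice
block that is retained on ingest but excluded from every statistic.
Asynchronies quantized to a 60 Hz frame clock (66.67, 133.33 ms) are
normalized to the nominal values on ingest, within a ±1 ms tolerance.

Three observer groups are built in — `percussion`, `brass`, `color_guard` —
with default sizes 25, 67, and 29, the included-cohort sizes of the study
design this package emulates.

## Sensitivity: d′ on a half-scaled z convention

Hits are "left first" responses at positive asynchronies, false alarms
"left first" responses at negative asynchronies, and

$$ d' = Z_{\mathrm{hits}} - Z_{\mathrm{FA}}, \qquad Z(p) = 0.5\,\Phi^{-1}(p). $$

The half-scaled convention makes $d' = 0.67$ the score of an unbiased
observer at 75% correct (`dprime(0.75, 0.25)`), which is also where the
psychometric threshold below is defined — the two sensitivity summaries are
deliberately commensurable. Sixteen entries are computed per participant:
for each of the four motion × direction cells, the $\pm 67$, $\pm 133$, and
$\pm 200$ ms pairs (20 trials per sign), plus a pooled entry aggregating all
60 positive against all 60 negative trials. Zero-asynchrony trials have no
objectively correct answer and never enter d′; they feed only the bias and
reaction-time analyses.

Counts of 0 or $n$ are replaced by $0.5$ and $n - 0.5$ before the
z-transform. The correction applies **only** at the extremes — interior
counts are untouched — and only for the pool sizes the design produces (20
and 60); pools of any other size indicate a malformed table and are
rejected rather than silently corrected (an `allow_any_n` escape hatch
exists for deliberately truncated designs).

## Psychometric functions and the 75% JND

For each group and motion × direction condition, each participant's
proportion of left-first responses is computed at each asynchrony, and the
group curve is the **median** across participants — medians, not means,
because the inferential machinery downstream is median-based and because
proportions near the floor/ceiling are skewed. The seven median points are
fit by unweighted least squares with the two-parameter logistic

$$ p(X) = \frac{1}{1 + e^{-K (X - X_o)}}. $$

No lapse parameter is fitted (the model has exactly $K$ and $X_o$), and no
weighting is applied; both choices keep the fitted object exactly the
two-parameter curve whose threshold has a closed form. The 75% JND is half
the asynchrony change that moves $p$ from 0.25 to 0.75:
$\mathrm{JND} = \ln(3)/K$, since $\mathrm{logit}(0.75) = \ln 3$. The test
suite verifies this closed form against numerically root-finding the fitted
curve at $p = 0.25$ and $0.75$ to $10^{-9}$ relative tolerance.

**Numerical choices.** The residual sum of squares is minimized over
$(\log K, X_o)$ — the log parametrization enforces $K > 0$ and improves
conditioning — by BFGS from a logit-linear starting value
($K_0$ from regressing $\mathrm{logit}(p)$ on $X$ with $p$ clamped to
$[0.01, 0.99]$; $X_{o,0}$ the asynchrony whose $p$ is nearest 0.5). A grid
of additional $K_0$ values ($10^{-4}$ to $1$) is always tried and the best
optimum kept, because the two-parameter surface develops plateaus when the
true curve is much shallower than the sampled ±200 ms range (thresholds of
several hundred ms are extrapolations). `nls` was deliberately not used: on
noiseless or near-step inputs both its Gauss-Newton and port algorithms
report spurious convergence failures, while multi-start quasi-Newton on the
same objective is robust across the full difficulty range the simulator can
produce. Standard errors use the usual nonlinear-least-squares
approximation ($\mathrm{cov} \approx \sigma^2 (H/2)^{-1}$ with $H$ the SSE
Hessian at the optimum), and the threshold SE follows by the delta method,
$\mathrm{SE}(\mathrm{JND}) = \ln(3)\,\mathrm{SE}(K)/K^2$. Goodness of fit
is reported as the Pearson correlation (and its square) between observed
and fitted ordinates.

## Median-statistic permutation inference

Group-level d′ distributions in this kind of data are often non-normal
(confirmed in-pipeline by a Lilliefors screen), so inference is
nonparametric and median-based.

**Pairwise group differences.** The statistic is
$\mathrm{median}(d'_{A}) - \mathrm{median}(d'_{B})$. The null distribution
comes from repeatedly re-partitioning the pooled values into the original
group sizes (shuffling group labels), 10,000 times by default. The test is
one-sided by construction: a difference is significant when it strictly
exceeds the 95th percentile of the simulated null. The p-value is the
plain rank proportion, $\#\{\text{null} \ge \text{observed}\}/n_{\rm sims}$;
the $( \#+1)/(n+1)$ convention is available behind a flag but off by
default, matching the rank-in-simulated-distribution description the
procedure implements. Strict (not non-strict) inequality is used at the
95th percentile; with continuous d′ values ties are measure-zero, so the
choice is documented rather than consequential.

**The 2 × 2 interaction.** The statistic is the contrast of cell medians
$(\mathrm{RadSame} - \mathrm{RadOpp}) - (\mathrm{RotSame} - \mathrm{RotOpp})$.
Each simulation permutes, independently within every participant, that
participant's four cell values across the four condition labels. This
preserves each individual's multiset of values exactly — consistent
individual differences survive into every simulation — which is precisely
why the test isolates the condition structure. The implementation draws
each participant's relabeling uniformly from the 24 permutations of four
labels via a precomputed table, which also makes the Monte Carlo procedure
directly comparable to the exhaustive $24^n$ enumeration oracle used in the
tests.

Both tests are fully determined by `(seed, n_sims)`. Calibration is tested
directly: under exchangeable nulls both tests reject
at $5\% \pm 1\%$ (2,000 replicates), and Monte Carlo p-values agree with
exhaustive enumeration within three Monte Carlo standard errors on
instances small enough to enumerate.

**Lilliefors screen.** The statistic is the Kolmogorov–Smirnov distance
between the sample's empirical CDF and a normal CDF with mean and SD
estimated from the same sample. Because parameters are estimated, the
classical KS null is invalid; the p-value is computed from a Monte Carlo
null table (10,000 standard-normal samples of matching size by default,
seeded). This keeps the test self-contained and directly testable; the
statistic is cross-checked against an independent analytic-approximation
implementation in the test suite.

## Reaction-time analyses

The data model's RT clock runs from stimulus offset to the response key
press. Medians are taken per participant in each of the 28 design cells,
then per group across participants. Group difference lists (one ordered
pair at a time, 28 cell-wise differences of group medians) are summarized
by their median and by the differences of smallest and largest magnitude
with signs retained — when one group is uniformly faster all differences
share a sign, and "minimum" then reads as the smallest advantage. The
chance probability that one fixed strict ordering of $g$ groups recurs in
all $c$ independent conditions is $(1/g!)^c$; at $g = 3$, $c = 28$ this is
$(1/6)^{28} \approx 1.6 \times 10^{-22}$.

Rank correlations use average ranks on ties (the standard convention) and
are Spearman correlations computed across **all** included participants
jointly within a condition — the plotted population is the full included
cohort, so ranks are assigned across groups, with per-group trendline
slopes reported separately. For RT-vs-d′ coupling, a participant's d′ in a
condition is the pooled (aggregate) entry and their RT the median over that
condition's analysis trials; d′ ranks are reversed (rank 1 = most
sensitive) so that speed–accuracy coupling appears as a positive
correlation. Between-condition consistency matrices (d′ and RT) are the
same Spearman machinery applied within groups to all six pairs of the four
conditions.

## Inclusion screening

A participant enters the analyses only if accuracy over the 480
nonzero-asynchrony analysis trials beats chance by an exact one-tailed
binomial test at $p < 0.001$ (strict). Exact tail summation puts the
minimal passing count at $k^* = 275$ of 480, i.e. 57.29% — consistent with,
and one trial below, the commonly quoted operational figure of 57.5%
(= 276/480). The package reports the exactly computed $k^*$ and leaves the
one-count discrepancy visible rather than reconciling it. Zero-asynchrony
trials never count: their "correct" answer is a coin flip designated for
feedback only.

## The synthetic-observer generator

The generator exists so every downstream stage is testable end-to-end. One
synthetic observer responds "left first" with probability

$$ P(\text{left first} \mid X) = \frac{\lambda}{2} +
   (1 - \lambda)\frac{1}{1 + e^{-K(X - X_o)}}, $$

a logistic core with a symmetric lapse floor/ceiling. The lapse enters
symmetrically so the generative midpoint stays at $X_o$ and parameter
recovery is well-posed. Reaction times are lognormal around an
observer-level base (positive support, right skew — the standard shape of
RT data) with an additive slowing at $X = 0$, emulating the empirical
slowdown when the stimulus carries no order information.

Cohort structure: each group has a target median threshold; an observer
draws a single lognormal factor that scales their threshold in **all four**
cells (so individual differences are consistent across conditions, which
the interaction test's within-participant shuffling deliberately
preserves), and per-condition multipliers impose the difficulty profile in
which radial-opposite cells are hardest and rotational-opposite slightly
easy — the crossover the 2 × 2 interaction statistic detects.

Defaults (chosen once, as the package's reference conditions):

| parameter | default | rationale |
|---|---|---|
| group sizes | 25 / 67 / 29 | included-cohort sizes of the emulated design |
| group median thresholds | 30 / 80 / 200 ms | an order-of-magnitude span, percussion < brass < color guard |
| condition multipliers | 1, 2, 1, 0.9 | radial-opposite roughly doubles thresholds; rotational-opposite slightly easy |
| threshold dispersion (sdlog) | 0.3 | lognormal spread giving realistic overlap between adjacent groups |
| bias $X_o$ SD | 10 ms | small, zero-mean: midpoints cluster at 0 |
| lapse $\lambda$ | 0.02 | a few attentional/motor errors per hundred trials |
| RT base | 400 / 474 / 540 ms | group gaps of ~74 and ~66 ms |
| RT zero-asynchrony penalty | 150 ms | visible central slowing at $X = 0$ |
| RT noise (sdlog) | 0.12 | trial-to-trial RT variability |

Two seeds govern generation — one for cohort sampling, one for trial
simulation — and both are recorded in the result's provenance and in the
pipeline manifest.

**What the generator does and does not emulate.** It reproduces the trial
bookkeeping, the logistic response structure, lapses, consistent individual
differences, the group threshold ordering, the condition crossover, and the
RT structure. It does **not** model perceptual mechanisms (attention
capture by looming stimuli, motion integration), sequential effects,
learning across blocks, or response bias beyond a static $X_o$; passing
tests therefore validate the *statistical machinery* on data with the
assumed structure, not claims about real observers.

## Problem sizes in the validation suite

The acceptance tests run: permutation-vs-enumeration agreement on 20
instances of ≤10 participants at 10,000 simulations each; type-I-error
calibration at 2,000 replicates of 500-simulation tests (group size 8);
and threshold recovery on 50 full-size cohorts (121 observers, 560 trials
each), requiring the median relative threshold error below 15% and the
generated group ordering recovered in at least 90% of seeds. These sizes
were chosen to keep the whole suite comfortably interactive while leaving
Monte Carlo error well inside every tolerance asserted.

## Known limitations

* Group-level thresholds are fit to median curves; no individual-level
  threshold fitting or adaptive-staircase support is provided.
* The fitted psychometric model has no lapse parameter, so group curves
  from high-lapse cohorts will bias $K$ slightly downward (threshold
  upward); at the default $\lambda = 0.02$ this bias is well inside the
  recovery tolerance.
* Thresholds far beyond the ±200 ms sampling range are extrapolations and
  carry large SEs; the fitter handles them, but they should be read as
  lower-precision estimates.
* No multiple-comparison correction is applied anywhere, by design; the
  permutation tests mirror the uncorrected reporting convention of the
  analysis they implement.
* The canonical CSV format is this package's own; adapters for external
  repositories' layouts are out of scope.
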