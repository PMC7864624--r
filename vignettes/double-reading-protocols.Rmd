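---
title: "Decision-fusion protocols for human-AI double reading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-fusion protocols for human-AI double reading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readfusion)
```

## The setting

Double reading with arbitration is the screening workflow in which two
readers independently interpret the same exam and a third reader is consulted
only when they disagree. `readfusion` studies what happens when the second
reader is a machine classifier: a panel of human radiologists and two
CNN-grade machine readers interpret a balanced set of 427 knee-MRI cases
(binary normal/abnormal decisions, a 5-level ordinal confidence self-report,
and a 4-level ordinal perceived case complexity), and three-reader teams
(human, machine, human) combine those readings under eight interaction
protocols. Two questions are asked:

1. Can ordinary reader teams, organized by a good protocol, outperform a
   "strong machine" that is more accurate than any individual reader?
2. Do teams of weak readers perform comparably to teams of strong readers
   under the same protocols?

The package implements the full pipeline: a calibrated synthetic panel
generator, the protocols, the team metrics, the two experiments, and the
statistical testing layer.

## The synthetic panel generator

The original annotation tables are not publicly deposited, so every analysis
here runs on synthetic panels that reproduce the published marginal
statistics and association structure. The generative model is deliberately
minimal — a two-parameter latent-difficulty model:

* Each case carries a latent difficulty $d \sim \mathrm{Beta}(2, 2)$ shared
  by all readers.
* A reader with base probabilities (sensitivity $se$, specificity $sp$) and
  difficulty slope $\lambda \ge 0$ answers a case correctly with probability
  $\mathrm{clamp}(p_{\mathrm{base}} - \lambda d,\, 0,\, 1)$, where
  $p_{\mathrm{base}}$ is $se$ on abnormal and $sp$ on normal cases.

The shared $d$ is what couples readers: all readers tend to fail the same
hard cases, which is the qualitative behaviour real panels show. Setting
$\lambda = 0$ recovers conditionally independent readers — the regime in
which the classical closed forms (majority accuracy $3p^2 - 2p^3$ for three
readers at accuracy $p$) hold, and which the tests use as an oracle.

Correctness indicators are drawn by *systematic probability-proportional
sampling* within each gold stratum rather than as independent Bernoulli
draws. Each case's marginal correctness probability is exactly the clamped
value above, but the number of correct answers per stratum is pinned to
within one case of its expectation. The rationale: the published per-reader
accuracies are fixed observed quantities of one concrete panel, and the
generator's job is to emulate *that panel*, not the sampling noise of a
hypothetical re-run. Between-seed variation in reader accuracy then comes
almost entirely from the difficulty-mean term $\lambda(\bar d - 1/2)$
(about $\pm 0.3$ percentage points), so a 427-case panel reproduces each
published accuracy to well within a point — while every per-case law, and
hence every protocol-level property, is unchanged.

The default profiles (`default_study_profiles()`) encode the published
operating points: ten humans with panel accuracies from 78.69% to 84.07%
(mean 80.77%), a MobileNet-like team machine at 81.72% accuracy, and an
InceptionV3-like strong machine with sensitivity 94.76% and specificity
76.27%. Humans share slope $\lambda = 0.25$ and are calibrated as
$p_{\mathrm{base}} = \mathrm{acc} + \lambda \,\mathbb E[d]$ so their marginal
accuracy equals the target; machines have $\lambda = 0$ so their printed
operating points hold verbatim. With balanced prevalence the human profiles
are symmetric ($se = sp$); the published tables only constrain the machines'
asymmetry.

Confidence and complexity are generated as ordinal discretizations of latent
logistic scores. Human confidence rises with correctness and falls with
difficulty — the coefficients are chosen to give the *modest* positive
confidence–success and negative complexity–success rank correlations the
study reports, not an oracle-grade confidence signal. Complexity is a noisy
monotone transform of $d$ whose mean sits near the study's reported mean
complexity (0.70). Machines have no self-report; they emit a latent
abnormality score $s$ and the package uses $2|s - 1/2|$ (quantized to the
5-level grid) as confidence and its complement (4-level grid) as complexity.
This convention is an implementation choice: how the study fed machine
confidence to the confidence-driven protocols is not documented.

Ordinal level $k$ of $L$ is always normalized as $(k-1)/(L-1)$, the unique
affine map of the level range onto $[0, 1]$. The 427 balanced cases split as
214 abnormal / 213 normal (half-up rounding). One root seed drives
everything; each reader consumes an independently derived substream, so
adding readers never perturbs existing readings.

### What the generator does *not* emulate

Real reader panels correlate through shared training, shared blind spots and
case features that a scalar difficulty cannot capture; the one-dimensional
model caps the achievable correctness correlation at roughly
$\lambda^2 \mathrm{Var}(d) / p(1-p) \approx 0.02$. Synthetic teams are
therefore *more* diverse than real ones and fusion gains are larger: the
simulated majority protocol reaches about 90% accuracy where the study
observed 87.66%. All cross-protocol comparisons here are directional and
structural — ordering of protocols, sign and significance patterns — not
numeric reproductions of the published tables, which would require the
undeposited annotations.

## The eight protocols

All protocols take the ordered team (first reader, machine second, third
reader) and produce a per-case decision plus the count of individual
judgments elicited (the denominator of efficiency). Abnormal is the positive
class throughout.

| id | rule | judgments |
|---|---|---|
| `majority` | third reader iff the first two disagree; best-of-three | 2-3 |
| `acc_weighted` | as majority, votes weighted by reader accuracy | 2-3 |
| `conf_weighted` | as majority, votes weighted by per-case confidence | 2-3 |
| `specific` | second reader iff first says abnormal; escalate on disagreement | 1-3 |
| `sensitive` | mirror image: second reader iff first says normal | 1-3 |
| `cautious` | if $|c_1 - c_2| \ge \tau$ and $(x_1+x_2)/2 \le \delta$, the more confident of the first two decides; else best-of-three | 2-3 |
| `presumptuous` | the strictly more confident of the first two decides; ties escalate | 2-3 |
| `or_rule` | abnormal iff either of the first two says abnormal | 1-2 |

$\tau$ and $\delta$ are the confidence-gap and complexity thresholds; the
study fixed them at its panel means, $\tau = 0.17$ and $\delta = 0.70$, and
those are the package defaults (`protocol_params()`). `compute_tau()` and
`compute_delta()` recompute the corresponding panel statistics for any reader
set — by default the humans only, matching the averaging coefficients of the
study's definitions (both options are exposed because the machine's
participation in those averages is not documented).

Three conventions the protocol definitions leave implicit are made explicit
here:

* **Weight ties.** Confidence weights live on a 5-point grid, so exact vote
  ties occur. They are resolved by a configurable `tie_rule`, default
  `abnormal_wins` — erring toward sensitivity, the screening-relevant
  direction. All-zero weight sums (possible since the lowest confidence level
  normalizes to 0) fall back to the simple majority of the involved readers
  and are flagged, rather than erroring.
* **Two-reader "majority".** When only two readers are involved and they
  agree, the majority of the involved readers is that unanimous decision;
  a third involvement is always decided best-of-three.
* **Cautious at an exact tie.** With $\tau = 0$ an exact confidence tie can
  satisfy the gap condition while "the more confident reader" is undefined;
  the first reader's decision is used. For any $\tau > 0$ the branch is
  unreachable.

Every protocol is verified against an independently coded brute-force oracle
on the exhaustive grid of decision triples (crossed with confidence orderings
and threshold regimes where relevant), and the reductions hold by
construction: equal weights collapse the weighted majorities onto the simple
one; $\tau > 1$ collapses cautious onto an always-escalate majority;
$\tau = 0, \delta = 1$ collapses cautious onto presumptuous away from
confidence ties.

## Metrics

Six team metrics, all reported in percent: accuracy, sensitivity and
specificity against the gold standard; *efficiency* — correct team decisions
divided by the total number of individual judgments elicited, a
workload-normalized accuracy that can never exceed accuracy; the 1-order
harmonic mean of sensitivity and specificity (the study's "F1 score"
column, named `hm_sens_spec` here); and the 2-order harmonic mean
$F_2(\mathrm{acc}, \mathrm{eff}) = 5\,\mathrm{acc}\cdot\mathrm{eff} /
(\mathrm{acc} + 4\,\mathrm{eff})$, which weights efficiency above accuracy.

Composites are always computed per team and then averaged across teams;
composing averaged ingredients generally gives a different (wrong) number.
Metrics whose gold stratum is empty are flagged `NA` rather than thrown.

## The experiments

**Experiment 1** enumerates all $10 \times 9 = 90$ ordered human pairs around
the fixed machine second reader, evaluates the eight protocols on each team,
and tests each protocol's 90 team values of accuracy, sensitivity,
specificity and `hm_sens_spec` against the strong machine's scalar with
two-sided one-sample t tests. Efficiency testing is optional (the study
reports protocol efficiencies without p-values). The Bonferroni family is
the 8 protocols within each metric, matching the visible comparison family
of the study's table; it is overridable.

**Experiment 2** ranks the humans by panel accuracy, splits them into the
five weakest and five strongest (20 teams each), and compares strong against
weak metric distributions for every ordered protocol pair with two-sample
Kolmogorov-Smirnov tests (8 × 8 matrix per metric, strong on rows), Bonferroni
family 64 per metric.

The outlier-trimming step (`trim_outlier_readers()`) reduces the original
12-reader panel to 10 by removing exactly the most and least accurate reader;
ties at either extreme are surfaced as errors rather than silently resolved.

The team-size sweep (`sweep_panel_size()`) evaluates the always-consulted
simple majority over all odd-sized human subsets from 1 to 9 readers,
summarizing mean/min/max accuracy per size.

## The statistical layer

The tests are written as the direct textbook formulas so that each is
checkable against an independent oracle:

* One-sample and two-sample t (pooled by default; the pooled form reproduces
  the study's printed df = 8 for the weak/strong reader comparison, with
  Welch available by flag). Zero-variance samples degenerate to p ∈ {0, 1}
  with a flag instead of an error.
* Two-sample KS with $D$ evaluated on the pooled sorted support — well
  defined under the heavy ties of team metrics, which are multiples of
  1/427 — and an exact two-sided p by lattice-path counting whenever both
  samples have at most 25 observations (the team samples have 20), falling
  back to the asymptotic Kolmogorov series. The exact p is verified against
  full enumeration of all $\binom{10}{5}$ interleavings at $n = m = 5$.
* Bonferroni correction $\min(1, m\,p)$, with $\alpha = 0.05$ on corrected
  p-values.

One published inconsistency is worth recording: the study prints p = 0.002
for its weak-vs-strong reader comparison, but t = 5.66 with df = 8 gives a
two-sided p of about 4.7 × 10⁻⁴. The package reports the computed value.
Similarly, the majority protocol's error under reader independence is
$3e^2(1-e) + e^3$ — second order in the individual error $e$, not the
cubic sometimes quoted; the tests assert the exact closed form.

## Problem sizes and runtime choices

The analysis scripts and tests use the study's native sizes throughout: 427
cases, 12 readers, 90/20/20 teams. Monte-Carlo checks use 200 seeds for
accuracy recovery, 100 seeds for directional protocol comparisons, and
10⁵-case panels for the independence-limit closed forms — sizes at which the
Monte-Carlo standard errors are comfortably below the asserted tolerances.

## Known limitations

* Machine operating points are fixed (no ROC modelling); the MobileNet-like
  machine's sensitivity/specificity split is unpublished, so it is modelled
  as symmetric at its published accuracy.
* The latent-difficulty model understates inter-reader correlation (see
  above), so absolute team performance is optimistic; only orderings and
  directions transfer to real panels.
* Reading time and monetary cost are outside scope; efficiency counts
  judgments only.
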