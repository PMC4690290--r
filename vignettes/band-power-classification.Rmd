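---
title: "Band-power depression classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power depression classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandsift)
library(dplyr)
```

## The problem

Resting-state EEG carries reproducible spectral differences between adults
with major depressive disorder (MDD) and healthy volunteers (HV), most
prominently in alpha-band (8–13 Hz) power. bandsift implements a complete
wrapper pipeline for turning multichannel resting EEG into a diagnostic
classifier:

1. **Spectral features** — re-reference (linked mastoids or Cz), cut the
   recording into 2-s epochs with 50% overlap, reject epochs whose amplitude
   strictly exceeds ±75 μV on any channel, and estimate per-electrode band
   power with a tapered FFT, averaged over epochs.
2. **Normalization** — per-feature min–max scaling to [0, 1].
3. **Feature selection** — a genetic algorithm (GA) searches the space of
   feature subsets; each candidate subset is scored by the held-out accuracy
   of the downstream classifier minus a penalty proportional to the selected
   fraction of features.
4. **Mapping** — the selected features are projected to one dimension with a
   Fisher linear discriminant (LDA).
5. **Classification** — a C4.5-style gain-ratio decision tree on the mapped
   feature.
6. **Evaluation** — sensitivity, specificity, likelihood ratios, predictive
   values, accuracy and per-class error counts on a held-out 30% partition.

Because the patient recordings behind the original study are not publicly
deposited, the package ships a synthetic-data generator that reproduces the
*structure* of such a study — 53 MDD / 43 HV subjects, 28 scalp electrodes,
the six classical bands, eyes-open/eyes-closed conditions — with a
controllable number of informative features and effect size. Every stage is
tested against that generator.

## The synthetic generator

`generate_feature_table()` draws band-power features from a class-conditional
log-normal model. On the log scale, feature $j$ of subject $i$ is

$$z_{ij} = \mu_j + \sqrt{\rho}\, g_i + \sqrt{1-\rho}\, \varepsilon_{ij}
          \pm d/2 \cdot [j \in I],$$

with a per-band baseline $\mu_j$, a per-subject common factor $g_i$ giving
inter-feature correlation $\rho$ (default 0.2), unit total variance, and a
standardized mean shift of $+d/2$ (MDD) / $-d/2$ (HV) restricted to the
informative set $I$. Absolute power is $e^{z_{ij}}$, hence strictly positive
and right-skewed, as empirical EEG band power is.

Why log-normal: band power is a sum of squared amplitudes and cannot be
negative; its empirical distributions are strongly right-skewed, and
ln-transformation is the standard normalizing device in quantitative EEG.
The class effect is therefore applied on the log scale, where "effect size"
has its usual Cohen's-d meaning.

Defaults follow the emulated study: 53/43 subjects, 28 electrodes, and the
four-band all-bands design (delta, theta, alpha1, beta), giving
28 × 4 = 112 feature columns per condition — the feature count of the
all-bands experiments. Tables are generated per condition because that is
how the result tables are organized; both conditions can be requested, which
doubles the columns. The default effect is d = 2.0 on 12 informative
features; that calibration makes the classification problem solvable but not
trivial (held-out accuracies in the 70–90% range) and is fixed once here, not
tuned per test.

`generate_recording()` emulates raw signals as sums of band-limited
sinusoids plus white noise: alpha amplitude dominates at rest, is halved
when the eyes open (`alpha_attenuation = 0.5`, the classical alpha
desynchronization), and is mildly elevated in MDD. The clean signal is
bounded within ±70 μV by construction so that an artifact-free recording
never trips the rejection criterion; optional artifacts are 200-ms square
pulses at ±150 μV, which unambiguously exceed ±75 μV. These recordings are
deliberately simple: no 1/f background, no volume conduction, no ocular
activity. Passing tests on them demonstrates that the *pipeline arithmetic*
is right, not that the generator is a realistic EEG simulator.

## Spectral estimation choices

* **Window.** The band-power estimator tapers each 2-s epoch with a 5%
  cosine-taper (Tukey) window by default. With half-open band edges
  (`[low, high)`, so 10.5 Hz belongs to alpha2, not alpha1), a full Hann
  window spreads exactly one sixth of an on-bin tone's power into the
  neighbouring bin across a band edge, which mislocates band-edge rhythms;
  the 5% taper keeps >97% of an on-bin alpha tone inside its own band while
  still suppressing edge discontinuities. A plain Hann window remains
  available via `window = "hann"`.
* **Scaling.** Spectra are scaled so the sum over all bins equals the
  window-corrected mean square of the epoch, $\sum x^2w^2 / \sum w^2$
  (a Parseval identity, asserted in the tests); a unit-amplitude sinusoid
  yields band power 1/2. Band power sums the one-sided spectrum over bins
  with `low ≤ f < high` and averages across epochs (a Welch-type estimate).
  Whether one sums or averages bins within a band only changes the scale of
  every sample equally and is neutralized by min–max normalization.
* **Artifact criterion.** "Exceeding ±75 μV" is read strictly: a sample at
  exactly ±75 μV is retained. Rejection is idempotent.
* **Bandpass filtering and ocular correction** of raw recordings are not
  re-implemented; the generator produces in-band signals by construction.

## Normalization and splitting

Min–max normalization maps $v' = \frac{v - \min_A}{\max_A - \min_A}
(\text{new\_max} - \text{new\_min}) + \text{new\_min}$ per feature. By
default the extremes are estimated **on the training partition only** and
then applied to the test partition, whose values may fall outside [0, 1];
they are deliberately not clipped, since the downstream tree thresholds are
monotone. `paper_mode = TRUE` instead fits the extremes on all rows before
splitting — the literal historical order of operations — for users who want
the un-firewalled variant. A constant feature is flagged and maps to
`new_min`.

Splitting is stratified (the classes are small and unbalanced):
`floor(0.7 · n_class)` training rows per class, so 53/43 gives 37 + 30 = 67
training and 29 test samples.

## The genetic algorithm

Chromosomes are bit vectors over the feature columns. Fitness is

$$\text{fitness} = \text{accuracy} - 100 \cdot
  \frac{\#\text{selected}}{\#\text{total}},$$

with accuracy (percent) measured by an **inner** stratified split of the
training partition: LDA and the tree are fitted on inner-train and scored on
inner-test, averaged over `inner_repeats = 3` splits. The outer test
partition is never visible to the fitness, preventing selection-level
leakage; `paper_mode` reproduces the literal single-inner-split reading.
Each chromosome's inner seed is derived from its own bit pattern, making
fitness a pure, cacheable function of the chromosome — converged populations
therefore cost little.

Operators are the classical trio: binary tournament selection (two uniform
draws, the fitter wins, ties by fair coin), one-point crossover (cut uniform
on 1..L−1) applied with probability 0.9, and independent per-bit flips with
probability 1/L. One elite is carried over unchanged, which makes best-ever
fitness non-decreasing (asserted in tests). A chromosome mutated to all
zeros is repaired by setting one random bit. The run stops after a fixed 50
generations (no convergence criterion is defined for this method), with a
population of 30. These hyperparameters are standard GA practice for
~100-bit problems and are all configurable in `ga_config()`.

Two consequences of the fitness penalty worth knowing:

* The penalty is 100/L points per selected feature. On small feature spaces
  it dominates and the optimum is genuinely very sparse; feature-recovery
  expectations should be calibrated to L.
* Under the single-factor correlation model, a non-informative feature
  shares the common factor with informative ones, so including it lets LDA
  cancel shared noise — selecting such features is rational, not a search
  failure. Strict informative/non-informative recovery is only expected at
  zero inter-feature correlation, and that is how the recovery test is run.

## LDA mapping

The projection is $w \propto (S_w + \lambda\,\mathrm{diag}(S_w))^{-1}
(\mu_{MDD} - \mu_{HV})$ with pooled within-class scatter $S_w$ and diagonal
shrinkage $\lambda = 10^{-3}$ by default. Scatter matrices are near-singular
when many features survive selection relative to the sample count, which is
exactly the regime the GA's early generations visit; shrinkage keeps every
fitness evaluation well-posed, and if a solve still fails, $\lambda$
escalates tenfold with a warning (pseudoinverse as last resort). The sign is
fixed so MDD projects higher and the decision threshold is the midpoint of
the projected class means. At $\lambda = 0$ the weights agree with a direct
linear solve to 1e-8 (asserted), and the projection is invariant under
invertible affine feature rescaling.

## The decision tree

A two-class C4.5-style tree on continuous features: candidate thresholds
are midpoints between consecutive distinct sorted values whose class
composition differs; among candidates with information gain at least the
mean gain of all candidates (the C4.5 guard against low-information
"chip" splits), the split with the highest gain ratio wins, with ties broken
by lowest feature index then lowest threshold. Values equal to a threshold
route left (`≤`). Leaves predict the majority class; exact ties go to MDD,
the first-listed class. Growth stops on purity, `min_leaf` (default 2) or
`max_depth`. Pessimistic pruning (off by default, confidence factor 0.25)
replaces a subtree by a leaf when the leaf's upper-confidence-bound error
estimate does not exceed the subtree's. Missing values and categorical
attributes are not handled — inputs are cleaned continuous features, and in
the pipeline the tree sees a single LDA-mapped column.

## Evaluation conventions

With A/B/C/D the true-positive/false-positive/false-negative/true-negative
counts (positive class MDD): sensitivity = A/(A+C)·100, specificity =
D/(D+B)·100, PPV = A/(A+B)·100, NPV = D/(D+C)·100, LR+ =
sensitivity/(100−specificity), LR− = (100−sensitivity)/specificity,
accuracy = (A+D)/n·100, error counts C (depressed) and B (healthy). Any zero
denominator yields the sentinel `Inf`, which result tables print literally.
Display rounding is integers for percentages and two decimals for likelihood
ratios; full precision is retained internally.

## A worked run

```{r pipeline, eval = FALSE}
tab <- generate_feature_table(synth_config(seed = 1))
report <- run_experiment(tab, experiment_config(seed = 1))
render_report(report)
glance(report)
```

On the default synthetic all-bands table this selects 50 of 112 features
(55% reduction) with held-out accuracy 86% — one draw from the stochastic
conditions the acceptance script averages over five seeds.

## Problem sizes and determinism

The shipped tests run the full pipeline at its default sizes (96 samples,
112 features, population 30 × 50 generations) for the headline checks and
smaller tables (20–100 samples, 8–28 features, reduced GA budgets) for
per-stage properties; these sizes were chosen so the whole suite exercises
every code path in minutes while keeping Monte-Carlo assertions stable.
Every stochastic stage draws from a stream derived from one master seed
(`derive_seed`), so toggling one stage (e.g. switching `mode`) does not
shift another stage's randomness, and identical seeds give bitwise-identical
runs.

## Known limitations

* The generator's recordings have discrete-line spectra plus white noise —
  no 1/f background, no non-stationarity, no ocular or muscle artifacts
  beyond injected square pulses. Results on it bound implementation
  correctness, not clinical performance.
* The tree is two-class and continuous-feature only; LDA is two-class.
* `paper_mode` exists to mirror the historical processing order
  (normalization before splitting; one inner fitness split); it is
  leak-prone by construction and off by default.
* Likelihood ratios inherit the Inf sentinel at degenerate operating points
  rather than a continuity correction.
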