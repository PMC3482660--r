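---
title: "From relative scores to molecules per cell: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From relative scores to molecules per cell: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absquant)
```

## The problem

Sequencing and mass spectrometry report *relative* quantities: reads per
feature, summed precursor intensities. Many questions — how many mRNAs does a
cell actually hold, whether one copy per cell is a meaningful expression
threshold, whether the proteome scales with cell volume — require *absolute*
molecule counts. `absquant` implements the calibration chain that converts
relative scores into copies/cell, anchored on a small set of species whose
absolute abundance is measured independently, together with the downstream
analyses built on those numbers. A synthetic-data generator reproduces the
statistical structure of the whole measurement process, so every stage can be
validated by parameter recovery against a known truth.

## The calibration model

Both arms share one model. For a feature with relative score $s$ (corrected
RPK for RNA, peptide-normalized intensity for protein) the absolute copy
number $c$ is assumed to follow a log-log linear law,

$$\log c = \alpha + \beta \log s,$$

fitted by ordinary least squares over the anchors: 49 mRNAs quantified
absolutely on a digital counting instrument (itself calibrated by external
spike-ins of known concentration) and 39 proteins quantified by heavy
reference peptides. The natural log is used internally; because the fit is
affine in log space, predictions are invariant to the log base, and a test
asserts this to 1e-12 relative.

Two deliberate choices:

* **Regression direction.** Copies are the response and the score the
  predictor, because the model's job is prediction of copies. With
  multiplicative noise on scores this inverse fit is slightly attenuated
  (errors-in-variables); the attenuation is part of the method, and accuracy
  is therefore assessed on the prediction scale (fold errors), not on the
  coefficients. The generating line of the synthetic distortion is identified
  by the forward fit, where the noise sits in the response.
* **Zeros are "not detected", not zero copies.** A zero corrected score
  carries no abundance information at the depth sequenced; such features go
  into a separate bucket rather than being assigned zone 1 or 0 copies.

The RNA arm adds two corrections before calibration: per-feature
*mappability factors* (median-centred RPK of uniform simulated reads; a
feature whose simulated score is half the median gets factor 0.5 and its
observed score is divided by it) and a *sequencibility* flag (median-centred
DNA-over-simulated ratio; ratios far from 1 mark unsequencable or
under-annotated duplicated regions). The protein arm divides each summed
intensity by the protein's census of *MS-suitable peptides*: fully tryptic
peptides (cleavage after K/R unless followed by P, zero missed cleavages)
with monoisotopic mass 700–6000 Da. Identification searches tolerate missed
cleavages, but the expected-peptide census that normalizes intensities uses
the fully cleaved set; both the cleavage count and the mass window are
arguments.

Measurement error is summarized by a bootstrap: resample anchors, refit,
predict every anchor, and report the mean of per-anchor fold errors
$\exp|\log \hat c - \log c|$. A perfect fit gives exactly 1. Under
multiplicative log-normal noise with coefficient of variation $v$ the
analytic expectation is $2 e^{s^2/2}\Phi(s)$ with $s^2 = \log(1+v^2)$ —
about 1.36 at $v = 0.35$ and 1.41 at $v = 0.4$ — and the test suite asserts
bands derived from this expectation rather than folklore values.

## Expression zones

Quantified features are stratified relative to the one-copy/cell mark:
zone 1 below 0.5 copies/cell, zone 2 from 0.5 to 2 inclusive, zone 3 above 2.
The boundaries are closed into zone 2 so that zone 2 is a closed interval;
thresholds are arguments. Features without signal form a fourth bucket.
`cumulative_share()` and `powerlaw_rank_fit()` quantify the skew of the
abundance distribution (top-fraction share and Zipf-style rank exponents).

## Cell-cycle deconvolution

An asynchronous culture averages over cell-cycle phases. For a periodic gene
with amplitude $A$ (peak/basal fold change) peaking during a fraction
$f_{peak}$ of the cycle, conservation of molecules gives

$$C_{bas} = \frac{C_{tot}}{A f_{peak} + (1 - f_{peak})}, \qquad
  C_{peak} = A\, C_{bas}.$$

Allowing a ramping fraction $f_{ramp}$ during which expression climbs in
$n_{step}$ equal increments of $A/n_{step}$,

$$C_{bas} = \frac{C_{tot}}{A f_{peak} + (1 - f_{peak} - f_{ramp}) + R},
  \qquad
  R = A\,\frac{f_{ramp}}{n_{step}} \sum_{k=1}^{n_{step}-1} \frac{k}{n_{step}}
    = A f_{ramp}\frac{n_{step}-1}{2 n_{step}}.$$

The basal-fraction term is written as $1 - f_{peak} - f_{ramp}$: the three
compartments (basal, ramp, peak) must partition the population, and this
reading reproduces both degenerate limits ($f_{ramp}=0$ recovers the
two-state model; $n_{step}=1$ gives an empty ramp sum) and an independent
brute-force check. That check, `simulate_phase_population()`, builds an
explicit population of $10^6$ cells assigned to compartments (ramp stage $k$
expressing $A k/n_{step}$ times basal) and solves for the basal level making
the population average equal $C_{tot}$; closed form and simulator agree
within the discreteness of the assignment (tested at 0.5% over a grid of
more than 100 parameter combinations, with the conservation identity at
1e-9 relative).

A gene is *switch-like* when its median basal level (across the available
per-experiment amplitudes) falls in zone 1 while the median peak level
reaches zone 2 or 3 — expression crossing the one-copy threshold rather than
merely being boosted. Amplitudes below 1 are clamped to 1 with a warning,
since an amplitude is a fold difference. `peak_length_scan()` exposes how the
switch census depends on the assumed $f_{peak}$ and $f_{ramp}$; ramping can
only add switches for amplitudes above $2 n_{step}/(n_{step}-1)$, which the
property test encodes.

## Enrichment along the abundance rank

`sliding_window_test()` slides a 200-gene window (size and stride are
arguments) along the abundance-ranked universe and tests each window's
overlap with a category by the one-sided Fisher exact test, computed as the
hypergeometric tail; p values are corrected per category with
Benjamini–Hochberg. Sidedness is a flag (one-sided over-representation by
default, since the question is enrichment); ranking ties are broken by
feature id so results are reproducible. The implementation is cross-checked
against both `stats::fisher.test` and an independent binomial-coefficient
enumeration on a systematic sweep of universes up to size 50.

## Condition comparison and volume scaling

Rod-shaped cells of diameter $D$ and length $L$ have volume
$V = \pi D^2 (L - D/3)/4$, the capped-rod formula ($L = D$ gives a sphere).
Retention between conditions is reported per cell
($100 \cdot \text{total}_B/\text{total}_A$) and per volume (per-cell divided
by the median-volume ratio $V_B/V_A$); the identity
per-volume/per-cell $= V_A/V_B$ is asserted to 1e-12. Fold-change censuses
treat ratios exactly at the threshold as "within" (uniform strict
inequality, configurable) and report single-condition detections separately.

Time-course ratios hybridized at equal RNA mass are compositional;
`correct_timecourse()` multiplies each time point by the fraction of total
RNA per cell remaining, which exactly inverts the distortion the generator
applies (the round trip is tested). `protein_mrna_ratios()` reports per-gene
protein/mRNA ratios, a sliding median along the protein-abundance rank
(`stats::runmed`), and a Wilcoxon contrast of a highlighted group against
nearest-rank abundance-matched background genes. Because it is unstated
whether a single "average amplification" factor should be the mean of
per-gene ratios, the ratio of totals, or the ratio of medians, all three are
reported.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: 5,110 protein-coding
genes (median 2.4 mRNA copies/cell, log-normal with $\sigma_{\log} = 1.6$),
1,557 lncRNAs centred at 0.1 copies/cell, rRNA totalling ~8e5 copies/cell,
49 RNA anchors, 13 spikes, 39 protein anchors, and a quiescent condition
with class-level scalings 0.18 (mRNA), 0.112 (rRNA) and 0.517 (protein) plus
per-gene log-normal jitter, with quiescent cell volume near 55% of
proliferating.

Key generator decisions, chosen once:

* **Counting law.** Read counts are Poisson with mean proportional to
  copies × length × mappability, normalized to the configured depth — the
  minimal counting model. `poisson_counts = FALSE` replaces draws by their
  expectations, the zero-noise limit used by the exactness tests.
* **Abundance law.** Log-normal per class; this reproduces a narrow range
  above one copy/cell plus a long tail, and mixing in the repressed lncRNA
  class makes the combined distribution bimodal, which the zone tests use.
  Synthetic functional categories (`translation`, `stress`, `meiosis`) shift
  gene abundance; a baseline offset is solved numerically (`uniroot` on the
  mixture CDF) so the configured median is the true mixture median.
* **Noise placement.** A per-feature multiplicative log-normal bias
  (CV 0.35) models library/capture effects on sequencing scores; nCounter
  counts carry CV 0.2 per technical replicate; MS intensities carry a
  per-protein response factor (CV 0.4, shared across replicates) plus
  per-replicate noise (CV 0.15). No instrument noise law is published for
  these platforms; the CVs are magnitudes consistent with reported replicate
  variability, and they are config arguments, not claims about any real
  data set.
* **Detection.** MS detection is logistic in log copies (midpoint 1400
  copies/cell, width 0.8), giving ~65% detected proteins spanning about four
  decades; a zero width gives the deterministic threshold needed for
  zero-noise collapse.
* **Coupling.** Quiescent truth is proliferating truth × class scaling ×
  per-gene jitter, preserving high cross-condition correlation. The
  protein/mRNA ratio is log-normal per gene, with optional logistic damping
  at high mRNA (off by default).

The generator does *not* simulate individual reads, spectra, fractionation,
library PCR, or UTR structure; passing tests demonstrate correctness of the
calibration and analysis chain under the stated statistical assumptions, not
robustness to artefacts those processes can introduce in real data.

## Numerical choices and problem sizes

Regressions use `stats::lm` (closed-form OLS inside the bootstrap for
speed); degenerate bootstrap resamples (all anchors identical) are skipped.
Zone thresholds, fold-change thresholds and the Fisher sidedness are
arguments with the defaults given above. Reported percentages are rounded to
one decimal via `percent_of()`. Unit tests run the pipeline on a reduced
genome (400 mRNAs, 120 lncRNAs, depth 2e6) chosen so the suite exercises
every stage in well under a minute, while the acceptance checks run the
full-size configuration (5,110/1,557 features, depth 2e7, $10^6$-cell
cell-cycle populations, 100-seed recovery studies).

## Known limitations

* The inverse calibration fit is attenuated under heavy score noise; for
  anchors spanning four decades at CV 0.4 this is a ~2% slope effect, well
  inside the reported fold errors, but it would grow if anchors covered a
  narrow range.
* Replicate CVs estimated from three replicates are biased low (the
  sample-SD factor $c_4 \approx 0.89$ at $n = 3$); summaries report the raw
  sample CV, as is conventional.
* `simulate_phase_population()` rounds compartment sizes, so oracle
  agreement is limited by $1/n_{cells}$ discreteness.
* The generator's quiescent condition scales classes uniformly; real
  quiescence remodels specific categories antagonistically, so retention
  statistics on synthetic data validate the bookkeeping, not the biology.
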