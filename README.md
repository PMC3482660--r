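# absquant

Absolute RNA and protein copy numbers per cell from calibrated relative
measurements.

Genome-scale assays report relative quantities — reads per feature, summed
MS intensities — but questions about the cellular economy (how many mRNAs a
cell holds, whether ~1 copy/cell is an expression threshold, whether the
proteome scales with cell volume in quiescence) need absolute molecule
counts. `absquant` implements the full calibration chain and the analyses
built on it:

* **RNA**: reads-per-kilobase (RPK) scores, mappability correction from
  simulated reads, "DNA over simulated" sequencibility flags, spike-in
  calibration of a digital-counting anchor set, and log-log anchor
  regression `log c = α + β log s` turning corrected scores into copies/cell,
  with bootstrap fold-error estimates.
* **Protein**: in-silico tryptic digestion (cleave after K/R unless before
  P), census of MS-suitable peptides (monoisotopic mass 700–6000 Da),
  peptide-count-normalized intensities, heavy-peptide anchor regression,
  replicate CVs and complex-stoichiometry checks.
* **Zones**: classification of features into abundance zones relative to the
  1 copy/cell mark (zone 1 < 0.5, zone 2 = 0.5–2, zone 3 > 2 copies/cell),
  cumulative expression shares, power-law rank fits.
* **Cell cycle**: deconvolution of asynchronous averages into basal and peak
  copies, `C_bas = C_tot / (A·f_peak + 1 − f_peak)` with an optional ramping
  term, switch-like gene classification, and scans over the phase-length
  assumptions — all verified against a discrete-population simulator.
* **Enrichment**: sliding-window Fisher exact tests along the abundance
  rank with Benjamini–Hochberg correction, and exact binomial association
  tests.
* **Condition comparison**: capped-rod cell volumes `V = πD²(L − D/3)/4`,
  per-cell versus per-volume retention, fold-change censuses,
  RNA-content-corrected time courses, protein/mRNA ratio analysis.
* **Synthetic data**: a seeded generator (`sim_config()`, `generate_*()`)
  emulating the entire measurement process, so every stage is testable by
  parameter recovery.

## Worked example

```r
library(absquant)

cfg     <- sim_config(seed = 7)          # genome-scale study conditions
catalog <- generate_catalog(cfg)
truth   <- generate_truth(catalog, cfg)

## relative measurements
reads <- generate_readcounts(truth, catalog, cfg)
simr  <- generate_readcounts(truth, catalog, cfg, type = "simulated")

## correct, calibrate, predict
scores  <- apply_correction(reads, mappability_factors(simr))
anchors <- calibrate_spikes(generate_ncounter(truth, cfg))
model   <- fit_anchor_model(scores, anchors)
model
#> <calibration_model> log(copies) = -2.4660 + 0.9902 * log(score)
#>   residual spread 0.4422 (natural log), 48 anchors

expr <- predict_copies(model, scores)
mrna <- expr[expr$id %in% catalog$id[catalog$class == "mRNA"], ]
median(mrna$copies[mrna$detected])
#> [1] 2.39567

zone_summary(mrna, universe = catalog$id[catalog$class == "mRNA"])
#> <zone_summary> universe 5110, no signal 181
#> # A tibble: 3 × 7
#>    zone     n fraction   pct n_protein protein_pct median_copies
#>   <int> <int>    <dbl> <dbl>     <int>       <dbl>         <dbl>
#> 1     1   960    0.188  18.8         0           0         0.224
#> 2     2  1302    0.255  25.5         0           0         1.05
#> 3     3  2667    0.522  52.2         0           0         7.18
#>   zone 2-3 below 10 copies: 73.9%

## cell-cycle deconvolution: a gene averaging 2.4 copies/cell with a 4-fold
## amplitude peaking during 10% of the cycle
basal_peak(2.4, A = 4, f_peak = 0.1)
#> $Cbas  [1] 1.846154
#> $Cpeak [1] 7.384615
```

The fitted slope near 1 says the corrected sequencing score is close to
proportional to copy number; the intercept converts score units into
copies/cell. The recovered median of ~2.40 mRNA copies/cell matches the
generating median (2.4) within the calibration's ~1.3-fold median error, and
the basal/peak split shows how a 4-fold periodic gene at 2.4 average copies
oscillates between ~1.85 and ~7.4 copies/cell.

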