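---
title: "Methods: genome instability scoring from plasma cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome instability scoring from plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaCNA)
```

## The measurement problem

Circulating tumor DNA is a minority admixture in plasma cell-free DNA.
At low sequencing depth individual mutations are invisible, but
chromosome-arm-scale copy-number alterations shift the *relative* read
depth of megabase windows by a factor of `1 + tf * (c - 2) / 2`, where
`tf` is the tumor fraction and `c` the tumor copy state. plasmaCNA
measures that shift bin by bin against a healthy reference panel and
condenses it into a genome-wide instability score.

## Pipeline and assumptions

1. **Binning.** Autosomes are tiled into fixed 1 Mb, 0-based half-open
   bins; the final partial bin of each chromosome is kept, so hg19
   contributes `ceiling(length / 1e6)` bins per autosome, 2897 in total.
   Sex chromosomes are excluded: their copy number differs by sex, which
   would contaminate a mixed-sex reference panel.
2. **Blacklisting.** Bins overlapping excluded regions (centromeres,
   telomeres, low-mappability intervals supplied as BED) by ≥ 1 bp are
   masked. Any-overlap is deliberately conservative: a 1 Mb bin whose
   count is even partially driven by unreliable sequence should not be
   standardized. `hg19_example_blacklist()` is a deterministic synthetic
   construction (first/last bin per autosome plus padded centromere gaps,
   163 bins) illustrating the bookkeeping; real analyses should supply a
   mappability-derived BED.
3. **Counting.** A read counts once, in the bin containing its leftmost
   aligned base, iff it is mapped, primary, non-duplicate and has
   MAPQ ≥ 60 — with BWA-MEM this keeps uniquely mapped reads. Leftmost-base
   assignment is the standard deterministic convention for shallow-WGS
   counting; at 1 Mb bins the boundary reads it reassigns are a ~0.01%
   effect. Duplicates are consumed as flags (Picard-style); each retained
   record counts once, appropriate for single-end data.
4. **GC correction.** Depth bias is a smooth function of bin GC content
   and acts multiplicatively, so the correction is the ratio form
   `raw * median(fitted) / fitted` with `fitted` from a LOESS regression
   of count on GC over usable bins. Defaults: span 0.3, degree 1,
   `family = "symmetric"` (robustness iterations downweight outlier bins
   such as focal amplifications, limiting leakage of true signal into the
   bias estimate). Requirements: ≥ 50 usable bins, non-degenerate GC;
   bins with non-positive fitted depth are demoted to unusable rather
   than producing negative corrected counts.
5. **Normalization and panel.** Corrected counts become percentages of
   the usable-bin total (sum = 100 within 1e-9), removing depth
   differences between libraries. Controls traverse the *identical*
   correction path before the panel's per-bin mean and SD are computed;
   a panel built on a different normalization would bias every Z-score.
   The SD uses the n−1 sample formula (a 14-subject panel is a sample,
   not a population; a population-SD switch is provided). Zero-SD bins
   cannot be standardized and are flagged unscorable.
6. **Scoring.** `Z_j = (pct_j - mean_j) / sd_j`;
   `I = sum(|Z_j|)` over bins with `|Z_j| > 2`, strictly — a bin at
   exactly |Z| = 2 contributes nothing and is called neutral. The strict
   threshold is applied identically in the score and the gain/loss calls
   so the two never disagree. `S = sum(Z_j^2)` over all scorable bins
   keeps every bin's contribution and is reported for comparison.

**The zero baseline.** A sample exactly equal to the panel means has
Z ≡ 0 and I = 0. A *random* healthy sample does not: with ~120 scorable
bins and standardized noise, chance excursions beyond |Z| > 2 produce a
small positive I-score (≈ 0.15–0.25 per bin with a 14-control panel,
whose estimated SDs make the Z distribution slightly heavier-tailed than
normal). The identity I = 0 is therefore a property of the exact-mean
sample, and healthy-sample I-scores should be interpreted against this
sampling baseline, not against zero.

## ddPCR copy number

Droplet partitioning is Poisson, so `lambda = -ln(1 - k/n)` copies per
droplet, and the target copy number per diploid genome is
`2 * lambda_target / lambda_ref`, assuming the reference locus (EIF2C1)
is diploid — the Poisson-corrected form used by instrument software, not
the raw positive-droplet ratio, because it remains unbiased as wells load
beyond the single-molecule regime. Saturated channels (k = n) are an
error: the rate is undefined there. Channels may differ in accepted
droplets (QC can reject different droplets per channel). Amplification is
called strictly above mean + 3 sample-SD of healthy-control copy numbers,
or a fixed externally established cutoff.

## Survival statistics

Biomarkers are dichotomized at the cohort median with ties to the low
group (matching "≤ median" table conventions; for odd N the median
subject is low) and quartiled with the same lower-boundary rule, making
both groupings rank-invariant. Kaplan–Meier medians use the earliest time
the curve reaches 0.5, with log–log confidence intervals; the log-rank
test is the standard observed-minus-expected chi-square. Cox models use
Efron tie handling (exact duplication invariance holds only under
Breslow, which is exposed as an option). The multivariable workflow
mirrors common biomarker practice: every covariate is screened
univariably and those with Wald p < 0.05 enter the joint model. Wald
binomial intervals are used for proportions (the convention behind the
printed intervals this style of analysis reports); exact binomial
intervals are available through `stats::binom.test` for small samples.
Percentiles (median split, quartiles, the healthy 90th percentile) use
R's default type-7 quantile.

## The synthetic cohort

`sim_config()` fixes the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_controls` | 14 | healthy reference panel size |
| `bin_size` | 1 Mb | the scoring resolution |
| genome | 3 × 40 Mb toy | 120 bins: smallest grid where LOESS and panel estimation behave as at genome scale, keeps the full pipeline in seconds |
| `reads_per_sample` | 900/bin | per-bin counts in the hundreds, the shallow-WGS regime |
| `dispersion` | 0.002 | negative-binomial extra-Poisson noise giving healthy-panel bin CVs of ~5%, the scale of GC-corrected 1 Mb cfDNA bins; Poisson alone would understate panel SDs |
| `cna_segments` | +1q, +8q, −1p, −4q, −8p (hg19) or half-chromosome analogues (toy) | the recurrent arm-level events of hepatocellular carcinoma |
| `tumor_fraction` | 0.2 | an advanced-disease ctDNA burden |
| `n_droplets` | 20,000 | a standard ddPCR well |
| `group_hr` | 3.5 | a strong prognostic separation, the scale reported for cfDNA biomarkers in advanced HCC |
| `baseline_median_months` | 14.8 | low-risk-group median overall survival |
| `censoring_rate` | 0.2 | moderate administrative censoring |

Counts are negative-binomial with mean
`bin_width * bias(gc) * (1 + tf * (state - 2) / 2)`, rescaled to the
target total. The simulated GC track is deterministic and *spatially
irregular* (a golden-angle sequence within [0.35, 0.55]): real bin GC
varies bin to bin, so a chromosome arm spans the whole GC range. A
spatially smooth track would confound arm-level copy number with GC and
let the LOESS absorb true signal — a coupling the generator must not
manufacture. The default bias polynomial (`-1.2 + 9 g - 10 g^2`) spans
roughly a 1.4× depth range over the simulated GC values, comparable to
uncorrected shallow-WGS bias.

Survival times are exponential; the high group's hazard is multiplied by
`group_hr`. Each subject carries an independent exponential censoring
clock whose rate is `rate * p / (1 - p)`, which makes the probability of
censoring before the event equal `p` exactly — a closed-form way to hit a
stated censoring rate. An optional shared log-normal frailty (default SD
0.5) induces the correlation between time-to-progression and overall
survival seen in real cohorts; parameter-recovery checks set it to 0,
since frailty attenuates the *marginal* hazard ratio below the
generating conditional one.

**What the generator does not emulate:** mappability structure, focal
(sub-bin) amplifications, subclonal mixtures, fragment-size biology,
read-level sequence errors, and between-run batch effects. Passing tests
therefore demonstrate the pipeline's statistical machinery — not
robustness to every artifact of real sequencing.

## The tumor-fraction dose response

Comparing mean I-scores along a tumor-fraction ladder
(`iscore_tf_battery()`) uses common random numbers: each replicate draws
one uniform stream and realizes counts at every fraction through the
negative-binomial quantile function. Because that quantile function is
monotone in its mean, the same replicate deviates at least as far in
every altered bin at a higher fraction, so the paired design removes
between-replicate noise from the comparison — the standard
variance-reduction device for ordered Monte Carlo contrasts. The
remaining noise is threshold-crossing granularity (a bin jumping across
|Z| = 2 changes the score by ~2), which sets the ~25-replicate scale at
which the smallest step (0 → 0.05, about +0.25 panel SDs in altered
bins) resolves. The detection floor is set by the panel CV: an
alteration shifts an altered bin by `tf/2` relative depth, so fractions
below roughly twice the panel CV are invisible per sample and emerge
only in replicate means.

## Numerical choices and degenerate inputs

- Strict inequalities throughout (|Z| > 2, copy number > cutoff,
  value > 90th percentile); boundary values go to the null side.
- LOESS is fit with `surface = "direct"` for deterministic, extrapolation-
  free predictions; non-positive fitted values demote bins rather than
  flipping count signs.
- Empty blacklists, empty I-score selections and all-censored groups are
  legal (no-op, 0, and "median not reached" respectively); saturated
  ddPCR wells, zero reference signal, degenerate GC tracks, all-identical
  biomarker values and off-contig reads raise errors or warnings naming
  the condition.
- All generators are pure functions of (config, seed); identical seeds
  give byte-identical outputs, and stage manifests record a config hash
  so reruns are verifiable.

## Problem sizes

Tests and the acceptance script run the toy 120-bin genome (LOESS fits
and panels at genome scale are identical code paths), 14-control panels,
25-replicate dose-response batteries, 100-replicate coverage checks, and
200-replicate ddPCR Monte-Carlo means — sizes chosen so the whole
validation suite completes in well under a minute while keeping
Monte-Carlo error a small fraction of every tested margin.

## Known limitations

- The I-score conflates tumor fraction with the genomic extent of
  alteration; it is a burden score, not a tumor-fraction estimator
  (no segmentation, ploidy or purity modelling).
- A 14-control panel estimates bin SDs with ~20% relative error, making
  Z tails heavier than normal; very large panels would sharpen the
  zero baseline.
- The example blacklist is illustrative; results on real data depend on
  a proper mappability track.
- Single-locus ddPCR assumes the reference locus is diploid in the
  sample; reference-locus loss inflates the ratio.
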