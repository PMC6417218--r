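---
title: "Predicting and measuring promoter strength with dualprom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and measuring promoter strength with dualprom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualprom)
```

`dualprom` chains two statistical procedures: a rank-based predictor of
promoter strength from multi-platform omics compendia, and a ratio
statistic that quantifies promoter (or RBS) strength from two-channel flow
cytometry of a dual fluorescent reporter. This vignette is the package's
account of the underlying models, the choices made where the procedure was
genuinely open, and what the simulation-based tests do and do not
demonstrate.

## 1. Rank-based strength prediction

Each omics platform contributes a genes-by-conditions matrix of log2
expression (microarray, RNA-seq) or abundance (proteomics) values. The
platforms are never normalized onto a common scale; instead each is reduced
to per-gene arithmetic means over its own conditions and ranked
internally. The strength classes are defined on the mean's percentile rank
`pr = rank / n` (mean rank for ties):

* **strong**: `pr >= 0.90` (top decile),
* **weak**: `pr <= 0.10` (bottom decile),
* **medium**: `0.40 <= pr <= 0.60`,
* otherwise unlabeled.

Two readings of "top 90%" are possible; we take the top-decile reading,
because the alternative (90% of all genes called strong) is inconsistent
with classes of roughly equal size and with a three-way consensus
producing tens, not thousands, of candidates. Boundaries are inclusive on
the side of the class, so `pr = 0.90` is strong and `pr = 0.40` medium.
This makes the strong set slightly larger than `0.1 n` on tie-free data
(e.g. 21 of 200 genes): a deliberate bias towards sensitivity at the
boundary.

Ties receive their mean rank. This matters for proteomics, where values
below the instrument's limit of detection are reported at a common floor:
all floor genes form one rank block and classify identically, rather than
being ordered arbitrarily.

A gene becomes a **consensus candidate** of class *c* only if it is labeled
*c* on every required platform — by default all three, matching a three-way
Venn intersection. Genes absent from a platform are excluded from consensus
(not imputed); this tolerates platforms with partial gene coverage.
Hand-picked additions (used in practice to broaden the weak range) can be
appended to the weak class and are tracked with `manual` provenance.
Hierarchical clustering is sometimes used upstream of such selections as an
exploratory view; the operational rule implemented here is the
quantile-plus-intersection rule, which is what determines membership.

## 2. Operon-aware promoter extraction

Promoters are defined operationally as the entire intergenic region between
a gene and the preceding open reading frame. Two refinements:

* **Operons.** A gene transcribed mid-operon has no promoter of its own;
  `resolve_anchor()` maps every operon member to the operon's first gene in
  transcription order, so all members share one promoter region. The operon
  table is an input (from an external operon predictor), not inferred.
* **Strand.** For a `+` anchor the region runs from one base past the
  nearest gene end to the left of the anchor start, up to the anchor start
  minus one; for a `-` anchor, the mirror image. "Preceding ORF" considers
  genes on *either* strand — the defining text says open reading frame, not
  same-strand gene. Coordinates are 1-based inclusive (GFF3 convention)
  throughout.

Degenerate cases are explicit: adjacent/overlapping ORFs raise an error
naming both genes (downstream stages never see empty sequences), and
contig-edge anchors truncate at position 1 or the contig end with a
`truncated` flag — circular-genome wrap-around is not modeled. No maximum
promoter length is imposed. Sequences are sliced with Biostrings and
reverse-complemented on `-` so they always read 5'→3' on the transcribed
strand.

## 3. The dual-reporter ratio statistic

The measurement model for one cell (event) *i* is

```
green_i = C_i · g(conc) · G · (1 + e_i)  + a_i
red_i   = C_i · R · (1 + e'_i)           + a'_i + s · green_i
```

with `C_i` the per-cell plasmid copy-number factor (lognormal, mean 1, CV
`copy_number_cv`), `G` and `R` the per-copy reporter strengths, `e, e'`
independent mean-zero Gaussian channel noises, `a, a'` exponential
autofluorescence backgrounds, and `s` the green-to-red spectral spillover.
`g(conc) = baseline + slope · conc` models an inducible test promoter over
the window in which its response is linear (0–1.0 µg/mL tetracycline);
`g = 1` for constitutive elements.

The strength readout is the **ratio of averaged means**: per-replicate
channel means, averaged across replicates, then divided. Because `C_i`
multiplies both channels, it cancels exactly from the expectation of this
ratio — the design reason for carrying the constitutive red reporter. The
across-replicate standard deviation of per-replicate ratios is reported as
the error estimate (with a single replicate it is 0 by convention, with a
warning). We use the ratio of averaged means rather than the mean of
per-replicate ratios as the headline number because that is how the
mean-fluorescence protocol composes; the per-replicate ratios still exist
internally because the SD is defined over them.

Other measurement-stage choices:

* **Compensation** inverts the 2×2 spillover matrix per event. It defaults
  to identity — ratios are computed on detector signals unless a measured
  matrix is supplied — since compensated ratios equal uncompensated ones up
  to the small spillover bias, and instrument matrices are
  acquisition-specific. Negative compensated values are clamped to 0 and
  counted (`n_clamped`), keeping channel means non-negative.
* **QC** is a flag, not an exception: samples with fewer than 20,000 events
  (inclusive boundary) are flagged and excluded from aggregation by
  default.
* **Means** are arithmetic, as "mean fluorescence intensity" without
  qualification implies; `geometric = TRUE` is available for sensitivity
  analysis.
* **RBS relative strength** is the induced minus uninduced ratio of the
  same construct; negative values are preserved, since a weak RBS can land
  within noise of zero.

## 4. Validation statistics

`linear_dose_fit()` regresses ratio on concentration by OLS and reports
`r_squared = cor(conc, ratio)^2`; a zero-variance (flat) series reports
`r_squared = 0` with a `degenerate` flag rather than `NaN`.
`prediction_correlation()` reports Pearson *r*, *r*², and Spearman ρ of each
platform's per-gene means against measured ratios; the log2-transformed
ratio is the default headline (the predictor axis is itself log2-scaled),
and both transforms are available — Spearman is identical under either,
being rank-based. No p-values are attached. `class_ordering()` checks the
qualitative prediction `mean(strong) > mean(medium) > mean(weak)`.

## 5. What the simulators emulate — and what they do not

The generators reproduce the statistical structure the analysis relies on:

* **Omics**: per-platform matrices are `latent + platform offset +
  per-condition shift + Gaussian noise`, with condition counts 109/8/4
  (microarray/RNA-seq/proteomics) matching the size structure of a typical
  public compendium, and proteomics left-censored at a detection floor of
  0.07 on its reporting scale — so sub-floor genes all report one value,
  as real peptide-count floors do. Noise SDs default to 1.5/1.0/0.8 log2
  units per platform: averaging over each platform's conditions then leaves
  standard errors of roughly 0.14–0.4, small against the
  one-log2-unit-plus separations between latent class blocks.
* **Latent strengths**: planted classes occupy disjoint uniform blocks
  (10% weak, 20% medium at the distribution's middle, 10% strong at the
  top) separated by gaps comparable to the between-class separations seen
  on real microarray scales. This idealization is what makes ground-truth
  recovery well-defined; a real genome's expression distribution is a
  continuum, where decile boundaries are necessarily arbitrary.
* **Flow events**: single lognormal-shaped modes per channel, a shared
  copy-number factor (the nuisance the dual reporter cancels),
  autofluorescence, spillover, and a linear dose response. Forward/side
  scatter, doublets, maturation kinetics and gating beyond the event-count
  rule are not simulated. The event-noise distribution is a modeling
  assumption — log-displayed single-mode histograms motivate the lognormal
  choice, but no measured distribution constrains it.
* **End-to-end coupling**: measured green strength is tied to the latent as
  `G ∝ 2^(0.4 · latent)`, giving the candidate set a ~30-fold dynamic range
  of ratios, comparable to the 0.02–0.38 spread of characterized promoters.

Consequently, passing tests demonstrate internal consistency and
recoverability under the stated noise model — they do not certify
performance on real compendia, where cross-platform disagreement is richer
than independent Gaussian noise, nor do they reproduce figure-level
correlation values that depend on unpublished event-level data.

## 6. Problem sizes and determinism

Simulation-based tests run at the sizes the procedures are specified for:
20,000 events per flow sample, triplicate samples, 1,000-gene genomes for
end-to-end recovery (10 seeds), 100 random annotations for extraction
invariants, 200 random vectors up to n = 5,000 for the classifier oracle.
Every generator takes an explicit seed, restores the caller's RNG state,
and is byte-identical for identical arguments — there is no hidden global
state, and `run_pipeline()` reproduces identical output files for an
identical config and seed.

## 7. Known limitations

* Ranking is within-platform only; no cross-platform normalization or
  operon-level expression aggregation is attempted.
* The consensus rule requires exact label agreement on all required
  platforms; near-misses (e.g. strong on two platforms, unlabeled on one)
  are not candidates. This favors precision over recall.
* Promoter extraction trusts the annotation; overlapping real ORFs can
  shrink regions to degeneracy, which is surfaced as an error rather than
  resolved.
* The dose-response model is linear by construction over the 0–1.0 µg/mL
  window; no saturation (Hill) behavior is modeled.
* Transcription start sites and −10/−35 motifs are out of scope; the
  "promoter" is an intergenic interval, not a mapped TSS.
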