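---
title: "Methods: integrating H3K9ac dysregulation, cell-type transcriptomics and homeostatic plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating H3K9ac dysregulation, cell-type transcriptomics and homeostatic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaPHP)
```

## The analysis

Amyloid-beta pathology perturbs histone acetylation at H3K9 in the
Alzheimer's disease brain, and the same patient cohorts have been profiled
both by H3K9ac ChIP-seq and by single-nucleus RNA-seq. gliaPHP implements a
reusable version of the integrative analysis that links these two layers
and carries the result into a fly electrophysiology readout:

1. **Integration.** Peaks whose H3K9ac signal is associated with amyloid
   burden (per-peak regression FDR < 0.05, strict) are collapsed to genes
   and overlapped with cell-type-resolved differentially expressed genes
   (DEGs) across six cortical cell types (Ex, In, Ast, Oli, OPC, Mic). The
   unit of analysis is the *(gene, cell type)* record, so one gene can
   contribute several records.
2. **Concordance.** For each record, the amyloid coefficient and the
   transcriptional log2 fold change either share a sign ("same sign") or
   not. The fraction of same-sign records is tested against 50% with an
   exact two-sided binomial test, and the two quantities are correlated
   (Pearson), pooled and per cell type.
3. **Cross-species enrichment.** The top-N most highly expressed
   "synaptic" genes (GO term names containing the keyword) per human cell
   type are mapped to fly homologues, and a bootstrap percentile asks
   whether those homologues are more highly expressed in fly perineurial
   glia than random expressed genes. Spearman correlations compare human
   and fly expression across the mapped pairs.
4. **Quantal PHP.** Per-cell quantal content (QC = EPSP/mEPSP) summarises
   presynaptic release. Philanthotoxin (PhTX) acutely reduces mEPSP
   amplitude; presynaptic homeostatic potentiation (PHP) is the
   compensatory QC increase that restores the EPSP. Per genotype we report
   percent-of-baseline metrics, a t-test PHP call, and genotype-level
   Spearman correlations between PHP impairment and the magnitude of the
   corresponding human gene's dysregulation.

Because the deposited patient and fly datasets are external, a
synthetic-data generator with controllable ground truth stands in for
them; every stage is tested against that truth.

## Statistical choices

**Exact binomial test.** `binom_exact_two_sided()` uses the
minimum-likelihood definition: the p-value sums the probabilities of all
outcomes no more likely than the observed count (relative tolerance 1e-7,
the convention used by `binom.test`). The source analysis says only
"two-sided"; the central (doubled-tail) variant is available via
`method = "central"`. For a symmetric null the two coincide. The exact
test is discrete: at n = 100 and alpha = 0.05 its rejection region is
k <= 39 or k >= 61 and its true size is 0.0352, not 0.05 — a property of
any exact binomial test at this sample size, visible in the package's own
calibration simulations.

**Same-sign classification.** A record with either value exactly zero is
unclassifiable and is excluded from both the numerator and denominator (a
zero has no direction). Trials are *records*, not distinct genes: the
per-cell-type record counts are what the pooled analysis reports, and the
published per-cell-type percentages are consistent with record counts.
No multiplicity correction is applied across the per-cell-type binomial
tests by default (the source analysis reports raw p-values);
Benjamini-Hochberg is available via `adjust = "BH"`.

**Correlations.** Pearson uses the t-distribution p-value. Spearman is
implemented as Pearson on mid-ranks with the same t approximation, which
handles ties without exact-test machinery and is invariant under strictly
monotone transforms. Scopes with fewer than 3 records report `NA`
correlations but keep their counts. Correlation p-values are two-sided
throughout.

**Peak-to-gene collapse.** The original study does not state how genes
annotated by several amyloid-associated peaks were resolved. The package
uses the peak with the smallest FDR (ties: largest |coefficient|, then
file order), recorded per gene alongside the number of contributing
peaks. The rule is deterministic and documented rather than guessed as a
hidden default.

**Primary cell-type assignment.** A gene that is a DEG in several cell
types is assigned to the one with the largest |log2 fold change|; an
exact tie is broken by the fixed order Ex, In, Ast, Oli, OPC, Mic, making
the assignment invariant under row permutations.

**Enrichment statistic.** The bootstrap null draws same-size gene sets
without replacement from the expressed universe (fraction expressing
> 0.01 by default; configurable) and compares mean expression. The
percentile uses a strict inequality — ties count as not-below — so a
degenerate universe cannot produce spurious 100th percentiles. An
EWCE-style specificity statistic (expression proportion relative to the
gene's total across cell types) is available via
`statistic = "specificity"`; the mean-expression form is the default
because the source describes "randomly sampled expressed genes". At the
default 10,000 bootstrap draws the percentile's standard error is at most
0.5.

**Quantal metrics.** QC is computed per cell before averaging.
Percent-of-baseline metrics are ratios of group means
(`100 * mean(+PhTX) / mean(-PhTX)`), which matches "percentage in PhTX
compared to the same genotype" and is robust to single-cell outliers; an
aggregate-QC variant (group EPSP mean over group mEPSP mean) is exposed
because the source is ambiguous on this point. The QC comparison uses a
Welch t-test by default — the source says only "Student's t-test", and
unequal variances are expected when QC roughly doubles — with the pooled
variant behind `var_equal = TRUE`. A PHP call requires both significance
and an *increase* in QC, since PHP is by definition compensatory
potentiation. Correlations with dysregulation magnitude are genotype-level
(one point per genotype).

## The synthetic-data generator

`simulation_truth()` fixes the generating parameters; its defaults are the
study conditions the pipeline is meant to recover: a record-level Pearson
correlation of 0.37 between amyloid coefficient and log2 fold change, 69%
same-sign concordance, per-cell-type record weights (35/13/5/30/5/12) and
down-regulated fractions (77% Ex, 100% In, 60% Ast, 30% Oli, 60% OPC,
67% Mic), PhTX halving the mEPSP, full homeostatic compensation in the
wild type and none in the mutant genotypes. Where the study prints no
value (e.g. Ast/OPC down fractions, amplitude noise), a single realistic
choice was made once: log-normal expression values (strictly positive,
right-skewed), truncated-normal amplitudes with a 15% coefficient of
variation around a 0.9 mV mEPSP and quantal content of 35, and a 0.8
human-to-fly homologue coverage.

**Joint control of correlation, concordance and direction.** Each
(coefficient, log2FC) record starts as standard bivariate normal with a
latent correlation `rho0`. Three deterministic-in-distribution adjustments
follow:

* *Concordance flips.* A bivariate normal with correlation `rho0` has
  same-sign probability `1/2 + asin(rho0)/pi`. To reach the target
  concordance, a random fraction of discordant records has the fold-change
  sign flipped (or of concordant records, when the target lies below the
  Gaussian value).
* *Direction flips.* Whole genes are sign-flipped (coefficient and every
  fold change together) with a probability chosen so the driving record's
  down probability equals its cell type's target. Pair flips change
  neither sign agreement nor the product `xy`, so concordance and
  covariance survive.
* *Calibration.* `rho0` is found by root-finding so that the *implied*
  record-level Pearson correlation — including the nonzero means the
  direction flips introduce — equals the target. The implied moments are
  analytic up to one 1-D Gaussian integral; the mean term of
  second-cell-type records uses a small linearised approximation, which
  enters the calibration only as a product of two already-small means.

Incompatible targets raise a parameterization error that reports the
attainable range: for example, a correlation of 0 cannot coexist with 69%
concordance (a concordant majority forces positive correlation), and 50%
concordance forces a correlation near 0.

When the concordance target equals the Gaussian-implied value and the
down fractions are 0.5, no flips occur and the pairs are exactly
bivariate normal — the regime used for the correlation-recovery
calibration experiments, where the Fisher-z interval is the right
yardstick. Away from that regime the flips make the joint distribution a
Gaussian mixture; the first two moments are calibrated, but
fourth-moment-sensitive procedures (e.g. normal-theory confidence
intervals) are only approximate there.

**Known approximations.** A gene that is a DEG in a second cell type
inherits its whole-gene sign flip from the driving record, so
second-record down fractions are pulled toward 50%; with the default 15%
multi-cell-type rate this moves a cell type's realised down fraction by a
few percentage points (visible in the generator tests, which use wider
tolerances for the defaults and tight ones for the no-multi-record case).
The ephys generator draws amplitudes as truncated normals and builds the
EPSP as `mEPSP x QC` with independent per-cell QC noise; it does not model
correlated drift within a preparation, recording-order effects, or the
mEPSP-variance changes real PhTX produces.

**What passing tests do and do not show.** The tests demonstrate that the
pipeline recovers known ground truth from data with the study's
statistical structure — they validate the estimators and their
calibration, not the biological claims, and they cannot surface artefacts
specific to real ChIP-seq/snRNA-seq processing (batch structure, ambient
RNA, peak-calling bias), which are upstream of this package's inputs.

**Reproducibility.** All generators are pure functions of
`(truth, seed)`: one user-facing seed fans out to labelled substreams
(`substream_seed()`), the caller's RNG state is never touched, and the
end-to-end pipeline writes a byte-identical summary for an identical
config and seed.

## Problem sizes

The bundled demo and the test-suite simulations use a 1,200-gene universe
(about 100 integrated records — the study's scale), 100 cells per ephys
group for calibration experiments and 12 for the demo, 500-10,000
bootstrap draws depending on context, and 100-2,000 replicate datasets
for the calibration checks (type-I error, Fisher-z coverage, enrichment
uniformity, gain recovery). These sizes were chosen so each calibration
experiment's Monte-Carlo error is small relative to the tolerance it
checks.

## Limitations

* The pipeline consumes *summary* tables (peaks with coefficients, DEG
  calls, per-cell-type expression summaries, per-cell amplitudes); it does
  not reprocess raw reads, call peaks, fit the amyloid regression, or
  detect events in voltage traces.
* The GO over-representation utility is generic (hypergeometric + BH);
  reproducing a specific curated annotation's term list is out of scope.
* Cross-species conclusions depend on the homologue map; the resolver
  keeps one fly gene per human gene (highest confidence, then
  alphabetical) and ignores paralog families.
* The exact binomial test's conservatism at moderate n (size 0.0352 at
  n = 100) is inherent to exact tests, not an implementation artefact.
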