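---
title: "Methods: validating array genotypes against sequencing and benchmark truth sets"
author: "arrayvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating array genotypes against sequencing and benchmark truth sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayvalid)
```

# The problem

BeadChip genotyping arrays call genotypes by clustering two-channel
hybridization intensities. Their failure modes are structured: assays
for rare alleles lack the homozygous-alternate exemplars needed to
build good clusters; transversions — especially between complementary
bases, where both strands report the same base pair — are harder to
resolve than transitions; probes in low-complexity sequence
cross-hybridize; wells near the physical edge of a chip degrade; and
DNA contamination silently shifts calls. Establishing that such an
array is fit for clinical screening means quantifying each of these
effects against independent truth: a benchmark call set and a
whole-genome-sequencing (WGS) re-call of the same samples.

`arrayvalid` implements that validation end to end, and ships a
synthetic-cohort generator that reproduces the statistical structure
the validation relies on, so the entire pipeline is exercised and
tested without access to controlled human data.

# Genotype representation

A call is an unordered pair of allele indices over the reference
(index 0) and up to three alternate alleles (1–3): ten possible
genotypes, plus a missing code for no-calls. Phase is discarded on
input (`0|1` and `1/0` both become `0/1`): the classification below is
defined on unordered genotypes, and array calls are unphased anyway.
Datasets are harmonized before comparison: loci are matched on
(chromosome, position, reference allele, alternate-allele *set*), and
a dataset listing the same alternates in a different order has its
genotype codes rewritten through the allele permutation. Loci with
conflicting reference alleles, mismatched allele sets, or missing from
any dataset are excluded and counted — no left-normalization of indels
is attempted, so only exact-representation matches compare.
Chromosome X and other non-autosomes are excluded from metric scopes
by default (genotype representation differs too much between platforms
to compare naively); the restriction is a flag, not a hard rule.

# Classification and metrics

Each test-vs-truth pair receives exactly one of six labels: `tn`
(both hom-ref), `tp` (equal with an alternate allele), `fp` (test has
an alternate, truth hom-ref), `fn` (the converse), `x` (both carry
alternates but differ — e.g. `0/1` vs `1/1`), `na` (either missing).
The pivotal convention is that alternate-containing mismatches are
`x`, not fp or fn: false positives/negatives are reserved for
disagreements about the *presence* of variation. With counts
$a,b,c,d,z$ of tp, fp, tn, fn, x:

$$C = \frac{a+c}{a+b+c+d+z},\quad S = \frac{a}{a+d},\quad
P = \frac{c}{c+b},\quad \mathrm{PPV} = \frac{a}{a+b}.$$

Discordant `x` pairs depress concordance (they sit in its denominator)
but touch neither sensitivity nor PPV; `na` pairs are reported but
enter no formula. Any zero denominator returns `NA` rather than a
value — a locus with no alternate calls has no defined PPV. Swapping
test and truth exchanges fp↔fn and fixes the other classes, so
concordance is symmetric while S and PPV trade roles; replicate
pairwise concordance exploits this symmetry.

WGS calls act as truth only above a confidence floor — depth ≥ 20 and
Phred quality ≥ 30 by default, both configurable — and assays
genotyped in fewer than 90% of WGS samples are excluded from
WGS-involving comparisons, since a sparsely covered assay's PPV is an
artifact of which samples happen to be called.

# Quality control

Per sample × replicate the pipeline computes:

* **Call rate** — non-missing calls over cluster-QC-pass assays.
  Assays failing cluster QC are no-calls by construction and are kept
  out of the denominator. Flag `LOW_CALL_RATE` at ≤ 0.98.
* **p10GC** — the 10th percentile (linear interpolation between order
  statistics, `quantile` type 7; the estimator is not prescribed
  anywhere authoritative, so the R default is used and documented) of
  per-call GenCall-like scores over called genotypes.
* **Het/hom ratio** — heterozygous over homozygous-alternate calls,
  autosomes only; `NA` (not an error) when a sample has no hom-alt
  calls. Under Hardy–Weinberg at frequency $q$ this tends to $2pq/q^2$.
* **Contamination** $\hat\alpha$ — see below. Flag `CONTAMINATED` at
  $\hat\alpha > 0.025$, chosen so the 1%-scale background separates
  cleanly from the ≥ 3–4% regime that visibly damages calls.
* **Replicate z-scores** — each call rate standardized by the global
  mean and SD across all sample × replicate records; flag `Z_OUTLIER`
  at $z \le -4$, with $-3$ the documented conservative alternative.
  A zero global SD yields all-zero z-scores.
* **Dispersion** — for each sample's three replicate call rates, the
  population variance (denominator 3) around their mean. The estimator
  choice matters at this scale and is deliberately the population
  form; it is invariant to replicate order.
* **Chip-position aggregation** — mean/SD/min/max of the metrics per
  (row, column) well, with `EDGE_WELL` marking first/last rows and
  columns (on a 12 × 2 chip every well sits on an edge column; the
  informative signal is the bottom rows).
* **PCA structure check** — genotypes coded as alternate-allele dosage
  0/1/2, missing calls mean-imputed per locus, all-missing loci
  dropped with a warning, loci subsampled to ~10,000 under a fixed
  seed, columns centered, `prcomp`. No LD pruning is performed — the
  check is for gross population structure and batch artifacts, not
  fine-scale inference, and a screening panel's LD structure is mild
  at 10k random assays.

## Contamination model and estimator

Contamination is modeled as two-sample DNA mixing expressed purely
through B-allele frequency: a sample with mixing fraction $\alpha$
has, at a truly homozygous locus, expected BAF displaced from its pole
by $\alpha$ times the population frequency of the unobserved allele
(hom-ref: $\alpha p$; hom-alt: $1 - \alpha(1-p)$). Writing $d_i$ for
the observed displacement and $q_i$ for that frequency, the estimator
is the least-squares fit through the origin

$$\hat\alpha = \frac{\sum_i d_i q_i}{\sum_i q_i^2},$$

over homozygous called genotypes, clamped to $[0,1]$, and undefined
(`NA`) below 100 usable homozygous calls. Intensity channels are not
modeled: BAF displacement is sufficient to exercise and test the
estimator. The upstream method this follows is intensity-likelihood
based and published only in outline; this re-derivation keeps its
principle (mixing moves homozygous BAF toward the population
frequency) in closed form.

A subtlety drove the simulator's noise model: BAF is bounded at 0 and
1, and truncating additive Gaussian noise at the poles gives every
clean homozygous call a small positive displacement. Because the
estimator divides by $\sum q_i^2$, a rare-variant-heavy panel
amplifies any constant offset (the effective factor
$\bar q/\overline{q^2}$ is ≈ 3 here), and a plausible-looking 0.02
additive noise SD inflates $\hat\alpha$ by ~0.024 on clean samples.
Real homozygous clusters are tight at the poles with spread roughly
proportional to displacement, so the simulator uses multiplicative
noise on the displacement (SD 0.15 of the displacement) plus a small
additive term (SD 0.002), with the wider heterozygous cluster (SD
0.03 around 0.5) kept separate. Under this model recovery is unbiased
to ~0.003 at the default panel, and the acceptance suite verifies
$|\hat\alpha - \alpha| \le 0.01$ for $\alpha \in \{0.01,\dots,0.05\}$
over 20 seeds per level at the default 10,000-assay panel — at much
smaller panels the estimator's sampling variance alone exceeds that
band, which is a property of the estimator, not of the
implementation.

# The synthetic cohort

`simConfig()` fixes the study conditions; `simulateCohort()` draws
truth genotypes, triplicate array call sets, and an independent
WGS-like call set, all deterministically from one seed (stages use
seed, seed+1, seed+2 so each stage is independently reproducible).

**What is emulated, and the defaults.** A cohort of 263 samples
genotyped in triplicate; assays targeting a 13-bin
alternate-allele-frequency spectrum weighted like a genome-wide
screening manifest (rare-heavy: ~26% of assays under 1% AF); 99.3%
SNV assays with 79.6% transitions and ~8% of transversions between
complementary bases; 8% of assays failing cluster QC (treated as
no-calls); truth genotypes drawn independently per sample under
Hardy–Weinberg at each locus's frequency (multi-allelic assays split
the alternate mass equally); a base no-call rate of 0.0017; per-call
miscall probabilities of order $10^{-4}$ (het→hom 2e-4, hom→het 1e-4,
false-positive at hom-ref 5e-5, false-negative 1e-4), multiplied
upward in the hard strata (transversions ×2, complementary
transversions ×4 further, insertions ×10, deletions ×20,
multi-allelic ×5, low-complexity ×3) so stratified analyses have
signal in the expected direction; GenCall-like scores Beta-distributed
(concentration 12) with mean declining linearly from 0.763 in chip
row 1 to 0.720 in row 12 — calibrated once so the per-row 10th
percentile sits near 0.60 and 0.55 respectively, the regime a
degraded bottom row shows; an extra no-call rate (default 0.01) in
the bottom two rows of column 1, producing edge-well z-score
outliers; contamination per the configured schedule, with a
contaminated replicate also suffering extra no-calls (1.5α — the
package's own coupling, since contaminated samples empirically lose
call rate too); and a WGS-like call set with negative-binomial depth
(mean 37, size 40), truncated-Gaussian Phred quality (mean 60, SD 15),
a 5e-5 genotype error rate, 0.002 background missingness and 0.5% of
assays systematically dropped in half the samples (so the WGS-coverage
filter has real work).

Error events are mutually exclusive per call and applied in a fixed
order — no-call first, then the miscall appropriate to the truth
genotype — which avoids ambiguity when probabilities would co-occur.
The chip is 12 rows × 2 columns (24-sample format), filled
column-major, configurable.

**What is not emulated.** Raw intensities and cluster files (cluster
pass/fail is consumed as a flag); read-level sequence data; linkage
disequilibrium between loci (genotypes are independent across loci,
so the PCA check sees population structure only if you construct
divergent cohorts); relatedness between samples; indel representation
ambiguity (the simulator always writes one canonical representation);
batch structure beyond the chip-row gradient and the contamination
schedule. Passing tests therefore demonstrate that the *pipeline*
measures what it claims under the stated generative model — they do
not certify any physical array.

**Default panel size.** The default is 10,000 assays, not the 6 × 10⁵
of a real manifest: it is the scale at which the structure checks are
already stable, and it keeps every stage fast enough to run hundreds
of times in the test suite. One visible consequence: per-sample
replicate concordance at ~9,200 eligible calls carries Poisson noise
of a few discordant calls, so a clean sample whose true pair
concordance is ~0.9993 can fall below 0.999 by chance; at full
manifest scale the same error model concentrates virtually every
clean sample above 0.999. The acceptance property for replicate
reproducibility therefore runs a 20,000-assay, low-error
configuration where the ≥ 99%-of-samples claim is a property of the
model rather than of sampling noise.

# Numerical and edge-case conventions

* **AF bins** are upper-inclusive with a closed first bin:
  $[0, 0.001]$, then $(l, u]$ — interval notation dictates that a
  frequency exactly at an edge belongs to the bin it closes (5% is in
  (1–5%]). An exhaustive edge sweep is part of the acceptance suite.
* **BED intersection** is 0-based half-open: a 1-based locus position
  $p$ is flagged iff $p-1 \in [\mathrm{start}, \mathrm{end})$.
  Low-complexity classes are independent and may overlap.
* **Percentages** for summary tables round half away from zero
  (`percentSummary`), matching how printed tables round, not R's
  banker's rounding.
* **Undefined metrics** (zero denominators, too few homozygous calls,
  no hom-alt calls) are `NA` sentinels; configuration errors (negative
  depth, probabilities outside [0,1], mixing fractions ≥ 1, spectra
  not summing to 1) fail fast with the offending field named.
* **MNVs** (equal-length multi-base substitutions) fit none of the
  four variant classes and are labeled and excluded with a warning
  rather than forced into one.
* **Determinism**: with a fixed seed, simulation, pipeline and all
  writers are byte-identical across runs; numeric per-call fields are
  written at fixed precision (scores and BAF at 4 decimals, generated
  at that precision) so files round-trip losslessly.

# Pipeline assembly

`runValidation()` chains the stages and applies one global exclusion
rule: sample × replicate records flagged `CONTAMINATED` or `Z_OUTLIER`
are removed from headline metric tables and reported separately. The
underlying study reports excluding contaminated samples from some
summaries without stating a global rule; making the rule explicit and
configurable seemed better than reproducing an ambiguity. Per-assay
tallies are pooled across the kept replicates before stratification,
and the three-way table cross-classifies assays by whether the array
and WGS each hold PPV = 1 against the same truth. Every stage appends
a structured log record so each reported count is traceable, and
`writeReport()` emits the tables with stable column order.

# Known limitations

* The contamination estimator is a closed-form re-derivation of a
  BAF-mixing principle, not a reproduction of the original
  intensity-likelihood method; its absolute calibration on real
  intensity data is untested here.
* Indels compare only under exact representation; left-normalization
  and haplotype-aware comparison are out of scope, so disagreeing
  representations are excluded rather than reconciled.
* The full classification grid behind the six labels was reconstructed
  from its category definitions; two further labels that appear in the
  source material's footnote ("f"/"t") have no visible definition and
  are not implemented.
* Hardy–Weinberg testing, Mendelian/pedigree checks, sex checks and
  relatedness are deliberately absent: the framework validates
  individual-sample genotyping, and those checks belong to downstream
  analyses.
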