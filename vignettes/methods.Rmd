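---
title: "Detecting TE gene traps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TE gene traps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrap)
```

## The problem

Transposable elements (TEs) inserted into introns on the sense strand of a
host gene carry cryptic splice sites and polyadenylation signals. When the
RNA-binding proteins that normally shield these sequences are depleted, an
intronic TE can be exonized (spliced into the mature mRNA) or act as a
gene trap: a cryptic splice acceptor plus a premature polyadenylation site
truncates the host transcript, which manifests as downregulation of the
exons downstream of the insertion. `tetrap` implements the computational
side of this biology as a reusable pipeline: strand-aware repeat
enrichment of RBP peak sets, differential usage of intronic peaks with
pre-/post-peak gene fragmentation, splice-junction analyses including an
intron-centric splicing index, long-read 3'-end alternative
polyadenylation (APA) calls, and peak-space clustering reports — together
with a synthetic-data generator that plants every effect the pipeline is
supposed to find.

## Coordinate model

All intervals live in `GRanges` (1-based, closed), the standard container
of the Bioconductor ecosystem; a single internal convention avoids
off-by-one drift between modules. Formats using other conventions are
converted only at the I/O boundary: BED is 0-based half-open, GTF and
repeatMasker `.out` are 1-based inclusive, and the repeatMasker "C" strand
code maps to `-`. The exported `gi()` constructor takes BED-style
coordinates, which keeps examples and tests readable next to files on
disk.

Genes are flattened exon unions — the package has no transcript-isoform
model, because every analysis it implements operates on flattened genes.
Overlapping genes are flattened independently of each other; a peak or
junction contained in more than one flattened gene is treated as
ambiguous rather than resolved.

## Priority fragmentation

`fragment_by_priority()` labels every base of a gene footprint with the
highest-priority feature covering it (typically exon > repeat > intron,
or exon > peak), producing the disjoint counting references used for
fragment-level binding quantification. The implementation is an integer
breakpoint sweep: all candidate segments are clipped to the footprint,
elementary segments between breakpoints are labeled by the best covering
candidate, and equal-labeled neighbours are merged. Within one priority
level, the feature earlier in genomic order wins overlapping bases; this
tie-break is arbitrary but deterministic. Tests compare the sweep against
a literal per-base oracle on thousands of random instances.

## The statistical engine

The differential machinery is intentionally compact and fully in-package:

* **Size factors** are median-of-ratios: per sample, the median over
  features (positive in all samples) of the count divided by the
  feature's geometric mean.
* **`nb_wald_test()`** models counts as negative binomial. Per condition
  the mean is estimated on normalized counts; the Wald statistic for the
  log2 fold change uses the delta-method variance
  `(1/mu + alpha)/n` per condition. With `lfc_threshold > 0` the null is
  the composite |log2FC| below the threshold, the form used for
  differential-gene calling with `lfcThreshold`-style semantics.
* **Dispersion.** The default estimator is a cohort-pooled
  method-of-moments ratio: the summed moment numerators `(s^2 - mu)`
  over the summed denominators `mu^2`, across all features and both
  conditions. At 2-3 replicates per condition, per-feature moment
  estimates are so noisy that a normal-reference Wald test becomes badly
  anticonservative (empirical type-I error near 0.12 at nominal 0.05 in
  our 3 vs 3 null simulations), while switching the reference to a
  t distribution restores calibration only by sacrificing most of the
  power against planted twofold effects. The pooled estimator is nearly
  unbiased, and with it the normal-reference test is both calibrated
  (type-I error near 0.05, p-values uniform under the null) and powered.
  The cost is the assumption of a shared dispersion across the feature
  cohort — adequate for the synthetic cohorts generated here and for the
  threshold-based classifications the pipeline makes, but cruder than
  the per-feature empirical-Bayes machinery of the large DE frameworks.
  `disp_mode = "per_feature"` restores the classical per-feature
  estimator (with a pooled fallback where the variance falls below the
  mean) for heterogeneous data. There is deliberately no shrinkage of
  fold changes; classifications threshold raw log2 estimates.
* **`relative_usage_test()`** tests a feature's share of its group total
  (an intronic peak or a junction within its host gene). Shares are
  computed on normalized counts with a 0.5 pseudo-count; the effect is
  the difference of mean log2 shares, and the variance is the larger of
  the empirical replicate variance and an NB-propagated analytic floor,
  so features with accidentally identical replicates are not reported
  with zero uncertainty. Because downstream classifications require both
  a small adjusted p *and* a large effect (log2 share change above 2),
  the usage test's false-positive side is additionally guarded by the
  effect threshold; the end-to-end precision property tests this
  directly.
* **`bh_adjust()`** delegates to the standard Benjamini-Hochberg step-up
  after validation; **`chi2_odds_ratio()`** is the closed-form Pearson
  statistic (no continuity correction by default) with the
  Haldane-Anscombe 0.5 correction applied, and flagged, only when a cell
  is zero.

## The exonization scan

The scan follows the published recipe: RNA-seq reads are counted on
annotated exons and on intronic peak fragments (exon-overlapping peak
parts are masked); every intronic peak is tested for differential usage
within its host gene; per gene, the peak with the smallest raw p-value
becomes the reference peak; exons strictly 5' of the reference peak (in
transcription direction) form the *pre* fragment and exons strictly 3'
the *post* fragment; both aggregates are tested for differential
expression; and genes are classified as

* **upregulated** — reference peak adjusted p below 0.05 and usage log2
  fold change above 2;
* **control** — adjusted p above 0.05 and effect inside (−0.5, 0.5);
* **other** — everything else, including filtered peaks.

"Log-fold change" thresholds are interpreted on the log2 scale (the
statistic's natural scale here) and are configurable. Exons overlapping
the reference peak span belong to neither side. A gene record that
extends beyond the terminal exons admits a reference peak 3' of the last
exon, which yields an empty post fragment (flagged, gene retained). Ties
in the reference-peak p-value are broken by smaller genomic start, then
peak id.

## Junction analyses

Junctions use the `SJ.out.tab` dialect (1-based first/last intronic
base); donor and acceptor positions are strand-oriented. The splicing
index of a junction at a site is its share of all junction reads using
that donor (or acceptor); shares sum to one per site by construction.

The stringent tissue-panel filter applies, in order: tissue inclusion
(at least 10^9 spliced reads), unambiguous host gene, annotated donor,
acceptor inside a fully intronic peak, donor used by at least two
junctions, splicing index above 1% in at least one tissue, and donor
support of at least 500 reads in every included tissue. Donor
multiplicity, splicing index and donor support are computed on the full
tissue-included panel; each junction is attributed to the first rule it
fails, and the attrition table records the sequential drops. Two
readings were genuinely open: whether the 500-read support applies to
the donor or to the junction (default: donor, the ubiquitous-usage
reading; `support = "junction"` selects the other), and whether the
splicing index is computed per sample or per pooled tissue (the panel
filter consumes per-tissue counts).

The splice-site strength survey is scorer-agnostic: any function mapping
a position to a score in [0, 1] can be plugged in (a neural splice model
adapter in production; the package ships a toy hexamer log-odds scorer
for tests). Candidates are AG (acceptor) or GT (donor) dinucleotides on
the site's strand within a 500 nt window; the survey reports the novel
site's score, the window's best candidate, and a seeded random sample of
candidates.

## Alternative polyadenylation

Single-base 3'-end coordinates are padded by 50 nt on both sides and
collapsed per chromosome and strand into putative polyadenylation
regions; every input end lies in exactly one region. Region counts per
condition give per-gene isoform fractions, and a gene is called
differentially polyadenylated when it has at least 20 reads (both
conditions pooled — the configurable default reading of "supported by at
least 20 reads") and some region's fraction shifts by at least 20
percentage points. Both thresholds are inclusive: a gene with exactly 20
reads and an exact 20-point shift is called. Regions are assigned to
genes by midpoint containment on the same strand; fractions are raw
read-count ratios, without length or depth normalization.

## Peak-space clustering

The unified peak-by-profile count matrix is column-standardized
(population standard deviation; constant profiles become zero columns
and are flagged). Embedding and clustering are injected dependencies
behind a two-function interface — the package defaults are a PCA
embedder and a k-means clusterer with 0-based labels (−1 reserved for
noise), and any manifold embedding or density clusterer with the same
shape can be substituted. The scientific outputs are the per-cluster
reports: provenance (exclusive and participating source fractions,
shared-peak fraction) and TE composition relative to the full peak
universe. Tests validate cluster *composition recovery* on planted
simulations, not any particular algorithm's geometry.

## The synthetic-data generator

The generators define the study conditions under which the pipeline is
validated:

* 500 genes on one toy chromosome, 4-8 exons each (median exon ~150 nt,
  median intron ~1.6 kb), both strands.
* TE insertions in 80% of introns (median ~800 nt, clipped to the
  intron), split between L1 and Alu, half sense / half antisense — TEs
  occupy roughly half of the intronic space, and per-family-orientation
  classes each hold well over 100 kb, large enough for stable fraction
  estimates. With sequences enabled, sense-TE bodies are adenosine-rich
  (A = 0.42 by default, emulating the composition of L1 ORFs).
* One intronic peak per gene (placed inside a TE when the chosen intron
  has one); NB counts with mean 100 per exon, dispersion 0.1, baseline
  peak signal 5% of the gene mean, 3 replicates per condition.
* Planted exonization in 10% of genes: treatment peak signal times 8,
  post-peak exon means times 0.5, plus a novel junction into the peak.
* Planted polyA switches in 15% of genes: a 30-percentage-point shift
  from the distal to the proximal isoform. The default of 600 reads per
  gene per condition estimates isoform fractions to about ±3 percentage
  points, so a 30-point planted switch sits ten standard errors from the
  20-point call threshold and recovery is deterministic in practice.
  Read ends are jittered by up to 10 nt, always inside the ±50 nt
  collapse radius.
* Peak-profile matrices with 3 planted clusters of 300 peaks over 6
  profiles (dominant-profile mean 200 vs background 5); 10% of peaks are
  attributed to a two-profile shared source set.

Each generator seeds the RNG from `spec$seed` plus a fixed per-component
offset and restores the caller's RNG state, so outputs are byte-identical
across reruns and components are independently reproducible.
`sample_peaks_preferential()` places peaks over gene bodies with a
per-base coverage multiplier for a chosen (family, orientation) class;
its single-base default keeps the realized coverage equal to the
multiplier times the genomic fraction (wider peaks would saturate under
interval merging).

What the generator does *not* emulate: read-level data (counts are drawn
directly, so alignment and counting artifacts are out of scope),
dispersion heterogeneity across genes, correlated TE nesting, overlapping
gene models, internal-priming artifacts in 3'-end data, and
batch effects. Passing tests therefore demonstrate that the algorithms
recover planted effects under clean NB noise at realistic sizes — not
that they are robust to every pathology of real libraries.

## Problem sizes and numerical choices

The validation suite uses 1,000 random instances per interval-algebra
oracle, 5,000 features for test calibration, 20,000 sampled peaks for
enrichment recovery, 500 genes for the exonization scan and 200 genes
for APA — sizes chosen so each property is measured with comfortable
statistical margin while the whole suite runs on a laptop. Dispersions
are floored at 1e-8; zero-count fold changes use a 0.5 pseudo-count;
degenerate enrichment ratios carry explicit ±Inf/NaN sentinels and a
`degenerate` flag; empirical p-values use the add-one rule. All
classification thresholds default to the published values (read filter
10; peak padj 0.05 and log2 fold change 2; control band ±0.5; APA pad
50 nt, 20 reads, 20 points; panel splicing index 1%, donor support 500,
tissue floor 10^9; survey window 500 nt) and are configurable in
`pipeline_config()`.

## Known limitations

The pooled-dispersion Wald test trades per-feature adaptivity for
small-sample calibration, as discussed above. Host-gene assignment uses
strict containment by default (configurable to any-overlap); real
overlapping gene annotations will leave more features ambiguous than the
simulated non-overlapping models do. The stringent panel filter's
chained rules are evaluated on the full tissue-included panel rather
than re-evaluated after each drop; on panels where one rule's outcome
depends on another's survivors the attrition attribution is the
first-fail reading documented here. The clustering module ships simple
default algorithms; claims about density-based cluster shapes require
plugging in the corresponding algorithms.
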