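---
title: "Methods: spatial localization and metabolic-labeling analysis of maternal transcripts"
author: "tomoslam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial localization and metabolic-labeling analysis of maternal transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoslam)
```

# Scope

`tomoslam` implements the computational core of a maternal-mRNA study design
in early embryos: (i) where maternal transcripts sit along the
animal-vegetal axis of the one-cell embryo (serial-section "tomo-seq"
count data, self-organizing-map profile clustering, multi-replicate
localization calling), (ii) which transcripts detected later in development
are maternal rather than zygotic (per-UMI T-to-C metabolic-labeling
classification with an analytic false-negative model), (iii) which cell
types inherit the maternal transcripts of localized genes (cell-type fold
changes, two-component Gaussian deconvolution, enrichment tests), and (iv)
what distinguishes the 3'UTRs of localized transcripts
(expression-weighted length statistics and discriminative k-mer
enrichment). Every input has a seeded synthetic generator with known ground
truth, so the full pipeline is testable without any sequencing data.

# Tomo-seq processing

A `SectionCounts` object holds raw gene x section counts of one replicate
(sections ordered 1 = animal pole to S = vegetal pole) plus summed ERCC
spike-in counts per section. Processing follows four steps, each a separate
function so intermediate objects can be inspected:

1. **Section QC** (`qcSections`): sections with poor spike-in recovery
   failed library preparation and are dropped. The threshold is either an
   absolute count (default 8000 transcripts) or a fraction of the library's
   mapped reads (e.g. 0.04%); both conventions are in use because the
   appropriate absolute cutoff scales with sequencing depth.
2. **Gene filter** (`filterGenes`): genes that never reach 5 counts in any
   section carry no usable spatial signal. The rule is "keep iff the
   maximum per-section count is at least `minCount`" -- the reading under
   which the filter removes only shallow genes rather than nearly all
   genes.
3. **Normalization** (`normalizeSections`): counts are divided by the
   section's total endogenous counts and rescaled to the median section
   total, so every retained section contributes the same mass. Spike-ins
   are excluded from the totals by default (`includeSpikeins = FALSE`):
   they calibrate recovery, not biology; the choice is exposed because
   either convention is defensible.
4. **Traces** (`cumulativeTraces`): the running animal-to-vegetal sum of
   each gene's normalized profile, scaled to end at exactly 1. Cumulative
   traces are monotone, bounded, and insensitive to single-section jitter,
   which is what makes them good SOM input. All-zero genes are flagged and
   excluded from training.

Conservation holds exactly: after normalization every section total equals
the median raw section total, and every nonzero cumulative row ends at 1.
`zscoreByGene` (population sd, constant rows to zero) reproduces the
per-gene scaling used for profile heatmaps, and `correlateReplicates`
computes Pearson correlation of log1p per-gene totals between replicates
(log scale because totals span orders of magnitude).

# SOM localization calling

`trainSom` fits a 1 x 50 linear Kohonen map to the cumulative traces:
winner by Euclidean distance, Gaussian neighborhood on the node grid,
learning rate (0.5 to 0.01) and neighborhood width (10 to 2) decaying
linearly over 50 epochs, genes presented in a seeded shuffled order. Two
design choices depart from textbook SOM training, and both exist to make
node indices interpretable as *occupancy quantiles* along the axis -- the
property that windowed calling rules ("profiles 46-50") implicitly assume:

* **Density-matched initialization.** Node j starts as the mean trace of
  the j-th centroid-rank bin (equal-size bins of genes ranked by the
  centroid of their trace increments). This starts the map at exactly
  proportional node allocation.
* **Conscience bias.** Plain Kohonen training drifts toward allocating
  extra nodes to tight isolated clusters (its magnification law), which
  inflates the node range a localized gene class occupies. Winner selection
  therefore subtracts `conscience * (1/n - winFreq)` from the squared
  distances (a DeSieno-style frequency-sensitive term, default
  `conscience = 40` for traces in [0,1]). The bias is small relative to
  between-cluster distances and large relative to within-cluster
  quantization error, so it equalizes node utilization without mixing
  distinct profile shapes. The final neighborhood width of 2 keeps
  prototypes within one profile cluster nearly identical, so the exact node
  a gene lands on within its cluster is driven by replicate noise rather
  than by persistent gene-level traits -- this is what lets the "at least
  48 in one replicate" relaxation of the calling rule do its job across
  replicates. Setting `conscience = 0` recovers plain Kohonen training.

After training, prototypes are projected back to valid cumulative traces
(`cummax`, rescale to end at 1). `orderNodes` sorts nodes by prototype
centroid so indices run animal to vegetal. Training cannot know which
physical end is which, so when per-section raw totals are supplied the map
is flipped if the heavy end of the library -- the blastodisc at the animal
pole -- sits at high section indices; this makes final calls invariant to
reversing the section order of all inputs.

`assignProfiles` is pure nearest-prototype assignment (ties to the lower
node). `callLocalization` applies the replicate rule: vegetal iff the
profile lies in 46-50 in *all* replicates and in 48-50 in *at least one*;
animal iff in 1-8 in all replicates; otherwise unlocalized. Genes
undetected in any replicate are reported separately rather than called.
One map is trained per replicate (profiles are per-replicate quantities in
the rule); a joint fit can be had by concatenating trace sets.
`intersectCalls` computes Venn overlaps of call sets restricted to the
genes expressed in all sets, resolving many-to-many orthology with "any
orthologue localized" semantics.

# Per-UMI labeling classification

Metabolic labeling converts incorporated 4sU so that labeled (zygotic)
molecules read out as T-to-C mismatches, while maternal molecules --
synthesized before injection -- carry none. `MismatchRecords` holds
read-level substitution evidence grouped by molecule (cell barcode, UMI,
gene). `aggregateUmis` counts T>C events with base quality strictly above
20 per molecule (`tcCountQ`) and tallies all 12 substitution types
unfiltered for spectra; `classifyUmis` labels a molecule iff
`tcCountQ >= minTc`.

`minTc = 1` is the default: the analytic false-negative model computes the
probability of *zero* conversions, which corresponds to a >= 1 threshold;
the description "more than one T to C mutation per UMI" read literally
(>= 2) is available via `minTc = 2` and is covered by the binomial tail in
`analyticFnr`. With ~4 reads of 99 nt per UMI and partial overlap, a
molecule exposes ~300 distinct nt; at 40% GC, 30% of positions are Us,
giving 90 covered Us, and at a 5% per-U conversion rate the false-negative
rate is `0.95^90 ~ 1%`. `analyticFnr` also offers the
`uCountModel = "binomial"` variant in which the per-molecule U count is
itself binomial -- the exact counterpart of the simulator (detected
conversions are then `Binomial(300, 0.3 * 0.05)`, about 1.07%).
`analyticFpr` gives the converse error from a uniform sequencing-error
background: `P(X >= minTc)`, `X ~ Binomial(396, errorRate/12 *
qualPassProb)`.

`splitMatrices` tabulates classified molecules into sparse labeled and
unlabeled gene x cell matrices inside one `SingleCellExperiment` (genes in
rows, the Bioconductor convention); additivity to the total UMI count per
(gene, cell) is exact. Diagnostics mirror the standard figures:
`mutationSpectrum` (frequencies per substitution over total sequenced
bases; the denominator convention is recorded in the output because other
choices -- e.g. per covered reference base -- exist), `tcHistogram`
(per-molecule counts and per-gene mean conversion frequency with Sarle's
bimodality coefficient; > 0.555 suggests bimodality), and
`labelingEfficiency` (fraction labeled per cell).

# Maternal fate analysis

`foldChange` computes, for each gene and cell type, `log2((mean in type +
eps) / (mean in others + eps))` on unlabeled (maternal) counts, with
`eps = 0.01` transcripts/cell -- a pseudocount is needed because maternal
expression of a localized gene is often zero outside its destination type;
the value is recorded in the output and configurable. Genes below 0.1
mean transcripts/cell are excluded (too shallow for a stable ratio).

`deconvolveBimodal` fits a univariate k=2 Gaussian mixture by EM:
initialization from a quantile split, several seeded extra starts keeping
the best final log-likelihood, convergence when the log-likelihood gain
drops below 1e-8, degenerate components (sd below 1e-6) restarted with
jitter. Components are reported in increasing-mean order to prevent label
switching. The log-likelihood trace is stored and is non-decreasing by
construction of EM; tests assert it at every iteration. Note a statistical
fact documented by our tests: at n = 2000 and component overlap like
(0.4, 0.5) vs (1.52, 0.4), the fully converged maximum-likelihood estimate
itself has enough sampling variance that individual component means miss
the truth by more than 0.1 in roughly 5-10% of datasets; this is a property
of the estimand, not an optimizer failure (an independent EM implementation
converges to numerically identical optima).

`compareMeansWelch` is one-sided Welch (unequal variance,
Welch-Satterthwaite df) for "is the high component's mean above a random
background sample" (`backgroundSample`: uniform, without replacement,
seeded). `setEnrichment` is the upper-tail hypergeometric
overrepresentation test; the source study reports an enrichment p-value
without naming a test, so this is a standard re-implementation, not a
claimed reproduction.

# 3'UTR features and k-mer enrichment

`weightedLengths` computes per-gene 3'UTR and CDS lengths with isoforms
weighted by their FPKM share, a convex combination bounded by the isoform
length range; genes under 10 FPKM total are flagged, all-zero-FPKM genes
excluded. `longestUtrPerGene` is the alternative selector used when
quantification is unavailable. `compareGroups` reports group means, their
ratio and a two-sided Wilcoxon rank-sum p (exact for tie-free n <= 50).
`gcContent` excludes undetermined bases from the denominator.

`kmerEnrichment` re-implements the discriminative core of DREME-style
motif discovery: for k = 3..10, every k-mer present in at least one
positive sequence is scored by a one-sided Fisher exact test on
sequence-level presence/absence against the background set; the E-value is
the p-value times the number of candidates tested across all k
(Bonferroni-style); the best motif is accepted if E <= 0.5, masked with Ns
in both sets, and the scan repeats. Only the given strand is scanned
(`-norc` semantics -- these are 3'UTRs), and candidates are exact k-mers:
the IUPAC-generalization refinement step of the original tool is omitted,
so reported motifs are consensus words, not degenerate patterns. K-mers
are encoded as 2-bit integers and presence tables are built once and
updated only for masked sequences; `kmerPresence`/`scoreKmers` are exposed
so label permutations can be rescored cheaply (the type-I check in the
tests rescans 100 label shuffles this way). When the positive set is much
longer than the background (as planted-length simulations are), many
unrelated k-mers become weakly "enriched" through sheer sequence length --
the same caveat applies to the original tool when background sets are not
length-matched; the planted motif still dominates the ranking by tens of
orders of magnitude.

# Synthetic data: what it emulates, and what it does not

`simulateTomoseq` draws gene x section counts for three spatial classes
(animal: decaying profile over the first 8 sections; uniform; vegetal: 95%
of mass in the last 3 sections), with log-normal per-gene depths
(meanlog = log(800), sdlog = 0.7), an animal-skewed per-section library
factor mimicking the blastodisc, constant-expectation Poisson spike-ins,
and negative-binomial counts (dispersion 0.2; Poisson at 0). The defaults
(96 sections, 200/1600/200 genes, 3 replicates) are the conditions under
which recovery is tested. `expectedSectionProfile` exposes the exact
mixture weights so tests derive expectations instead of re-implementing
the generator. Note one deliberate distortion: with 10% of genes vegetal,
the terminal sections are partly crowded by the vegetal class itself, so
normalized vegetal traces plateau around 0.7-0.9 rather than 0.95 -- a
composition effect that real data (where localized genes are ~1% of the
transcriptome) shows much more weakly.

`simulateSlamReads` draws molecules per (cell, gene) from Poisson rates
with maternal and zygotic programs over somatic types plus a rare PGC-like
type (6 cells by default): a designated vegetal subset of maternal genes
is 8-fold elevated in PGCs, and the PGC zygotic program is reduced 5-fold,
encoding the structure the fate analysis must recover. Per molecule, the
U count is `Binomial(min(4 x 99, 300), 0.3)`; zygotic molecules convert
each U with p = 0.05; sequencing errors are `Binomial(396, 0.001)` spread
uniformly over the 12 substitution types (the per-base error rate is an
assumption, not a measured value; it is exposed in the config). Base
qualities are drawn from a discrete distribution concentrated above Q20
(37/33/27 at 0.8/0.15/0.05), as in quality-filtered real libraries.

`simulateUtrs` draws gamma-distributed sequence lengths (background mean
600 nt, positives 1.7-fold longer), 40% GC, and plants a CAC-core 6-mer
(`CACCAC`) verbatim at a uniform position in 60% of positives and 5% of
background sequences.

None of the generators model PCR duplication, positional coverage bias,
doublets, ambient RNA, or alignment artifacts; passing tests demonstrate
that the algorithms recover what they claim under the stated statistical
model, not that real libraries meet that model.

# Numerical and degenerate-input conventions

Quality filtering is strict (`> 20`); ties in profile assignment go to the
lower node; z-scores use population sd with constant rows mapped to zero;
cumulative rows of all-zero genes are zero and flagged rather than NaN;
EM component order is by increasing mean; masked motif positions are `N`
and never re-enter candidate enumeration; all stochastic functions take
explicit seeds and restore the caller's RNG state. Problem sizes in the
test-suite and acceptance script (2000 genes x 96 sections x 3 replicates;
~26,000 molecules; 1200 UTR sequences; 100-1000 statistical repetitions)
were chosen as the smallest sizes at which the tested properties are
statistically stable.

# Known limitations

* Profile windows (46-50 / 48-50 / 1-8) are calibrated for 50 nodes; other
  map sizes need rescaled windows, which are parameters throughout.
* The orientation flip needs a library-size asymmetry; perfectly symmetric
  inputs would be left as-given.
* The conscience bias coefficient is scaled for cumulative traces in
  [0,1]; training other feature spaces would need rescaling.
* `kmerEnrichment` reports exact words only and does not merge reverse
  complements or build PWMs.
* The GMM reports a maximum-likelihood fit; no uncertainty intervals on
  component parameters are provided.
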