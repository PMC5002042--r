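---
title: "Methods: genetically driven co-expression modules in an RI panel"
author: "rixnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically driven co-expression modules in an RI panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rixnet)
```

## The problem

Recombinant inbred (RI) panels are sets of inbred strains derived from two
progenitors by repeated sibling mating. Each strain is a fixed homozygous
mosaic of the two parental genomes, so a phenotype measured once per strain
can be mapped against the strain distribution pattern (SDP) of each genomic
marker. `rixnet` implements a systems-genetics workflow for such panels:
define a liver (or other tissue) transcriptome from the two progenitors,
quantify it across the panel with masked microarrays, find co-expression
modules, and ask which modules are *genetically driven* — represented well
by their first principal component and mapped to a genome-wide-significant
locus — then attach biology to them through gene-set overrepresentation,
overlap with phenotypic QTLs, and cell-type expression profiles.

Everything runs end-to-end on synthetic data with known truth, so each
stage's behaviour can be scored exactly.

## Stage models and parameters

### Transcriptome assembly

Per-strain transcript models (GTF) are filtered to *high confidence*:
FPKM at or above 1 and transcribed length strictly over 300 bp (the
fragment length that survives extraction and library size selection). The
two strain transcriptomes are then merged: an A/B pair becomes one
transcript when the transcripts overlap on compatible strands and either
(1) all splice junctions match, or (2) both are single-exon with start and
stop sites each within 100 bp (inclusive; the tolerance is exposed as
`end_tolerance`). Merged models take the union span. Transcripts are then
grouped into genes when transcription start sites match exactly, stop
sites match exactly, or any splice junction matches exactly; genes are
connected components of this relation, since the pairwise rules are not
transitive on their own.

Expression support uses *coverage* — average read mass per nucleotide.
Reads shared among transcripts (splice variants) are reallocated
proportionally to current coverage estimates, iterated to a fixed point
(`tolerance` 1e-6); a transcript whose coverage falls below 50 in **every**
strain is dropped, and quantitation repeats until fewer than 5% of
survivors fall below the threshold. The loop always terminates because the
set strictly shrinks. Coordinates are 1-based inclusive throughout (the
GTF/IRanges convention), so interval arithmetic goes straight through
`IRanges`.

### Probe mask and gene clusters

Microarray probes are kept only when they align perfectly and singularly
and do not overlap a sequence variant between the progenitors; probe sets
keep at least 3 surviving probes or are eliminated. A probe set maps to a
gene only when its target interval is contained in the gene's exonic union
and in no other gene. Gene clusters are summarized as the mean of their
probe sets' log2 intensities (the package consumes normalized
intensities; array summarization and batch correction are upstream
concerns), and a cluster must be detected above background (DABG p <
1e-4) in at least 5% of samples. A cluster's per-sample DABG p is taken
as the minimum over its probe sets — detected when any probe set is
detected — a documented stand-in, since vendor software defines
cluster-level detection only per probe set.

### Co-expression network and modules

The network substrate is the strain-mean expression matrix. Similarity is
the absolute Pearson correlation across strains; the unsigned weighted
adjacency raises it to power β = 7 (soft thresholding chosen for
approximate scale-free topology; `scale_free_fit()` reports the binned
log–log fit as a diagnostic, it does not choose β). The topological
overlap measure

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}$$

combines direct and shared-neighbour evidence and damps spurious pairwise
correlations. Modules come from average-linkage clustering of
$1 - \mathrm{TOM}$ with a two-stage dynamic cut:

* a static cut severs merges above `cut_height` (default 0.99). TOM
  dissimilarities are bounded by 1, and merges near 1 join effectively
  unrelated genes, so an absolute height is meaningful here; we chose it
  over a quantile-based height because a quantile moves with the
  module/noise mix of the panel.
* each large cluster is refined recursively: internal merges above the
  cluster's mean merge height plus `split_alpha` (default 1) standard
  deviations are severed at once, and the split is accepted only when at
  least two parts reach `min_module_size` (default 5). A homogeneous
  module only sheds sub-minimum clumps at such a cut, so it is kept
  intact; without this acceptance rule, recursion shreds true modules
  into sub-minimum fragments.

Genes in clusters below the minimum size stay unassigned (label 0).
Module eigengenes are unit-norm first principal components of the
standardized member expression, sign-oriented to correlate positively
with the module's mean profile (PC signs are otherwise arbitrary, and
determinism matters downstream). Modules whose eigengenes correlate at
|r| ≥ 0.75 are merged iteratively, highest pair first, until no pair
qualifies — this also re-unites any module the tree cut over-split.
Intramodular connectivity $k^{IM}_i$ is the sum of a gene's adjacency to
co-members; its maximizer is the module hub (ties break
lexicographically), and a gene's connection count is the number of
co-members with |r| strictly above 0.5.

### Module eigengene QTLs

Each eigengene is regressed on every biallelic marker;
$\mathrm{LOD} = (n/2)\log_{10}(1/(1-R^2))$. Markers with fewer than two
strains in either genotype class are skipped as unstable. Genome-wide
significance comes from permuting the eigengene across strains (1000
permutations by default) and recording each permutation's maximum LOD;
the genome-wide p-value is the fraction of permutation maxima at or above
the observed peak, reported as `<1/n_perm` at the floor, matching the
count-based reporting convention. One permutation stream is shared across
modules by default (configurable) — cheaper, and the per-module
thresholds are exchangeable. A module is *genetically driven* when its
eigengene explains over 50% of module variance and its meQTL reaches
genome-wide p < 0.05 (both strict).

### Partial correlation, enrichment, cell types

When a driven module's genes co-locate near its meQTL, their correlation
may reflect only the shared locus. Conditioning every member pair on the
peak-marker genotype,

$$r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

and recounting connections at |partial r| > 0.5 separates linkage-only
pairs (connection lost) from pairs sharing residual biology (connection
kept). The conditioning variable is the single peak-marker genotype, not
a haplotype.

Overrepresentation of annotation terms uses the exact binomial tail
$P(X \ge k)$, $X \sim \mathrm{Binomial}(n, m/N)$, with the reference set
restricted to the genes in the network analysis; a Bonferroni adjustment
multiplies by the number of terms actually tested. Two gates guard
against artifacts: modules need at least 10 annotated genes to be tested
at all, and a term must hit at least 2 module genes to be reported (a
single rare-term gene can otherwise reach significance alone). A
hypergeometric tail is available as an option. Phenotypic QTL overlap
reports catalog intervals containing the meQTL peak with LOD ≥ 10
(inclusive).

Cell-type differential expression fits a per-gene two-way ANOVA
(cell type × strain) and tests, with one F statistic, the joint null of
no cell-type main effects and no cell × strain interaction — i.e. no
cell-type-related difference, strain dependent or independent — against
the strain-only model; Benjamini–Hochberg controls the FDR across genes.
Display ratios divide linear-scale (unlogged) expression by the gene's
across-strain Kupffer-cell mean, since "twice the expression" is a linear
statement; a within-strain denominator is a config switch.

## What the generator emulates — and what it does not

`simulation_config()` fixes the study conditions: 21 strains (the RI
panel size), a biallelic map of 10 chromosomes × 15 markers whose
per-chromosome mosaics are first-order Markov with switch probability 0.1
per interval (the panel-size and marker-map values are free parameters of
the design; marker count and spacing were chosen once as a realistic
desk-scale genome), five planted modules of sizes 40/30/25/15/10 whose
latent drivers satisfy
$d = \sqrt{f}\,\tilde g + \sqrt{1-f}\,\varepsilon$ with
$f = R^2(\text{driver, genotype}) = 0.6$ by default, gene loadings
uniform on [0.75, 0.95] with noise sd 0.5, and 80 background genes. The
variance-fraction parameterization makes power statements directly in
terms of the genotype R². Each generator stage draws from its own stream
derived from `(seed, stage name)`, so stages reproduce independently and
identical seeds give byte-identical outputs.

The transcript fixture plants every case the assembly rules must decide:
identical-junction pairs, single-exon pairs at offsets up to 200 bp
including both sides of the 100 bp boundary, opposite-strand overlaps,
within-strain isoforms sharing junctions and read mass, low-FPKM and
short decoys, and low-coverage decoys making up exactly 10% of the
surviving transcriptome (plus one rescue case low in only one strain).
Probe sets are planted clean, boundary-crossing, ambiguous (inside two
genes), contaminated, or intergenic; one annotation term is planted to
cover over half of one module's genes; the QTL catalog plants intervals
that do and do not contain each planted peak with LODs straddling 10.

Deliberately **not** emulated: read-level sequencing noise, realistic
linkage maps in centimorgans, batch effects, array summarization
internals, and annotation ontology structure (terms are flat sets).
Passing tests therefore demonstrate the correctness and calibration of
the algorithms under the assumed statistical structure — not robustness
to the messiness of real arrays or real genomes.

In the full synthetic run, the assembly and probe-mask stages operate on
the transcript/probe fixture while the network stages operate on the
module-structured strain-mean panel; on real data the two would be one
matrix. Keeping them separate lets each fixture target its own stage's
decision rules at desk scale.

## Numerical choices and degenerate inputs

* Zero-variance genes are removed (with a warning) before correlation;
  a zero-variance eigengene or conditioning genotype is an error.
* Shared-mass allocation falls back to equal splits when all members of
  a group have zero coverage; allocation conserves mass exactly.
* A perfect marker fit reports LOD = Inf (logged sentinel); permutation
  maxima handle it naturally.
* Partial correlations are clamped to [-1, 1] against floating-point
  drift; genes perfectly correlated with the conditioning genotype get
  NA rows.
* Hub ties and PC signs are broken deterministically (lexicographic id;
  positive correlation with the module mean).
* Eigengene merging joins the highest-correlated pair first and
  recomputes, so the exit state has all pairwise eigengene correlations
  below the threshold.

## Problem sizes used in the tests

The packaged checks run at desk scale, chosen to finish in minutes while
keeping Monte-Carlo error well inside the asserted tolerances: 200-gene
panels over 21–30 strains, 150-marker maps, 200–1000 permutations per
scan, 100–500 replicate simulations for calibration and power
properties, and 20–100 random instances for the oracle-equivalence
checks (TOM vs a brute-force triple loop, eigengenes vs an
eigendecomposition, LOD vs a one-way ANOVA, partial correlations vs
residual regression, binomial tails vs explicit summation).

## Known limitations

* The dynamic tree cut is the top-down static-cut-plus-recursive-split
  variant described above, not the bottom-up hybrid variant with a PAM
  stage; on panels where modules differ greatly in tightness a single
  absolute `cut_height` may need adjusting.
* Marker regression only: no interval mapping between markers, no
  covariates, no multi-QTL models.
* The binomial overrepresentation tail treats genes as independent
  draws; the hypergeometric option is the finite-population analogue.
* At 20–30 strains the sampling spread of a LOD score is large: a locus
  explaining half the eigengene variance clears a genome-wide threshold
  in only about three quarters of replicate panels (the acceptance suite
  measures exactly this), so non-replication of a true module QTL at
  this panel size is expected behaviour, not a bug.
* Permutation p-values are reported as count/n_perm to match the
  standard reporting convention; users wanting the positively biased
  (count+1)/(n_perm+1) estimator can derive it from the returned
  permutation maxima.

## A worked run

```{r run, eval = FALSE}
cfg <- pipeline_config(sim = simulation_config(seed = 1))
res <- run_pipeline(cfg)
res$meqtl$driven
score_against_truth(res)
```

See the README for the printed output of this exact run and what each
number means.
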