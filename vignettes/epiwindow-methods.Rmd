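---
title: "Window-based enrichment analysis: models, parameters and design notes"
author: "epiwindow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based enrichment analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwindow)
```

This vignette is the package's own account of the methods it implements:
what each stage assumes, which parameters matter and why they default to the
values they do, what the synthetic-data generators emulate (and what they do
not), and where the design was genuinely open and a choice had to be made.

## The quantification model

Enrichment sequencing (MeDIP-seq, ChIP-seq) yields two fragment libraries
per sample: an immunoprecipitated (IP) library whose local density reflects
the assayed mark, and a sheared non-immunoprecipitated input that carries
the shared biases (shearing, amplification, mappability at coarse scale).
The model here is deliberately minimal:

1. **Binning.** The genome is partitioned into fixed windows of
   `window_size` = 200 bp (the last window of each chromosome is kept at its
   native, shorter width). Each fragment contributes exactly 1 to the window
   containing its midpoint `floor((start + end)/2)` in 0-based coordinates.
   The midpoint rule (rather than overlap-proportional spreading) makes the
   count total exactly conserved, which in turn makes conservation a
   testable invariant.
2. **Depth normalization.** Window scores are scaled so each track sums to
   10⁶ (reads per million). Any common scale yields identical downstream
   calls; the invariance is tested, not assumed.
3. **Input subtraction.** `max(IP − input, 0)` per window. The floor at
   zero follows from how the result is used: enrichment is defined as
   positive excess over background, and no downstream consumer interprets a
   negative deficit. A window is *enriched* when the subtracted score is
   strictly positive.

Assumptions worth keeping in mind: fragments are treated strandless
(double-stranded immunoprecipitated material carries no usable strand
signal at this resolution); no GC, mappability or duplicate correction is
attempted; the input is assumed to be sequenced deeply enough that its
per-window estimate is not the dominant noise source.

## Peak calling

Thresholds come from a designated reference sample — the wild-type serum
condition in the original design — so that peak counts are comparable
across samples: the threshold is the nearest-rank 95th percentile of the
reference's *positive* subtracted scores, reused verbatim everywhere.

Two choices here were genuinely open:

* **Percentile over positive windows only.** On sparse input-subtracted
  data the large majority of windows are exactly zero; a 95th percentile
  over all windows would collapse toward zero and the "top 5%" reading of
  the threshold would be lost. Restricting to positive windows keeps the
  threshold meaningful at any sparsity, at the cost of making it depend on
  how much of the genome is enriched at all. Nearest-rank (the value at
  rank ⌈p·n/100⌉) keeps it deterministic and attained by an observed score.
* **"Above" is strict.** A score exactly equal to the threshold does not
  qualify, consistent with percentile semantics; tie behaviour is pinned by
  a test.

A window run of `region_windows` = 3 (600 bp) containing at least
`min_qualifying` = 2 qualifying windows marks its full span; overlapping or
book-ended spans merge into maximal peaks. The scanner is verified against
exhaustive triplet enumeration on a thousand random grids.

Peaks map to six genomic compartments in strict precedence order
(promoter core ≻ promoter proximal ≻ promoter distal ≻ exonic ≻ intronic ≻
intergenic), with bounds `core_bp` = 100, `proximal_bp` = 1000,
`distal_bp` = 2000 around the strand-aware TSS. The "TSS + 1 kb" style of
notation for promoter bands is directional on its face, but promoters
conventionally extend upstream of the TSS; the default therefore reads the
bands as **symmetric** about the TSS, with a `promoter_side = "downstream"`
switch exposing the literal directional reading. A peak overlapping
compartments of several genes resolves purely by the precedence order, not
by gene distance — the six labels partition the peak set exactly, which is
tested.

## Profiles, stratifications and set operations

"Sliding window" profiles are realized as fixed binning with
overlap-length-weighted averaging (step = bin width): a bin's value is the
per-base-pair mean of the window scores beneath it, which makes the
feature × bin matrix well defined and lets a per-base expansion oracle
check the implementation to 10⁻⁹. Bin counts (40 for promoters ± 2 kb, 100
body + 25 per flank for gene bodies, 25 per segment for elements) are
defaults, configurable; no authoritative values exist for them. Minus-strand
features are reversed so bin 1 is always 5′/upstream. Profile anchors use
the 5′ *edge* of the first transcribed base (not the base centre), which
makes profiles exactly mirror-symmetric under genome reversal — an exact,
tested equivariance rather than an approximate one.

Genes whose flanks run off a chromosome contribute their available part; a
gene is dropped only when nothing overlaps. Zero-length genes are an error.

Expression quartiles rank genes in descending order (Q1 = highest), break
ties lexicographically by gene id, and distribute remainders to the earlier
quartiles, so the partition is deterministic. Promoter peak-state
stratification calls a gene enriched when any peak overlaps TSS ± 1 kb.
Nearest-gene mapping for TF binding sites measures the gap to the **gene
body** (0 when overlapping), reported within 10 kb, ties to the smaller
gene id; body-level distance was chosen because "nearest neighbouring gene"
is body-level language, and a TSS-distance variant would change results
only for sites beyond gene ends. Consensus differential sets intersect
per-condition calls at |FC| ≥ 2 and adjusted p ≤ 0.05; a gene up in one
table and down in another lands in neither set by construction.

## Repeat counting

Fragments (a read pair is one unit spanning its outer coordinates) are
assigned to at most one repeat: the maximal-overlap annotation, with exact
ties resolved to the smallest (chromosome, start). This makes the
assignment independent of input order and guarantees that per-subfamily
counts sum exactly to the number of assigned fragments. Counts are reported
per million mapped fragments. Differential testing of the resulting count
matrix is delegated to dedicated count-model tools and is out of scope
here.

## Methylation quantification

Bisulfite percent methylation is `100 · m/(m + u)` over a clone × CpG call
matrix, missing calls excluded. The observation unit for between-condition
comparison is the **per-clone** methylation level: clones are the
independent sequencing units (plasmid clones picked and sequenced
separately), whereas CpG columns within a clone are strongly dependent. The
two-tailed Mann–Whitney U test is exact (via the tie-free null
distribution, equivalent to full enumeration) when the combined sample size
is at most 20 and there are no ties — which is where realistic clone counts
live — and otherwise uses the normal approximation with tie and continuity
corrections. Both per-clone and per-CpG comparisons are possible by
feeding either unit's levels to `mann_whitney_u()`; per-clone is the
package default.

HPLC 5mC percent converts the two peak areas to molar amounts with the
extinction coefficients ε(dCMP) = 8.86 × 10³ (276 nm) and
ε(5mdCMP) = 9.0 × 10³ (282 nm) and reports 5mdCMP as a percentage of total
cytosine; the quantity is invariant to common rescaling of both areas.

## DigiWest analytics

Each antibody yields a sample × 96 molecular-weight-fraction intensity
matrix (background-subtracted, hence non-negative). Scaling divides by the
antibody-wide maximum so the strongest signal is exactly 1. Blot rendering
paints each cell as an element-height-tall block and applies a Gaussian
diffusion with radius half the element height; the blur uses a separable
kernel (σ = radius, truncated at 3σ) with reflective padding, which
conserves total intensity exactly and maps constant images to themselves.

The analyte value is the sum over a per-antibody band window of fractions —
the aggregation in the original analysis tool is not recoverable, so the
band window is an explicit input; a ± 3σ window captures ≥ 99% of a
Gaussian band, which is tested. Values are normalized to β-actin and log2
transformed; zeros are lifted to half the analyte's smallest positive value
so the transform stays finite.

The permutation two-factor ANOVA computes observed F statistics for both
main effects and the interaction from Type-II sums of squares (on the
balanced 2 × 3 × 2-replicate design, Type I/II/III coincide; Type II keeps
the behaviour sensible if a synthetic design is unbalanced). The null
distribution permutes the sample labels jointly — both factors together,
the same permutation set shared across analytes, seeded — and
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so the smallest attainable p is
1/1001 at the default `n_perm` = 1000. Two properties follow and are
tested: p-values are invariant to affine rescaling of an analyte (F is),
and identical seeds give identical p-values bitwise.

One discreteness effect deserves a note: a tiny fraction (2·6!·6!/12! ≈
0.2%) of random sample permutations happen to reproduce the treatment
partition; for a very large planted effect such a permutation reproduces
the observed F, so the reported p for an overwhelming effect is 1/1001 in
most runs but can be 2/1001 or 3/1001 depending on the permutation draw.
This is inherent to unrestricted label permutation, not an implementation
artefact.

Analytes significant at `alpha` = 0.005 (minimum of the three p-values) are
clustered on their sample vectors with Euclidean distance and average
linkage — the defaults of the clustering tool the procedure mirrors — with
rows pre-sorted by analyte name so the leaf order is deterministic.

## What the synthetic data emulates

The generators define the study conditions the tests run under:

* **Fragments.** Lengths on [150, 700] bp with mean 300 bp, the stated
  sonication range. A triangular distribution cannot realise that mean on
  that support (its mean is confined to [333, 517] bp), so lengths follow a
  scaled Beta(2, β) with β solved from the target mean — unimodal with mode
  ≈ 250 bp and right-skewed, a reasonable shape for sonicated material.
  Input fragments are uniform over the genome; IP fragments are drawn by
  rejection sampling so the density inside a planted region is exactly
  `fold` times the outside density (membership decided by the fragment
  midpoint, matching the counting rule).
* **Genome.** Non-overlapping stranded genes (1–3 exons, terminal exons
  touching the gene ends) placed in evenly sized slots; repeat intervals
  labelled from a small catalogue of murine retrotransposon subfamilies;
  TF-binding-site intervals of 150–400 bp.
* **Clone matrices.** Bernoulli calls at the per-condition methylation
  probability, cells missing independently at 5% by default, 24 clones × 20
  CpGs (the minimum clone count picked per condition in the assay the
  module mirrors).
* **DigiWest.** A 2 × 3 factorial (serum/2i × three cell lines) with two
  replicates per cell; each analyte a Gaussian band whose amplitude carries
  additive factor effects in units of the replicate noise SD.
* **Expression.** Three epitype tables sharing planted consensus up/down
  sets (log2 effect 2.5) over a null background, plus lognormal baseline
  expression for quartile stratification.

What the generators deliberately do **not** model: sequence content (no
reads, no GC bias, no mappability structure), fragment-level duplicates,
copy-number variation, chromatin-state autocorrelation beyond the planted
blocks, bisulfite conversion failure, and antibody cross-reactivity.
Passing tests therefore demonstrate that the *computational procedure*
recovers planted truth under idealized noise — they do not certify
performance on real libraries with those artefacts.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed in memory (the GenomicRanges convention),
  converted from/to BED's 0-based half-open on I/O; round trips are tested
  to 6 decimal places for track scores.
* All-zero reference tracks, empty groups, zero library totals, all-missing
  clone matrices, empty design cells and all-zero antibodies are errors
  with named messages rather than silent NaNs; all-constant analytes take
  the F = 0, p = 1 convention.
* Records on chromosomes absent from the size table are dropped with a
  logged count (annotation/assembly mismatches should not abort a run);
  malformed records are hard errors naming the line.
* Seeded functions save and restore the caller's RNG state, so package
  randomness never perturbs user-level reproducibility.

## Problem sizes in the shipped tests

The test suite and acceptance script run on deliberately compact
configurations chosen to make the statistical claims sharp: a 1 Mb genome
with ten planted 2 kb regions at fold 10 and 10⁵ fragments per library for
peak recovery; sixty planted regions at 10⁶ fragments for the
enriched-territory halving comparison (deep coverage makes the
enriched-window count concentrate on the planted territory, as in a genome
where most enrichment lives in methylated domains); 200 null analytes at
1000 permutations for the ANOVA size check; 2 × 10⁵ fragments for the
3-fold repeat-elevation recovery. These sizes keep the whole suite in the
low minutes on one core while leaving the acceptance margins wide.

## Known limitations

Single-end versus paired-end conventions are absorbed into "intervals in,
counts out"; BAM input is not parsed directly (convert to BED first). The
peak caller reports no per-peak significance — it is a reference-calibrated
descriptive caller, matching the procedure it reimplements, not an
FDR-controlled one. The original analysis's exact percentile base
(all windows versus enriched windows) and the original profile step sizes
are not recoverable; both choices here are documented above and exposed as
parameters.
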