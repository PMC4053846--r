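---
title: "Screening for conserved A-to-I RNA editing sites: methods and design"
author: "EditScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for conserved A-to-I RNA editing sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EditScreen)
```

# The problem

ADAR enzymes deaminate adenosines to inosines in double-stranded RNA;
sequencers and ribosomes read inosine as guanosine, so editing sites appear
as A-to-G mismatches between a genome and RNA reads aligned to it.
Transcriptome-wide surveys list over a million candidate sites in human
alone, but the overwhelming majority sit in lineage-specific inverted
repeats and are thought to be by-products of ADAR's affinity for any long
dsRNA. The biologically committed core — sites maintained across tens of
millions of years — is much smaller, and finding it is a comparative
problem: a site matters if the *same* adenosine, in the *same* sequence
context, is edited in distantly related species.

EditScreen implements that comparison as a reusable pipeline, together with
the quantification and descriptive statistics that characterize a conserved
set once found, and a seeded simulator that generates ortholog genome pairs
with planted ground truth so that every stage can be validated end to end
without any external data.

# The conservation screen

For every candidate site we extract the genomic window of `flank` = 40 nt
on each side of the edited adenosine, read on the edited strand, giving an
81-nt sequence whose center base is A. Query-species windows are aligned
against all subject-species windows, and a pair is called conserved when

1. the optimal local alignment contains at least `minIdentical` = 70
   identical columns (out of at most 81), and
2. the two edited positions occupy the same alignment column, and
3. that column is an identical match (A aligned to A).

A query site with at least one passing subject hit enters the conserved
set; multiple hits are all reported but the site counts once. There is no
reciprocal-best requirement — the criterion is deliberately a conservation
test, not an orthology assignment.

## The aligner

The screen uses an exact Smith–Waterman aligner with affine gaps,
implemented in C++ in this package, with discontiguous-megablast-like
rewards: match +2, mismatch −3, and a gap of length $k$ costing $5 + 2k$.
`N` never matches anything, including another `N`. A search over
81-nt windows does not need a heuristic seed-and-extend engine; exactness
buys reproducible identical-column counts and direct access to the
traceback, from which the center-correspondence flags are computed.

Determinism is part of the contract, so tie-breaking is pinned down:

* the traceback starts at the highest-scoring cell, ties resolved by the
  smallest query index, then the smallest subject index;
* within the traceback, diagonal moves are preferred over up (gap in the
  subject) over left;
* gap runs are closed as early as possible;
* the traceback stops at the first zero-score cell.

The test suite checks the aligner against two independent references: a
naive dynamic-programming oracle written in plain R, and
`Biostrings::pairwiseAlignment` scores under the same scheme.

## Identity threshold

The conservation rule is a count of identical columns (≥ 70 of 81), not a
percent identity of the aligned region. The distinction matters: a short,
locally perfect alignment cannot pass, because 70 identical columns force
the alignment to span almost the whole window. This makes a separate
alignment-length threshold unnecessary.

## SNP control and signal-to-noise

Any cross-species screen will produce some hits by chance. To
calibrate that rate, the identical machinery is run on single-nucleotide
polymorphism panels from both species — same windows, same scoring, same
requirement that the two variant positions share an alignment column — with
one relaxation: the center base is not constrained to be A, and the shared
column need not be an identical match (a SNP has no edited base to match).
Raw control hits are scaled to the editing dataset sizes,

$$\text{controlNormalized} = \text{rawHits}\cdot
  \frac{n^{edit}_{query}}{n^{ctrl}_{query}}\cdot
  \frac{n^{edit}_{subject}}{n^{ctrl}_{subject}},$$

and the signal-to-noise ratio is the conserved editing count divided by
that normalized chance level. At the simulator's desk scale the planted
shared-SNP fraction (see below) makes chance coincidence vastly more
frequent per SNP than in genome-scale panels, so the synthetic
signal-to-noise ratio is small by construction; the statistic's value lies
in the normalization arithmetic, which is what the tests pin down.

# Editing-level quantification

Editing levels are measured from samtools-mpileup text. Base calls with
Phred quality below 30 are discarded while parsing; read-strand case is
folded so counts are reference-strand base counts. At a site, the
edited-strand A and G counts are the reference-strand (A, G) counts on plus
and (T, C) on minus, and the editing level is $G/(A+G)$, undefined at zero
informative coverage.

Each (site, sample) measurement gets one of three states:

* `no_data` — fewer than `minTotal` = 3 quality-passing reads;
* `edited` — at least `minEditedReads` = 2 G reads at a level of at least
  `minLevel` = 0.01;
* `covered_unedited` — otherwise.

The evidence thresholds are configuration, not biology: a single G read at
Phred 30 is indistinguishable from sequencing error, hence the two-read
default. De-novo candidate calling from a pileup uses the stricter
published rule — more than five edited reads *and* a level strictly above
0.01 — and, because unstranded pileups cannot assign strand, scans
plus-strand reference-A columns by default (T/C scanning is a flag).

Site-by-sample measurements assemble into a `SummarizedExperiment`
subclass with count, level and state assays; summaries report per-site
means and standard deviations over defined levels, an expression proxy
(read count in the deepest sample, chosen automatically), group means, and
Pearson correlations between matrices restricted to sites defined in both.

# Downstream statistics

**Accumulation curves.** Samples are ordered greedily: first the smallest
site set, then whichever sample adds the fewest uncovered sites, ties
broken lexicographically by name — the ordering that makes saturation
visible. The greedy order is checked against an exhaustive minimal-addition
oracle in the tests.

**Motif matrices.** Base frequencies at offsets −10..+10 around the edited
base, the ADAR neighbor-preference signature (G depleted at −1, enriched at
+1). Rows are probability vectors; an information-content attribute
supports logo rendering.

**Region and recoding classification.** Region counts come from the site
annotations; a coding site is non-synonymous iff the reference and
alternate amino acids of its substitution annotation differ, with stop
gains counted as non-synonymous. Coding sites without an annotation are
counted separately and excluded from the synonymy denominator, and both
the raw and the annotated coding counts are reported — the packaged
59-site table contains one unannotated coding row, so the two legitimate
coding totals (38 raw, 37 annotated) are both visible rather than silently
chosen between. An intronic site is "in a recoding gene" when its gene
also carries a coding site in the same table — the signature of an exon
complementary sequence serving a recoding site.

**ECS scan.** Candidate exon complementary sequences are detected at the
sequence level: the site's window is locally aligned against the reverse
complement of a surrounding locus; non-self hits with ≥ 70 identical
columns are reported, the matched stretch is masked and the scan repeats.
No secondary structure or free energy is computed — hits are labelled
candidate ECS, never structures.

**Reversion asymmetry.** For each editing site the base paired with the
edited position in the other genome is read from the best window alignment
(identity ≥ 70 still required). Here the center-match requirement *must*
be relaxed: requiring A-A would exclude exactly the hardwired-G
counterparts being counted. Fractions of G counterparts are computed in
both directions, a control repeats the procedure on the nearest non-edited
A within ±20 nt (distance ties resolve upstream), and the direction
asymmetry is tested with a two-sided Fisher exact test on the 2×2 G/non-G
× direction table. The sample odds ratio and its Woolf 95% interval are
reported. Both the all-counterpart and the A/G-only denominators are
exposed, since either convention is defensible.

# The synthetic study

`simulationConfig()` fixes the study conditions; `simulateOrthologPair()`
generates a random query genome, plants sites on a collision-free grid
(spacing ≥ 110 nt, which also keeps SNPs ≥ 100 nt from editing sites), and
derives the subject genome by i.i.d. uniform substitution: rate $d$ = 0.05
genome-wide, $d_c$ = 0.02 inside conserved windows, the edited base frozen
in both species. There are no indels by default — the conservation
criterion counts identical columns, and no indel model is claimed by the
screen. Lineage-specific sites receive forced counterpart bases (G with
the configured reversion fractions 0.26/0.18, A otherwise) so the
reversion analysis has exact planted truth. Conserved sites carry the
ADAR-like neighbor bias (upstream G 0.05, downstream G 0.45). A
post-generation self-check realigns every planted conserved pair and
aborts if any fails the criterion, guarding the $d_c$ margin
($81(1-d_c) \ge 72$ is enforced at configuration time).

True editing levels are Beta-distributed, drawn independently per site and
strain: conserved sites with mean 0.515 and SD 0.1 (the conserved set's
published mean editing level is near one half, and tightly regulated),
non-conserved sites with mean 0.1 and SD 0.2 (low and variable). Pileups
draw depth from Poisson(30), edited reads binomially, substitute uniform
errors at rate 0.001, and emit 10% of base calls below Phred 30 so the
quality filter is always exercised; low-quality assignment is independent
of the base call, keeping the filtered estimator unbiased.

A fraction (0.1) of SNP control positions is shared between the species'
SNP panels. Real SNP panels collide by descent and by chance at rates far
below this, but a desk-scale control with zero expected hits would make
the signal-to-noise ratio degenerate (infinite) in every run; the shared
fraction gives the normalization a finite, testable value.

For the strain panel, conserved sites are present in each strain with
probability 0.97 and capped at one absent strain each, so any two strains
jointly cover nearly the whole conserved set — the saturation behaviour
that distinguishes a conserved set from an accumulating one; other sites
are present independently at 0.5.

**What the simulator does not emulate:** repeat-element sequence
(Alu/B1/LINE context), indels and rearrangements between species, mapping
ambiguity, duplicate reads, strand-biased coverage, dsRNA-structure-driven
site placement, and clustered editing. Passing tests therefore demonstrate
that the algorithms are correct under their stated model, not that the
screen's published counts would reproduce on real genomes — reproducing the
full-genome screen requires the original million-site datasets and
assemblies and is out of scope by design.

# Numerical and testing choices

* Problem sizes: the packaged tests run the screen at 110×110 windows per
  seed over 20 seeds, reversion at 500–1000 sites per direction, motif
  recovery at 5000 windows, level calibration at 1000 binomial replicates —
  sizes at which the binomial/hypergeometric tolerances asserted in the
  tests are comfortably non-trivial.
* The symmetric-reversion null asserts that the 95% Woolf interval covers
  an odds ratio of 1 in at least 17 of 20 seeds: a 95% interval misses
  about one seed in twenty by construction, so demanding all 20 would fail
  a correct implementation more often than not
  ($0.95^{20} \approx 0.36$), while 17-of-20 fails a correct one with
  probability below 0.003.
* Fisher p-values are delegated to `stats::fisher.test` and verified
  against a hypergeometric enumeration oracle to $10^{-12}$.
* Pipeline outputs serialize floating point at 6 decimals, making reruns
  byte-identical and diffs meaningful.
* All generators run under a locally scoped RNG (`withSeed`), so identical
  configurations give byte-identical artifacts and the caller's RNG state
  is untouched.

# Interfaces

The package's surface is its exported functions; `runPipeline()` is the
orchestrated entry point (simulate → screen → control → quantify →
accumulate → motif → regions → reversion), writing each stage's plain-text
outputs before the next stage reads anything, so any stage can be re-run
or inspected in isolation. An R session (or `Rscript -e`) is the intended
driver; the configuration objects take the place of command-line flags.

# Known limitations

* The screen's all-pairs search is quadratic in the number of windows; it
  is meant for curated candidate sets (up to ~10^5 windows), not for
  genome-scale all-vs-all discovery, which is what heuristic aligners are
  for. An external-aligner hook would slot in at `runScreen()` without
  changing the criterion.
* Counterpart lookup in the reversion analysis assumes a shared coordinate
  system (true for simulated pairs); real cross-species use requires a
  liftover step that is out of scope.
* Editing-level estimation ignores duplicate reads and allelic imbalance;
  levels from low-complexity or paralogous regions inherit whatever
  mapping errors the upstream aligner made.
* The evidence threshold for "edited" (2 reads, 1%) is a package default,
  configurable and documented as such — it is not a published constant.
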