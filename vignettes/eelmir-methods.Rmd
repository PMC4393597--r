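---
title: "Methods: small-RNA miRNA discovery and tissue profiling with eelmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA discovery and tissue profiling with eelmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eelmir)
```

`eelmir` reimplements, as tested and reusable functions, the
computational workflow of a small-RNA study of electric fish tissue
panels: miRNA discovery from small RNA-seq, mismatch-tolerant 5p/3p arm
quantification across eight tissues (spinal cord, brain, kidney, heart,
skeletal muscle and the three electric organs), co-expression clustering
with elim-style Gene Ontology enrichment, and promoter scanning with
binomial binding-site enrichment.  Everything runs against synthetic data
with planted ground truth, so every stage can be verified without any
external download.

## The discovery pipeline

Reads are adapter-trimmed by exact matching against a prefix of the 3'
adapter (minimum overlap 5 nt, suffix overlap at the read end allowed),
filtered to the canonical mature-miRNA window of 20-23 nt, purged of
ambiguous bases, and collapsed to distinct sequences with counts
(`process_small_rna()`).

`call_loci()` then runs, in order:

1. **Conserved matching** (`match_conserved()`): 5'-anchored ungapped
   comparison against a catalog of conserved mature sequences, tolerating
   up to 2 mismatches, where a 3' length difference of up to 2 nt counts
   toward the mismatch total.  This end-anchored contract replaces a
   local aligner with unstated parameters by something exactly testable,
   and mirrors the quantification tolerance motivated by non-template 3'
   additions.
2. **Contaminant removal** (`filter_contaminants()`): exact substring
   search of unmatched sequences against both strands of an
   rRNA/snoRNA/snRNA/tRNA-style database.
3. **Perfect genome mapping** (`map_perfect()`): exhaustive exact
   matching on both strands; a multi-mapping sequence yields one
   candidate per placement.
4. **Precursor extraction** (`extract_precursor()`): the match plus 140
   bp of flanking sequence on each side, truncated (and flagged) at
   contig edges, reverse-complemented for minus-strand placements.
5. **Folding and hairpin classification** (`fold()`,
   `classify_hairpin()`), described below.
6. **Merging and naming**: candidates whose precursor windows overlap on
   the same contig and strand merge into one locus with 5p/3p arms;
   conserved loci are named by family, unmatched survivors with at least
   10 raw reads of support become `novel-N` loci.

Sequences with fewer than `map_min_count = 5` total raw reads are not
mapped at all: one-off sequencing-error variants cannot seed a locus
(novel calls need 10 reads) and skipping them keeps the pipeline fast.

### Folding and hairpin criteria

`fold()` is a base-pair-maximization (Nussinov-style) dynamic program
over Watson-Crick plus GU-wobble pairs with a minimum hairpin loop of 3
nt and a deterministic 5'-most traceback.  Its chief virtue is that an
exhaustive enumeration oracle exists: for sequences up to 12 nt the test
suite verifies the DP against brute-force recursion over all nested
structures.  For 300-nt precursors, however, maximum-pairing structures
are massively degenerate and the traceback need not select the
biological stem, so locus classification defaults to a thermodynamic
backend (ViennaRNA's `RNAfold` binary, the field-standard tool) whenever
it is on the `PATH`, falling back to the internal folder otherwise.

A candidate passes hairpin classification when at least 75% of its
mature bases pair into a single contiguous star window of width
`mature_len + bulge_tol` (default tolerance 4 nt) on one side of the
mature; the arm is 5p when that window lies 3' of the mature, 3p
otherwise.  Counting partners inside a best window, rather than taking
the full range of partner positions, makes the check robust to a stray
long-range pair without weakening the 75% requirement.  A mature
spanning the terminal loop splits its partners between sides and cannot
reach the threshold on either.  Because minimum-free-energy folds of a
302-nt retrieval window sometimes let distal flank structure outcompete
the local stem, `call_loci()` re-folds a failing candidate on a
`mature +/- 70` nt window — the scale of a real pre-miRNA — before
rejecting it.

## Quantification and transforms

`count_arm_expression()` assigns each collapsed read to the arm it
matches with the fewest mismatches under the same end-anchored, 2-
mismatch, 2-nt-3'-overhang contract; exact ties between arms are
discarded and logged (conservative and deterministic), and 5p/3p
products are counted separately.  `map_to_foreign_precursors()` applies
the identical contract to reads from a second species that lacks its own
assembly.

The transform pipeline is a small state machine
(raw → normalized → filtered → transformed) enforced by the
`ExpressionMatrix` class, so a stage cannot silently run on the wrong
values:

* **Normalization**: each tissue column is scaled by (median column
  total)/(column total), after which all totals equal the median total
  exactly; a second, optional *linear normalization* divides each column
  by the slope of a zero-intercept least-squares fit against the
  across-column mean profile, computed on rows nonzero everywhere.  The
  study names this step without defining it; zero-intercept regression
  against the mean profile is the most common reading, and the flag
  `linear = FALSE` exposes the depth-only alternative.  Parameter
  recovery checks use `linear = FALSE`, since planted library fractions
  are defined on depth-corrected scale and the regression step corrects
  composition biases the simulation does not contain.
* **Expression filter**: rows need at least 16 normalized reads in at
  least one tissue; the boundary is inclusive.
* **Transform**: `log2(v + 1)`, row median-centering, clamping to
  [-3, +3].

`tissue_distance()` offers Euclidean (default) and Pearson-correlation
distances — the source material uses both in different places, and the
Euclidean default follows its figure legends.  `complete_linkage()`
delegates to `stats::hclust`, whose complete-linkage merges match
hand-computed fixtures.  `select_differential()` screens
electric-organ-versus-muscle fold changes on normalized values with a
pseudocount of 1 and a strict 4-fold threshold; the EO aggregate is the
arithmetic mean of the three electric organs, with per-organ ratios also
reported.

## mRNA clustering and GO enrichment

`covariance_filter()` ranks genes by coefficient of variation across
tissues (pseudocount 1) and keeps the top quarter by default, matching a
filter described only as removing about three quarters of genes with low
covariance.  `kmeans_cluster()` is Lloyd's algorithm via `stats::kmeans`
(best of 10 seeded restarts; empty-cluster failures are retried with
derived seeds).  Clustering runs on log-median-centered values.

`elim_enrichment()` implements graph-decorrelated GO enrichment: terms
are processed from most specific (longest path to a root; ties by term
id) upward, each tested with a one-sided Fisher's exact test
(`stats::phyper`) on its *current* gene set within the background
universe; terms with fewer than 3 annotated background genes are
skipped, and when a term's p-value is at most `alpha_elim = 0.01` its
genes are removed from all ancestors before those are tested.  With
elimination disabled the procedure reduces exactly to classic per-term
Fisher tests — a property the suite checks on random toy DAGs — and on a
two-term chain where all parental signal comes from the child, the
parent is significant under classic testing and has p = 1 under elim.
No multiple-testing correction is applied by default, matching the
practice of reporting raw elim p-values below 0.01; BH adjustment is
available behind a flag.  The annotation universe defaults to every gene
carrying at least one (propagated) annotation.

## Promoter TFBS enrichment

A `pwm()` carries counts, pseudocount-normalized frequencies
(pseudocount 0.01), per-position information weights
`Ci = (100/ln 4)(ln 4 + sum_b p ln p)` — 0 for uniform, 100 for
invariant columns — and a core of the 4 consecutive positions maximizing
summed Ci.  Window scores are Ci-weighted ratios
`sum Ci p(i, w_i) / sum Ci max_b p(i, b)`, with the core similarity the
same ratio restricted to core positions; thresholds default to 0.75
(core) and 0.85 (matrix).  Scanning covers every offset on both strands
(implemented in C++; promoters are concatenated with `N` separators so a
set is scanned in one pass), and the number of binomial trials for a
promoter of length n is `2(n - L + 1)`.  Degenerate all-uniform matrices
score 0 with a warning rather than erroring.

`run_enrichment()` estimates a per-position background hit rate from a
background promoter set (subsampled without replacement to 2984 when
larger, mirroring the random-gene control of the source design) and
computes `P(X >= observed)` for a Binomial(trials, rate) at group,
top-subset, and single-gene scopes.  Trials are pooled across promoters
rather than averaged per promoter: pooling makes the binomial
well-defined and robust to promoter-length variation.  Overlapping hits
count separately, consistent with per-position trials.

## The synthetic-data generators

`simulate_genome()` builds random contigs (default 2 x 50 kb) and plants
10 conserved plus 3 novel hairpin loci: mature arm, 4-15 nt loop, and a
star arm that is the reverse complement of the mature with 1-2 random
substitutions.  Two substitutions are the ceiling because a 20-23-nt
duplex with three can drop below 75% mature pairing under an MFE fold,
and the generator must emit loci the classifier can legitimately
recover.  Novel matures are rejected-sampled to sit at least 4
mismatches from every catalog entry.  Contaminant families are written
both into the genome (so their reads map perfectly) and into the
contaminant database (so they are filterable), deliberately exercising
filter order.

Expression profiles assign each locus a tissue template: a shared
muscle/EO myomiR block, muscle-restricted, EO-restricted (electro-miR),
neural, kidney, or ubiquitous, with log-normal jitter (sd 0.2), scaled
so planted arms take 70% of each library; the dominant arm receives 80%
of a locus' expression.  The template mix makes EO-restricted arms a
small minority and the muscle/EO shared block large, reflecting the
myogenic origin of electrocytes — most miRNAs are shared between
electric organ and muscle, and only a minority are differential.  These
defaults were fixed once and drive the clustering topology check (the
three electric organs join skeletal muscle before brain or spinal cord
in 10/10 seeded panels).

`simulate_small_rna_libraries()` draws each tissue's 10,000 reads from a
multinomial over planted arms (70%), contaminant fragments (15%), and
random junk; miRNA reads carry 1-2 non-template 3' A/U additions with
probability 0.1, every read is extended with the adapter to 50 nt, and
substitution errors are applied at 0.5% per base.  Realized (pre-error)
per-arm draws are recorded as the quantification truth: with error and
addition rates set to zero the raw count matrix reproduces them exactly.
What the generator does *not* model: indels, quality-score-dependent
errors, realistic base composition, ligation biases, or isomiR 5'
heterogeneity — so passing tests demonstrate contract correctness and
statistical calibration, not performance on real libraries.

`simulate_expression_matrix()` plants block-structured co-expression
clusters (high in 1-3 tissues, 8-fold over baseline, log-normal noise)
plus a configurable fraction of flat genes for the covariance filter.
`simulate_promoters_and_pwms()` plants PWM consensus sites into uniform
random promoters at Poisson rates per promoter, on random strands, all
recorded in a truth table.

All generators derive independent RNG streams from one root seed and are
byte-deterministic given their configuration.

## Numerical and design notes

* Coordinates are 1-based inclusive internally (the R/Bioconductor
  convention); BED export converts to 0-based half-open, GFF3 stays
  1-based.
* Ties: catalog matches break toward the lexicographically earlier
  family; multi-arm read assignments at equal mismatch count are
  discarded, not split; k-means determinism comes from seeded restarts.
* `fisher_term_test()` and `binomial_enrichment()` are thin, exactly
  specified wrappers over `phyper`/`pbinom`; the suite checks both
  against direct combinatorial summation to 1e-12.
* Fold-change recovery: at the default depth of 1e4 reads/tissue, arms
  with ~100 reads in the tissues being compared carry binomial noise of
  roughly 0.1-0.15 on the log2 scale, so the +/-0.25 recovery check is
  comfortable for well-covered arms and tight for arms near the 100-read
  qualifying floor.
* Problem sizes used by the checks — 13 planted loci in 100 kb, 1e4
  reads/tissue (1e5 for fold-recovery property tests), 200 null and 100
  powered promoter simulations, enumeration folding up to 12 nt — were
  chosen as the smallest panels at which the planted effects are
  unambiguous relative to their sampling noise.

## Known limitations

The internal folder maximizes pairing rather than free energy, so it is
only used directly where an enumeration oracle makes it verifiable; the
thermodynamic backend requires the external `RNAfold` binary.  The
discovery sensitivity target is demanding at desk scale — with 13 loci a
single marginal hairpin costs 7.7 points — and individual random seeds
can leave one planted locus one paired base short of the 75% rule.
Cross-species quantification inherits every limitation of end-anchored
matching (no indels).  GO enrichment implements the elim algorithm only;
weighted variants are out of scope, as are count-model differential
statistics (the screening here is fold-change-based by design).
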