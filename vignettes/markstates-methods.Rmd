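---
title: "Calling chromatin-state dynamics between callus and seedling with markstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin-state dynamics between callus and seedling with markstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific setting

Rice callus is a dedifferentiated, pluripotent cell mass induced from
seed in tissue culture; seedling shoots are its differentiated
counterpart. Comparing the two tissues' chromatin reveals how histone
methylation reprograms cell fate: H3K27me3 (a Polycomb-deposited,
repressive mark) is broadly removed from developmental regulators in
callus, while H3K4me3 (an activating mark) and DNase I hypersensitive
sites (DHSs, open chromatin) accumulate there. Genes carrying both
H3K4me3 and H3K27me3 are *bivalent* — poised regulators first described
in mammalian embryonic stem cells and equally characteristic of plant
developmental genes.

`markstates` implements the downstream integration of this design: peak
sets and signal tracks per mark and tissue come in, and out come genomic
region distributions, per-gene mark assignments, tissue-differential
deposition sets, meta-gene profiles, active/bivalent/repressed state
calls with their between-tissue transitions, hypergeometric gene-set
enrichment, preferential-expression calls from a multi-tissue panel, and
multi-mark k-means clusters. Upstream read alignment and peak calling
are out of scope: the package consumes BED/narrowPeak, bedGraph/wiggle,
GFF3 and TSV.

```{r, eval = FALSE}
library(markstates)
st  <- simulate_study(sim_config(seed = 42), "sim")
res <- run_pipeline(pipeline_config(seed = 42), st$paths$manifest, "out")
```

## Models and procedures

### Region classification

Every base of the genome is assigned to exactly one of six classes:
promoter, 5' UTR, 3' UTR, coding exon, intron, intergenic. The promoter
is the 2 kb immediately upstream of the TSS on the gene's strand
(clipped at chromosome edges); coding exon is exon minus UTRs; what no
genic label covers is intergenic. Where labels from different genes
collide on a base, precedence is 5'UTR > 3'UTR > coding exon > promoter
> intron > intergenic, so a gene's fine structure is never masked by a
neighbour's promoter. The partition property (class lengths sum to the
genome length) holds for any annotation and is asserted by the tests.

Peak distributions over the classes are base-weighted — each peak base
counts toward the class labelling it, so fractions sum to 1 — with a
secondary per-peak majority-label view for comparison with peak-count
figures.

### Mark assignment and differential deposition

A gene *carries* a mark in a tissue iff its window — gene body plus 2 kb
upstream of the TSS, strand-aware — overlaps at least one peak of that
mark by one base or more. One base is the most literal reading of an
"overlapping" rule; the window is monotone in the upstream extension,
so enlarging it never removes a mark.

Differential deposition between tissues A and B is a deliberately
explicit, auditable rule rather than a black-box peak-caller
comparison: a gene is A-preferential iff it carries the mark in A only,
or carries it in both tissues and the windowed mean-signal ratio
`(mean_A + c) / (mean_B + c)` is at least `min_fold` (default 2,
pseudocount `c = 1`). Tracks must be depth-normalized first
(`normalize_signal_pair()` scales both to the smaller genome-wide
total; totals differing by more than 1% are an error). The rule is
symmetric — swapping the tissues swaps the sets — and reduces exactly to
the presence/absence set differences as `min_fold` grows.

### Meta-gene and TSS-centred profiles

The scaled meta-gene profile maps every gene onto fixed-width upstream
flank bins (default 1 kb in 20 bins), equal-fraction gene-body bins
(default 60), and downstream flank bins. Bin values are mean per-base
signal — not sums — so flank and rescaled body bins are directly
comparable. Minus-strand genes are reversed so bin 1 is always 5'.
Genes with bodies shorter than the body bin count are skipped with a
logged count rather than interpolated. TSS-centred matrices use
fixed-width bins (default 3 kb flanks at 100 bp; 5 kb is the
convention for state heatmaps); windows running off a chromosome
contribute zeros and are flagged. Both computations are linear in the
track and translation-invariant, and the test suite pins them to a
literal per-base averaging loop.

### Chromatin states and the seven transitions

State is a pure function of the two histone-mark flags: H3K4me3 only =
active, H3K27me3 only = repressed, both = bivalent. Genes with neither
mark get a fourth state, "none": the source analyses never assign such
genes, and a total function avoids inventing semantics for them.
Across the 3 x 3 grid of informative state pairs between callus and
seedling, exactly seven ordered pairs are named transitions
(bivalent-active, active-bivalent, repressed-bivalent,
bivalent-repressed, active-repressed, repressed-active,
bivalent-bivalent); the two static cells and anything involving "none"
are "unclassified".

Enrichment of a gene set within each transition uses the upper-tail
hypergeometric probability P(X >= k) — one-tailed, enrichment only,
matching the star conventions *P < 0.01 and ***P < 0.001. Whether any
multiple-testing correction was applied in the original figures is
unstated, so raw p and Benjamini-Hochberg q are emitted side by side.
The default universe is the genes with a classified transition,
configurable to any superset.

### Gene-set enrichment over a TF catalog

`family_enrichment()` tests each transcription-factor family for
over-representation in a query set. For TF query sets the right
universe is the TF catalog itself (the rice catalog of interest has
2,683 entries), not the whole genome — otherwise every family is
trivially "enriched"; the universe is configurable. `stats::phyper()`
supplies the tail probability (stable in log space, exact for small N);
the tests additionally pin it to literal subset enumeration for all
parameter grids with N <= 12 at 1e-12.

### Expression integration

Two-condition FPKM tables are filtered by the bare fold-change rule
(strictly greater than 2 by default) with a pseudocount of 1 FPKM,
which makes the ratio well defined at zero expression.

Preferential expression over a multi-tissue panel (the design emulates
45 arrays over 13 tissues) is summarized per gene by
`Z = (mean_target - mean_others) / sd_others` with the sample sd, and
`p = P(N(0,1) > Z)` at cutoff 0.05. This is the most common
tissue-specificity Z; a median/MAD variant is available by flag. Using
the sd of individual non-target samples (rather than a standard error)
makes the null conservative, which is the desired behaviour for a
screen. Genes whose non-target samples are constant are flagged by the
sign of the target difference with p set to the smallest positive
double and a `degenerate` note — silently dropping the most extreme
cases would be worse than an honest sentinel.

Panel normalization defaults to *level scaling* — every sample is
scaled so its mean matches the grand mean. Quantile normalization is
available, but its assumption that few genes change is violated
whenever the preferential fraction is large (in the bundled synthetic
design, 150 of 500 study genes), in which case it visibly compresses
the planted effect; level scaling matches the "normalized to the same
level" description of the emulated panel and is robust to large
changed fractions.

Multi-mark clustering concatenates one TSS-centred matrix per
mark/tissue, standardizes each bin to zero mean and unit variance
(constant bins map to zero), and runs `stats::kmeans` with 10 restarts
under a fixed seed, so assignments are reproducible. The default k = 5
follows the cluster count conventionally used for this design; any
k >= 1 is accepted.

## The synthetic study and what it shows

`simulate_study()` generates every input the pipeline consumes, with
machine-readable planted truth. Design choices:

* **Geometry.** Two 2-Mb chromosomes, 500 genes in disjoint slots wide
  enough (gene + 2 kb upstream on both sides + 100 bp margins) that no
  gene's assignment window can touch a neighbour's. This makes the
  planted mark flags *exactly* recoverable — peak-to-gene assignment is
  unambiguous by construction. Peaks are log-normal (median 1 kb,
  truncated to the gene body with 100 bp clearance), so ordinary runs
  never test boundary luck; a `boundary_stress` mode places exactly
  1-bp overlaps instead to exercise the half-open edge semantics.
* **States and transitions.** Per-tissue states are drawn independently
  (active 0.35, repressed 0.25, bivalent 0.20, none 0.20), so all
  seven transitions and both static cells occur in every run; DHS
  presence is conditioned on the state (0.7/0.5/0.2/0.2).
* **Differential signal.** Among genes marked in both tissues, 20% are
  planted at a fold-4 amplitude ratio, split evenly between tissues;
  single-tissue carriers are presence/absence differentials. The base
  amplitude (50) is chosen so the smallest peaks in the largest windows
  still dominate the pseudocount at the fold cutoff. Per-mark tissue
  pairs are depth-equalized by a compensating run in a reserved,
  peak-free 10-kb tail region — normalization therefore never rescales
  the planted per-gene fold ratios. Amplitude noise is truncated
  Gaussian (relative sd 0.1 by default; 0 gives exact recovery).
* **Expression.** The two-condition table plants 100 genes per
  direction at fold 4 with log-normal noise (sdlog 0.15). The panel is
  emitted as log2-scale normalized intensities — the form in which
  array panels are analysed — for 500 study genes plus 2,000 background
  probes (on a real chip the preferential genes are a few percent of
  probes, and cross-sample normalization relies on that), with tissue
  effects (sd 0.15), residual noise (sd 0.5), and 150 planted
  callus-preferential genes shifted by 4 total-sd units.
* **Archetypes.** Genes active in callus (sharp H3K4me3, no H3K27me3)
  versus repressed (the reverse) form two orthogonal signal archetypes
  used for the k = 2 clustering check.

What passing these tests shows — and does not show. Recovery is exact
by construction in the noiseless setting, so those tests verify the
*implementations* of the rules, not their biological power. The
generator does not emulate overlapping genes, isoforms, replicate
structure, peak-calling uncertainty, mappability artifacts, or
correlated mark co-occurrence along chromosomes; conclusions about real
data should rest on the rule definitions, not on the synthetic
recovery rates.

## Numerical and interface choices

* Internal containers are `GenomicRanges` (1-based, closed), the
  R/Bioconductor convention; 0-based half-open BED/bedGraph coordinates
  are converted exactly once, at the format boundary, and restored on
  write. Round-trips are byte-faithful: the writers emit shortest
  exactly-round-tripping decimal forms, and the bedGraph reader parses
  values directly rather than through a lossy intermediate.
* Overlapping signal runs with conflicting values are an error — the
  reader never averages silently; equal-value overlapping or abutting
  runs are merged.
* Determinism: one seed in the config drives k-means and the generator;
  no other randomness exists. Two runs with the same inputs and seed
  produce byte-identical TSVs (asserted by digest in the tests), and
  the provenance file records the config hash and seed but no
  timestamps.
* The R functions (`run_pipeline()`, `simulate_study()`, and the
  per-stage functions) are the interface, as is conventional for
  analysis packages in this tier; every stage also runs standalone from
  files.
* Test problem sizes: the per-module suites use 120-gene studies on
  2 x 0.8 Mb; the end-to-end checks use the default 500-gene fixture,
  a 200 x 500 brute-force assignment oracle, exhaustive hypergeometric
  enumeration to N = 12, a 12-gene 100-kb genome for per-base profile
  oracles, and 1,000-replicate null calibration at
  (N, K, n) = (2683, 500, 300) — a design whose attainable rejection
  rate at alpha = 0.05 is 0.0499, so discreteness of the hypergeometric
  support does not confound the calibration check.

## Known limitations

* One representative (longest) transcript per gene; no isoform
  resolution.
* The differential-deposition rule is deliberately simple (presence,
  fold, pseudocount); it is not a replicate-aware statistical test and
  the original analyses' exact gene counts, which depended on unshared
  peak-caller intermediates, are not reproducible from it.
* The preferential-expression p-value treats the Z against a standard
  normal; with few non-target samples it is a screening score, not a
  calibrated test.
* DHS intervals are accepted as published peaks; the package does not
  re-call them, and DHSs play no role in state calling (states use the
  two histone marks only).
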