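---
title: "Repeat landscapes from unassembled reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat landscapes from unassembled reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

`repeatscape` characterizes the repetitive portion of a genome directly from
low-coverage shotgun reads.  Because repeats are, by definition, sampled many
times even at 1x genome coverage, reads from one repeat family recognize each
other by sequence similarity without any assembly.  The package builds that
similarity graph, extracts repeat families as graph clusters, summarizes each
family by two numbers — its average pairwise nucleotide diversity
(&theta;<sub>&pi;</sub>, an age proxy) and its copy number (read depth over
the family consensus) — and interprets the relation between the two under a
steady-state birth–death model of transposable-element (TE) turnover.

This vignette documents the underlying models, the tunable parameters and
their defaults, the numerical choices, and the limits of what the bundled
simulator can demonstrate.

## The birth–death model and the half-life

Retrotransposons proliferate by copy–paste: a new insertion starts out
essentially identical to the active element and then decays neutrally,
accumulating substitutions at a rate &mu; per site per unit time, while
insertions are also lost from the genome at a per-copy rate &delta;.  A
copy's divergence from the active (ancestral) element therefore measures its
insertion age.  At steady state (birth rate &beta; equal to &delta;, constant
expected family size), the ages of surviving copies are exponentially
distributed with rate &delta;, so the number of surviving copies at
divergence &theta; decays as exp(−(&delta;/&mu;)&theta;).

On a log-linear plot of copy number against divergence this is a straight
line with slope b = −&delta;/&mu;.  The **half-life** — the divergence by
which half of all insertions have been lost — is

> h = ln 2 / (−b) = ln 2 · &mu; / &delta;.

`fit_halflife()` estimates b by ordinary least squares on ln(copy number)
and reports h in divergence-proportion units (a percent column is emitted
alongside, since both conventions are common).  Natural logarithms are the
default; `log10 = TRUE` rescales the displayed slope without changing h.
The slope sign carries the dynamics: negative is the neutral decay of the
steady state; positive means copies proliferated *after* diverging — a
recent population expansion or directional selection — and the half-life is
then undefined; slopes within `tol` (default 1e−6) of zero are flat.

The regression can be fed at two granularities: across consensus contigs of
one repeat class (one `DivergenceRecord` per contig, as in classic
divergence/copy-number scatter plots), or within a single large family by
binning the reads themselves by their divergence from the family consensus
(`binned_copy_profile()`, `estimate_family_halflife()`).  Both modes are
exposed because per-cluster and per-class regressions answer slightly
different questions and real analyses use both.

## The simulator is the ground truth

`simulate_family()` runs the birth–death count process by Gillespie
simulation and applies Poisson(&mu;·L·age) substitution events to each
surviving copy.  Two bookkeeping choices matter:

* **Insertions copy the conserved master element, not their parent's
  mutated state.**  Under literal parent-copying every root-to-tip lineage
  would carry the same total mutation time and all copies would sit at the
  same divergence — no decay curve would exist.  The master-gene reading is
  the standard interpretation under which divergence measures insertion
  age and the exponential law above holds; it also matches the biology of
  an active element maintained by selection while its dead copies decay.
* **`per_copy_divergence` counts substitution *events* per site**, the
  expected divergence from the ancestor, rather than the realized Hamming
  fraction.  The two differ only through multiple hits (about 5% at
  divergence 0.07); counting events keeps the exponential invariant exact,
  and the realized sequences are returned for anyone who wants Hamming
  values.

A critical process (&beta; = &delta;) started from a single copy dies or
stays small; the `n_initial` parameter starts the family at its stationary
size so that scenarios with 500+ surviving copies are reachable.  `duration`
is chosen in the shipped scenarios so that &delta;·T &ge; 5, making the
age-truncation at T negligible (&lt; 1% of mass).  A `copy_cap` (default
10,000) aborts supercritical explosions with a clear error; extinction is
reported, not an error.

`simulate_genome()` surrounds the TE families with the other repeat
signatures the analysis must distinguish: a tandem rDNA array whose units
are drawn at a fixed small divergence from the array master (default
&epsilon; = 0.003) — concerted evolution modelled by its observable
signature (high copy, near-zero diversity) rather than by an explicit
gene-conversion process; simple repeats as mutated tandem k-mers (k drawn
from 2–10, default stretch divergence 0.15); and i.i.d. background.
Features are shuffled, strands assigned uniformly, and the exact feature
table (BED-style, 0-based half-open) plus per-family truths are returned.
`shotgun_reads()` draws `round(coverage·G/L)` reads uniformly from both
strands, adds substitution errors, and encodes each read's true origin in
its name so that clustering can be scored against the planted truth.

What the simulator does **not** emulate — and hence what green tests do not
show about real data: indels and gapped alignment, LTR internal structure,
insertional nesting, non-uniform read sampling, quality-score decay along
reads, paired ends, and contamination.  Conclusions about those require
real reads.

## Clustering: thresholds and graph machinery

Edges join reads whose best alignment reaches **90% identity over at least
55% of the shorter read** — the published defaults of graph-based repeat
clustering pipelines, adopted here and exposed as `min_similarity` /
`min_overlap_fraction`.  Clusters are connected components: simpler and
fully deterministic compared to community detection; a pruning hook (drop
edges below a weight quantile before clustering) can approximate community
splitting if needed.  Reads with more than 10% ambiguous bases are dropped
first.  All tie-breaks are deterministic (cluster size, then smallest
member id), so runs are reproducible bit-for-bit under a fixed seed.

The all-to-all comparison is seeded by shared 13-mers: occurrences vote for
alignment diagonals and only the one or two best-supported diagonals per
read pair are evaluated, gaplessly, in C++.  For substitution-only data
this loses nothing; with indels it is a heuristic, which is why
`build_graph(method = "exact")` provides a full Smith–Waterman path
(match +1, mismatch −1, gap open −5, extend −2) used by the tests as the
reference.  A k of 13 makes chance seed hits between unrelated 100-bp reads
rare (~10<sup>−4</sup> per pair) while divergence up to ~10% still leaves
shared seeds in a 55-bp overlap with high probability.

Coverage matters: at several-fold coverage even single-copy sequence tiles
into chains of overlapping reads, which is why the classic protocol
subsamples to ~1x (`subsample()`) before clustering, and why
`repeat_fraction()` only counts clusters above a size threshold
(`min_cluster_fraction` of total reads).  The default threshold (10<sup>−4</sup>)
is calibrated for multi-million-read inputs; at desk scale (10<sup>3</sup>–10<sup>4</sup>
reads) a threshold of ~0.01 separates planted families from chance
background chains, and the pipeline exposes it in the `cluster` block.

Topology metrics label cluster shapes the way repeat-graph practitioners
read them: density &ge; 0.30 "dense-circularizable" (globular TE clusters),
density &le; 0.05 with BFS-diameter &ge; 10 "diffuse" (simple/low-complexity
repeats), otherwise "linear-thread".  The thresholds are package choices —
the shapes are qualitative in the literature — and are configurable.  The
diameter estimate takes the maximum eccentricity over at most 50 BFS seeds
(exact for clusters of up to 50 reads).

## Consensus assembly

`assemble_consensus()` is a greedy seed-and-extend layout: the
highest-degree read seeds a consensus; all cluster reads are remapped to it
each round (both orientations, gapless), overhangs extend it, and columns
are called by majority vote with ties resolved to the alphabetically first
base.  Rounds repeat until the sequence stabilizes (cap 30).  Two trimming
rules clean the ends: columns need depth &ge; 2 *and* a majority base
fraction &ge; 0.6, and depth at least a quarter of the contig median.  The
latter two matter because each genomic copy carries private flanking
sequence — boundary columns pile up high-depth but majority-free flank
bases, which would otherwise contaminate both &theta;<sub>&pi;</sub> (random
flank columns look maximally diverse) and copy number.  Contigs shorter
than 500 bp are discarded, the conventional cutoff for repeat-library
entries.

## Divergence and copy number

Reads are aligned back to the consensus contigs with the same seeded
gapless mapper (`align_reads()`, default identity cutoff 0.85; ties go to
the leftmost contig, then leftmost position).  Externally produced SAM
alignments can be ingested instead; records with indels are skipped, since
the estimators are substitution-only.

Per qualifying pileup site (depth &ge; `min_depth`, default 4 — common
pooled-sequencing practice), diversity is the unbiased estimator

> &pi;<sub>site</sub> = n/(n−1) · (1 − &Sigma;<sub>b</sub> (c<sub>b</sub>/n)²),

which equals the number of differing read pairs over C(n,2) exactly; the
test suite holds the two routes equal to 10<sup>−12</sup>.
&theta;<sub>&pi;</sub> is the mean over qualifying sites; if fewer than
`min_covered_fraction` (default 0.6) of positions qualify the record is
flagged low-coverage.  Copy number is mean depth over *all* contig
positions (zeros included) divided by `single_copy_depth`, the sampling
coverage — at 1x, raw depth is copy number.  Sequencing error is not
subtracted from &theta;<sub>&pi;</sub>; at error rate e it inflates
&pi; by ~2e(1−e), a shift of the intercept but not of regression slopes.
Per-read divergences feeding the binned half-life profile are Jukes–Cantor
corrected (`jc_correct()`) to undo multiple-hit saturation, and the binned
profile drops bins truncated by the divergence cutoff, which would
otherwise bias the slope.

## Annotation and cross-genome comparison

Contigs are classified by direct k-mer-seeded/local-alignment search
against a repeat library with `name#Class/Subclass` headers (thresholds
80% identity over 80 bp, package choices, configurable and echoed in
reports).  Cross-genome library similarity uses reciprocal best hits per
repeat class and reports the mean percent identity over RBH pairs — the
aggregation across multiple hits is a stated package choice; classes absent
from one library yield missing entries rather than zeros.  Contaminant
screening is classify-and-drop against a user-supplied FASTA; no database
is bundled.

## Ancestry networks

For one family, reads fully spanning a window (default: the contig's
highest-depth window, length capped below the read length so that spanning
reads exist) are collapsed into haplotypes with multiplicities.  The
ancestor–descendant network is a deliberately transparent surrogate for
Bayesian ancestral inference: a minimum spanning tree on pairwise Hamming
distances, rooted at the multiplicity-weighted medoid, edges directed away
from the root.  It is *not* a posterior; it reproduces the qualitative
readout that matters — a star (one ancestral haplotype spawning many
descendants, `star_score` near 1) versus a chain (gradual accumulation,
score near 0).  Arborescence invariants (|E| = |V|−1, acyclicity,
root-reachability) are asserted on every emitted network, and MST weight
optimality is checked against exhaustive spanning-tree enumeration in the
tests for up to 8 haplotypes.

## Group comparisons

`group_compare()` reports per-genome medians and standard deviations of
finite half-lives, all pairwise two-sided Mann–Whitney tests (exact for
groups of up to 20 without ties, normal approximation with tie correction
otherwise), and both one-way ANOVA and Kruskal–Wallis omnibus tests — the
latter added because half-life distributions are heavy-tailed.  No
multiplicity correction is applied by default; a `p_adjust` method can be
requested.

## Problem sizes and validation scenarios

The shipped validation scenarios are sized for a desktop: steady-state
recovery uses one family of ~1000 surviving 1-kb copies in a 1.1-Mb genome
read at 1x with 150-bp reads (half-life recovered within ±20%, typically
±10%); planted-cluster recovery uses two 100-copy families plus equal
background, 20,000 100-bp reads at 5x subsampled to 1x (&ge;95% of each
family's reads in one cluster and repeat fraction within ±0.05 of the
planted 0.5); the concerted-evolution scenario plants a 40-unit rDNA array
against two TE families and checks that rDNA sits strictly below every TE
family in &theta;<sub>&pi;</sub>.  Expansion dynamics are demonstrated with
pure-birth (&delta; = 0) families: amplification waves whose copy number
rises with their diversity give the positive slope, and a currently
bursting high-copy family gives the star signature (score &ge; 0.6).  A
family whose copies are literally all near-identical occupies a single
divergence bin and cannot be regressed — the wave construction is the
generative scenario consistent with "proliferation after divergence".

## A small worked run

```{r, eval = FALSE}
cfg <- list(
  seed = 7,
  simulate = list(
    families = list(
      list(family_id = "famA", element_length = 700, birth_rate = 0,
           death_rate = 0, mutation_rate = 0.02, duration = 1,
           n_initial = 25, seed = 8)),
    background_length = 15000,
    coverage = 2, read_length = 100, error_rate = 0.001),
  assembly = list(min_contig_length = 400),
  divergence = list(single_copy_depth = 2),
  cluster = list(min_cluster_fraction = 0.02))
run <- run_pipeline(cfg, out_dir = "run1")
run$records
summarize_run(run)
```

## Known limitations

Gapless alignment throughout (by design, matched to the substitution-only
simulator); indel-rich repeats need external alignments via the SAM path.
Tandem repeats assemble into consensus sequences of ill-defined unit count
(diagonal ambiguity), though their diversity estimates remain valid.
Copy numbers inherit a small negative bias (~read length / element length)
from junction reads whose flanking bases cannot align.  The ancestry
network is a point estimate with no uncertainty.  Absolute insertion-time
dating would need a substitution-rate calibration, which the package
deliberately does not assume.
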