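# repeatscape

Characterize the repeat landscape of a genome straight from low-coverage
shotgun reads — no assembly required.

Repetitive DNA (LTR retrotransposons, rDNA arrays, simple repeats) makes up
most of many plant genomes, and its turnover can be read from sequence data
alone: a repeat family's copies are sampled many times even at 1x coverage,
so reads from one family find each other by similarity.  `repeatscape`
implements that analysis end to end for people studying transposable-element
dynamics:

* **Clustering** — quality filtering, subsampling to a target coverage, an
  all-to-all read similarity graph (90% identity over ≥55% of the shorter
  read, k-mer seeded, C++ core), connected-component repeat clusters,
  graph-topology metrics and the repetitive genome fraction.
* **Consensus & annotation** — greedy majority-vote consensus contigs per
  cluster (≥500 bp), classification against a `name#Class/Subclass` repeat
  library, contaminant screening, and cross-genome repeat-library similarity
  via reciprocal best hits.
* **Divergence & copy number** — reads realigned to contigs, pileups, the
  unbiased per-site diversity
  `π = n/(n−1) · (1 − Σ_b (c_b/n)²)` averaged into θπ, and copy number as
  mean depth over single-copy depth.
* **Birth–death half-life** — under a steady-state birth–death model the
  copy count decays exponentially in divergence; the OLS slope *b* of
  `ln(copy number) ~ θπ` gives the family half-life `ln 2 / (−b)` (the
  divergence by which half of all insertions are lost), with dynamics
  classified by slope sign (decay / expansion / flat) and Mann–Whitney,
  ANOVA and Kruskal–Wallis comparisons across genomes.
* **Ancestry networks** — haplotypes from reads spanning a contig window,
  joined by a medoid-rooted minimum spanning tree whose directed edges read
  ancestor → descendant; a star score near 1 flags recent expansion.
* **Simulator** — a Gillespie birth–death TE simulator with exact ground
  truth (plus concerted rDNA, simple repeats and background), emitting
  FASTA/FASTQ/BED/TSV, used to validate every stage.

## Worked example

Simulate one steady-state family (β = δ = 5, μ = 5/13.8629, so the true
half-life is ln2·μ/δ = 0.0500), sample 1x reads, cluster, assemble the
consensus, and fit the half-life from the binned read divergences:

```r
library(repeatscape)

fp <- family_params("gypsy1", element_length = 1000, birth_rate = 5,
                    death_rate = 5, mutation_rate = 5 / 13.8629,
                    duration = 1, n_initial = 600, seed = 11)
genome <- simulate_genome(genome_config(families = list(fp),
                                        background_length = 80000, seed = 12))
reads  <- shotgun_reads(genome, coverage = 1, read_length = 150,
                        error_rate = 0.001, seed = 13)
seqs   <- setNames(as.character(reads), names(reads))

graph    <- build_graph(seqs)
clusters <- cluster_reads(graph)
contig   <- assemble_consensus(seqs, clusters$clusters[[1]], graph)
fit      <- estimate_family_halflife(seqs, contig[1], single_copy_depth = 1)
print(fit)
```

```
Half-life fit for 'c1' (7 points)
  slope -14.4292  intercept 5.1236  r^2 0.9633
  dynamics: decay; half-life: 0.0480 (4.80% divergence)
```

The fitted slope −14.43 is the decay rate −δ/μ of surviving copies with
divergence; the recovered half-life 0.048 sits within 5% of the true 0.050.
The per-contig record used for class-level regressions reads:

```r
aln <- align_reads(seqs, contig[1], min_identity = 0.8)
divergence_records(pileup(aln, contig[1]), single_copy_depth = 1)
#>   contig_id theta_pi mean_depth copy_number n_sites_used low_coverage
#> 1        c1    0.107        593         593          977        FALSE
```

θπ = 0.107 is the family's mean pairwise diversity (about twice the mean
copy age in divergence units), and mean depth 593 at 1x coverage estimates
~593 surviving copies (the simulation planted ~600).

`run_pipeline(config, out_dir)` chains every stage (filter → subsample →
cluster → assemble → annotate → align → divergence → half-life → networks)
from a single validated config list or YAML file and writes TSV/FASTA
outputs plus a parameter manifest; `summarize_run()` turns a run into the
per-class genome-percentage table.

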