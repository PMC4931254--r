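# smdb — single-molecule droplet barcoding: simulation, clustering, per-molecule variant calling

Short-read sequencing destroys long-range information: once a long DNA
molecule is fragmented, nothing ties its fragments back together. In
single-molecule droplet barcoding, individual templates are isolated in
picolitre droplets at limiting dilution, clonally amplified, fragmented,
and every fragment receives the droplet's barcode before sequencing. Reads
sharing a barcode are then regrouped into a *barcode cluster* — the set of
reads from one physical molecule — enabling synthetic long reads,
per-molecule haplotypes, and detection of variants far below the
sequencer's error floor.

`smdb` is for people building or analysing such libraries (and for anyone
who wants a fully controlled testbed for barcode-deconvolution methods).
It provides:

* **A generative simulator** (`simulate_run()`) of the droplet workflow —
  Poisson co-encapsulation (occupancy `p` ⇒ rate `λ = −log(1−p)`), a
  branching amplification process with per-cycle substitution errors,
  biased fragmentation (template-end depletion, optional GC bias),
  barcode mis-tagging, flat sequencing error — emitting R1/R2/I1 FASTQ
  plus complete ground-truth tables.
* **Barcode clustering** (`cluster_barcodes_dfs()`): depth-first-search
  connected components over the graph joining observed barcodes within
  Hamming distance 1, collapsing each error cloud onto its parent
  barcode; clusters with <500 read pairs are removed.
* **Cluster QC** (`dominant_template_fraction()`, `coverage_entropy()`):
  a cluster is *single-template* when >90% of its mapped reads hit one
  reference, and *viable* when the entropy of its normalised coverage,
  `H = −Σ p_i log2 p_i`, exceeds 7 bits with >100 reads.
* **Per-molecule variant calling** (`call_cluster_snps()`): mono-allelic
  SNPs (alt fraction ≥ 0.9, runner-up < 0.1) are kept as true template
  variants; di-allelic ~50/50 sites — the signature of a first-cycle
  amplification error — are suppressed. Consensus haplotypes, population
  SNP frequencies, neighbour-joining haplotype trees, and the detection
  limit `f_min = 1 − β^(1/n)` follow.
* **Loading & collision statistics** (`poisson_loading_stats()`,
  `barcode_collision_probability()`, `nn_hamming_stats()`).

See `vignettes/smdb-methods.Rmd` for the models, parameter meanings and
design decisions.

## Worked example

Simulate 2,000 droplets at the canonical operating point (occupancies
0.1/0.1, eight random 3–5 kb templates, 2% mis-tagging, 0.1% sequencing
error) and run the full analysis:

```r
library(smdb)
cfg <- sim_config(n_droplets = 2000, seed = 7)
simulate_run(cfg, "runs/demo")        # writes FASTQ + truth tables
run <- run_pipeline("runs/demo")      # cluster, map, QC, call
run
#> <smdb_run>
#>   reads                  36868 (18434 pairs)
#>   observed barcodes      262
#>   clusters (kept/all)    23 / 23
#>   single-template        91.3%
#>   viable                 100.0%
#>   mono-allelic SNPs      0
#>   LOD (beta = 0.05)      0.122
```

2,000 droplets at a 1-in-100 pairing rate gave 23 barcode clusters (the
262 observed barcode sequences are the 23 true barcodes plus their
sequencing-error cloud, collapsed by clustering). 91.3% of clusters are
single-template — the rest are Poisson double encapsulations — and all
are uniform enough to assemble (entropy ≈ 11.9 bits vs the ≈ 12 bit
maximum for these templates; threshold 7). No mono-allelic SNPs is the
right answer here: the eight templates *are* the references.

```r
head(run$qc[, c("cluster_id", "n_reads", "dominant_reference",
                "dominant_fraction", "entropy")], 3)
#>   cluster_id n_reads dominant_reference dominant_fraction  entropy
#> 1    bc00001    1738              tpl01         0.9753231 11.88343
#> 2    bc00002    1686              tpl06         0.9768997 11.66990
#> 3    bc00003    1674              tpl01         0.9829268 11.89450
```

Dominant fractions sit near 0.98, not 1.0 — that is the 2% mis-tagging
background, visible but safely above the 0.9 single-template line.

The closed-form loading arithmetic:

```r
poisson_loading_stats(0.1, 0.1, 1e6)
#> Poisson loading at occupancies 0.100 (template) / 0.100 (barcode)
#>   lambda_template                0.1054
#>   P(single | occupied)           0.9482
#>   pairing (productive) fraction  0.0100  (~1 in 100 droplets)
#>   droplets                       1e+06
#>   expected barcoded templates    1e+04
#>   expected barcode droplets      1e+05

limit_of_detection(3000, 0.05)
#> [1] 0.000998079   # a 0.1% variant is detectable from 3,000 molecules
```

A command-line wrapper covers the same stages
(`inst/scripts/smdb simulate|cluster|qc|call|stats|pipeline`).

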