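---
title: "Single-molecule droplet barcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule droplet barcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdb)
```

## The problem

Short-read sequencers read a few hundred bases at a time, and once a long
DNA molecule is fragmented for sequencing, the information about which
fragments came from the *same* molecule is lost. Droplet barcoding restores
it: single template molecules are co-encapsulated with single barcode
species in picolitre droplets at limiting dilution, clonally amplified,
fragmented, and every fragment is tagged with its droplet's barcode before
sequencing. Reads sharing a (error-corrected) barcode can then be regrouped
into per-molecule *barcode clusters*, which makes three things possible that
pooled short reads cannot do:

* **synthetic long reads** — each cluster covers one template end to end and
  can be assembled independently;
* **rare-variant detection far below the sequencer's error floor** — a true
  template variant appears in essentially *all* reads of its cluster,
  while sequencing errors are diluted across the cluster;
* **direct haplotypes** — the SNPs co-occurring in one cluster sit on one
  physical molecule by construction.

`smdb` implements this computational workflow end to end, together with a
generative simulator of the wet-lab process so that every stage can be
validated against a known ground truth.

## Poisson loading

Both templates and barcodes are loaded at limiting dilution. We
parameterise by the *occupancy* $p$ = P(a droplet holds at least one
molecule), the quantity a lab actually titrates, and derive the Poisson
rate $\lambda = -\log(1-p)$. A droplet is *productive* when it holds at
least one template and a barcode, so

$$P(\text{productive}) = p_t \, p_b,$$

which at the canonical $p_t = p_b = 0.1$ gives 1 productive droplet in 100:
$10^6$ droplets yield $\sim 10^4$ barcoded templates.

```{r}
poisson_loading_stats(0.1, 0.1, 1e6)
```

The price of dilution is multiple occupancy: conditional on being occupied,
a droplet holds a single template with probability
$\lambda e^{-\lambda}/(1-e^{-\lambda})$ (about 95% at $p=0.1$). The ~5%
multi-template droplets are the main source of impure clusters downstream.

Because barcodes are drawn at random from $4^L$ sequences, two templates
can collide on one barcode. `barcode_collision_probability()` evaluates the
exact birthday-problem product rather than the exponential approximation
(both are reported); at $L = 15$ and a few thousand templates the
probability of *any* collision is below 1%.

## The simulator

`simulate_run()` chains four stages, all driven by one seeded RNG stream so
that a seed fixes the run byte for byte:

1. **`encapsulate()`** — Poisson template counts, independent barcode
   arrival, optional droplet coalescence (coalesced droplets are removed
   before emission, as merged droplets are discarded in the real
   workflow).
2. **`amplify()`** — a branching copy process: every molecule is copied
   each cycle with probability `amplification_efficiency`, and each copy
   event adds independent per-base substitutions at
   `per_base_error_per_cycle`. Mutations are stored as position/alt sets
   and inherited along the lineage, so a substitution made in the single
   first-cycle copy event ends up in exactly half of a fully efficient
   pool — the signature that separates amplification errors from true
   variants. Pools are capped (default 512 molecules) by deterministic
   evenly-spaced subsampling; computations that need the exact $2^c$ pool
   (such as the 50% check) pass an explicit larger cap.
3. **`fragment()`** — fragment lengths uniform over a configured range;
   start positions uniform, then rejection-sampled against (a) a linear
   acceptance ramp over the terminal `end_bias_depth` bases, emulating
   transposase end depletion, and (b) a GC weight
   $\exp(-g\,\lvert \mathrm{GC}_{\text{frag}} - 0.5\rvert)$.
4. **`barcode_and_sequence()`** — paired reads from the fragment ends (R2
   reverse-complemented), a barcode read I1, flat per-base substitution
   error on all three, and whole-read barcode swaps at `mis_tag_rate`
   emulating chimeric mis-tagging.

Every emitted pair gets a truth row (droplet, template, true barcode,
mis-tag flag, inherited substitutions), which is what the test-suite
oracles consume.

Default parameters are the workflow's canonical operating point:
occupancies 0.1/0.1, 15-nt barcodes, 25 PCR cycles at efficiency 1 with
per-cycle error $10^{-6}$, fragments 350–1000 bp, 250 bp reads with
$10^{-3}$ sequencing error, 2% mis-tagging, 250 bp end-bias depth, GC bias
off. Two quantities have no canonical published value and are package
choices: the mean number of read pairs per productive droplet
(`pairs_per_droplet`, default 800 — a desk-scale stand-in for the few
thousand reads per cluster of a full sequencing run) and the eight default
templates, drawn at random with lengths 3–5 kb to match a known-template
validation library.

**What the simulator does not model:** indels (the mapper and caller are
substitution-only; indel-bearing real data should enter through
`parse_sam_minimal()`), quality-score profiles beyond a flat error rate,
chimeric breakpoints inside reads (mis-tagging swaps whole reads), droplet
volume/chemistry, and MDA-style amplification kinetics. Passing tests
therefore demonstrate correctness of the algorithms under a clean
substitution-error regime, not robustness to every artefact of real
libraries.

## Barcode clustering

Amplification and sequencing errors surround each true barcode with a
"cloud" of mutated copies, typically one substitution away, while distinct
random 15-mers sit on average about three substitutions apart. This gap is
what makes error correction by clustering safe.

`cluster_barcodes_dfs()` builds a graph whose edges join observed barcodes
within Hamming distance `max_dist` (default 1) and takes connected
components by iterative depth-first search. Two design choices matter:

* **Neighbour search.** For `max_dist = 1` neighbours are found by
  enumerating the $3L$ single-substitution variants of each barcode and
  looking them up in a hash, which is exact and near-linear; a blocked
  pairwise scan is the fallback for larger radii.
* **Low-count barcodes** (below `min_count`, default 2) cannot seed or
  bridge components — a rare artefact halfway between two true barcodes
  must not fuse their clusters. They are attached to a neighbouring
  component when one exists and dropped otherwise; dropped counts are
  reported so read totals always reconcile.

`hamming_distance()` counts `N` as a mismatch against everything,
including another `N`: an unread base never supports identity. Clusters
with fewer than 500 read pairs are removed (`filter_clusters()`): they
carry too little coverage for per-molecule analysis. The read-pair
convention (the barcode read is one record per pair) and the threshold are
both exposed as arguments.

## Cluster QC

**Dominant-template fraction.** For each cluster, reads are mapped
(`map_reads_simple()`: exact 20-mer seed, both strands, ungapped extension,
best-mismatch wins, ties flagged) and the fraction of mapped reads on the
most-hit reference is computed. A cluster is *single-template* when that
fraction exceeds 0.9 — strictly, so a 50/50 co-encapsulation is never
"single". With 2% mis-tagging, genuine single-molecule clusters sit near
0.98, comfortably above the threshold, and the classification is driven by
the ~5% multi-template droplets, as intended.

**Coverage entropy.** Coverage uniformity is summarised as the Shannon
entropy of the normalised per-base coverage $p_i$ over *all* positions of
the reference:

$$H = -\sum_{p_i > 0} p_i \log_2 p_i .$$

Uniform coverage over a length-$L$ reference maximises $H$ at $\log_2 L$;
coverage piled on one position gives 0. Taking the denominator over the
full reference (not only covered positions) makes "peaky" and "flat"
clusters of the same template directly comparable. The logarithm base is
configurable; the viability default pairs base 2 with a threshold of 7
bits, and the two must be changed together (a nats threshold of 7 would
mean something entirely different). A cluster is *viable* when entropy
exceeds 7 and it has more than 100 reads; either gate can be disabled, and
whether "reads" means records or pairs is an explicit argument since
conventions differ between instruments.

**Contig evaluation.** Externally assembled contigs are scored by
`contig_accuracy_eval()`: 250 bp are trimmed from each contig end (end
coverage is depleted by the fragmentation bias, so contig ends are
unreliable), the trimmed contig is placed on its reference by seed match,
and mismatches are reported overall and in 50 bp bins on a Phred scale
$-10\log_{10}(\max(m,1)/\text{bin})$.

## Variant calling

`pileup_cluster()` builds per-position base counts from a cluster's
alignments; `N` bases are tabulated but excluded from allele fractions.
`call_cluster_snps()` then applies the mono-allelic rule at every column
with non-N depth ≥ 10 (the depth default is ours; only the mono-allelic
principle is canonical):

* the strongest non-reference allele at fraction ≥ 0.9, with every other
  allele below 0.1 → a **mono-allelic SNP**, a true template variant;
* a (co-)dominant non-reference allele with a persistent second allele →
  recorded as **di-allelic and suppressed**. This is precisely the
  first-cycle amplification error: an error in the first copy event
  propagates to ~50% of reads and masquerades as heterozygosity in a
  single molecule.

Because each cluster is one molecule, the fraction of clusters carrying a
SNP (`population_snp_frequencies()`) estimates its population frequency
directly — a 5% variant planted in the simulator is recovered within its
exact binomial confidence interval. Consensus sequences are the reference
with each called SNP substituted (`consensus_and_haplotypes()`), identical
SNP sets are collapsed with multiplicity, and `build_tree()` builds a
neighbour-joining tree over the symmetric-difference distances between SNP
sets, with the reference included as a taxon. Neighbour joining was chosen
over maximum likelihood deliberately: it is deterministic,
dependency-light, and exact on additive distances, which is all a
topology-level analysis of consensus haplotypes needs; consensus FASTA is
exported for external ML tools.

The limit of detection follows from sampling alone: a variant at frequency
$f$ is missed by all $n$ sequenced molecules with probability $(1-f)^n$,
so at type-II error $\beta$

$$f_{\min} = 1 - \beta^{1/n},$$

e.g. $n = 3000$, $\beta = 0.05$ gives $f_{\min} \approx 10^{-3}$, and the
limit keeps falling as more molecules are sequenced — unlike pooled
sequencing, whose floor is set by the error rate of the instrument.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at the SAM and VCF boundaries (1-based).
* FASTQ qualities are Phred+33 only; lowercase bases are uppercased on
  input.
* Ties are broken deterministically throughout: cluster representatives
  and mapper ties go to the lexicographically smallest candidate (and are
  flagged), the caller's allele ordering is alphabetical within equal
  counts.
* All-zero coverage profiles and occupancies of exactly 1 are errors, not
  silent NaNs; empty read sets, empty barcode tables and empty call sets
  flow through as empty results.
* Every stochastic entry point demands a seed; a fixed seed reproduces
  simulator output byte-identically.

## Problem sizes used in the checks

The packaged checks run the whole workflow at desk scale, chosen so the
suite completes in about a minute: simulated runs of $10^3$–$10^4$
droplets (tens to ~100 productive droplets), 40–800 read pairs per
droplet, templates of 0.7–5 kb, and ~500 sequenced molecules for the
planted-variant recovery. These sizes are two orders of magnitude below a
real sequencing run in read count; the statistics asserted (Poisson
pairing, purity percentages, frequency recovery, entropy contrasts) are
scale-free or carry explicit binomial tolerances, so the conclusions
transfer, but absolute cluster counts from a full MiSeq-scale library are
out of desk-scale reach by design.

## Known limitations

* The mapper is ungapped and substitution-only; structural variation and
  indels are invisible to it (import external alignments instead).
* Mis-tagging is modelled as whole-read swaps; partial chimeras would
  look slightly different in real data.
* The entropy threshold/base pairing is a convention, not a derived
  constant; recalibrate it if you change the base or bin coverage.
* Collision statistics assume uniform random barcodes; synthesis
  composition bias would raise collision rates slightly.
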