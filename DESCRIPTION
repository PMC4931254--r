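Package: smdb
Title: Single-Molecule Droplet Barcoding: Simulation, Barcode Clustering and
    Per-Molecule Variant Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing droplet-barcoded sequencing libraries in
    which single long DNA templates are isolated, clonally amplified,
    fragmented and tagged with a droplet barcode before short-read
    sequencing. Provides a generative simulator of the droplet workflow
    (Poisson co-encapsulation at limiting dilution, per-cycle amplification
    errors, biased fragmentation, barcode mis-tagging, sequencing error)
    with full ground-truth tables; Hamming-distance depth-first-search
    clustering of barcode reads; cluster quality control via
    dominant-template purity and coverage entropy; per-cluster pileup,
    mono-allelic SNP calling, consensus haplotype reconstruction and
    neighbour-joining haplotype trees; and analytic calculators for Poisson
    loading yields, barcode collision probabilities and the limit of
    detection of rare variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
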