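# End-to-end pipeline: simulate (or load) a run, cluster barcodes, QC
# clusters, call per-molecule SNPs, and summarise.

#' Run the full droplet-barcoding analysis
#'
#' Chains barcode extraction, Hamming-distance clustering, the read-count
#' filter, read mapping, cluster QC (dominant-template fraction, coverage
#' entropy, viability), per-cluster mono-allelic SNP calling, population
#' SNP frequencies and consensus haplotypes. Inputs are either a directory
#' written by [simulate_run()] or explicit read/reference sets.
#'
#' @param input Directory containing `reads_R1.fastq.gz`,
#'   `reads_R2.fastq.gz`, `reads_I1.fastq.gz` and `references.fasta`
#'   (e.g. from [simulate_run()]), or a list with elements `r1`, `r2`,
#'   `i1` (read data.frames) and `references`.
#' @param out_dir Optional output directory for TSV/VCF/FASTA/JSON
#'   artifacts.
#' @param barcode_length Barcode length (default 15).
#' @param max_dist Clustering edge threshold (default 1).
#' @param min_count Minimum barcode observations to seed a component
#'   (default 2).
#' @param min_reads Cluster read-count filter, counting pairs once
#'   (default 500).
#' @param entropy_min,reads_min Viability gates (defaults 7 bits / 100
#'   read records).
#' @param min_depth,mono_frac,di_frac SNP-caller thresholds.
#' @param max_mismatch_frac Mapper mismatch tolerance (default 0.05).
#' @return List of class `smdb_run`: `clusters`, `qc` (per-cluster table),
#'   `viability`, `calls`, `di_allelic`, `frequencies`, `haplotypes`,
#'   `summary` (flat list), `alignments`.
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         barcode_length = 15L, max_dist = 1L,
                         min_count = 2L, min_reads = 500L,
                         entropy_min = 7, reads_min = 100L,
                         min_depth = 10L, mono_frac = 0.9, di_frac = 0.1,
                         max_mismatch_frac = 0.05) {
  if (is.character(input)) {
    input <- list(
      r1 = parse_fastq(file.path(input, "reads_R1.fastq.gz")),
      r2 = parse_fastq(file.path(input, "reads_R2.fastq.gz")),
      i1 = parse_fastq(file.path(input, "reads_I1.fastq.gz")),
      references = parse_fasta(file.path(input, "references.fasta"))
    )
  }
  references <- input$references
  tab <- extract_barcodes(input$i1, barcode_length)
  clusters <- cluster_barcodes_dfs(tab, max_dist = max_dist,
                                   min_count = min_count)
  kept <- filter_clusters(clusters, min_reads = min_reads)
  idx <- build_reference_index(references)
  r1 <- input$r1; r1$id <- paste0(r1$id, "/1")
  r2 <- input$r2; r2$id <- paste0(r2$id, "/2")
  al <- map_reads_simple(rbind(r1, r2), idx,
                         max_mismatch_frac = max_mismatch_frac)
  al$pair_id <- sub("/[12]$", "", al$read_id)
  # cluster membership is per pair; expand to both mates
  kept <- lapply(kept, function(cl) {
    cl$read_ids <- c(paste0(cl$read_ids, "/1"), paste0(cl$read_ids, "/2"))
    cl
  })
  qc <- cluster_qc_table(kept, al, references)
  via <- viability_filter(qc, entropy_min = entropy_min,
                          reads_min = reads_min)
  ref_by_id <- stats::setNames(references$sequence, references$id)
  calls_list <- vector("list", length(kept))
  dial_list <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    cl <- kept[[i]]
    if (is.na(qc$dominant_reference[i])) next
    dom <- qc$dominant_reference[i]
    cl_al <- al[al$read_id %in% cl$read_ids & al$mapped &
                  al$reference_id == dom, , drop = FALSE]
    cols <- pileup_cluster(cl_al, ref_by_id[[dom]], dom)
    cc <- call_cluster_snps(cols, cl$cluster_id, min_depth = min_depth,
                            mono_frac = mono_frac, di_frac = di_frac)
    calls_list[[i]] <- cc
    dial_list[[i]] <- attr(cc, "di_allelic")
  }
  calls <- do.call(rbind, calls_list[!vapply(calls_list, is.null, TRUE)])
  if (is.null(calls)) calls <- call_cluster_snps(
    data.frame(reference_id = character(), position = integer(),
               ref_base = character(), A = integer(), C = integer(),
               G = integer(), T = integer(), N = integer(),
               depth = integer()))
  dial <- do.call(rbind, dial_list[!vapply(dial_list, is.null, TRUE)])
  freqs <- population_snp_frequencies(calls, max(length(kept), 1L))
  haplotypes <- NULL
  if (length(kept) && length(unique(references$id)) == 1L) {
    haplotypes <- consensus_and_haplotypes(
      calls, references$sequence[1],
      cluster_ids = vapply(kept, `[[`, "", "cluster_id"))
  }
  summary <- list(
    n_reads = nrow(input$r1) + nrow(input$r2),
    n_pairs = nrow(input$r1),
    n_observed_barcodes = nrow(tab),
    n_clusters_all = length(clusters),
    n_clusters_kept = length(kept),
    pct_single_template = if (nrow(qc)) 100 * mean(qc$single_template)
                          else NA_real_,
    pct_viable = if (nrow(qc)) 100 * nrow(via$viable) / nrow(qc)
                 else NA_real_,
    n_mono_allelic_snps = nrow(calls),
    n_haplotypes = if (is.null(haplotypes)) NA_integer_ else nrow(haplotypes),
    lod_beta05 = if (length(kept)) limit_of_detection(length(kept), 0.05)
                 else NA_real_
  )
  out <- structure(list(clusters = kept, qc = qc, viability = via,
                        calls = calls, di_allelic = dial,
                        frequencies = freqs, haplotypes = haplotypes,
                        summary = summary, alignments = al),
                   class = "smdb_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir, references)
  out
}

write_run_outputs <- function(run, out_dir, references) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  assign_rows <- lapply(run$clusters, function(cl) {
    data.frame(read_id = cl$read_ids, cluster_id = cl$cluster_id,
               representative = cl$representative, stringsAsFactors = FALSE)
  })
  if (length(assign_rows)) wt(do.call(rbind, assign_rows), "assignments.tsv")
  wt(cluster_summary(run$clusters), "clusters.tsv")
  wt(run$qc, "cluster_qc.tsv")
  if (nrow(run$calls)) wt(run$calls, "snp_calls.tsv")
  write_snps_vcf(run$calls, file.path(out_dir, "snp_calls.vcf"))
  if (!is.null(run$frequencies$frequencies) &&
      nrow(run$frequencies$frequencies)) {
    wt(run$frequencies$frequencies, "snp_frequencies.tsv")
  }
  if (!is.null(run$haplotypes)) {
    wt(run$haplotypes[, setdiff(names(run$haplotypes), "consensus")],
       "haplotypes.tsv")
    write_fasta(data.frame(id = run$haplotypes$haplotype_id,
                           sequence = run$haplotypes$consensus),
                file.path(out_dir, "consensus.fasta"))
    if (nrow(run$haplotypes) >= 2L) {
      ape::write.tree(build_tree(run$haplotypes),
                      file.path(out_dir, "haplotypes.nwk"))
    }
  }
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.smdb_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<smdb_run>\n",
    "  reads                  %d (%d pairs)\n",
    "  observed barcodes      %d\n",
    "  clusters (kept/all)    %d / %d\n",
    "  single-template        %.1f%%\n",
    "  viable                 %.1f%%\n",
    "  mono-allelic SNPs      %d\n",
    "  LOD (beta = 0.05)      %.3g\n"),
    s$n_reads, s$n_pairs, s$n_observed_barcodes, s$n_clusters_kept,
    s$n_clusters_all, s$pct_single_template, s$pct_viable,
    s$n_mono_allelic_snps, s$lod_beta05))
  invisible(x)
}
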