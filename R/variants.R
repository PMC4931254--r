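# Per-cluster pileup, mono-allelic SNP calling, consensus haplotypes,
# population SNP frequencies, haplotype trees, and the limit-of-detection
# model.
#
# Because all reads in a cluster derive from one molecule, a true template
# variant appears in essentially every read (mono-allelic), whereas an
# error made in the first round of droplet amplification propagates to
# ~50% of reads (di-allelic) and is suppressed.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

#' Pile up a cluster's alignments on one reference
#'
#' One column per covered position; N bases are counted under N and
#' excluded from allele fractions downstream.
#'
#' @param alignments Alignment data.frame (rows on other references
#'   ignored); substitution-only, reference-oriented sequences.
#' @param reference `seq_record`, sequence string, or data.frame row.
#' @param reference_id Reference to pile up (default: the reference's id,
#'   or the single reference id present in `alignments`).
#' @return data.frame: `reference_id`, `position` (0-based), `ref_base`,
#'   `A`, `C`, `G`, `T`, `N`, `depth`; covered positions only.
#' @export
pileup_cluster <- function(alignments, reference, reference_id = NULL) {
  if (is.data.frame(reference)) {
    if (is.null(reference_id)) reference_id <- reference$id[1]
    reference <- reference$sequence[1]
  } else if (inherits(reference, "seq_record")) {
    if (is.null(reference_id)) reference_id <- reference$id
    reference <- reference$sequence
  }
  al <- alignments[alignments$mapped, , drop = FALSE]
  if (!is.null(reference_id) && "reference_id" %in% names(al)) {
    al <- al[al$reference_id == reference_id, , drop = FALSE]
  }
  L <- nchar(reference)
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(names(BASE_CODES), NULL))
  if (nrow(al)) {
    code_of <- integer(256)
    code_of[utf8ToInt("A")] <- 1L; code_of[utf8ToInt("C")] <- 2L
    code_of[utf8ToInt("G")] <- 3L; code_of[utf8ToInt("T")] <- 4L
    code_of[utf8ToInt("N")] <- 5L
    # accumulate in chunks via tabulate over a combined (base, position) key
    chunk <- 2000L
    for (lo in seq(1L, nrow(al), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(al))
      keys <- vector("list", hi - lo + 1L)
      for (i in lo:hi) {
        b <- code_of[as.integer(charToRaw(al$aligned_sequence[i]))]
        p <- al$start[i] + seq_along(b)
        keys[[i - lo + 1L]] <- (p - 1L) * 5L + b
      }
      tab <- tabulate(unlist(keys), nbins = 5L * L)
      counts <- counts + matrix(tab, nrow = 5L)
    }
  }
  depth <- colSums(counts)
  covered <- which(depth > 0L)
  if (length(covered) == 0L) {
    return(data.frame(reference_id = character(), position = integer(),
                      ref_base = character(), A = integer(), C = integer(),
                      G = integer(), T = integer(), N = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  data.frame(reference_id = if (is.null(reference_id)) NA_character_
             else reference_id,
             position = covered - 1L,
             ref_base = strsplit(reference, "", fixed = TRUE)[[1]][covered],
             A = counts[1L, covered], C = counts[2L, covered],
             G = counts[3L, covered], T = counts[4L, covered],
             N = counts[5L, covered],
             depth = as.integer(depth[covered]),
             stringsAsFactors = FALSE)
}

#' Call mono-allelic SNPs for one cluster
#'
#' At each column with depth >= `min_depth` (non-N depth), the top non-N
#' allele is examined. If it differs from the reference and its fraction is
#' at least `mono_frac` while the runner-up stays below `di_frac`, a
#' mono-allelic SNP is emitted. If the top allele differs from the
#' reference but the runner-up reaches `di_frac`, the site is recorded as
#' di-allelic and suppressed (the first-cycle amplification-error
#' signature). Reference-dominant sites emit nothing.
#'
#' @param columns Pileup from [pileup_cluster()].
#' @param cluster_id Carried into the calls.
#' @param min_depth Minimum non-N depth (default 10).
#' @param mono_frac Minimum top-allele fraction (default 0.9).
#' @param di_frac Runner-up fraction marking a di-allelic site
#'   (default 0.1).
#' @return data.frame of mono-allelic calls: `cluster_id`, `reference_id`,
#'   `position`, `ref_base`, `alt_base`, `alt_fraction`, `depth`,
#'   `mono_allelic` (all TRUE). Suppressed di-allelic sites are attached as
#'   `attr(, "di_allelic")`.
#' @export
call_cluster_snps <- function(columns, cluster_id = NA_character_,
                              min_depth = 10L, mono_frac = 0.9,
                              di_frac = 0.1) {
  empty <- data.frame(cluster_id = character(), reference_id = character(),
                      position = integer(), ref_base = character(),
                      alt_base = character(), alt_fraction = numeric(),
                      depth = integer(), mono_allelic = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(columns) == 0L) {
    attr(empty, "di_allelic") <- empty
    return(empty)
  }
  m <- as.matrix(columns[, c("A", "C", "G", "T")])
  acgt_depth <- rowSums(m)
  keep <- acgt_depth >= min_depth
  calls <- list(); dial <- list()
  for (i in which(keep)) {
    cnt <- m[i, ]
    # candidate alt = strongest non-reference allele (ties: alphabetical)
    nonref <- cnt[names(cnt) != columns$ref_base[i]]
    alt <- names(nonref)[order(-nonref, names(nonref))][1]
    f_alt <- cnt[[alt]] / acgt_depth[i]
    if (f_alt < di_frac) next  # reference-dominant site
    f_second <- max(cnt[names(cnt) != alt]) / acgt_depth[i]
    row <- data.frame(cluster_id = cluster_id,
                      reference_id = columns$reference_id[i],
                      position = columns$position[i],
                      ref_base = columns$ref_base[i],
                      alt_base = alt,
                      alt_fraction = unname(f_alt),
                      depth = unname(acgt_depth[i]),
                      stringsAsFactors = FALSE)
    if (f_alt >= mono_frac && f_second < di_frac) {
      row$mono_allelic <- TRUE
      calls[[length(calls) + 1L]] <- row
    } else if (f_alt >= f_second) {
      # alt is (co-)dominant but a second allele persists: the
      # first-cycle amplification-error signature, recorded and suppressed
      row$mono_allelic <- FALSE
      dial[[length(dial) + 1L]] <- row
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty
  attr(out, "di_allelic") <- if (length(dial)) do.call(rbind, dial) else empty
  rownames(out) <- NULL
  out
}

#' Population frequency of each SNP across clusters
#'
#' Each cluster represents one template molecule, so the fraction of
#' clusters carrying a SNP estimates its frequency among templates.
#'
#' @param calls data.frame of mono-allelic calls across clusters (rbind of
#'   [call_cluster_snps()] outputs).
#' @param n_clusters Total number of clusters analysed (the denominator).
#' @return List: `frequencies` (data.frame `reference_id`, `position`,
#'   `ref_base`, `alt_base`, `n_clusters`, `frequency`) sorted by
#'   decreasing frequency, and `fraction_no_snp` (fraction of clusters with
#'   zero calls).
#' @export
population_snp_frequencies <- function(calls, n_clusters) {
  stopifnot(n_clusters > 0)
  if (nrow(calls) == 0L) {
    return(list(frequencies = data.frame(reference_id = character(),
                                         position = integer(),
                                         ref_base = character(),
                                         alt_base = character(),
                                         n_clusters = integer(),
                                         frequency = numeric(),
                                         stringsAsFactors = FALSE),
                fraction_no_snp = 1.0))
  }
  key <- paste(calls$reference_id, calls$position, calls$alt_base, sep = ":")
  agg <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    r <- calls[idx[1], c("reference_id", "position", "ref_base", "alt_base")]
    r$n_clusters <- length(unique(calls$cluster_id[idx]))
    r
  })
  freq <- do.call(rbind, agg)
  freq$frequency <- freq$n_clusters / n_clusters
  freq <- freq[order(-freq$frequency, freq$position), ]
  rownames(freq) <- NULL
  list(frequencies = freq,
       fraction_no_snp = 1 - length(unique(calls$cluster_id)) / n_clusters)
}

snp_key <- function(calls) {
  if (nrow(calls) == 0L) return("")
  paste(sort(paste0(calls$position, calls$alt_base)), collapse = ";")
}

#' Build per-molecule consensus sequences and deduplicated haplotypes
#'
#' The consensus of a cluster is the reference with each called SNP
#' substituted at its position; clusters with identical SNP sets collapse
#' into one haplotype with recorded multiplicity.
#'
#' @param calls Mono-allelic calls across clusters.
#' @param reference `seq_record` or sequence string (single reference).
#' @param cluster_ids Ids of all clusters under analysis (clusters without
#'   calls form the reference-identical haplotype); default: ids present in
#'   `calls`.
#' @return data.frame of haplotypes: `haplotype_id`, `snp_key`, `n_snps`,
#'   `multiplicity`, `cluster_ids` (comma string), `consensus`; sorted by
#'   decreasing multiplicity.
#' @export
consensus_and_haplotypes <- function(calls, reference, cluster_ids = NULL) {
  ref_seq <- if (inherits(reference, "seq_record")) reference$sequence
             else reference
  if (is.null(cluster_ids)) cluster_ids <- unique(calls$cluster_id)
  by_cl <- split(calls, factor(calls$cluster_id, levels = cluster_ids))
  # mono-allelic gate makes within-cluster position conflicts impossible
  for (cl in by_cl) {
    stopifnot(!anyDuplicated(cl$position))
  }
  keys <- vapply(by_cl, snp_key, "")
  ukeys <- unique(keys)
  rows <- lapply(ukeys, function(k) {
    ids <- names(keys)[keys == k]
    cl_calls <- by_cl[[ids[1]]]
    cons <- ref_seq
    if (nrow(cl_calls)) {
      s <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
      s[cl_calls$position + 1L] <- cl_calls$alt_base
      cons <- paste0(s, collapse = "")
    }
    data.frame(snp_key = k, n_snps = nrow(cl_calls),
               multiplicity = length(ids),
               cluster_ids = paste(ids, collapse = ","),
               consensus = cons, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$multiplicity, out$n_snps), ]
  out <- cbind(data.frame(haplotype_id = sprintf("h%03d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Neighbour-joining tree over haplotypes
#'
#' Pairwise distances are the sizes of the symmetric differences of the
#' haplotypes' SNP sets (a Hamming distance on the implied consensus
#' sequences); the reference (empty SNP set) is included as a taxon. The
#' tree is built by neighbour joining — deterministic and adequate for
#' topology-level analysis; consensus sequences can be exported for
#' external maximum-likelihood tools.
#'
#' @param haplotypes data.frame from [consensus_and_haplotypes()] (distinct
#'   haplotypes; duplicates must already be collapsed).
#' @param include_reference Add a "reference" taxon with no SNPs (default
#'   TRUE; skipped when a zero-SNP haplotype is already present).
#' @return An `ape::phylo` tree with haplotype ids as tip labels.
#' @export
build_tree <- function(haplotypes, include_reference = TRUE) {
  sets <- lapply(strsplit(haplotypes$snp_key, ";", fixed = TRUE),
                 function(x) x[nzchar(x)])
  labels <- haplotypes$haplotype_id
  if (include_reference && !any(lengths(sets) == 0L)) {
    sets <- c(sets, list(character(0)))
    labels <- c(labels, "reference")
  }
  n <- length(sets)
  if (n < 3L) {
    stop("build_tree: need at least 2 distinct haplotypes besides the ",
         "reference (neighbour joining requires 3 taxa)")
  }
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- length(union(sets[[i]], sets[[j]])) -
        length(intersect(sets[[i]], sets[[j]]))
    }
  }
  ape::nj(stats::as.dist(d))
}

#' Limit of detection of a rare variant
#'
#' With `n` molecules sampled and detection defined as at least one sampled
#' molecule carrying the variant, the smallest detectable frequency at
#' type-II error `beta` solves `(1 - f)^n <= beta`:
#' `f = 1 - beta^(1/n)`. Strictly decreasing in `n`.
#'
#' @param n_templates Number of molecules sequenced (>= 1).
#' @param beta Accepted probability of missing the variant, in (0, 1).
#' @return Minimal detectable variant frequency.
#' @export
limit_of_detection <- function(n_templates, beta = 0.05) {
  stopifnot(all(n_templates >= 1))
  if (any(beta <= 0 | beta >= 1)) {
    stop("limit_of_detection: beta must be in (0, 1)")
  }
  1 - beta^(1 / n_templates)
}

#' Write mono-allelic SNP calls as a minimal single-sample VCF
#'
#' VCFv4.2, one record per call, positions converted to 1-based; the
#' cluster id is carried in the INFO field.
#'
#' @param calls data.frame from [call_cluster_snps()] (possibly rbind-ed).
#' @param path Output path.
#' @param reference_name Name written in the header.
#' @return `path`, invisibly.
#' @export
write_snps_vcf <- function(calls, path, reference_name = "reference") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##reference=", reference_name),
               "##INFO=<ID=CLUSTER,Number=1,Type=String,Description=\"Barcode cluster id\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Within-cluster allele fraction\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Non-N depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCLUSTER=%s;AF=%.4f;DP=%d",
                       calls$reference_id, calls$position + 1L,
                       calls$ref_base, calls$alt_base, calls$cluster_id,
                       calls$alt_fraction, calls$depth), con)
  }
  invisible(path)
}
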