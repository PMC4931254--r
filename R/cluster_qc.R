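# Cluster quality control: mapping cluster reads back to references,
# dominant-template purity (single-template classification), coverage
# profiles and their informational entropy, viability filtering, and
# contig-accuracy conventions for externally assembled contigs.

#' Build a k-mer seed index over references
#'
#' @param references data.frame (`id`, `sequence`).
#' @param k Seed length (default 20). References shorter than `k` are
#'   skipped with a warning.
#' @return Index object used by [map_reads_simple()].
#' @export
build_reference_index <- function(references, k = 20L) {
  keep <- nchar(references$sequence) >= k
  if (any(!keep)) {
    warning("build_reference_index: skipped ",
            sum(!keep), " reference(s) shorter than k = ", k)
  }
  references <- references[keep, , drop = FALSE]
  ord <- order(references$id)
  references <- references[ord, , drop = FALSE]
  kmers <- character(0); ref_i <- integer(0); pos <- integer(0)
  for (i in seq_len(nrow(references))) {
    s <- references$sequence[i]
    L <- nchar(s)
    starts <- seq_len(L - k + 1L)
    kmers <- c(kmers, substring(s, starts, starts + k - 1L))
    ref_i <- c(ref_i, rep(i, length(starts)))
    pos <- c(pos, starts - 1L)
  }
  uk <- unique(kmers)
  hits <- split(seq_along(kmers), factor(kmers, levels = uk))
  list(k = k,
       references = references,
       ref_raw = lapply(references$sequence, charToRaw),
       ref_len = nchar(references$sequence),
       unique_kmers = uk,
       hits = hits,
       hit_ref = ref_i,
       hit_pos = pos)
}

# first offset (0-based) of a k-long window without N, or NA
first_clean_window <- function(seq, k) {
  npos <- gregexpr("N", seq, fixed = TRUE)[[1]]
  if (npos[1] == -1L) return(0L)
  L <- nchar(seq)
  cand <- 0L
  for (p in c(npos, L + 1L)) {
    if (p - cand >= k) return(cand)
    cand <- p
  }
  NA_integer_
}

#' Map reads to references by exact seed and ungapped extension
#'
#' The first N-free `k`-mer of the read (and of its reverse complement) is
#' looked up in the reference index; each hit implies an ungapped,
#' full-length alignment whose mismatches are counted directly. The best
#' reference (fewest mismatches) wins; a read is unmapped when its best
#' alignment has more than `max_mismatch_frac * length` mismatches. Ties
#' across references go to the lexicographically smallest reference id and
#' are flagged `ambiguous`. Substitution-only: indel-bearing data should
#' come through [parse_sam_minimal()].
#'
#' @param reads Read data.frame (`id`, `sequence`).
#' @param references data.frame (`id`, `sequence`), or a prebuilt index
#'   from [build_reference_index()].
#' @param max_mismatch_frac Mismatch tolerance as a fraction of read length
#'   (default 0.05).
#' @param k Seed length when `references` is a data.frame.
#' @return data.frame of aligned reads: `read_id`, `reference_id`, `start`
#'   (0-based), `strand` (+/-), `aligned_sequence` (reference-oriented),
#'   `n_mismatch`, `mapped`, `ambiguous`.
#' @export
map_reads_simple <- function(reads, references, max_mismatch_frac = 0.05,
                             k = 20L) {
  idx <- if (is.data.frame(references)) {
    build_reference_index(references, k)
  } else references
  k <- idx$k
  n <- nrow(reads)
  out_ref <- rep(NA_character_, n)
  out_start <- rep(NA_integer_, n)
  out_strand <- rep(NA_character_, n)
  out_seq <- rep(NA_character_, n)
  out_mm <- rep(NA_integer_, n)
  out_amb <- rep(FALSE, n)
  fwd <- reads$sequence
  rev <- revcomp(fwd)
  # seed lookups for both orientations, vectorised via match()
  seed_at <- vapply(fwd, first_clean_window, 0L, k = k, USE.NAMES = FALSE)
  seed_at_r <- vapply(rev, first_clean_window, 0L, k = k, USE.NAMES = FALSE)
  sf <- substring(fwd, seed_at + 1L, seed_at + k)
  sr <- substring(rev, seed_at_r + 1L, seed_at_r + k)
  mf <- match(sf, idx$unique_kmers)
  mr <- match(sr, idx$unique_kmers)
  for (i in seq_len(n)) {
    cands <- list()
    if (!is.na(mf[i])) {
      cands <- c(cands, list(list(strand = "+", s0 = seed_at[i],
                                  hits = idx$hits[[mf[i]]],
                                  seq = fwd[i])))
    }
    if (!is.na(mr[i])) {
      cands <- c(cands, list(list(strand = "-", s0 = seed_at_r[i],
                                  hits = idx$hits[[mr[i]]],
                                  seq = rev[i])))
    }
    if (length(cands) == 0L) next
    len <- nchar(fwd[i])
    best_mm <- Inf; best <- NULL; tie <- FALSE
    for (cd in cands) {
      rr <- charToRaw(cd$seq)
      for (h in cd$hits) {
        ri <- idx$hit_ref[h]
        start <- idx$hit_pos[h] - cd$s0
        if (start < 0L || start + len > idx$ref_len[ri]) next
        mm <- sum(idx$ref_raw[[ri]][(start + 1L):(start + len)] != rr)
        if (mm < best_mm) {
          best_mm <- mm
          best <- list(ref = ri, start = start, strand = cd$strand,
                       seq = cd$seq)
          tie <- FALSE
        } else if (mm == best_mm && !is.null(best) && ri != best$ref) {
          tie <- TRUE  # references already in lexicographic order
        }
      }
    }
    if (is.null(best) || best_mm > max_mismatch_frac * len) next
    out_ref[i] <- idx$references$id[best$ref]
    out_start[i] <- best$start
    out_strand[i] <- best$strand
    out_seq[i] <- best$seq
    out_mm[i] <- as.integer(best_mm)
    out_amb[i] <- tie
  }
  data.frame(read_id = reads$id, reference_id = out_ref, start = out_start,
             strand = out_strand, aligned_sequence = out_seq,
             n_mismatch = out_mm, mapped = !is.na(out_ref),
             ambiguous = out_amb, stringsAsFactors = FALSE)
}

#' Dominant-template purity of a barcode cluster
#'
#' Over the cluster's *mapped* reads, reports the fraction mapping to the
#' dominant template (argmax over references), the number of references
#' attracting more than 10% of mapped reads, and the single-template
#' classification (dominant fraction > 0.9).
#'
#' @param alignments Alignment data.frame for one cluster (from
#'   [map_reads_simple()] or [parse_sam_minimal()]).
#' @param cluster_id Optional id carried through to the report.
#' @param single_template_min Dominant-fraction threshold (default 0.9).
#' @param above_frac Reporting threshold for "references above" count
#'   (default 0.1).
#' @return One-row data.frame: `cluster_id`, `n_reads`, `n_mapped`,
#'   `dominant_reference`, `dominant_fraction`, `n_references_above_10pct`,
#'   `single_template`, `tied`.
#' @export
dominant_template_fraction <- function(alignments, cluster_id = NA_character_,
                                       single_template_min = 0.9,
                                       above_frac = 0.1) {
  mapped <- alignments[alignments$mapped, , drop = FALSE]
  n_mapped <- nrow(mapped)
  if (n_mapped == 0L) {
    return(data.frame(cluster_id = cluster_id, n_reads = nrow(alignments),
                      n_mapped = 0L, dominant_reference = NA_character_,
                      dominant_fraction = NA_real_,
                      n_references_above_10pct = 0L,
                      single_template = FALSE, tied = FALSE,
                      stringsAsFactors = FALSE))
  }
  counts <- sort(table(mapped$reference_id), decreasing = TRUE)
  frac <- as.numeric(counts) / n_mapped
  tied <- length(counts) > 1L && frac[2] == frac[1]
  data.frame(cluster_id = cluster_id, n_reads = nrow(alignments),
             n_mapped = n_mapped,
             dominant_reference = names(counts)[1],
             dominant_fraction = frac[1],
             n_references_above_10pct = sum(frac > above_frac),
             single_template = frac[1] > single_template_min,
             tied = tied, stringsAsFactors = FALSE)
}

#' Per-position coverage of a cluster on one reference
#'
#' @param alignments Alignment data.frame (rows on other references are
#'   ignored).
#' @param reference_id Reference to profile.
#' @param reference_length Length of that reference.
#' @param cluster_id Optional id.
#' @return A `coverage_profile`: list with `cluster_id`, `reference_id`,
#'   `depth` (integer vector over all reference positions), `n_reads`.
#' @export
coverage_profile <- function(alignments, reference_id, reference_length,
                             cluster_id = NA_character_) {
  al <- alignments[alignments$mapped &
                     alignments$reference_id == reference_id, , drop = FALSE]
  depth <- integer(reference_length)
  if (nrow(al)) {
    lens <- nchar(al$aligned_sequence)
    # difference-array accumulation of [start, start+len) intervals
    d <- integer(reference_length + 1L)
    starts <- al$start + 1L
    ends <- pmin(al$start + lens, reference_length) + 1L
    for (i in seq_along(starts)) {
      d[starts[i]] <- d[starts[i]] + 1L
      d[ends[i]] <- d[ends[i]] - 1L
    }
    depth <- cumsum(d[seq_len(reference_length)])
  }
  structure(list(cluster_id = cluster_id, reference_id = reference_id,
                 depth = as.integer(depth), n_reads = nrow(al)),
            class = "coverage_profile")
}

#' Informational entropy of a coverage distribution
#'
#' Normalises depth over *all* reference positions to a probability
#' distribution and returns `H = -sum(p_i log_base p_i)` over positions with
#' nonzero depth. Uniform coverage over the whole reference maximises H at
#' `log_base(reference length)`; coverage piled on one position gives 0.
#' The (base, threshold) pair used for viability must be chosen together.
#'
#' @param profile A `coverage_profile`, or a bare depth vector.
#' @param base Logarithm base (default 2: bits).
#' @return Entropy (non-negative real).
#' @export
coverage_entropy <- function(profile, base = 2) {
  depth <- if (inherits(profile, "coverage_profile")) profile$depth else profile
  tot <- sum(as.numeric(depth))
  if (tot <= 0) stop("coverage_entropy: all-zero coverage profile")
  p <- depth[depth > 0] / tot
  -sum(p * log(p, base = base))
}

#' Partition cluster reports into viable and non-viable
#'
#' A cluster is viable when its coverage entropy exceeds `entropy_min` and
#' its read count exceeds `reads_min` (either gate can be disabled with
#' `NULL`). Entropy > 7 bits (roughly uniform coverage over >128 effective
#' positions) together with > 100 reads marks clusters assemblable into
#' full-length templates.
#'
#' @param reports data.frame with columns `entropy` and `n_reads` (e.g.
#'   from [cluster_qc_table()]).
#' @param entropy_min Entropy gate (default 7 bits); NULL disables.
#' @param reads_min Read-count gate (default 100 read records); NULL
#'   disables.
#' @param total_reads Optional total reads sequenced, for the
#'   read-utilization summary; defaults to `sum(reports$n_reads)`.
#' @return List: `viable`, `non_viable` (row subsets), and `utilization`
#'   (viable clusters per million reads).
#' @export
viability_filter <- function(reports, entropy_min = 7, reads_min = 100L,
                             total_reads = NULL) {
  ok <- rep(TRUE, nrow(reports))
  if (!is.null(entropy_min)) ok <- ok & reports$entropy > entropy_min
  if (!is.null(reads_min)) ok <- ok & reports$n_reads > reads_min
  ok[is.na(ok)] <- FALSE
  if (is.null(total_reads)) total_reads <- sum(reports$n_reads)
  list(viable = reports[ok, , drop = FALSE],
       non_viable = reports[!ok, , drop = FALSE],
       utilization = if (total_reads > 0) sum(ok) / total_reads * 1e6
                     else NA_real_)
}

#' Full QC table for a set of clusters
#'
#' Runs [dominant_template_fraction()], builds the coverage profile on each
#' cluster's dominant reference and computes its entropy.
#'
#' @param clusters List of `barcode_cluster`s.
#' @param alignments Alignment data.frame for all reads (read ids matching
#'   cluster membership).
#' @param references data.frame (`id`, `sequence`).
#' @param entropy_base Logarithm base for entropy (default 2).
#' @return data.frame with one row per cluster: purity fields plus
#'   `entropy`. Coverage profiles are attached as `attr(, "profiles")`.
#' @export
cluster_qc_table <- function(clusters, alignments, references,
                             entropy_base = 2) {
  ref_len <- stats::setNames(nchar(references$sequence), references$id)
  al_by_read <- split(seq_len(nrow(alignments)), alignments$read_id)
  profiles <- vector("list", length(clusters))
  rows <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    rows_i <- unlist(al_by_read[cl$read_ids], use.names = FALSE)
    al <- alignments[rows_i, , drop = FALSE]
    rep_row <- dominant_template_fraction(al, cl$cluster_id)
    ent <- NA_real_
    if (!is.na(rep_row$dominant_reference)) {
      prof <- coverage_profile(al, rep_row$dominant_reference,
                               ref_len[[rep_row$dominant_reference]],
                               cl$cluster_id)
      profiles[[i]] <- prof
      ent <- coverage_entropy(prof, base = entropy_base)
    }
    rep_row$entropy <- ent
    rows[[i]] <- rep_row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  out
}

#' Evaluate an assembled contig against its reference
#'
#' Trims `end_trim` bases from both contig ends (coverage is depleted near
#' template termini, so contig ends are unreliable), locates the trimmed
#' contig on the reference by exact seed match, and reports percent
#' identity plus per-bin mismatch counts and a per-bin Phred-scaled
#' accuracy `-10*log10(max(mismatches, 1)/bin)`.
#'
#' @param contig,reference `seq_record`s or sequence strings.
#' @param end_trim Bases trimmed from each contig end (default 250).
#' @param bin Bin width for positional accuracy (default 50).
#' @return List: `identity_pct`, `n_mismatch`, `span`, `offset` (0-based
#'   reference offset of the trimmed contig), `bins` (data.frame
#'   `bin_start`, `mismatches`, `phred`).
#' @export
contig_accuracy_eval <- function(contig, reference, end_trim = 250L,
                                 bin = 50L) {
  cs <- if (inherits(contig, "seq_record")) contig$sequence else contig
  rs <- if (inherits(reference, "seq_record")) reference$sequence else reference
  L <- nchar(cs)
  if (L < 2L * end_trim + bin) {
    stop("contig_accuracy_eval: contig (", L, " bp) shorter than 2*end_trim",
         " + bin = ", 2L * end_trim + bin)
  }
  trimmed <- substr(cs, end_trim + 1L, L - end_trim)
  # locate by seed; slide the seed until it matches (tolerates a mismatch
  # inside the first window)
  k <- 20L
  off <- -1L
  for (s0 in seq(0L, nchar(trimmed) - k, by = k)) {
    hit <- regexpr(substr(trimmed, s0 + 1L, s0 + k), rs, fixed = TRUE)
    if (hit > 0L) { off <- as.integer(hit) - 1L - s0; break }
  }
  if (off < 0L || off + nchar(trimmed) > nchar(rs)) {
    stop("contig_accuracy_eval: could not place contig on reference")
  }
  a <- charToRaw(trimmed)
  b <- charToRaw(substr(rs, off + 1L, off + length(a)))
  mism <- a != b
  n_mm <- sum(mism)
  span <- length(a)
  bin_start <- seq(0L, span - 1L, by = bin)
  mm_by_bin <- vapply(bin_start, function(s) {
    sum(mism[(s + 1L):min(s + bin, span)])
  }, 0L)
  bins <- data.frame(bin_start = bin_start, mismatches = mm_by_bin,
                     phred = -10 * log10(pmax(mm_by_bin, 1L) / bin))
  list(identity_pct = 100 * (1 - n_mm / span), n_mismatch = n_mm,
       span = span, offset = off, bins = bins)
}
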