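# Minimal, dialect-explicit sequence I/O.
#
# Conventions used throughout the package:
#   * coordinates are 0-based, half-open; conversion to/from 1-based happens
#     only at the SAM/VCF boundary
#   * FASTQ qualities are Phred+33; no Phred+64 support
#   * sequences are uppercased on read; alphabet {A,C,G,T,N}

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a sequence record
#'
#' A named sequence with optional per-base Phred qualities, used for
#' templates, consensus sequences and individual reads.
#'
#' @param id Non-empty identifier.
#' @param sequence String over A/C/G/T/N (lowercase is uppercased).
#' @param qualities Optional integer vector of Phred scores, one per base.
#' @return An object of class `seq_record` (a list with fields `id`,
#'   `sequence`, `qualities`).
#' @export
seq_record <- function(id, sequence, qualities = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("sequence for '", id, "' contains characters outside {A,C,G,T,N}: ",
         substr(bad, 1, 10))
  }
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(sequence)) {
      stop("qualities length (", length(qualities),
           ") != sequence length (", nchar(sequence), ") for '", id, "'")
    }
    if (any(qualities < 0L)) stop("negative Phred quality for '", id, "'")
  }
  structure(list(id = id, sequence = sequence, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp%s)\n", x$id, nchar(x$sequence),
              if (is.null(x$qualities)) "" else ", with qualities"))
  invisible(x)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors (one per input string).
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#' @param q Integer vector of Phred scores.
#' @return A single quality string.
#' @export
int_to_phred <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

#' Reverse-complement DNA sequences
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

open_text <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Parse a 4-line FASTQ file
#'
#' Qualities are decoded as Phred+33 and kept as the raw quality string in
#' the `qual` column (decode on demand with [phred_to_int()]); sequences are
#' uppercased. Gzip input is handled transparently by file extension.
#'
#' @param path Path to a FASTQ (optionally .gz) file.
#' @return A data.frame with columns `id`, `sequence`, `qual`, one row per
#'   read, in file order. Empty file gives zero rows.
#' @export
parse_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", n,
         " lines is not a multiple of 4 (truncated record near line ", n, ")")
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- toupper(lines[seq(2L, n, by = 4L)])
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad_at <- which(!startsWith(hdr, "@"))
  if (length(bad_at)) {
    stop("malformed FASTQ '", path, "': missing '@' at line ",
         (bad_at[1L] - 1L) * 4L + 1L)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ '", path, "': missing '+' at line ",
         (bad_plus[1L] - 1L) * 4L + 3L)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    stop("malformed FASTQ '", path, "': sequence/quality length mismatch at line ",
         (bad_len[1L] - 1L) * 4L + 2L)
  }
  ids <- sub("^@", "", hdr)
  ids <- sub("\\s.*$", "", ids)
  data.frame(id = ids, sequence = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#' @param reads data.frame with columns `id`, `sequence`, `qual`, or a list
#'   of `seq_record`s with qualities.
#' @param path Output path; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_frame(reads, need_qual = TRUE)
  con <- open_text(path, "wt")
  on.exit(close(con))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$qual
  writeLines(out, con)
  invisible(path)
}

as_read_frame <- function(reads, need_qual = FALSE) {
  if (is.data.frame(reads)) return(reads)
  if (inherits(reads, "seq_record")) reads <- list(reads)
  data.frame(
    id = vapply(reads, `[[`, "", "id"),
    sequence = vapply(reads, `[[`, "", "sequence"),
    qual = vapply(reads, function(r) {
      if (is.null(r$qualities)) {
        if (need_qual) stop("record '", r$id, "' has no qualities")
        NA_character_
      } else int_to_phred(r$qualities)
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Parse a FASTA file
#'
#' Multi-line sequences are concatenated and uppercased. A header with no
#' sequence lines yields an empty sequence with a warning.
#'
#' @param path Path to a FASTA (optionally .gz) file.
#' @return A data.frame with columns `id`, `sequence`.
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("malformed FASTA '", path, "': sequence before first '>' header")
  }
  grp <- cumsum(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste0, "", collapse = "")
  out <- character(length(ids))
  names(out) <- as.character(seq_along(ids))
  out[names(seqs)] <- seqs
  empty <- !nzchar(out)
  if (any(empty)) {
    warning("FASTA '", path, "': ", sum(empty),
            " header(s) with empty sequence: ",
            paste(utils::head(ids[empty], 3L), collapse = ", "))
  }
  data.frame(id = ids, sequence = toupper(unname(out)),
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#' @param seqs data.frame with `id`, `sequence` columns, a named character
#'   vector, or a list of `seq_record`s.
#' @param path Output path; `.gz` suffix compresses.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs) && !is.null(names(seqs))) {
    seqs <- data.frame(id = names(seqs), sequence = unname(seqs),
                       stringsAsFactors = FALSE)
  } else if (!is.data.frame(seqs)) {
    seqs <- as_read_frame(seqs)
  }
  con <- open_text(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$sequence[i]
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

# -- SAM import (minimal subset) ---------------------------------------------

parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Parse a SAM file (minimal subset)
#'
#' Consumes only QNAME, FLAG, RNAME, POS, CIGAR and SEQ. POS is converted to
#' the package's 0-based convention; reads with the unmapped flag (0x4) are
#' returned with `mapped = FALSE`. Soft-clipped bases are trimmed from the
#' aligned sequence; records whose CIGAR contains operations other than
#' M, =, X or S are skipped with a warning.
#'
#' @param path Path to a text SAM file (optionally .gz).
#' @param references Optional data.frame (`id`, `sequence`); when given,
#'   mismatch positions (0-based reference offsets) are computed for mapped
#'   reads and returned in the list-column `mismatch_positions`.
#' @return A data.frame of aligned reads: `read_id`, `reference_id`, `start`
#'   (0-based), `aligned_sequence`, `mapped`, and `mismatch_positions` when
#'   `references` is supplied.
#' @export
parse_sam_minimal <- function(path, references = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  n_skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) {
      n_skipped <- n_skipped + 1L
      next
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) {
      rows[[i]] <- data.frame(read_id = f[1], reference_id = NA_character_,
                              start = NA_integer_,
                              aligned_sequence = NA_character_,
                              mapped = FALSE, stringsAsFactors = FALSE)
      next
    }
    cig <- parse_cigar(f[6])
    if (any(!cig$op %in% c("M", "=", "X", "S"))) {
      n_skipped <- n_skipped + 1L
      next
    }
    seq <- toupper(f[10])
    # trim soft clips off the aligned span
    if (length(cig$op) && cig$op[1] == "S") {
      seq <- substr(seq, cig$len[1] + 1L, nchar(seq))
    }
    no <- length(cig$op)
    if (no && cig$op[no] == "S") {
      seq <- substr(seq, 1L, nchar(seq) - cig$len[no])
    }
    rows[[i]] <- data.frame(read_id = f[1], reference_id = f[3],
                            start = as.integer(f[4]) - 1L,
                            aligned_sequence = seq, mapped = TRUE,
                            stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    warning("parse_sam_minimal: skipped ", n_skipped,
            " record(s) with unsupported CIGAR operations or too few fields")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(read_id = character(), reference_id = character(),
                      start = integer(), aligned_sequence = character(),
                      mapped = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (!is.null(references)) {
    refs <- stats::setNames(references$sequence, references$id)
    out$mismatch_positions <- lapply(seq_len(nrow(out)), function(i) {
      if (!out$mapped[i]) return(integer())
      ref <- refs[[out$reference_id[i]]]
      s <- out$start[i]
      a <- charToRaw(out$aligned_sequence[i])
      b <- charToRaw(substr(ref, s + 1L, s + length(a)))
      s + which(a != b) - 1L
    })
  }
  out
}

#' Replace low-quality bases with N
#'
#' Every base whose Phred quality is below `q_min` is replaced with N;
#' qualities and length are unchanged. Operates on a single `seq_record`
#' (which must carry qualities) or on a read data.frame with a `qual`
#' column. Idempotent.
#'
#' @param read A `seq_record` with qualities, or a data.frame with columns
#'   `sequence` and `qual`.
#' @param q_min Phred threshold; bases with quality `< q_min` are masked.
#' @return The input with masked sequences.
#' @export
mask_low_quality <- function(read, q_min = 20L) {
  if (inherits(read, "seq_record")) {
    if (is.null(read$qualities)) {
      stop("mask_low_quality: record '", read$id, "' has no qualities")
    }
    s <- strsplit(read$sequence, "", fixed = TRUE)[[1]]
    s[read$qualities < q_min] <- "N"
    return(seq_record(read$id, paste0(s, collapse = ""), read$qualities))
  }
  if (!is.data.frame(read) || is.null(read$qual)) {
    stop("mask_low_quality: expected a seq_record or data.frame with 'qual'")
  }
  thr <- as.raw(33L + q_min)
  n_raw <- charToRaw("N")
  read$sequence <- vapply(seq_len(nrow(read)), function(i) {
    s <- charToRaw(read$sequence[i])
    q <- charToRaw(read$qual[i])
    s[q < thr] <- n_raw
    rawToChar(s)
  }, "")
  read
}
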