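# Barcode extraction and Hamming-distance clustering.
#
# Errors during barcode amplification and sequencing surround each original
# barcode with a "cloud" of mutated sequences sitting ~1 Hamming distance
# from their nearest neighbour, while original barcodes sit ~3 apart. The
# clustering below collapses each cloud onto its parent by depth-first
# search over the graph whose edges join barcodes within `max_dist`.

#' Hamming distance between two equal-length strings
#'
#' Counts positions with differing symbols; `N` mismatches every base,
#' including another `N`.
#'
#' @param a,b Strings of equal length.
#' @return Integer distance.
#' @export
hamming_distance <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming_distance: unequal lengths (", length(ra), " vs ",
         length(rb), ")")
  }
  n_raw <- charToRaw("N")
  sum(ra != rb | ra == n_raw)
}

#' Tabulate barcode sequences from reads
#'
#' Takes the barcode from the I1 read (default) or from a configured offset
#' of R1. Reads whose barcode is not exactly `barcode_length` long are
#' skipped (count reported via message); barcodes containing N are
#' tabulated but flagged.
#'
#' @param reads Barcode read data.frame (`id`, `sequence`) — the I1 set, or
#'   R1 when `offset` is given.
#' @param barcode_length Expected barcode length (default 15).
#' @param offset 0-based offset of an embedded barcode within `reads`
#'   sequences; NULL (default) uses the whole read (I1 convention).
#' @return A `barcode_table`: data.frame (`barcode`, `count`, `has_n`)
#'   sorted by decreasing count, with the read ids per barcode in
#'   `attr(, "read_ids")`.
#' @export
extract_barcodes <- function(reads, barcode_length = 15L, offset = NULL) {
  bc <- if (is.null(offset)) reads$sequence else
    substring(reads$sequence, offset + 1L, offset + barcode_length)
  ok <- nchar(bc) == barcode_length
  if (any(!ok)) {
    message("extract_barcodes: skipped ", sum(!ok),
            " read(s) with barcode length != ", barcode_length)
  }
  bc <- bc[ok]
  ids <- reads$id[ok]
  read_ids <- split(ids, bc)
  tab <- data.frame(barcode = names(read_ids),
                    count = lengths(read_ids),
                    stringsAsFactors = FALSE)
  tab$has_n <- grepl("N", tab$barcode, fixed = TRUE)
  ord <- order(-tab$count, tab$barcode)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "read_ids") <- read_ids[tab$barcode]
  class(tab) <- c("barcode_table", "data.frame")
  tab
}

# all sequences at Hamming distance exactly 1 from x (substitutions over
# A/C/G/T; used for exact neighbour lookup at max_dist = 1)
one_mismatch_neighbours <- function(x) {
  L <- nchar(x)
  bases <- c("A", "C", "G", "T")
  out <- character(3L * L)
  k <- 0L
  for (i in seq_len(L)) {
    b <- substring(x, i, i)
    for (alt in bases[bases != b]) {
      k <- k + 1L
      out[k] <- paste0(substring(x, 1L, i - 1L), alt,
                       substring(x, i + 1L, L))
    }
  }
  out[seq_len(k)]
}

# adjacency lists among `barcodes` at Hamming distance <= max_dist.
# max_dist = 1 uses single-mismatch enumeration (exact, near-linear);
# larger radii fall back to blocked pairwise comparison.
barcode_adjacency <- function(barcodes, max_dist = 1L) {
  n <- length(barcodes)
  adj <- vector("list", n)
  if (n <= 1L) return(adj)
  if (max_dist == 1L && !any(grepl("N", barcodes, fixed = TRUE))) {
    for (i in seq_len(n)) {
      hit <- match(one_mismatch_neighbours(barcodes[i]), barcodes)
      hit <- hit[!is.na(hit)]
      adj[[i]] <- hit
    }
    return(adj)
  }
  # pairwise fallback (also handles N-containing barcodes, where N
  # mismatches everything)
  L <- nchar(barcodes[1])
  m <- matrix(unlist(strsplit(barcodes, "", fixed = TRUE)), nrow = n,
              byrow = TRUE)
  is_n <- m == "N"
  block <- 512L
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    d <- matrix(0L, hi - lo + 1L, n)
    for (j in seq_len(L)) {
      d <- d + outer(m[lo:hi, j], m[, j], "!=") +
        outer(is_n[lo:hi, j], is_n[, j], "&")
    }
    for (i in lo:hi) {
      hit <- which(d[i - lo + 1L, ] <= max_dist)
      adj[[i]] <- hit[hit != i]
    }
  }
  adj
}

# iterative depth-first search returning a component label per node
dfs_components <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- adj[[v]]
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

#' Cluster barcodes by depth-first search over the Hamming graph
#'
#' Builds a graph with an edge between barcodes at Hamming distance
#' `<= max_dist` (among barcodes observed at least `min_count` times) and
#' takes connected components by depth-first search. Barcodes below
#' `min_count` are attached to a neighbouring component when one exists
#' (preferring the highest-count neighbour; ties broken lexicographically)
#' and dropped otherwise, so that rare sequencing artefacts cannot bridge
#' two true clusters. The representative is the highest-count member (ties:
#' lexicographically smallest); a representative containing N is never
#' chosen while an N-free member exists.
#'
#' @param table A `barcode_table` from [extract_barcodes()], or any
#'   data.frame with `barcode` and `count` columns.
#' @param max_dist Edge threshold (default 1: mutated barcodes sit ~1
#'   distance from their parent, true barcodes ~3 apart).
#' @param min_count Minimum observations for a barcode to seed a component
#'   (default 2).
#' @return List of `barcode_cluster` objects ordered by decreasing
#'   `total_reads`: each has `cluster_id`, `representative`, `members`
#'   (data.frame barcode/count), `read_ids`, `total_reads`. Dropped
#'   barcodes are recorded in `attr(, "dropped")`.
#' @export
cluster_barcodes_dfs <- function(table, max_dist = 1L, min_count = 2L) {
  if (nrow(table) == 0L) {
    out <- list()
    attr(out, "dropped") <- table
    return(out)
  }
  if (length(unique(nchar(table$barcode))) != 1L) {
    stop("cluster_barcodes_dfs: barcodes of mixed length")
  }
  read_ids <- attr(table, "read_ids")
  high <- table$count >= min_count
  hb <- table$barcode[high]
  comp <- if (length(hb)) dfs_components(barcode_adjacency(hb, max_dist))
          else integer(0)
  assign_of <- stats::setNames(comp, hb)
  # attach low-count barcodes to a neighbouring component
  lb <- table$barcode[!high]
  dropped <- character(0)
  low_assign <- integer(0)
  if (length(lb)) {
    cnt_of <- stats::setNames(table$count[high], hb)
    low_assign <- vapply(lb, function(b) {
      nb <- if (max_dist == 1L && !grepl("N", b, fixed = TRUE)) {
        intersect(one_mismatch_neighbours(b), hb)
      } else {
        hb[vapply(hb, function(h) hamming_distance(h, b) <= max_dist, TRUE)]
      }
      if (length(nb) == 0L) return(NA_integer_)
      nb <- nb[order(-cnt_of[nb], nb)]
      assign_of[[nb[1L]]]
    }, 0L)
    dropped <- lb[is.na(low_assign)]
  }
  all_bc <- c(hb, lb[!is.na(low_assign)])
  all_comp <- c(comp, low_assign[!is.na(low_assign)])
  clusters <- lapply(split(all_bc, all_comp), function(members) {
    cnt <- table$count[match(members, table$barcode)]
    ord <- order(-cnt, members)
    members <- members[ord]; cnt <- cnt[ord]
    # prefer an N-free representative
    rep_pool <- members[!grepl("N", members, fixed = TRUE)]
    representative <- if (length(rep_pool)) rep_pool[1L] else members[1L]
    ids <- if (is.null(read_ids)) character(0) else
      unname(unlist(read_ids[members]))
    structure(list(cluster_id = NA_character_,
                   representative = representative,
                   members = data.frame(barcode = members, count = cnt,
                                        stringsAsFactors = FALSE),
                   read_ids = ids,
                   total_reads = sum(cnt)),
              class = "barcode_cluster")
  })
  clusters <- unname(clusters)
  ord <- order(-vapply(clusters, `[[`, 0, "total_reads"),
               vapply(clusters, `[[`, "", "representative"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$cluster_id <- sprintf("bc%05d", i)
  }
  attr(clusters, "dropped") <-
    table[table$barcode %in% dropped, c("barcode", "count")]
  clusters
}

#' @export
print.barcode_cluster <- function(x, ...) {
  cat(sprintf("<barcode_cluster> %s rep=%s members=%d reads=%d\n",
              x$cluster_id, x$representative, nrow(x$members),
              x$total_reads))
  invisible(x)
}

#' Remove under-sequenced barcode clusters
#'
#' Clusters with fewer than `min_reads` reads contain too little
#' information for per-molecule analysis and are removed. A read pair
#' counts once (the barcode read is one record per pair).
#'
#' @param clusters List of `barcode_cluster`s.
#' @param min_reads Minimum `total_reads` to retain (default 500).
#' @return Retained clusters, ordered by decreasing `total_reads`.
#' @export
filter_clusters <- function(clusters, min_reads = 500L) {
  keep <- vapply(clusters, `[[`, 0, "total_reads") >= min_reads
  kept <- clusters[keep]
  ord <- order(-vapply(kept, `[[`, 0, "total_reads"))
  kept[ord]
}

#' Summarise clusters as a data.frame
#' @param clusters List of `barcode_cluster`s.
#' @return data.frame: `cluster_id`, `representative`, `n_barcodes`,
#'   `total_reads`.
#' @export
cluster_summary <- function(clusters) {
  data.frame(
    cluster_id = vapply(clusters, `[[`, "", "cluster_id"),
    representative = vapply(clusters, `[[`, "", "representative"),
    n_barcodes = vapply(clusters, function(cl) nrow(cl$members), 0L),
    total_reads = vapply(clusters, function(cl) as.integer(cl$total_reads), 0L),
    stringsAsFactors = FALSE
  )
}
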