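# Pileup, mono-allelic SNP calling, haplotypes, trees, limit of detection.

mk_alignments <- function(reads, starts, ref_id = "ref") {
  n <- length(reads)
  data.frame(read_id = sprintf("r%d", seq_len(n)),
             reference_id = rep(ref_id, n), start = starts,
             strand = rep("+", n), aligned_sequence = reads,
             n_mismatch = rep(0L, n), mapped = rep(TRUE, n),
             ambiguous = rep(FALSE, n), stringsAsFactors = FALSE)
}

test_that("pileup counts every aligned base once, with N segregated", {
  ref <- "ACGTACGTAC"
  al <- mk_alignments(rep("GTACG", 10), rep(2L, 10))
  cols <- pileup_cluster(al, ref, "ref")
  expect_equal(cols$position, 2:6)
  expect_true(all(cols$depth == 10L))
  expect_equal(cols$G[cols$position == 2], 10L)
  expect_equal(cols$ref_base, c("G", "T", "A", "C", "G"))

  al2 <- mk_alignments(c("GTACG", "GNACG"), c(2L, 2L))
  cols2 <- pileup_cluster(al2, ref, "ref")
  expect_equal(cols2$N[cols2$position == 3], 1L)
  expect_equal(cols2$depth[cols2$position == 3], 2L)

  expect_equal(nrow(pileup_cluster(mk_alignments(character(0), integer(0)),
                                   ref, "ref")), 0L)
})

test_that("pileup of a simulated cluster matches truth-table reconstruction", {
  res <- simulate_run(clean_config(n_droplets = 900L, seed = 91L))
  truth <- res$reads$truth
  d1 <- truth$droplet_id[1]
  sel <- truth$droplet_id == d1
  tpl <- truth$template_id[sel][1]
  r1 <- res$reads$r1[sel, ]
  al <- map_reads_simple(r1, res$references)
  cols <- pileup_cluster(al, res$references[res$references$id == tpl, ])
  # depth from truth fragment coordinates (R1 covers the first
  # read_length bases of each fragment)
  L <- nchar(res$references$sequence[res$references$id == tpl])
  depth <- integer(L)
  for (i in which(sel)) {
    s <- truth$fragment_start[i]
    e <- s + min(250L, truth$fragment_length[i])
    depth[(s + 1L):e] <- depth[(s + 1L):e] + 1L
  }
  got <- integer(L)
  got[cols$position + 1L] <- cols$depth
  expect_equal(got, depth)
  # zero-noise run: every column is pure reference
  ref_counts <- vapply(seq_len(nrow(cols)), function(i)
    cols[[cols$ref_base[i]]][i], 0L)
  expect_equal(ref_counts, cols$depth)
})

test_that("SNP caller keeps mono-allelic calls and suppresses di-allelic sites", {
  cols <- data.frame(reference_id = "ref", position = c(10L, 20L, 30L, 40L),
                     ref_base = c("A", "A", "A", "A"),
                     A = c(2L, 50L, 100L, 3L), C = c(0L, 0L, 0L, 0L),
                     G = c(98L, 50L, 0L, 4L), T = c(0L, 0L, 0L, 0L),
                     N = c(0L, 0L, 5L, 0L),
                     depth = c(100L, 100L, 105L, 7L),
                     stringsAsFactors = FALSE)
  calls <- call_cluster_snps(cols, "cl1")
  # 98% G at position 10: mono-allelic SNP
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$position, 10L)
  expect_equal(calls$alt_base, "G")
  expect_true(calls$mono_allelic)
  expect_equal(calls$alt_fraction, 0.98)
  # 50/50 (the first-cycle amplification error signature): suppressed
  dial <- attr(calls, "di_allelic")
  expect_equal(dial$position, 20L)
  expect_false(dial$mono_allelic)
  # all-reference and below-depth columns emit nothing
  expect_false(30L %in% c(calls$position, dial$position))
  expect_false(40L %in% c(calls$position, dial$position))
})

test_that("caller thresholds act on non-N fractions at the configured margins", {
  col <- function(G, A, N = 0L) {
    data.frame(reference_id = "ref", position = 0L, ref_base = "A",
               A = A, C = 0L, G = G, T = 0L, N = N, depth = G + A + N,
               stringsAsFactors = FALSE)
  }
  # alt fraction exactly at mono_frac with the runner-up below di_frac
  ok <- call_cluster_snps(data.frame(
    reference_id = "ref", position = 0L, ref_base = "A", A = 9L, C = 0L,
    G = 90L, T = 1L, N = 0L, depth = 100L, stringsAsFactors = FALSE))
  expect_equal(nrow(ok), 1L)
  # runner-up exactly at di_frac tips the site into the di-allelic bin
  r2 <- call_cluster_snps(col(90L, 10L))
  expect_equal(nrow(r2), 0L)
  expect_equal(nrow(attr(r2, "di_allelic")), 1L)
  expect_equal(nrow(call_cluster_snps(col(89L, 11L))), 0L)
  # N bases don't dilute the fraction
  ok_n <- call_cluster_snps(data.frame(
    reference_id = "ref", position = 0L, ref_base = "A", A = 9L, C = 0L,
    G = 90L, T = 1L, N = 50L, depth = 150L, stringsAsFactors = FALSE))
  expect_equal(nrow(ok_n), 1L)
  expect_equal(ok_n$alt_fraction, 0.9)
  expect_equal(nrow(call_cluster_snps(col(5L, 1L))), 0L)  # depth gate
})

test_that("population SNP frequencies count carrier clusters", {
  calls <- do.call(rbind, lapply(sprintf("c%03d", 1:330), function(id) {
    data.frame(cluster_id = id, reference_id = "ref", position = 1066L,
               ref_base = "C", alt_base = "G", alt_fraction = 1,
               depth = 50L, mono_allelic = TRUE, stringsAsFactors = FALSE)
  }))
  pf <- population_snp_frequencies(calls, 6000L)
  expect_equal(pf$frequencies$frequency, 0.055)
  expect_equal(pf$frequencies$n_clusters, 330L)
  expect_equal(pf$fraction_no_snp, 1 - 330 / 6000)

  empty <- population_snp_frequencies(calls[0, ], 100L)
  expect_equal(nrow(empty$frequencies), 0L)
  expect_equal(empty$fraction_no_snp, 1.0)
})

test_that("consensus substitutes called SNPs and deduplicates haplotypes", {
  ref <- "AAAAAAAAAA"
  mk_call <- function(cl, pos, alt) {
    data.frame(cluster_id = cl, reference_id = "ref", position = pos,
               ref_base = "A", alt_base = alt, alt_fraction = 1,
               depth = 50L, mono_allelic = TRUE, stringsAsFactors = FALSE)
  }
  calls <- rbind(mk_call("c1", 2L, "G"), mk_call("c2", 2L, "G"),
                 mk_call("c3", 2L, "G"), mk_call("c3", 7L, "T"))
  hap <- consensus_and_haplotypes(calls, ref,
                                  cluster_ids = c("c1", "c2", "c3", "c4"))
  expect_equal(nrow(hap), 3L)
  h_ref <- hap[hap$n_snps == 0L, ]
  expect_equal(h_ref$consensus, ref)
  expect_equal(h_ref$multiplicity, 1L)
  h_g <- hap[hap$n_snps == 1L, ]
  expect_equal(h_g$multiplicity, 2L)
  expect_equal(h_g$consensus, "AAGAAAAAAA")
  h_gt <- hap[hap$n_snps == 2L, ]
  expect_equal(h_gt$consensus, "AAGAAAATAA")
  expect_equal(h_gt$cluster_ids, "c3")
})

test_that("derived haplotypes group with their parent against the reference", {
  # lineage ref -> {S1} -> {S1,S2}: the doubly mutated haplotype sits
  # closer to its parent than to the reference
  hap <- data.frame(haplotype_id = c("h_s1", "h_s1s2"),
                    snp_key = c("100G", "100G;200T"),
                    n_snps = c(1L, 2L), multiplicity = c(5L, 1L),
                    cluster_ids = c("a", "b"),
                    consensus = c("x", "y"), stringsAsFactors = FALSE)
  tree <- build_tree(hap)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("h_s1", "h_s1s2", "reference"))
  d <- ape::cophenetic.phylo(tree)
  expect_lt(d["h_s1s2", "h_s1"], d["h_s1s2", "reference"])
  expect_error(build_tree(hap[1, ]), "at least 2")
})

test_that("neighbour joining recovers a 4-taxon additive topology exactly", {
  # perfect-phylogeny SNP sets: distances are additive on ((A,B),(C,D))
  hap <- data.frame(
    haplotype_id = c("A", "B", "C", "D"),
    snp_key = c("1x;10a", "1x;20b;21b", "2y;30c", "2y;40d;41d;42d"),
    n_snps = c(2L, 3L, 2L, 4L), multiplicity = 1L, cluster_ids = "z",
    consensus = "s", stringsAsFactors = FALSE)
  tree <- build_tree(hap, include_reference = FALSE)
  want <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(ape::dist.topo(ape::unroot(tree), want)[1], 0)
  # NJ on an additive matrix reproduces the input distances exactly
  d <- ape::cophenetic.phylo(tree)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "D"], 7)
  expect_equal(d["C", "D"], 4)
})

test_that("the detection-limit formula matches Monte-Carlo binomial sampling", {
  expect_equal(limit_of_detection(1, 0.05), 0.95)
  expect_equal(limit_of_detection(3000, 0.05), 1 - 0.05^(1 / 3000))
  expect_equal(limit_of_detection(3000, 0.05), 9.986e-4, tolerance = 1e-3)
  expect_error(limit_of_detection(10, 1.2), "beta")
  # strictly decreasing in n
  f <- limit_of_detection(c(1, 10, 100, 1000, 10000), 0.05)
  expect_true(all(diff(f) < 0))
  # miss probability at the computed frequency equals beta (3 sigma MC)
  set.seed(41)
  for (case in list(c(50, 0.05), c(500, 0.1), c(3000, 0.05))) {
    n <- case[1]; beta <- case[2]
    f <- limit_of_detection(n, beta)
    miss <- mean(rbinom(20000, n, f) == 0L)
    se <- sqrt(beta * (1 - beta) / 20000)
    expect_lt(abs(miss - beta), 3 * se)
  }
})

test_that("VCF output is 1-based and round-trips the essential fields", {
  calls <- data.frame(cluster_id = "c1", reference_id = "ref",
                      position = 1066L, ref_base = "C", alt_base = "G",
                      alt_fraction = 0.98, depth = 55L,
                      mono_allelic = TRUE, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_snps_vcf(calls, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  rec <- strsplit(lines[!startsWith(lines, "#")], "\t")[[1]]
  expect_equal(rec[2], "1067")
  expect_equal(rec[4], "C")
  expect_equal(rec[5], "G")
})
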