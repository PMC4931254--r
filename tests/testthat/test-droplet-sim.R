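# Simulator: Poisson loading, amplification error propagation,
# fragmentation bias, barcode mis-tagging, determinism.

test_that("template counts per droplet follow Poisson(-log(1 - occupancy))", {
  cfg <- sim_config(n_droplets = 1e5, template_occupancy = 0.1,
                    barcode_occupancy = 0.1,
                    templates = data.frame(id = "t1",
                                           sequence = rand_seq(1200)),
                    fragment_length = c(100L, 300L), seed = 5L)
  dr <- encapsulate(cfg)
  lambda <- -log(0.9)
  # chi-square against the analytic pmf, alpha = 0.01
  kmax <- 3L
  obs <- vapply(0:kmax, function(k) sum(dr$n_templates == k), 0)
  obs <- c(obs, sum(dr$n_templates > kmax))
  p <- dpois(0:kmax, lambda)
  p <- c(p, 1 - sum(p))
  chi <- sum((obs - 1e5 * p)^2 / (1e5 * p))
  expect_lt(chi, qchisq(0.99, df = kmax + 1L))
  # occupied fraction matches the configured occupancy
  expect_equal(mean(dr$n_templates > 0), 0.1, tolerance = 0.05)
})

test_that("productive fraction approaches the product of the occupancies", {
  cfg <- sim_config(n_droplets = 1e5, seed = 6L,
                    templates = data.frame(id = "t1",
                                           sequence = rand_seq(1200)),
                    fragment_length = c(100L, 300L))
  dr <- encapsulate(cfg)
  frac <- mean(dr$productive)
  se <- sqrt(0.01 * 0.99 / 1e5)
  expect_lt(abs(frac - 0.01), 4 * se)
})

test_that("zero occupancy empties every droplet and occupancy 1 is rejected", {
  cfg <- sim_config(n_droplets = 500, template_occupancy = 0,
                    templates = data.frame(id = "t1",
                                           sequence = rand_seq(1200)),
                    fragment_length = c(100L, 300L), seed = 7L)
  expect_true(all(encapsulate(cfg)$n_templates == 0L))
  expect_error(sim_config(template_occupancy = 1, seed = 1), "< 1")
})

test_that("error-free fully-efficient amplification gives 2^cycles identical copies", {
  cfg <- sim_config(templates = data.frame(id = "t", sequence = rand_seq(500)),
                    fragment_length = c(100L, 200L),
                    per_base_error_per_cycle = 0, seed = 1L)
  pool <- amplify(cfg$templates, cfg, n_cycles = 5L, max_pool = 64L)
  expect_length(pool$molecules, 32L)
  expect_true(all(vapply(pool$molecules, function(m) length(m$pos) == 0L,
                         TRUE)))
})

test_that("a substitution planted in the cycle-1 copy event reaches exactly half the pool", {
  set.seed(2)
  cfg <- sim_config(templates = data.frame(id = "t", sequence = rand_seq(800)),
                    fragment_length = c(100L, 200L),
                    per_base_error_per_cycle = 0, seed = 2L)
  for (cycles in c(5L, 10L)) {
    pool <- amplify(cfg$templates, cfg, n_cycles = cycles,
                    force_first_cycle_error = 123L, max_pool = 2048L)
    expect_length(pool$molecules, 2^cycles)
    expect_equal(pool_mutant_fraction(pool, 123L), 0.5)
  }
})

test_that("mean substitutions per molecule match the branching-process expectation", {
  # with efficiency 1, a uniformly chosen final molecule has on average
  # cycles/2 copy events in its ancestry, hence rate*L*cycles/2 mutations
  set.seed(3)
  L <- 1000L; cycles <- 8L; rate <- 1e-3
  cfg <- sim_config(templates = data.frame(id = "t", sequence = rand_seq(L)),
                    fragment_length = c(100L, 200L),
                    per_base_error_per_cycle = rate, seed = 3L)
  means <- replicate(30, {
    pool <- amplify(cfg$templates, cfg, n_cycles = cycles, max_pool = 256L)
    mean(vapply(pool$molecules, function(m) length(m$pos), 0L))
  })
  expected <- rate * L * cycles / 2
  expect_equal(mean(means), expected, tolerance = 0.1)
})

test_that("fragments respect length bounds and end bias depletes template ends", {
  set.seed(4)
  L <- 3000L
  cfg <- sim_config(templates = data.frame(id = "t", sequence = rand_seq(L)),
                    per_base_error_per_cycle = 0,
                    fragment_length = c(350L, 600L), seed = 4L)
  pool <- amplify(cfg$templates, cfg, n_cycles = 3L)
  fr <- fragment(pool, 4000L, cfg)
  expect_true(all(fr$length >= 350L & fr$length <= 600L))
  expect_true(all(fr$start >= 0L & fr$start + fr$length <= L))
  cover <- integer(L)
  for (i in seq_len(nrow(fr))) {
    idx <- (fr$start[i] + 1L):(fr$start[i] + fr$length[i])
    cover[idx] <- cover[idx] + 1L
  }
  interior <- mean(cover[600:(L - 600)])
  ends <- mean(c(cover[1:250], cover[(L - 249):L]))
  expect_lt(ends, interior)

  # biases off: interior per-base coverage is flat within binomial noise
  cfg0 <- sim_config(templates = cfg$templates, end_bias_depth = 0L,
                     per_base_error_per_cycle = 0,
                     fragment_length = c(350L, 600L), seed = 4L)
  fr0 <- fragment(pool, 4000L, cfg0)
  cover0 <- integer(L)
  for (i in seq_len(nrow(fr0))) {
    idx <- (fr0$start[i] + 1L):(fr0$start[i] + fr0$length[i])
    cover0[idx] <- cover0[idx] + 1L
  }
  # a position well inside the template is covered by a length-l fragment
  # with probability l/(L - l + 1) (starts uniform over L - l + 1 offsets)
  lens <- 350:600
  p_cover <- mean(lens / (L - lens + 1))
  expected <- 4000 * p_cover
  sigma <- sqrt(4000 * p_cover * (1 - p_cover))
  interior0 <- cover0[600:(L - 600)]
  expect_lt(abs(mean(interior0) - expected), 3 * sigma)
})

test_that("fragment length bounds wider than the template are rejected", {
  cfg <- sim_config(templates = data.frame(id = "t", sequence = rand_seq(500)),
                    fragment_length = c(100L, 200L),
                    per_base_error_per_cycle = 0, seed = 1L)
  pool <- amplify(cfg$templates, cfg, n_cycles = 2L)
  cfg$fragment_length <- c(600L, 700L)
  expect_error(fragment(pool, 10L, cfg), "shorter than")
})

test_that("barcode reads carry the droplet barcode; mis-tagging hits the configured rate", {
  res <- simulate_run(clean_config(n_droplets = 1500L, seed = 41L))
  expect_true(all(res$reads$i1$sequence ==
                    res$reads$truth$true_barcode))
  expect_true(all(nchar(res$reads$i1$sequence) == 15L))

  cfg <- sim_config(n_droplets = 4000L, mis_tag_rate = 0.02,
                    seq_error_rate = 0, per_base_error_per_cycle = 0,
                    pairs_per_droplet = 500, pcr_cycles = 6L, seed = 42L)
  res <- simulate_run(cfg)
  n <- nrow(res$reads$truth)
  expect_gt(n, 1e4)
  frac <- mean(res$reads$truth$mis_tagged)
  se <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(frac - 0.02), 3 * se)
  # mis-tagged reads carry a different droplet's barcode
  mt <- res$reads$truth$mis_tagged
  expect_true(all(res$reads$i1$sequence[mt] !=
                    res$reads$truth$true_barcode[mt]))
})

test_that("simulate_run is byte-identical under a fixed seed and errors on zero yield", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- clean_config(n_droplets = 800L, seed = 51L)
  simulate_run(cfg, d1)
  simulate_run(cfg, d2)
  for (f in c("reads_R1.fastq.gz", "reads_R2.fastq.gz", "reads_I1.fastq.gz",
              "references.fasta", "truth_reads.tsv")) {
    expect_identical(readLines(gzfile(file.path(d1, f)), warn = FALSE),
                     readLines(gzfile(file.path(d2, f)), warn = FALSE),
                     label = f)
  }
  cfg_tiny <- sim_config(n_droplets = 5L, seed = 52L,
                         template_occupancy = 0.001,
                         barcode_occupancy = 0.001)
  expect_error(simulate_run(cfg_tiny), "productive")
})

test_that("coalescence removes the expected fraction of productive droplets", {
  cfg <- sim_config(n_droplets = 3e4, coalescence_rate = 0.3,
                    per_base_error_per_cycle = 0, seq_error_rate = 0,
                    mis_tag_rate = 0, pairs_per_droplet = 5,
                    pcr_cycles = 4L, seed = 61L)
  res <- simulate_run(cfg)
  dr <- res$droplets
  n_prod <- sum(dr$productive)
  n_emit <- sum(dr$productive & !dr$coalesced)
  se <- sqrt(n_prod * 0.3 * 0.7)
  expect_lt(abs(n_emit - 0.7 * n_prod), 4 * se)
})

test_that("every emitted read pair has exactly one truth row from its own droplet", {
  res <- simulate_run(clean_config(n_droplets = 1200L, seed = 71L))
  truth <- res$reads$truth
  expect_identical(truth$read_id, res$reads$r1$id)
  expect_identical(truth$read_id, res$reads$r2$id)
  expect_false(anyDuplicated(truth$read_id) > 0)
  dr <- res$droplets
  tpl_of <- setNames(dr$template_ids, dr$droplet_id)
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    truth$template_id[i] %in% tpl_of[[truth$droplet_id[i]]]
  }, TRUE)
  expect_true(all(ok[!truth$mis_tagged]))
})
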