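# Shared in-code fixtures for the suite.

random_reads_df <- function(n, len = 50L, with_qual = TRUE) {
  seqs <- vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                  prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  }, "")
  quals <- if (with_qual) {
    vapply(seq_len(n), function(i) {
      int_to_phred(sample(0:41, len, replace = TRUE))
    }, "")
  } else NA_character_
  data.frame(id = sprintf("r%04d", seq_len(n)), sequence = seqs,
             qual = quals, stringsAsFactors = FALSE)
}

# uniform random A/C/G/T string(s)
rand_seq <- function(len, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = "")
  }, "")
}

# independent positionwise Hamming oracle (strsplit route, distinct from
# the raw-byte implementation)
hamming_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  sum(x != y | x == "N" | y == "N")
}

# small zero-noise simulator config: every stochastic knob that can hide a
# defect is off
clean_config <- function(n_droplets = 2000L, seed = 101L, ...) {
  sim_config(n_droplets = n_droplets,
             per_base_error_per_cycle = 0,
             mis_tag_rate = 0,
             seq_error_rate = 0,
             pairs_per_droplet = 150,
             pcr_cycles = 8L,
             seed = seed,
             ...)
}
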