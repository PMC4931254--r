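# Generative model of the droplet barcoding workflow: Poisson
# co-encapsulation of templates and barcodes at limiting dilution, clonal
# droplet PCR with per-cycle substitution errors, random fragmentation with
# template-end depletion and optional GC bias, barcode splicing with
# mis-tagging, and paired-end sequencing with flat per-base error.
#
# Every emitted read is recorded in a truth table (read -> droplet ->
# template -> barcode -> planted errors) so downstream stages can be tested
# against a known answer.

#' Simulator configuration
#'
#' Occupancies are parameterised as the probability that a droplet contains
#' at least one molecule (the experimentally controlled dilution), from which
#' the Poisson rate is derived as `lambda = -log(1 - occupancy)`.
#'
#' @param n_droplets Number of droplets generated.
#' @param template_occupancy P(droplet contains >= 1 template); default 0.1
#'   (limiting dilution, ~1 in 10 droplets loaded).
#' @param barcode_occupancy P(droplet receives a barcode); default 0.1.
#' @param templates Optional data.frame (`id`, `sequence`) of template
#'   molecules; when NULL, `simulate_run()` draws a default pool of 8 random
#'   templates of 3-5 kb.
#' @param template_weights Sampling probabilities over `templates`
#'   (default uniform).
#' @param references Optional data.frame (`id`, `sequence`) of mapping
#'   references written alongside the reads; defaults to `templates`.
#' @param pcr_cycles Droplet PCR cycles; default 25.
#' @param per_base_error_per_cycle Substitution probability per base per
#'   copying event; default 1e-6.
#' @param amplification_efficiency Probability a molecule is copied in a
#'   cycle; default 1.
#' @param max_pool Molecule-pool cap per droplet; when a cycle would exceed
#'   it the pool is deterministically subsampled (evenly spaced). Default 512.
#' @param fragment_length Length-2 vector (min, max) of fragment lengths.
#' @param end_bias_depth Bases of terminal coverage depletion (transposase
#'   end bias); default 250. 0 disables.
#' @param gc_bias_strength Coefficient of the GC acceptance weight
#'   `exp(-gc_bias_strength * |GC_local - 0.5|)`; default 0 (off).
#' @param mis_tag_rate Probability a read pair is tagged with a uniformly
#'   chosen different droplet's barcode; default 0.02.
#' @param coalescence_rate Probability a droplet coalesces with another
#'   before barcoding (coalesced droplets are removed before emission);
#'   default 0.
#' @param seq_error_rate Per-base sequencing substitution probability;
#'   default 1e-3.
#' @param read_length Read length in bp; default 250.
#' @param barcode_length Barcode length in bp; default 15.
#' @param n_barcode_species Size of the barcode pool; default `Inf`
#'   (barcodes drawn i.i.d. uniform over 4^L, collisions negligible).
#' @param pairs_per_droplet Mean read pairs emitted per productive droplet
#'   (Poisson); default 800.
#' @param seed Integer seed; mandatory for any stochastic run.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_droplets = 10000L,
                       template_occupancy = 0.1,
                       barcode_occupancy = 0.1,
                       templates = NULL,
                       template_weights = NULL,
                       references = NULL,
                       pcr_cycles = 25L,
                       per_base_error_per_cycle = 1e-6,
                       amplification_efficiency = 1.0,
                       max_pool = 512L,
                       fragment_length = c(350L, 1000L),
                       end_bias_depth = 250L,
                       gc_bias_strength = 0,
                       mis_tag_rate = 0.02,
                       coalescence_rate = 0,
                       seq_error_rate = 1e-3,
                       read_length = 250L,
                       barcode_length = 15L,
                       n_barcode_species = Inf,
                       pairs_per_droplet = 800,
                       seed = NULL) {
  probs <- c(template_occupancy = template_occupancy,
             barcode_occupancy = barcode_occupancy,
             mis_tag_rate = mis_tag_rate,
             coalescence_rate = coalescence_rate,
             seq_error_rate = seq_error_rate,
             per_base_error_per_cycle = per_base_error_per_cycle,
             amplification_efficiency = amplification_efficiency)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (template_occupancy >= 1 || barcode_occupancy >= 1) {
    stop("occupancy must be < 1 (Poisson rate -log(1 - p) undefined at 1)")
  }
  stopifnot(length(fragment_length) == 2L,
            fragment_length[1] <= fragment_length[2],
            barcode_length >= 1L, pcr_cycles >= 1L, read_length >= 1L)
  if (!is.null(templates)) {
    if (min(nchar(templates$sequence)) < fragment_length[2]) {
      stop("fragment_length max exceeds the shortest template")
    }
    if (is.null(template_weights)) {
      template_weights <- rep(1 / nrow(templates), nrow(templates))
    }
    stopifnot(length(template_weights) == nrow(templates))
  }
  structure(list(
    n_droplets = as.integer(n_droplets),
    template_occupancy = template_occupancy,
    barcode_occupancy = barcode_occupancy,
    templates = templates,
    template_weights = template_weights,
    references = references,
    pcr_cycles = as.integer(pcr_cycles),
    per_base_error_per_cycle = per_base_error_per_cycle,
    amplification_efficiency = amplification_efficiency,
    max_pool = as.integer(max_pool),
    fragment_length = as.integer(fragment_length),
    end_bias_depth = as.integer(end_bias_depth),
    gc_bias_strength = gc_bias_strength,
    mis_tag_rate = mis_tag_rate,
    coalescence_rate = coalescence_rate,
    seq_error_rate = seq_error_rate,
    read_length = as.integer(read_length),
    barcode_length = as.integer(barcode_length),
    n_barcode_species = n_barcode_species,
    pairs_per_droplet = pairs_per_droplet,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

require_seed <- function(config) {
  if (is.null(config$seed)) {
    stop("a seed is mandatory for stochastic simulation; set sim_config(seed=)")
  }
}

random_dna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Draw random template sequences
#' @param n Number of templates.
#' @param min_len,max_len Length range in bp (default 3-5 kb, as for a
#'   known-template validation library).
#' @return data.frame (`id`, `sequence`). Uses the current RNG stream.
#' @export
random_templates <- function(n = 8L, min_len = 3000L, max_len = 5000L) {
  lens <- if (min_len == max_len) rep(min_len, n) else
    sample(min_len:max_len, n, replace = TRUE)
  data.frame(id = sprintf("tpl%02d", seq_len(n)),
             sequence = vapply(lens, function(L) random_dna(1L, L), ""),
             stringsAsFactors = FALSE)
}

#' Draw a pool of random barcodes with a guaranteed minimum pairwise distance
#'
#' Rejection-samples uniform random barcodes until `n` sequences with all
#' pairwise Hamming distances `>= min_dist` are collected. Used to build
#' pools where error-corrected clustering is guaranteed to be exact
#' (`min_dist >= 2*max_dist + 1`).
#'
#' @param n Pool size.
#' @param length Barcode length (default 15).
#' @param min_dist Minimum pairwise Hamming distance (0 disables the check).
#' @return Character vector of `n` barcodes. Uses the current RNG stream.
#' @export
make_barcode_pool <- function(n, length = 15L, min_dist = 0L) {
  pool <- character(0)
  guard <- 0L
  while (length(pool) < n) {
    guard <- guard + 1L
    if (guard > 1000L * n) stop("make_barcode_pool: rejection sampling stalled")
    cand <- random_dna(1L, length)
    if (min_dist > 0L && length(pool) > 0L) {
      d <- vapply(pool, function(p) hamming_distance(p, cand), 0L)
      if (any(d < min_dist)) next
    }
    if (cand %in% pool) next
    pool <- c(pool, cand)
  }
  pool
}

#' Encapsulate templates and barcodes into droplets
#'
#' Template count per droplet is Poisson with rate
#' `lambda = -log(1 - template_occupancy)` (so P(>= 1) equals the configured
#' occupancy); a barcode arrives independently with probability
#' `barcode_occupancy`. A droplet is *productive* iff it holds at least one
#' template and a barcode. With `coalescence_rate > 0`, coalescing droplets
#' are paired, their contents merged, and both marked `coalesced` (removed
#' before emission by `simulate_run()`).
#'
#' @param config A `sim_config` (seed set by the caller or via
#'   `config$seed`).
#' @param set_seed Whether to seed the RNG from `config$seed` (default TRUE;
#'   `simulate_run()` passes FALSE to keep a single stream).
#' @return data.frame: `droplet_id`, `n_templates`, `template_ids`
#'   (list-column), `barcode` (NA when absent), `coalesced`, `productive`.
#' @export
encapsulate <- function(config, set_seed = TRUE) {
  if (set_seed) {
    require_seed(config)
    set.seed(config$seed)
  }
  n <- config$n_droplets
  lambda <- -log(1 - config$template_occupancy)
  n_tpl <- stats::rpois(n, lambda)
  has_bc <- stats::runif(n) < config$barcode_occupancy
  templates <- config$templates
  if (is.null(templates) && any(n_tpl > 0)) {
    stop("encapsulate: config has no templates")
  }
  tpl_ids <- vector("list", n)
  occupied <- which(n_tpl > 0L)
  if (length(occupied)) {
    draws <- sample(templates$id, sum(n_tpl), replace = TRUE,
                    prob = config$template_weights)
    tpl_ids[occupied] <- split(draws, rep(occupied, n_tpl[occupied]))
  }
  bc <- rep(NA_character_, n)
  if (any(has_bc)) {
    if (is.finite(config$n_barcode_species)) {
      pool <- make_barcode_pool(config$n_barcode_species,
                                config$barcode_length)
      bc[has_bc] <- sample(pool, sum(has_bc), replace = TRUE)
    } else {
      bc[has_bc] <- random_dna(sum(has_bc), config$barcode_length)
    }
  }
  # productivity is a property of a droplet's own contents; coalesced
  # droplets additionally carry their partner's contents for the record
  # but are removed before emission regardless
  productive <- lengths(tpl_ids) > 0L & !is.na(bc)
  coalesced <- rep(FALSE, n)
  if (config$coalescence_rate > 0) {
    hit <- which(stats::runif(n) < config$coalescence_rate)
    coalesced[hit] <- TRUE
    # merge consecutive pairs of coalescing droplets: union of contents
    if (length(hit) >= 2L) {
      pairs <- matrix(hit[seq_len(2L * (length(hit) %/% 2L))], ncol = 2L,
                      byrow = TRUE)
      for (k in seq_len(nrow(pairs))) {
        u <- unique(c(tpl_ids[[pairs[k, 1]]], tpl_ids[[pairs[k, 2]]]))
        tpl_ids[pairs[k, ]] <- list(u, u)
      }
    }
  }
  out <- data.frame(droplet_id = sprintf("d%06d", seq_len(n)),
                    n_templates = lengths(tpl_ids),
                    barcode = bc,
                    coalesced = coalesced,
                    productive = productive,
                    stringsAsFactors = FALSE)
  out$template_ids <- tpl_ids
  out
}

new_molecule <- function(pos = integer(), alt = character()) {
  list(pos = pos, alt = alt)
}

mutate_molecule <- function(mol, template_raw, k) {
  # add k new substitutions at uniform positions (alt drawn from the other 3)
  pos <- sample.int(length(template_raw), k)
  cur <- rawToChar(template_raw[pos], multiple = TRUE)
  i <- match(pos, mol$pos)
  cur[!is.na(i)] <- mol$alt[i[!is.na(i)]]
  alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                "")
  keep <- !(mol$pos %in% pos)
  new_molecule(c(mol$pos[keep], pos), c(mol$alt[keep], unname(alt)))
}

#' Clonally amplify a template inside a droplet
#'
#' Branching copy process: in each cycle every molecule is copied with
#' probability `amplification_efficiency`; each copying event introduces
#' independent per-base substitutions at `per_base_error_per_cycle`. Each
#' final molecule's substitution set is the union along its ancestry. When
#' the pool would exceed `max_pool` it is subsampled deterministically
#' (evenly spaced indices) and a note is logged via `message()`.
#'
#' @param template A single sequence string, or data.frame row with
#'   `sequence`.
#' @param config A `sim_config`.
#' @param n_cycles Number of cycles (default `config$pcr_cycles`).
#' @param force_first_cycle_error If TRUE (or an integer position, 0-based),
#'   plant exactly one substitution in the single cycle-1 copy event —
#'   the "error in the first round of amplification" scenario.
#' @param max_pool Pool cap (default `config$max_pool`).
#' @param quiet Suppress the pool-cap note (used by [simulate_run()], which
#'   logs one aggregate note instead).
#' @return List of class `molecule_pool`: `template` (string), `molecules`
#'   (list of `list(pos, alt)` with 1-based template positions), `n_cycles`.
#' @export
amplify <- function(template, config, n_cycles = config$pcr_cycles,
                    force_first_cycle_error = FALSE,
                    max_pool = config$max_pool, quiet = FALSE) {
  if (is.data.frame(template)) template <- template$sequence[1]
  if (inherits(template, "seq_record")) template <- template$sequence
  stopifnot(n_cycles >= 1L)
  tpl_raw <- charToRaw(template)
  L <- length(tpl_raw)
  rate <- config$per_base_error_per_cycle
  eff <- config$amplification_efficiency
  pool <- list(new_molecule())
  capped <- FALSE
  for (cycle in seq_len(n_cycles)) {
    n <- length(pool)
    copied <- if (eff >= 1) rep(TRUE, n) else stats::runif(n) < eff
    idx <- which(copied)
    if (length(idx) == 0L) next
    n_err <- stats::rbinom(length(idx), L, rate)
    copies <- pool[idx]
    if (cycle == 1L && !isFALSE(force_first_cycle_error)) {
      # the single cycle-1 copy event carries one planted substitution
      stopifnot(length(copies) == 1L)
      p <- if (is.numeric(force_first_cycle_error)) {
        as.integer(force_first_cycle_error) + 1L
      } else sample.int(L, 1L)
      b <- rawToChar(tpl_raw[p])
      copies[[1]] <- new_molecule(p, sample(setdiff(c("A", "C", "G", "T"), b), 1L))
    }
    err_at <- which(n_err > 0L)
    for (j in err_at) {
      copies[[j]] <- mutate_molecule(copies[[j]], tpl_raw, n_err[j])
    }
    pool <- c(pool, copies)
    if (length(pool) > max_pool) {
      keep <- unique(round(seq(1L, length(pool), length.out = max_pool)))
      pool <- pool[keep]
      capped <- TRUE
    }
  }
  if (capped && !quiet) {
    message("amplify: pool capped at ", max_pool,
            " molecules (deterministic evenly-spaced subsampling)")
  }
  structure(list(template = template, molecules = pool,
                 n_cycles = n_cycles), class = "molecule_pool")
}

#' Fraction of a molecule pool carrying a substitution at a position
#' @param pool A `molecule_pool`.
#' @param position 0-based template position; NULL counts molecules with any
#'   substitution.
#' @return Fraction in [0, 1].
#' @export
pool_mutant_fraction <- function(pool, position = NULL) {
  if (is.null(position)) {
    return(mean(vapply(pool$molecules, function(m) length(m$pos) > 0L, TRUE)))
  }
  p1 <- as.integer(position) + 1L
  mean(vapply(pool$molecules, function(m) p1 %in% m$pos, TRUE))
}

gc_cumsum <- function(template) {
  cumsum(strsplit(chartr("ACGTN", "01100", template), "", fixed = TRUE)[[1]] == "1")
}

#' Fragment an amplified molecule pool
#'
#' Fragment lengths are uniform over `fragment_length`; start positions are
#' uniform, then rejection-sampled against two acceptance weights: a linear
#' ramp over the terminal `end_bias_depth` bases of the template (modelling
#' transposase end depletion) and `exp(-gc_bias_strength*|GC_frag - 0.5|)`.
#'
#' @param pool A `molecule_pool`.
#' @param n_fragments Number of fragments to draw.
#' @param config A `sim_config`.
#' @return data.frame: `molecule` (index into `pool$molecules`), `start`
#'   (0-based template offset), `length`.
#' @export
fragment <- function(pool, n_fragments, config) {
  L <- nchar(pool$template)
  fmin <- config$fragment_length[1]
  fmax <- min(config$fragment_length[2], L)
  if (fmin > L) stop("fragment: template shorter than minimum fragment length")
  D <- config$end_bias_depth
  g <- config$gc_bias_strength
  gccs <- if (g > 0) gc_cumsum(pool$template) else NULL
  out_m <- integer(0); out_s <- integer(0); out_l <- integer(0)
  guard <- 0L
  while (length(out_m) < n_fragments) {
    guard <- guard + 1L
    if (guard > 200L) stop("fragment: rejection sampling stalled")
    need <- n_fragments - length(out_m)
    nb <- max(need * 2L, 100L)
    len <- if (fmin == fmax) rep(fmin, nb) else
      sample(fmin:fmax, nb, replace = TRUE)
    start <- floor(stats::runif(nb) * (L - len + 1L))
    w <- rep(1, nb)
    if (D > 0L) {
      w <- w * pmin(1, (start + 1) / D) *
        pmin(1, (L - (start + len) + 1) / D)
    }
    if (g > 0) {
      gc <- (gccs[start + len] - ifelse(start > 0, gccs[start], 0)) / len
      w <- w * exp(-g * abs(gc - 0.5))
    }
    acc <- stats::runif(nb) < w
    out_m <- c(out_m, sample.int(length(pool$molecules), sum(acc),
                                 replace = TRUE))
    out_s <- c(out_s, as.integer(start[acc]))
    out_l <- c(out_l, as.integer(len[acc]))
  }
  data.frame(molecule = out_m[seq_len(n_fragments)],
             start = out_s[seq_len(n_fragments)],
             length = out_l[seq_len(n_fragments)])
}

# materialise fragment sequences, applying each source molecule's
# substitutions that fall inside the fragment
fragment_sequences <- function(pool, frags) {
  seqs <- substring(pool$template, frags$start + 1L,
                    frags$start + frags$length)
  for (i in seq_len(nrow(frags))) {
    mol <- pool$molecules[[frags$molecule[i]]]
    if (length(mol$pos) == 0L) next
    inside <- mol$pos > frags$start[i] &
      mol$pos <= frags$start[i] + frags$length[i]
    if (!any(inside)) next
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    s[mol$pos[inside] - frags$start[i]] <- mol$alt[inside]
    seqs[i] <- paste0(s, collapse = "")
  }
  seqs
}

add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    s[pos] <- vapply(s[pos], function(b) {
      sample(setdiff(bases, b), 1L)
    }, "")
    seqs[i] <- paste0(s, collapse = "")
  }
  seqs
}

#' Attach droplet barcodes and sequence fragments
#'
#' Emits paired reads of `read_length` from the two fragment ends (R2
#' reverse-complemented) plus a barcode read I1 carrying the droplet's
#' barcode. All three reads receive independent per-base substitutions at
#' `seq_error_rate`. With probability `mis_tag_rate` a pair's I1 barcode is
#' swapped for a uniformly chosen different productive droplet's barcode and
#' the truth row is marked `mis_tagged`.
#'
#' @param frag_tbl data.frame with columns `droplet_id`, `template_id`,
#'   `sequence`, `start`, `length`, `mutation_positions` (comma string of
#'   0-based template offsets carried by the source molecule).
#' @param droplets Droplet table from [encapsulate()] (productive rows used
#'   for barcode lookup and mis-tag swaps).
#' @param config A `sim_config`.
#' @return List: `r1`, `r2`, `i1` read data.frames (`id`, `sequence`,
#'   `qual`) and `truth` (per-pair rows).
#' @export
barcode_and_sequence <- function(frag_tbl, droplets, config) {
  n <- nrow(frag_tbl)
  rl <- config$read_length
  bc_of <- stats::setNames(droplets$barcode, droplets$droplet_id)
  true_bc <- unname(bc_of[frag_tbl$droplet_id])
  if (anyNA(true_bc)) {
    stop("barcode_and_sequence: fragment from a droplet without a barcode")
  }
  read_id <- sprintf("%s_f%07d", frag_tbl$droplet_id, seq_len(n))
  r1 <- substr(frag_tbl$sequence, 1L, rl)
  r2 <- revcomp(substring(frag_tbl$sequence,
                          pmax(1L, frag_tbl$length - rl + 1L),
                          frag_tbl$length))
  r1 <- add_seq_errors(r1, config$seq_error_rate)
  r2 <- add_seq_errors(r2, config$seq_error_rate)
  obs_bc <- true_bc
  mis <- stats::runif(n) < config$mis_tag_rate
  candidates <- unique(droplets$barcode[droplets$productive])
  if (any(mis)) {
    for (i in which(mis)) {
      other <- setdiff(candidates, true_bc[i])
      if (length(other) == 0L) { mis[i] <- FALSE; next }
      obs_bc[i] <- sample(other, 1L)
    }
  }
  obs_bc <- add_seq_errors(obs_bc, config$seq_error_rate)
  qual_of <- function(s) vapply(nchar(s), function(k)
    paste0(rep("F", k), collapse = ""), "")
  truth <- data.frame(read_id = read_id,
                      droplet_id = frag_tbl$droplet_id,
                      template_id = frag_tbl$template_id,
                      true_barcode = true_bc,
                      observed_barcode = obs_bc,
                      mis_tagged = mis,
                      fragment_start = frag_tbl$start,
                      fragment_length = frag_tbl$length,
                      planted_error_positions = frag_tbl$mutation_positions,
                      stringsAsFactors = FALSE)
  list(
    r1 = data.frame(id = read_id, sequence = r1, qual = qual_of(r1),
                    stringsAsFactors = FALSE),
    r2 = data.frame(id = read_id, sequence = r2, qual = qual_of(r2),
                    stringsAsFactors = FALSE),
    i1 = data.frame(id = read_id, sequence = obs_bc, qual = qual_of(obs_bc),
                    stringsAsFactors = FALSE),
    truth = truth
  )
}

#' Simulate a full droplet barcoding sequencing run
#'
#' Chains [encapsulate()] -> [amplify()] -> [fragment()] ->
#' [barcode_and_sequence()], removing coalesced droplets before emission,
#' and writes R1/R2/I1 FASTQ (gzip), the reference FASTA, truth tables
#' (TSV) and the resolved configuration (JSON) to `out_dir`. The same seed
#' gives byte-identical outputs.
#'
#' @param config A `sim_config` with a seed.
#' @param out_dir Output directory (created if needed); NULL returns the
#'   read sets in memory without writing files.
#' @return Invisibly, a list: `droplets`, `reads` (r1/r2/i1/truth),
#'   `references`, `paths` (NULL if `out_dir` is NULL).
#' @export
simulate_run <- function(config, out_dir = NULL) {
  require_seed(config)
  set.seed(config$seed)
  if (is.null(config$templates)) {
    config$templates <- random_templates(8L)
    config$template_weights <- rep(1 / 8, 8L)
  }
  if (is.null(config$references)) config$references <- config$templates
  droplets <- encapsulate(config, set_seed = FALSE)
  emit <- droplets[droplets$productive & !droplets$coalesced, ]
  if (nrow(emit) == 0L) {
    stop("simulate_run: no productive droplets emitted; increase n_droplets ",
         "(expected productive fraction is template_occupancy * ",
         "barcode_occupancy = ",
         config$template_occupancy * config$barcode_occupancy, ")")
  }
  if (2^config$pcr_cycles > config$max_pool) {
    message("simulate_run: per-droplet molecule pools capped at ",
            config$max_pool, " (deterministic subsampling)")
  }
  tpl_seq <- stats::setNames(config$templates$sequence, config$templates$id)
  frag_list <- vector("list", nrow(emit))
  n_pairs <- stats::rpois(nrow(emit), config$pairs_per_droplet)
  for (i in seq_len(nrow(emit))) {
    ids <- emit$template_ids[[i]]
    if (n_pairs[i] == 0L) next
    # reads split evenly across co-encapsulated templates
    per_tpl <- as.vector(stats::rmultinom(1L, n_pairs[i],
                                          rep(1 / length(ids), length(ids))))
    sub <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      if (per_tpl[j] == 0L) next
      pool <- amplify(tpl_seq[[ids[j]]], config, quiet = TRUE)
      fr <- fragment(pool, per_tpl[j], config)
      fr$sequence <- fragment_sequences(pool, fr)
      fr$mutation_positions <- vapply(pool$molecules[fr$molecule],
                                      function(m) paste(m$pos - 1L, collapse = ","),
                                      "")
      fr$template_id <- ids[j]
      sub[[j]] <- fr
    }
    sub <- do.call(rbind, sub[!vapply(sub, is.null, TRUE)])
    if (!is.null(sub)) {
      sub$droplet_id <- emit$droplet_id[i]
      frag_list[[i]] <- sub
    }
  }
  frag_tbl <- do.call(rbind, frag_list[!vapply(frag_list, is.null, TRUE)])
  reads <- barcode_and_sequence(frag_tbl, droplets, config)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      r1 = file.path(out_dir, "reads_R1.fastq.gz"),
      r2 = file.path(out_dir, "reads_R2.fastq.gz"),
      i1 = file.path(out_dir, "reads_I1.fastq.gz"),
      references = file.path(out_dir, "references.fasta"),
      truth_reads = file.path(out_dir, "truth_reads.tsv"),
      truth_droplets = file.path(out_dir, "truth_droplets.tsv"),
      config = file.path(out_dir, "config.json")
    )
    write_fastq(reads$r1, paths$r1)
    write_fastq(reads$r2, paths$r2)
    write_fastq(reads$i1, paths$i1)
    write_fasta(config$references, paths$references)
    utils::write.table(reads$truth, paths$truth_reads, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dtab <- droplets
    dtab$template_ids <- vapply(dtab$template_ids, paste, "", collapse = ",")
    utils::write.table(dtab, paths$truth_droplets, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$templates <- NULL
    cfg$references <- NULL
    cfg$template_weights <- unlist(cfg$template_weights)
    jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(list(droplets = droplets, reads = reads,
                 references = config$references, paths = paths))
}

#' Build a template population with planted SNPs
#'
#' Generates variant templates from a single reference for rare-variant
#' studies: each variant carries one or more substitutions at stated
#' positions, and templates are sampled by `simulate_run()` in proportion to
#' the supplied frequencies (the wild type takes the remaining mass).
#'
#' @param reference A `seq_record` or single sequence string.
#' @param variants data.frame with columns `id`, `frequency`, and `snps`
#'   (list-column of data.frames with 0-based `pos` and `alt`).
#' @return List: `templates` (data.frame id/sequence), `weights`,
#'   `truth_snps` (data.frame template_id/pos/ref/alt).
#' @export
make_template_population <- function(reference, variants) {
  if (inherits(reference, "seq_record")) {
    ref_id <- reference$id; ref_seq <- reference$sequence
  } else {
    ref_id <- "reference"; ref_seq <- reference
  }
  stopifnot(sum(variants$frequency) <= 1)
  tpl <- data.frame(id = c(ref_id, variants$id),
                    sequence = c(ref_seq, vapply(seq_len(nrow(variants)),
      function(i) {
        s <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
        sn <- variants$snps[[i]]
        s[sn$pos + 1L] <- sn$alt
        paste0(s, collapse = "")
      }, "")), stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    sn <- variants$snps[[i]]
    data.frame(template_id = variants$id[i], pos = sn$pos,
               ref = substring(ref_seq, sn$pos + 1L, sn$pos + 1L),
               alt = sn$alt, stringsAsFactors = FALSE)
  }))
  list(templates = tpl,
       weights = c(1 - sum(variants$frequency), variants$frequency),
       truth_snps = truth)
}
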