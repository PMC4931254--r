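# Analytic and Monte-Carlo calculators for limiting-dilution loading
# yields, barcode collision likelihood, and the Hamming-distance structure
# of random barcode libraries.

#' Poisson loading statistics for droplet barcoding
#'
#' Templates and barcodes are loaded at limiting dilution; occupancy `p`
#' (probability a droplet holds >= 1 molecule) implies Poisson rate
#' `lambda = -log(1 - p)`. A droplet is productive when it holds at least
#' one template and a barcode, so the pairing fraction is the product of
#' the two occupancies.
#'
#' @param template_occupancy,barcode_occupancy Occupancies in (0, 1).
#' @param n_droplets Droplets generated (for the expected yield).
#' @return List of class `loading_stats`: `lambda_template`,
#'   `lambda_barcode`, `fraction_occupied`, `fraction_single_given_occupied`,
#'   `pairing_fraction`, `n_droplets`, `expected_yield`,
#'   `expected_barcode_droplets`.
#' @export
poisson_loading_stats <- function(template_occupancy = 0.1,
                                  barcode_occupancy = 0.1,
                                  n_droplets = 1e6) {
  if (template_occupancy <= 0 || template_occupancy >= 1 ||
      barcode_occupancy <= 0 || barcode_occupancy >= 1) {
    stop("occupancies must lie strictly inside (0, 1)")
  }
  lt <- -log(1 - template_occupancy)
  lb <- -log(1 - barcode_occupancy)
  pairing <- template_occupancy * barcode_occupancy
  structure(list(
    lambda_template = lt,
    lambda_barcode = lb,
    fraction_occupied = template_occupancy,
    fraction_single_given_occupied =
      lt * exp(-lt) / (1 - exp(-lt)),
    pairing_fraction = pairing,
    n_droplets = n_droplets,
    expected_yield = n_droplets * pairing,
    expected_barcode_droplets = n_droplets * barcode_occupancy
  ), class = "loading_stats")
}

#' @export
print.loading_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Poisson loading at occupancies %.3f (template) / %.3f (barcode)\n",
    "  lambda_template                %.4f\n",
    "  P(single | occupied)           %.4f\n",
    "  pairing (productive) fraction  %.4f  (~1 in %.0f droplets)\n",
    "  droplets                       %.3g\n",
    "  expected barcoded templates    %.3g\n",
    "  expected barcode droplets      %.3g\n"),
    x$fraction_occupied, 1 - exp(-x$lambda_barcode),
    x$lambda_template, x$fraction_single_given_occupied,
    x$pairing_fraction, 1 / x$pairing_fraction, x$n_droplets,
    x$expected_yield, x$expected_barcode_droplets))
  invisible(x)
}

#' Probability that two templates receive the same barcode
#'
#' Barcodes are uniform random sequences over `4^L`; the analytic mode
#' uses the exact birthday-problem product
#' `p_any = 1 - prod_{i=0}^{n-1} (1 - i/4^L)` with
#' `expected_collisions = choose(n, 2)/4^L` (the exponential approximation
#' `1 - exp(-choose(n,2)/4^L)` is reported alongside). Monte-Carlo mode
#' draws barcode assignments and counts runs with any duplicate.
#'
#' @param n_templates Number of barcoded templates (>= 1).
#' @param barcode_length Barcode length L (>= 1).
#' @param mode "analytic" (default) or "monte_carlo".
#' @param n_rep Monte-Carlo replicates (>= 1000 recommended).
#' @param seed Seed, mandatory for Monte-Carlo.
#' @return List of class `collision_estimate`: `n_templates`,
#'   `barcode_length`, `p_any_collision`, `expected_collisions`,
#'   `p_any_approx`; Monte-Carlo adds `ci95` (normal-approximation
#'   half-width-based interval) and `n_rep`.
#' @export
barcode_collision_probability <- function(n_templates, barcode_length = 15L,
                                          mode = c("analytic", "monte_carlo"),
                                          n_rep = 2000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_templates >= 1, barcode_length >= 1)
  space <- 4^barcode_length
  exp_coll <- choose(n_templates, 2) / space
  out <- list(n_templates = n_templates, barcode_length = barcode_length,
              expected_collisions = exp_coll,
              p_any_approx = 1 - exp(-exp_coll))
  if (mode == "analytic") {
    i <- seq_len(n_templates) - 1
    out$p_any_collision <- -expm1(sum(log1p(-i / space)))
  } else {
    if (is.null(seed)) stop("Monte-Carlo mode requires a seed")
    if (space > 2^53) stop("barcode space too large for integer sampling")
    set.seed(seed)
    hits <- vapply(seq_len(n_rep), function(r) {
      draws <- if (space <= .Machine$integer.max) {
        sample.int(space, n_templates, replace = TRUE)
      } else {
        # compose codes from two sub-draws to stay within integer range
        half <- 4^ceiling(barcode_length / 2)
        rest <- space / half
        (sample.int(half, n_templates, replace = TRUE) - 1) * rest +
          sample.int(rest, n_templates, replace = TRUE)
      }
      anyDuplicated(draws) > 0L
    }, TRUE)
    p <- mean(hits)
    se <- sqrt(p * (1 - p) / n_rep)
    out$p_any_collision <- p
    out$ci95 <- c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
    out$n_rep <- n_rep
  }
  structure(out, class = "collision_estimate")
}

#' @export
print.collision_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "Barcode collision for n = %d templates, L = %d\n",
    "  P(any collision)      %.4g\n",
    "  expected collisions   %.4g\n"),
    x$n_templates, x$barcode_length, x$p_any_collision,
    x$expected_collisions))
  invisible(x)
}

nn_distances <- function(m) {
  # blocked all-pairs nearest-neighbour Hamming distances for an n x L
  # integer/character matrix
  n <- nrow(m); L <- ncol(m)
  nn <- rep(Inf, n)
  block <- 256L
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    d <- matrix(0L, hi - lo + 1L, n)
    for (j in seq_len(L)) {
      d <- d + outer(m[lo:hi, j], m[, j], "!=")
    }
    d[cbind(seq_len(hi - lo + 1L), lo:hi)] <- .Machine$integer.max
    nn[lo:hi] <- apply(d, 1L, min)
  }
  as.integer(nn)
}

#' Nearest-neighbour Hamming-distance structure of a barcode library
#'
#' Draws `n` uniform random barcodes of length `L` and computes exact
#' all-pairs nearest-neighbour distances (feasible up to n = 10^4; larger
#' libraries are refused). Optionally repeats the computation for a
#' mutated-cloud model in which each original barcode is accompanied by
#' `cloud_k` single-substitution derivatives — the error cloud that
#' surrounds each parent barcode after amplification and sequencing, whose
#' members sit ~1 distance from their nearest neighbour while originals
#' average ~3 apart.
#'
#' @param n_barcodes Number of original barcodes (>= 2).
#' @param barcode_length Barcode length (default 15).
#' @param seed Seed (mandatory).
#' @param cloud_k Single-error derivatives per original barcode (default 0:
#'   originals only).
#' @return List: `mean_nn`, `histogram` (table of NN distances), and, when
#'   `cloud_k > 0`, `mean_nn_cloud` and `histogram_cloud` for the combined
#'   originals-plus-derivatives set.
#' @export
nn_hamming_stats <- function(n_barcodes, barcode_length = 15L, seed = NULL,
                             cloud_k = 0L) {
  if (n_barcodes < 2L) stop("nn_hamming_stats: need n >= 2")
  if (n_barcodes * (cloud_k + 1L) > 1e4) {
    stop("nn_hamming_stats: exact all-pairs computation capped at 10^4 ",
         "sequences")
  }
  if (is.null(seed)) stop("nn_hamming_stats: seed is mandatory")
  set.seed(seed)
  m <- matrix(sample.int(4L, n_barcodes * barcode_length, replace = TRUE),
              nrow = n_barcodes)
  nn <- nn_distances(m)
  out <- list(mean_nn = mean(nn), histogram = table(nn))
  if (cloud_k > 0L) {
    rows <- vector("list", n_barcodes)
    for (i in seq_len(n_barcodes)) {
      derived <- matrix(rep(m[i, ], cloud_k), nrow = cloud_k, byrow = TRUE)
      pos <- sample.int(barcode_length, cloud_k, replace = TRUE)
      for (j in seq_len(cloud_k)) {
        derived[j, pos[j]] <- sample(setdiff(1:4, derived[j, pos[j]]), 1L)
      }
      rows[[i]] <- rbind(m[i, , drop = FALSE], derived)
    }
    mc <- do.call(rbind, rows)
    nnc <- nn_distances(mc)
    out$mean_nn_cloud <- mean(nnc)
    out$histogram_cloud <- table(nnc)
  }
  out
}
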