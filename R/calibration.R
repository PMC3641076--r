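# k-mer threshold calibration: sample reads, compute both distances on
# all sampled pairs, and place beta at the zero-false-positive point.

#' Randomly sample sequence ids for calibration
#'
#' Draws `min(n, nrow(seqs))` distinct ids uniformly without
#' replacement. With `n` at least the input size, all ids are returned
#' (no sampling noise on small inputs). Reproducible for a fixed seed;
#' the caller's RNG state is left untouched.
#'
#' @param seqs Sequence tibble.
#' @param n Target sample size.
#' @param seed Integer RNG seed.
#' @return Character vector of sampled ids.
#' @export
sample_sequences <- function(seqs, n, seed) {
  stopifnot(n >= 2)
  if (nrow(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (nrow(seqs) <= n) return(seqs$id)
  withr::with_seed(seed, sample(seqs$id, n))
}

#' Categorise distance pairs against (alpha, beta)
#'
#' A pair is a true positive when both distances fall below their
#' thresholds (`nw_dist <= alpha` and `kmer_dist <= beta`), a false
#' positive when only the k-mer distance does, a false negative when
#' only the NW distance does, and a true negative otherwise.
#'
#' @param pairs Tibble with `kmer_dist` and `nw_dist` columns, both
#'   complete.
#' @param alpha NW distance threshold.
#' @param beta k-mer distance threshold (inclusive comparison).
#' @return One-row tibble with integer columns `TP`, `FP`, `FN`, `TN`.
#' @export
categorize_pairs <- function(pairs, alpha, beta) {
  if (!all(c("kmer_dist", "nw_dist") %in% names(pairs))) {
    stop("pairs must have both 'kmer_dist' and 'nw_dist'", call. = FALSE)
  }
  if (anyNA(pairs$kmer_dist) || anyNA(pairs$nw_dist)) {
    stop("pairs contain missing distances", call. = FALSE)
  }
  d_ok <- pairs$nw_dist <= alpha
  k_ok <- pairs$kmer_dist <= beta
  tibble::tibble(TP = sum(d_ok & k_ok), FP = sum(!d_ok & k_ok),
                 FN = sum(d_ok & !k_ok), TN = sum(!d_ok & !k_ok))
}

#' Determine the k-mer threshold beta
#'
#' Finds the largest observed k-mer distance at which no sampled pair is
#' a false positive: with `m` the smallest k-mer distance among pairs
#' whose NW distance exceeds `alpha`, beta is the largest observed k-mer
#' distance strictly below `m` (0 if none). If no pair exceeds `alpha`,
#' beta is the largest observed k-mer distance. The inclusive `<= beta`
#' test then guarantees `FP == 0` on the sample.
#'
#' @inheritParams categorize_pairs
#' @return The threshold beta, a number in \[0, 1\].
#' @export
determine_beta <- function(pairs, alpha) {
  if (nrow(pairs) == 0) stop("empty pair set", call. = FALSE)
  if (anyNA(pairs$kmer_dist) || anyNA(pairs$nw_dist)) {
    stop("pairs contain missing distances", call. = FALSE)
  }
  over <- pairs$kmer_dist[pairs$nw_dist > alpha]
  if (length(over) == 0) return(max(pairs$kmer_dist))
  m <- min(over)
  under_m <- pairs$kmer_dist[pairs$kmer_dist < m]
  beta <- if (length(under_m) > 0) max(under_m) else 0
  if (beta == 0 && !any(pairs$kmer_dist <= beta & pairs$nw_dist <= alpha)) {
    warning("beta = 0 admits no true positives; k-mer distance does not ",
            "separate pairs at alpha = ", alpha, call. = FALSE)
  }
  beta
}

#' Calibrate the k-mer threshold on a random sample
#'
#' Runs the first stage of the pipeline: sample reads, compute k-mer and
#' NW distances for every sampled pair, and place the k-mer threshold
#' beta so that the sample contains no false positives at the user's NW
#' threshold alpha. The squared Pearson correlation between the two
#' distance vectors is recorded as a diagnostic (NA when either vector
#' is constant, e.g. on identical reads).
#'
#' @param seqs Sequence tibble.
#' @param alpha NW distance threshold in (0, 1); the pipeline calibrates
#'   once at 0.03.
#' @param sample_size Number of reads to sample (default 1000, the size
#'   at which the k-mer/NW correlation stabilises).
#' @param k k-mer size (default 7).
#' @param seed Integer RNG seed (required; calibration is the only
#'   stochastic stage).
#' @param scoring An [nw_scoring()] list.
#' @return An object of class `clustom_calibration`: list with `alpha`,
#'   `beta`, `sample_ids`, `pairs` (the distance table), `confusion`
#'   (one-row TP/FP/FN/TN tibble), `r2`, `k`, `sample_size`, `seed`.
#' @examples
#' seqs <- amplicon_tbl(paste0("s", 1:6),
#'                      rep(c("ACGTACGTACGTACG", "TTGCATTGCATTGCA"), 3))
#' calibrate(seqs, alpha = 0.03, seed = 1, k = 5)
#' @export
calibrate <- function(seqs, alpha = 0.03, sample_size = 1000, k = 7,
                      seed, scoring = nw_scoring()) {
  stopifnot(alpha > 0, alpha < 1)
  if (missing(seed)) stop("calibration requires an explicit seed",
                          call. = FALSE)
  ids <- sample_sequences(seqs, sample_size, seed)
  sub <- seqs[match(ids, seqs$id), ]
  pairs <- pair_distances(sub, k = k, scoring = scoring)
  beta <- determine_beta(pairs, alpha)
  confusion <- categorize_pairs(pairs, alpha, beta)
  r2 <- if (stats::sd(pairs$kmer_dist) == 0 || stats::sd(pairs$nw_dist) == 0) {
    NA_real_
  } else {
    r_square(pairs$kmer_dist, pairs$nw_dist)
  }
  structure(list(alpha = alpha, beta = beta, sample_ids = ids,
                 pairs = pairs, confusion = confusion, r2 = r2,
                 k = as.integer(k), sample_size = as.integer(sample_size),
                 seed = seed, scoring = scoring),
            class = "clustom_calibration")
}

#' @export
print.clustom_calibration <- function(x, ...) {
  cat("<clustom_calibration>\n")
  cat("  alpha:", x$alpha, " beta:", signif(x$beta, 4), "\n")
  cat("  sample:", length(x$sample_ids), "reads,",
      nrow(x$pairs), "pairs (k =", x$k, ", seed =", x$seed, ")\n")
  cat("  confusion: TP", x$confusion$TP, " FP", x$confusion$FP,
      " FN", x$confusion$FN, " TN", x$confusion$TN, "\n")
  cat("  R-square(kmer, NW):",
      if (is.na(x$r2)) "NA (constant distances)" else signif(x$r2, 4), "\n")
  invisible(x)
}
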