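# The two distances the algorithm is built on: gap-ignoring NW distance
# and the k-mer profile distance, plus the pairwise-table driver.

#' Needleman-Wunsch scoring parameters
#'
#' Scoring scheme for the global alignment underlying the NW distance.
#' A gap run of length L costs `gap_open + L * gap_extend`. By default
#' terminal gaps are penalized like internal ones (classic global NW);
#' the distance later strips the end-gap columns. With
#' `free_end_gaps = TRUE` terminal gap runs cost nothing (overlap-style
#' alignment) -- useful for reads covering different stretches of the
#' gene, but unrelated sequences then score spurious short perfect
#' overlaps, so it is not the default.
#'
#' @param match Score for an identical aligned pair (default +5).
#' @param mismatch Score for a substituted pair (default -4).
#' @param gap_open Cost charged once per gap run (default -10).
#' @param gap_extend Cost per gapped position (default -1).
#' @param free_end_gaps Logical; leave terminal gap runs unpenalized
#'   (default FALSE).
#' @return A named list of class `nw_scoring`.
#' @export
nw_scoring <- function(match = 5, mismatch = -4, gap_open = -10,
                       gap_extend = -1, free_end_gaps = FALSE) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend),
            is.logical(free_end_gaps), length(free_end_gaps) == 1)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 free_end_gaps = free_end_gaps),
            class = "nw_scoring")
}

#' Optimal global pairwise alignment
#'
#' Aligns two sequences with the Needleman-Wunsch algorithm under affine
#' gap costs. The traceback is deterministic: score ties are resolved
#' diagonal > up > left, and (with free end gaps) among equally good end
#' points the full-corner alignment is preferred, so repeated calls are
#' bit-identical.
#'
#' @param seq_i,seq_j Non-empty base strings.
#' @param scoring An [nw_scoring()] list.
#' @return An object of class `nw_alignment`: list with `aligned_i`,
#'   `aligned_j` (equal-length gapped strings) and `score`.
#' @examples
#' nw_align("ACGT", "AGT")
#' @export
nw_align <- function(seq_i, seq_j, scoring = nw_scoring()) {
  stopifnot(is.character(seq_i), is.character(seq_j),
            length(seq_i) == 1, length(seq_j) == 1)
  if (!nzchar(seq_i) || !nzchar(seq_j)) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  res <- nw_align_cpp(seq_i, seq_j, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend,
                      isTRUE(scoring$free_end_gaps))
  structure(res, class = "nw_alignment")
}

#' @export
print.nw_alignment <- function(x, ...) {
  cat("<nw_alignment> score", x$score, "\n")
  cat(" ", x$aligned_i, "\n ", x$aligned_j, "\n")
  invisible(x)
}

#' Gap-ignoring NW distance of an alignment
#'
#' Computes the dissimilarity used for OTU thresholds: terminal columns
#' in which either row is gapped are stripped, every remaining column
#' containing a gap is ignored, and the distance is the fraction of
#' mismatching gap-free columns. Treating all indels as missing data
#' matches common 16S practice and avoids scoring homopolymer
#' sequencing errors as substitutions.
#'
#' @param alignment An `nw_alignment` from [nw_align()].
#' @return A number in \[0, 1\].
#' @export
nw_distance <- function(alignment) {
  stopifnot(inherits(alignment, "nw_alignment"))
  res <- aligned_dist_cpp(alignment$aligned_i, alignment$aligned_j)
  if (res$comparable == 0) {
    stop("no comparable positions (all columns gapped after end-gap stripping)",
         call. = FALSE)
  }
  res$dist
}

#' k-mer occurrence profile of a sequence
#'
#' Counts every window of length `k` consisting solely of A/C/G/T;
#' windows containing an ambiguity code are skipped.
#'
#' @param seq A base string of length >= `k`.
#' @param k Word length in nucleotides (default 7, the size at which the
#'   k-mer/NW correlation plateaus for 16S variable regions).
#' @return A tibble with columns `kmer`, `count`, carrying attributes
#'   `k`, `seq_length` and `effective_length` (number of counted
#'   windows).
#' @examples
#' kmer_profile("ACGTACGT", k = 3)
#' @export
kmer_profile <- function(seq, k = 7) {
  stopifnot(is.character(seq), length(seq) == 1, k >= 1)
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k (", n, " < ", k, ")", call. = FALSE)
  words <- substring(seq, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  words <- words[grepl("^[ACGT]+$", words)]
  tab <- table(words)
  out <- tibble::tibble(kmer = names(tab), count = as.integer(tab))
  attr(out, "k") <- as.integer(k)
  attr(out, "seq_length") <- n
  attr(out, "effective_length") <- length(words)
  out
}

#' k-mer distance between two profiles
#'
#' Alignment-free dissimilarity `1 - sum_w min(n_i(w), n_j(w)) /
#' (min(L_i, L_j) - k + 1)`: the shared word count normalised by the
#' window count of the shorter sequence, clamped to \[0, 1\].
#'
#' @param profile_i,profile_j Profiles from [kmer_profile()] built with
#'   the same `k`.
#' @return A number in \[0, 1\]; symmetric in its arguments.
#' @export
kmer_distance <- function(profile_i, profile_j) {
  ki <- attr(profile_i, "k"); kj <- attr(profile_j, "k")
  if (is.null(ki) || is.null(kj) || ki != kj) {
    stop("profiles built with different k (", ki, " vs ", kj, ")",
         call. = FALSE)
  }
  shared <- dplyr::inner_join(profile_i, profile_j, by = "kmer",
                              suffix = c("_i", "_j"))
  num <- sum(pmin(shared$count_i, shared$count_j))
  denom <- min(attr(profile_i, "seq_length"), attr(profile_j, "seq_length")) -
    ki + 1
  if (denom <= 0) return(1)
  min(max(1 - num / denom, 0), 1)
}

#' All unordered pairs of ids
#'
#' Enumerates the pairs the pairwise stages iterate over, with
#' `id_i < id_j` in the input order.
#'
#' @param ids Character vector of distinct ids (length >= 2).
#' @return A tibble with columns `id_i`, `id_j` and `choose(n, 2)` rows.
#' @seealso [n_pairs()] for the closed-form count.
#' @export
enumerate_pairs <- function(ids) {
  stopifnot(length(ids) >= 2, !anyDuplicated(ids))
  n <- length(ids)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1) + i
  tibble::tibble(id_i = ids[i], id_j = ids[j])
}

#' Number of unordered pairs
#'
#' Closed-form pair count `choose(n, 2)`; e.g. 50,000 reads already
#' imply over a billion pairwise comparisons, which is why exhaustive NW
#' is replaced by the k-mer filter.
#'
#' @param n Number of sequences.
#' @return `choose(n, 2)` as a double.
#' @export
n_pairs <- function(n) {
  stopifnot(is.numeric(n), n >= 0)
  choose(n, 2)
}

#' Pairwise k-mer and NW distances
#'
#' Computes both distances for every unordered pair of the given
#' sequences (or for a supplied pair subset). Pairs whose alignment
#' leaves no comparable positions are assigned NW distance 1 with a
#' warning: such reads share no usable overlap and must never satisfy a
#' distance threshold.
#'
#' @param seqs Sequence tibble from [amplicon_tbl()] /
#'   [read_amplicon_fasta()].
#' @param k k-mer size (default 7).
#' @param scoring An [nw_scoring()] list.
#' @param compute What to compute: both distances, or one of them.
#' @return A tibble with columns `id_i`, `id_j`, `kmer_dist`,
#'   `nw_dist` (columns not computed are omitted), `id_i < id_j`
#'   lexicographically.
#' @export
pair_distances <- function(seqs, k = 7, scoring = nw_scoring(),
                           compute = c("both", "kmer", "nw")) {
  compute <- match.arg(compute)
  stopifnot(nrow(seqs) >= 2)
  n <- nrow(seqs)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1) + i
  swap <- seqs$id[i] > seqs$id[j]
  out <- tibble::tibble(id_i = ifelse(swap, seqs$id[j], seqs$id[i]),
                        id_j = ifelse(swap, seqs$id[i], seqs$id[j]))
  if (compute %in% c("both", "kmer")) {
    out$kmer_dist <- kmer_dist_pairs_cpp(seqs$seq, i, j, as.integer(k))
  }
  if (compute %in% c("both", "nw")) {
    d <- nw_dist_pairs_cpp(seqs$seq, i, j, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           isTRUE(scoring$free_end_gaps))
    if (anyNA(d)) {
      warning(sum(is.na(d)),
              " pair(s) share no comparable positions; NW distance set to 1",
              call. = FALSE)
      d[is.na(d)] <- 1
    }
    out$nw_dist <- d
  }
  out
}

#' Squared Pearson correlation
#'
#' The R-square statistic used to diagnose how linearly the k-mer
#' distance tracks the NW distance on the calibration sample.
#'
#' @param xs,ys Numeric vectors of equal length >= 2.
#' @return The square of the Pearson correlation, in \[0, 1\].
#' @export
r_square <- function(xs, ys) {
  stopifnot(is.numeric(xs), is.numeric(ys), length(xs) == length(ys),
            length(xs) >= 2)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  cor(xs, ys)^2
}
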