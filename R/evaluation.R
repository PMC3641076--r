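# The two accuracy frameworks: taxonomy-based per-taxon confusion with
# precision/recall/F-measure, and distance-based false conjunction /
# disjunction rates against per-OTU core sequences.

#' Assign each taxon its representative OTU
#'
#' For every taxon, the OTU holding the largest number of that taxon's
#' sequences is its representative. Taxa whose maximum is achieved in
#' several OTUs are excluded (their representative is ambiguous); taxa
#' sharing one representative OTU are merged into a composite taxon and
#' scored as a unit -- this is how indistinguishable 16S species groups
#' (e.g. *Escherichia coli*/*Shigella*) are handled without any external
#' species-group list.
#'
#' @param clustering An `otu_clustering` (or any tibble with `otu`,
#'   `id`).
#' @param taxonomy Tibble with columns `id`, `label` covering every
#'   clustered id.
#' @return List with `representatives` (tibble `taxon`, `labels`
#'   list-column, `otu`) and `excluded` (character vector of taxa).
#' @export
assign_representatives <- function(clustering, taxonomy) {
  lab <- taxonomy$label[match(clustering$id, taxonomy$id)]
  if (anyNA(lab)) {
    stop("unlabeled sequence id(s): ",
         paste(head(clustering$id[is.na(lab)], 5), collapse = ", "),
         call. = FALSE)
  }
  counts <- dplyr::count(tibble::tibble(label = lab, otu = clustering$otu),
                         .data$label, .data$otu)
  per_taxon <- dplyr::summarise(
    dplyr::group_by(counts, .data$label),
    n_max = sum(.data$n == max(.data$n)),
    otu = .data$otu[which.max(.data$n)],
    .groups = "drop")
  excluded <- per_taxon$label[per_taxon$n_max > 1]
  kept <- per_taxon[per_taxon$n_max == 1, ]
  groups <- split(kept$label, kept$otu)
  reps <- tibble::tibble(
    taxon = vapply(groups, function(g) paste(lex_sort(g), collapse = "+"),
                   "", USE.NAMES = FALSE),
    labels = unname(lapply(groups, lex_sort)),
    otu = names(groups))
  reps <- reps[order(reps$taxon, method = "radix"), ]
  list(representatives = reps, excluded = lex_sort(excluded))
}

#' Per-taxon confusion counts, precision and recall
#'
#' For each (possibly composite) taxon with representative OTU `O`:
#' TP = the taxon's sequences inside `O`; FP = other labelled sequences
#' inside `O`; FN = the taxon's sequences outside `O`; TN = other
#' labelled sequences outside `O`. Precision is TP/(TP+FP), recall
#' TP/(TP+FN).
#'
#' @inheritParams assign_representatives
#' @param representatives Optional result of [assign_representatives()];
#'   computed if missing.
#' @return Tibble with one row per scored taxon: `taxon`, `otu`, `TP`,
#'   `FP`, `FN`, `TN`, `precision`, `recall`.
#' @export
taxon_confusion <- function(clustering, taxonomy, representatives = NULL) {
  if (is.null(representatives)) {
    representatives <- assign_representatives(clustering, taxonomy)
  }
  reps <- representatives$representatives
  lab <- taxonomy$label[match(clustering$id, taxonomy$id)]
  otu <- clustering$otu
  n_total <- length(lab)
  rows <- purrr::pmap(list(reps$taxon, reps$labels, reps$otu),
                      function(taxon, labels, rep_otu) {
    in_taxon <- lab %in% labels
    in_rep <- otu == rep_otu
    TP <- sum(in_taxon & in_rep)
    FP <- sum(!in_taxon & in_rep)
    FN <- sum(in_taxon & !in_rep)
    TN <- n_total - TP - FP - FN
    tibble::tibble(taxon = taxon, otu = rep_otu,
                   TP = TP, FP = FP, FN = FN, TN = TN)
  })
  out <- dplyr::bind_rows(rows)
  zero <- out$TP == 0 & out$FP == 0
  if (any(zero)) {
    warning("taxon with empty representative intersection; ",
            "precision set to 0 for: ",
            paste(out$taxon[zero], collapse = ", "), call. = FALSE)
  }
  out$precision <- ifelse(out$TP + out$FP > 0, out$TP / (out$TP + out$FP), 0)
  out$recall <- ifelse(out$TP + out$FN > 0, out$TP / (out$TP + out$FN), 0)
  out
}

#' F-measure over per-taxon precision and recall
#'
#' The harmonic mean of the unweighted taxon averages:
#' `F2 = 2 * P * R / (P + R)` with `P` and `R` the means of per-taxon
#' precision and recall (averaging first, then combining). The
#' alternative convention -- per-taxon F then averaging -- gives
#' different values and is deliberately not used.
#'
#' @param confusions Tibble from [taxon_confusion()].
#' @return A number in \[0, 1\].
#' @export
f_measure <- function(confusions) {
  stopifnot(nrow(confusions) >= 1)
  p_bar <- mean(confusions$precision)
  r_bar <- mean(confusions$recall)
  if (p_bar + r_bar == 0) stop("precision and recall both average to zero",
                               call. = FALSE)
  2 * p_bar * r_bar / (p_bar + r_bar)
}

#' Core sequence of a set of reads
#'
#' The member with the minimum average NW distance to the other members
#' -- the observed sequence closest to the cluster centre. Ties go to the
#' lexicographically smallest id; a single member is its own core.
#'
#' @param seqs Sequence tibble restricted to the members of one OTU.
#' @param scoring An [nw_scoring()] list.
#' @return The core sequence id.
#' @export
core_sequence <- function(seqs, scoring = nw_scoring()) {
  if (nrow(seqs) == 0) stop("empty OTU has no core sequence", call. = FALSE)
  if (nrow(seqs) == 1) return(seqs$id)
  n <- nrow(seqs)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1) + i
  d <- nw_dist_pairs_cpp(seqs$seq, i, j, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend,
                         isTRUE(scoring$free_end_gaps))
  d[is.na(d)] <- 1
  total <- numeric(n)
  for (ix in seq_along(d)) {
    total[i[ix]] <- total[i[ix]] + d[ix]
    total[j[ix]] <- total[j[ix]] + d[ix]
  }
  avg <- total / (n - 1)
  lex_min(seqs$id[avg == min(avg)])
}

#' False conjunction and false disjunction rates
#'
#' Distance-based, taxonomy-free accuracy. Each OTU's core sequence is
#' found first; then a sequence is a false conjunction when its NW
#' distance to its own OTU's core exceeds `alpha` (wrongly included),
#' and a false disjunction when it lies within `alpha` of some other
#' OTU's core (wrongly separated). Both counts are divided by the total
#' number of sequences.
#'
#' @param clustering An `otu_clustering`.
#' @param seqs Sequence tibble covering every clustered id.
#' @param alpha NW distance threshold the clustering was built at
#'   (default: the clustering's own alpha).
#' @param scoring An [nw_scoring()] list.
#' @return One-row tibble: `alpha`, `false_conjunction`,
#'   `false_disjunction`, `n`; the per-OTU cores are attached as
#'   attribute `cores` (tibble `otu`, `core_id`).
#' @export
false_rates <- function(clustering, seqs, alpha = attr(clustering, "alpha"),
                        scoring = nw_scoring()) {
  stopifnot(!is.null(alpha))
  ids <- clustering$id
  if (!all(ids %in% seqs$id)) stop("clustering references unknown ids",
                                   call. = FALSE)
  otus <- unique(clustering$otu)
  cores <- vapply(otus, function(o) {
    member_ids <- clustering$id[clustering$otu == o]
    core_sequence(seqs[match(member_ids, seqs$id), ], scoring = scoring)
  }, "")
  core_tbl <- tibble::tibble(otu = otus, core_id = unname(cores))

  # distances of every sequence to every core, N x n_otus
  all_seq <- seqs[match(unique(c(ids, core_tbl$core_id)), seqs$id), ]
  seq_idx <- match(ids, all_seq$id)
  core_idx <- match(core_tbl$core_id, all_seq$id)
  ii <- rep(seq_idx, times = length(core_idx))
  jj <- rep(core_idx, each = length(seq_idx))
  d <- nw_dist_pairs_cpp(all_seq$seq, ii, jj, scoring$match,
                         scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, isTRUE(scoring$free_end_gaps))
  d[is.na(d)] <- 1
  dmat <- matrix(d, nrow = length(ids), ncol = length(core_idx))

  own_col <- match(clustering$otu, core_tbl$otu)
  own_d <- dmat[cbind(seq_len(length(ids)), own_col)]
  conj <- own_d > alpha
  foreign_close <- vapply(seq_len(length(ids)), function(r) {
    any(dmat[r, -own_col[r]] <= alpha)
  }, TRUE)
  out <- tibble::tibble(alpha = alpha,
                        false_conjunction = mean(conj),
                        false_disjunction = mean(foreign_close),
                        n = length(ids))
  attr(out, "cores") <- core_tbl
  out
}
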