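# Core algorithm: beta-thresholded k-mer graph, greedy max-degree
# extraction, NW refinement over seeds + singletons, and recovery.

lex_min <- function(x) sort(x, method = "radix")[1]
lex_sort <- function(x) sort(x, method = "radix")

new_similarity_graph <- function(nodes, adj, criterion, threshold) {
  structure(list(nodes = nodes, adj = adj, criterion = criterion,
                 threshold = threshold),
            class = "similarity_graph")
}

graph_from_pairs <- function(nodes, id_i, id_j, criterion, threshold) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  adj[] <- list(character(0))
  for (ix in seq_along(id_i)) {
    a <- id_i[ix]; b <- id_j[ix]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, lex_sort)
  new_similarity_graph(nodes, adj, criterion, threshold)
}

#' @export
print.similarity_graph <- function(x, ...) {
  n_edges <- sum(lengths(x$adj)) / 2
  cat("<similarity_graph> ", length(x$nodes), " nodes, ", n_edges,
      " edges (", x$criterion, " distance <= ", signif(x$threshold, 4),
      ")\n", sep = "")
  invisible(x)
}

#' Build the k-mer similarity graph
#'
#' Connects every pair of reads whose k-mer distance is at most `beta`.
#' This is the only stage that touches all `choose(n, 2)` pairs, and it
#' does so with the cheap alignment-free distance; exact NW alignment is
#' reserved for the much smaller refinement stage.
#'
#' @param seqs Sequence tibble.
#' @param beta k-mer distance threshold from [calibrate()].
#' @param k k-mer size (must match the calibration).
#' @return A `similarity_graph` over all sequence ids.
#' @export
build_kmer_graph <- function(seqs, beta, k = 7) {
  stopifnot(beta >= 0, beta <= 1)
  short <- seqs$length < k
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than k = ", k,
            " cannot share k-mers and will remain singletons",
            call. = FALSE)
  }
  dm <- kmer_dist_matrix_cpp(seqs$seq, as.integer(k))
  hit <- which(dm <= beta & upper.tri(dm), arr.ind = TRUE)
  graph_from_pairs(seqs$id, seqs$id[hit[, 1]], seqs$id[hit[, 2]],
                   criterion = "kmer", threshold = beta)
}

# Iterative maximum-degree extraction shared by the initial and the
# refined stage. Ties on degree go to the lexicographically smallest id
# (C collation) so extraction is deterministic.
extract_max_degree <- function(graph) {
  adj <- graph$adj
  clusters <- list()
  repeat {
    deg <- lengths(adj)
    if (length(deg) == 0 || max(deg) == 0) break
    seed <- lex_min(names(adj)[deg == max(deg)])
    members <- c(seed, adj[[seed]])
    clusters[[length(clusters) + 1]] <-
      list(seed_id = seed, member_ids = lex_sort(members))
    adj <- adj[!(names(adj) %in% members)]
    adj <- lapply(adj, function(v) v[!(v %in% members)])
  }
  list(clusters = clusters, singletons = lex_sort(names(adj)))
}

#' Greedy initial clustering of a similarity graph
#'
#' Repeatedly takes the node of maximum degree as a seed, emits the seed
#' plus its current neighbours as a cluster, and deletes them from the
#' graph, until only degree-zero nodes remain; those are returned as
#' singletons. The most-connected node stands in for the (possibly
#' virtual) centre of the local cloud of similar sequences.
#'
#' @param graph A `similarity_graph`, typically from [build_kmer_graph()].
#' @return List with `clusters` (each a list with `seed_id`,
#'   `member_ids`) in extraction order, and `singletons` (character).
#' @export
initial_clustering <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  extract_max_degree(graph)
}

#' NW refinement graph over seeds and singletons
#'
#' Computes exact NW distances for every pair drawn from the initial
#' seeds and the singletons, and connects the pairs at the user
#' threshold `alpha`. This rescues k-mer false negatives: reads within
#' `alpha` of a seed whose k-mer distance exceeded `beta`.
#'
#' @param initial Result of [initial_clustering()].
#' @param seqs Sequence tibble.
#' @param alpha NW distance threshold.
#' @param scoring An [nw_scoring()] list.
#' @param nw_pairs Optional precomputed distance tibble over the
#'   seed/singleton set (columns `id_i`, `id_j`, `nw_dist`), reused when
#'   refining at several thresholds.
#' @return A `similarity_graph` whose nodes are the seeds and
#'   singletons, with edges at `nw_dist <= alpha`.
#' @export
refine <- function(initial, seqs, alpha, scoring = nw_scoring(),
                   nw_pairs = NULL) {
  nodes <- lex_sort(c(vapply(initial$clusters, `[[`, "", "seed_id"),
                      initial$singletons))
  if (length(nodes) < 2) {
    return(new_similarity_graph(nodes,
                                setNames(rep(list(character(0)),
                                             length(nodes)), nodes),
                                "nw", alpha))
  }
  if (is.null(nw_pairs)) {
    nw_pairs <- refine_pair_distances(nodes, seqs, scoring)
  }
  keep <- nw_pairs$nw_dist <= alpha
  graph_from_pairs(nodes, nw_pairs$id_i[keep], nw_pairs$id_j[keep],
                   criterion = "nw", threshold = alpha)
}

# NW distances over the reduced seed/singleton set; exactly
# choose(length(nodes), 2) alignments.
refine_pair_distances <- function(nodes, seqs, scoring) {
  sub <- seqs[match(nodes, seqs$id), ]
  suppressWarnings(pair_distances(sub, scoring = scoring, compute = "nw"))
}

#' Recover final clusters from the refined graph
#'
#' Runs the same max-degree extraction on the refined graph; each final
#' cluster is the refined seed, its refined-graph neighbours, and the
#' initial-cluster members of every one of those nodes that was an
#' initial seed (singleton neighbours contribute only themselves).
#' Refined-graph leftovers keep their initial cluster (seeds) or stay
#' singleton OTUs.
#'
#' @param refined_graph A `similarity_graph` from [refine()].
#' @param initial Result of [initial_clustering()].
#' @param alpha The NW threshold the refinement used.
#' @param provenance Optional named list stored on the result (beta, k,
#'   seed, sample_size).
#' @return An `otu_clustering`: tibble with columns `otu`, `seed_id`,
#'   `id`, one row per sequence, labelled by decreasing OTU size.
#' @export
recover_clusters <- function(refined_graph, initial, alpha,
                             provenance = list()) {
  members_of <- setNames(lapply(initial$clusters, `[[`, "member_ids"),
                         vapply(initial$clusters, `[[`, "", "seed_id"))
  expand <- function(node) {
    if (!is.null(members_of[[node]])) members_of[[node]] else node
  }
  ext <- extract_max_degree(refined_graph)
  clusters <- lapply(ext$clusters, function(cl) {
    list(seed_id = cl$seed_id,
         member_ids = lex_sort(unique(unlist(lapply(cl$member_ids, expand)))))
  })
  for (s in ext$singletons) {
    clusters[[length(clusters) + 1]] <-
      list(seed_id = s, member_ids = expand(s))
  }
  all_ids <- unlist(lapply(clusters, `[[`, "member_ids"))
  input_ids <- unlist(lapply(initial$clusters, `[[`, "member_ids"))
  input_ids <- c(input_ids, initial$singletons)
  if (anyDuplicated(all_ids) || length(all_ids) != length(input_ids) ||
      !setequal(all_ids, input_ids)) {
    stop("internal error: recovered clusters do not partition the input",
         call. = FALSE)
  }
  new_otu_clustering(clusters, alpha = alpha, provenance = provenance)
}

# Label clusters OTU1, OTU2, ... by decreasing size, ties by
# lexicographically smallest seed id, and flatten to the tidy form.
new_otu_clustering <- function(clusters, alpha, provenance = list()) {
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), 0L)
  seeds <- vapply(clusters, `[[`, "", "seed_id")
  ord <- order(-sizes, seeds, method = "radix")
  clusters <- clusters[ord]
  out <- tibble::tibble(
    otu = rep(paste0("OTU", seq_along(clusters)), sizes[ord]),
    seed_id = rep(seeds[ord], sizes[ord]),
    id = unlist(lapply(clusters, `[[`, "member_ids"))
  )
  structure(out, alpha = alpha, provenance = provenance,
            class = c("otu_clustering", class(out)))
}

#' Cluster amplicon reads into OTUs
#'
#' The full pipeline. Calibration (random sample, zero-false-positive
#' beta) and the k-mer graph stage run once at a 3% NW distance
#' regardless of the requested thresholds; refinement and recovery then
#' run at every requested `alpha`, so one run yields the whole threshold
#' ladder.
#'
#' @param seqs Sequence tibble from [read_amplicon_fasta()] /
#'   [amplicon_tbl()].
#' @param alphas NW distance thresholds, each typically in
#'   \[0.03, 0.10\] (3% approximates species, 5% genus); values outside
#'   that range trigger a warning, not an error.
#' @param k k-mer size (default 7).
#' @param sample_size Calibration sample size (default 1000).
#' @param seed Integer RNG seed for the calibration sample.
#' @param scoring An [nw_scoring()] list.
#' @param calibration_alpha NW threshold the calibration stage uses
#'   (default 0.03; the refinement stage handles larger thresholds).
#' @return An object of class `clustom_result`: list with
#'   `clusterings` (named list of `otu_clustering`, one per alpha),
#'   `calibration`, and `params`. Use [tidy()] / [glance()] /
#'   [autoplot()] to inspect it, [write_otu_files()] to export one
#'   clustering.
#' @examples
#' com <- generate_community(community_spec(
#'   n_species = 2, ancestor_length = 120, abundances = c(5, 5), seed = 1))
#' fit <- clustom(com$seqs, alphas = 0.03, seed = 1)
#' glance(fit)
#' @export
clustom <- function(seqs, alphas = 0.03, k = 7, sample_size = 1000,
                    seed = 1, scoring = nw_scoring(),
                    calibration_alpha = 0.03) {
  stopifnot(is.numeric(alphas), length(alphas) >= 1,
            all(alphas > 0), all(alphas < 1))
  alphas <- sort(unique(alphas))
  if (any(alphas < 0.03 - 1e-12 | alphas > 0.10 + 1e-12)) {
    warning("threshold(s) outside the supported range [0.03, 0.10]: ",
            paste(signif(alphas[alphas < 0.03 | alphas > 0.10], 3),
                  collapse = ", "), call. = FALSE)
  }
  if (nrow(seqs) == 1) {
    warning("single input sequence: returning one singleton OTU",
            call. = FALSE)
    cal <- structure(list(alpha = calibration_alpha, beta = 0,
                          sample_ids = seqs$id,
                          pairs = tibble::tibble(id_i = character(0),
                                                 id_j = character(0),
                                                 kmer_dist = numeric(0),
                                                 nw_dist = numeric(0)),
                          confusion = tibble::tibble(TP = 0L, FP = 0L,
                                                     FN = 0L, TN = 0L),
                          r2 = NA_real_, k = as.integer(k),
                          sample_size = as.integer(sample_size),
                          seed = seed, scoring = scoring),
                     class = "clustom_calibration")
    provenance <- list(beta = 0, k = as.integer(k), seed = seed,
                       sample_size = as.integer(sample_size))
    one <- list(list(seed_id = seqs$id, member_ids = seqs$id))
    clusterings <- lapply(alphas, function(a) {
      new_otu_clustering(one, alpha = a, provenance = provenance)
    })
    names(clusterings) <- format(alphas, trim = TRUE)
    return(structure(list(clusterings = clusterings, calibration = cal,
                          initial = list(clusters = one,
                                         singletons = character(0)),
                          params = list(alphas = alphas, k = as.integer(k),
                                        sample_size = as.integer(sample_size),
                                        seed = seed, scoring = scoring)),
                     class = "clustom_result"))
  }
  cal <- calibrate(seqs, alpha = calibration_alpha,
                   sample_size = sample_size, k = k, seed = seed,
                   scoring = scoring)
  graph <- build_kmer_graph(seqs, beta = cal$beta, k = k)
  initial <- initial_clustering(graph)
  nodes <- lex_sort(c(vapply(initial$clusters, `[[`, "", "seed_id"),
                      initial$singletons))
  nw_pairs <- if (length(nodes) >= 2) {
    refine_pair_distances(nodes, seqs, scoring)
  } else NULL
  provenance <- list(beta = cal$beta, k = as.integer(k), seed = seed,
                     sample_size = as.integer(sample_size))
  clusterings <- lapply(alphas, function(a) {
    rg <- refine(initial, seqs, alpha = a, scoring = scoring,
                 nw_pairs = nw_pairs)
    recover_clusters(rg, initial, alpha = a, provenance = provenance)
  })
  names(clusterings) <- format(alphas, trim = TRUE)
  structure(list(clusterings = clusterings, calibration = cal,
                 initial = initial,
                 params = list(alphas = alphas, k = as.integer(k),
                               sample_size = as.integer(sample_size),
                               seed = seed, scoring = scoring)),
            class = "clustom_result")
}

#' @export
print.clustom_result <- function(x, ...) {
  cat("<clustom_result>\n")
  cat("  beta:", signif(x$calibration$beta, 4),
      "(calibrated at alpha =", x$calibration$alpha,
      "on", length(x$calibration$sample_ids), "reads)\n")
  cat("  initial: ", length(x$initial$clusters), " clusters, ",
      length(x$initial$singletons), " singletons\n", sep = "")
  for (nm in names(x$clusterings)) {
    cl <- x$clusterings[[nm]]
    cat("  alpha ", nm, ": ", length(unique(cl$otu)), " OTUs over ",
        nrow(cl), " reads\n", sep = "")
  }
  invisible(x)
}
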