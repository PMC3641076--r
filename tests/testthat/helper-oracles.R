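# Independent oracles used across the suite: exhaustive alignment
# enumeration for NW scores, and a matrix-based reimplementation of
# max-degree extraction. Both are deliberately naive and share no code
# with the package internals they check.

# Maximum alignment score by exhaustive enumeration of all monotone
# alignments (move sequences over M = aligned column, X = gap in b,
# Y = gap in a). A gap run of length L costs gap_open + L*gap_extend.
# With free_end_gaps, the leading gap run (single type) costs nothing
# and the trailing run is refunded at the leaf, matching the overlap
# convention of the dynamic program.
oracle_nw_score <- function(a, b, scoring = nw_scoring()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  free <- isTRUE(scoring$free_end_gaps)
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  best <- -Inf
  rec <- function(i, j, prev, lead, score, run_cost) {
    if (i == m && j == n) {
      total <- score
      if (free && prev %in% c("X", "Y")) total <- total - run_cost
      if (total > best) best <<- total
      return(invisible())
    }
    if (i < m && j < n) {
      s <- if (av[i + 1] == bv[j + 1]) scoring$match else scoring$mismatch
      rec(i + 1, j + 1, "M", "done", score + s, 0)
    }
    if (i < m) {  # X: consume a, gap in b
      if (free && lead %in% c("start", "X")) {
        rec(i + 1, j, "X", "X", score, 0)
      } else {
        cost <- if (prev == "X") ge else go + ge
        rc <- if (prev == "X") run_cost + cost else cost
        rec(i + 1, j, "X", "done", score + cost, rc)
      }
    }
    if (j < n) {  # Y: consume b, gap in a
      if (free && lead %in% c("start", "Y")) {
        rec(i, j + 1, "Y", "Y", score, 0)
      } else {
        cost <- if (prev == "Y") ge else go + ge
        rc <- if (prev == "Y") run_cost + cost else cost
        rec(i, j + 1, "Y", "done", score + cost, rc)
      }
    }
  }
  rec(0, 0, "start", "start", 0, 0)
  best
}

# Matrix-based greedy max-degree clustering: repeatedly take the
# highest-degree active node (lexicographic tie-break), emit it with its
# active neighbours, deactivate them.
oracle_max_degree <- function(amat) {
  ids <- rownames(amat)
  active <- ids
  clusters <- list()
  repeat {
    sub <- amat[active, active, drop = FALSE]
    deg <- rowSums(sub)
    if (length(deg) == 0 || max(deg) == 0) break
    seed <- sort(names(deg)[deg == max(deg)], method = "radix")[1]
    nbrs <- names(which(sub[seed, ] > 0))
    members <- sort(c(seed, nbrs), method = "radix")
    clusters[[length(clusters) + 1]] <- list(seed_id = seed,
                                             member_ids = members)
    active <- setdiff(active, members)
  }
  list(clusters = clusters,
       singletons = sort(active, method = "radix"))
}

# Random adjacency matrix (symmetric, zero diagonal) with edge
# probability p, plus the package's graph object over the same edges.
random_graph <- function(n, p, ids = sprintf("n%02d", seq_len(n))) {
  amat <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) amat[i, j] <- amat[j, i] <- 1L
    }
  }
  hit <- which(amat == 1 & upper.tri(amat), arr.ind = TRUE)
  graph <- clustom:::graph_from_pairs(ids, ids[hit[, 1]], ids[hit[, 2]],
                                      criterion = "kmer", threshold = 0.1)
  list(amat = amat, graph = graph)
}

# Build a similarity graph directly from an edge list (test scaffolding).
graph_from_edges <- function(nodes, edges) {
  clustom:::graph_from_pairs(nodes,
                             vapply(edges, `[[`, "", 1),
                             vapply(edges, `[[`, "", 2),
                             criterion = "nw", threshold = 0.03)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exactly n_sub substitutions at distinct positions (forced to differ).
substitute_bases <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# Small planted community used by several tests.
two_species_community <- function(seed = 11, reads = 8, len = 200) {
  generate_community(community_spec(
    n_species = 2, ancestor_length = len, between_divergence = 0.15,
    within_divergence = 0.01, abundances = rep(reads, 2), seed = seed))
}
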