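test_that("k-mer graph connects exactly the pairs within beta", {
  seqs <- amplicon_tbl(
    c("a", "b", "c"),
    c(strrep("ACGT", 10),
      strrep("ACGT", 10),                       # identical to a
      paste0(strrep("ACGT", 5), strrep("TTTT", 5))))  # shares half with a/b
  g_tight <- build_kmer_graph(seqs, beta = 0, k = 4)
  expect_setequal(g_tight$adj[["a"]], "b")
  expect_equal(g_tight$adj[["c"]], character(0))
  g_loose <- build_kmer_graph(seqs, beta = 1, k = 4)
  expect_setequal(g_loose$adj[["a"]], c("b", "c"))
  expect_setequal(g_loose$adj[["b"]], c("a", "c"))
  expect_setequal(g_loose$adj[["c"]], c("a", "b"))
})

test_that("max-degree extraction handles simple hand-built graphs", {
  # path a - b - c: b has maximum degree, one cluster, no singletons
  path <- graph_from_edges(c("a", "b", "c"),
                           list(c("a", "b"), c("b", "c")))
  res <- initial_clustering(path)
  expect_equal(length(res$clusters), 1L)
  expect_equal(res$clusters[[1]]$seed_id, "b")
  expect_setequal(res$clusters[[1]]$member_ids, c("a", "b", "c"))
  expect_equal(res$singletons, character(0))

  # edgeless graph: everything is a singleton
  lone <- graph_from_edges(letters[1:5], list())
  res2 <- initial_clustering(lone)
  expect_equal(length(res2$clusters), 0L)
  expect_equal(res2$singletons, letters[1:5])

  # degree ties break to the lexicographically smallest id
  tie <- graph_from_edges(c("x", "y", "z", "w"),
                          list(c("x", "y"), c("z", "w")))
  res3 <- initial_clustering(tie)
  expect_equal(vapply(res3$clusters, `[[`, "", "seed_id"), c("w", "x"))
  expect_setequal(res3$clusters[[1]]$member_ids, c("w", "z"))
})

test_that("extraction and recovery walk a hub-and-singleton example", {
  # initial network: hub A over B..E, hub G over F/H/N, the pair K-L,
  # and isolated reads I, J, M
  nodes <- LETTERS[1:14]
  g <- graph_from_edges(nodes, list(
    c("A", "B"), c("A", "C"), c("A", "D"), c("A", "E"), c("B", "C"),
    c("G", "F"), c("G", "H"), c("G", "N"),
    c("K", "L")))
  initial <- initial_clustering(g)
  expect_equal(vapply(initial$clusters, `[[`, "", "seed_id"),
               c("A", "G", "K"))
  expect_setequal(initial$clusters[[1]]$member_ids,
                  c("A", "B", "C", "D", "E"))
  expect_setequal(initial$clusters[[2]]$member_ids, c("F", "G", "H", "N"))
  expect_equal(initial$singletons, c("I", "J", "M"))

  # refined network over seeds + singletons: J reaches A and I, so the
  # first final cluster is J, its neighbours, and A's initial members
  refined <- graph_from_edges(c("A", "G", "I", "J", "K", "M"),
                              list(c("J", "A"), c("J", "I")))
  cl <- recover_clusters(refined, initial, alpha = 0.03)
  top <- cl[cl$otu == "OTU1", ]
  expect_equal(unique(top$seed_id), "J")
  expect_setequal(top$id, c("A", "B", "C", "D", "E", "I", "J"))
  expect_setequal(cl$id[cl$otu == "OTU2"], c("F", "G", "H", "N"))
  expect_setequal(cl$id[cl$otu == "OTU3"], c("K", "L"))
  expect_equal(cl$id[cl$otu == "OTU4"], "M")
  expect_equal(nrow(cl), 14L)
})

test_that("greedy extraction matches a brute-force oracle on random graphs", {
  withr::local_seed(314)
  for (rep in 1:40) {
    n <- sample(4:18, 1)
    rg <- random_graph(n, p = stats::runif(1, 0.05, 0.6))
    got <- initial_clustering(rg$graph)
    want <- oracle_max_degree(rg$amat)
    expect_equal(length(got$clusters), length(want$clusters))
    for (i in seq_along(want$clusters)) {
      expect_equal(got$clusters[[i]]$seed_id, want$clusters[[i]]$seed_id)
      expect_equal(got$clusters[[i]]$member_ids,
                   want$clusters[[i]]$member_ids)
    }
    expect_equal(got$singletons, want$singletons)
  }
})

test_that("refinement connects seed/singleton pairs at the NW threshold", {
  com <- two_species_community(seed = 15, reads = 6, len = 150)
  fit <- clustom(com$seqs, alphas = 0.03, seed = 2)
  initial <- fit$initial
  nodes <- sort(c(vapply(initial$clusters, `[[`, "", "seed_id"),
                  initial$singletons), method = "radix")
  pd <- refine_pair_distances(nodes, com$seqs, nw_scoring())
  # exactly one alignment per node pair
  expect_equal(nrow(pd), n_pairs(length(nodes)))
  rg <- refine(initial, com$seqs, alpha = 0.03, nw_pairs = pd)
  expect_setequal(rg$nodes, nodes)
  for (i in seq_len(nrow(pd))) {
    connected <- pd$id_j[i] %in% rg$adj[[pd$id_i[i]]]
    expect_equal(connected, pd$nw_dist[i] <= 0.03)
  }
})

test_that("recovery always partitions the input and checks itself", {
  initial <- list(
    clusters = list(list(seed_id = "a", member_ids = c("a", "b"))),
    singletons = "c")
  rg <- graph_from_edges(c("a", "c"), list(c("a", "c")))
  cl <- recover_clusters(rg, initial, alpha = 0.03)
  expect_setequal(cl$id, c("a", "b", "c"))
  # a refined graph that drops the seed of an initial cluster loses that
  # cluster's members; the partition check must catch it
  bad_rg <- graph_from_edges(c("b", "c"), list(c("b", "c")))
  expect_error(recover_clusters(bad_rg, initial, alpha = 0.03),
               "partition")
})

test_that("the pipeline recovers a planted two-species partition", {
  com <- two_species_community(seed = 31, reads = 8, len = 250)
  fit <- clustom(com$seqs, alphas = 0.03, sample_size = 16, seed = 5)
  cl <- fit$clusterings[["0.03"]]
  expect_setequal(cl$id, com$seqs$id)
  joined <- dplyr::inner_join(tibble::as_tibble(cl), com$truth, by = "id")
  tab <- table(joined$otu, joined$label)
  expect_equal(sort(dim(tab)), c(2L, 2L))
  # each OTU maps to exactly one species and vice versa
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("identical reads collapse into a single OTU", {
  seqs <- amplicon_tbl(sprintf("r%02d", 1:8), rep(strrep("ACGTT", 30), 8))
  fit <- clustom(seqs, alphas = 0.03, sample_size = 8, seed = 1)
  cl <- fit$clusterings[["0.03"]]
  expect_equal(unique(cl$otu), "OTU1")
  expect_equal(nrow(cl), 8L)
})

test_that("mutually distant reads all stay singleton OTUs", {
  withr::local_seed(77)
  seqs <- amplicon_tbl(sprintf("u%d", 1:6),
                       vapply(1:6, function(i) random_seq(60), ""))
  fit <- suppressWarnings(
    clustom(seqs, alphas = 0.03, sample_size = 6, seed = 1))
  cl <- fit$clusterings[["0.03"]]
  expect_equal(length(unique(cl$otu)), 6L)
  expect_equal(cl$seed_id, cl$id)
})

test_that("a planted three-level hierarchy splits and merges with alpha", {
  # centroid a2 sits at exactly 16/400 = 4% substitution distance from
  # a1; centroid b is far from both. At a 3% threshold the three groups
  # must stay apart; at 5% the a1/a2 pair must merge.
  withr::local_seed(404)
  a1 <- random_seq(400)
  a2 <- substitute_bases(a1, 16)
  b <- substitute_bases(a1, 80)
  seqs <- amplicon_tbl(
    c(sprintf("a1_%d", 1:4), sprintf("a2_%d", 1:4), sprintf("b_%d", 1:4)),
    c(rep(a1, 4), rep(a2, 4), rep(b, 4)))

  # verify the construction really puts the centroid distances in the
  # intended bands before trusting the clustering outcome
  d12 <- nw_distance(nw_align(a1, a2))
  d1b <- nw_distance(nw_align(a1, b))
  d2b <- nw_distance(nw_align(a2, b))
  expect_equal(d12, 0.04)
  expect_gt(d1b, 0.10)
  expect_gt(d2b, 0.10)

  fit <- clustom(seqs, alphas = c(0.03, 0.05), sample_size = 12, seed = 9)
  cl3 <- fit$clusterings[["0.03"]]
  cl5 <- fit$clusterings[["0.05"]]
  expect_equal(length(unique(cl3$otu)), 3L)
  expect_equal(length(unique(cl5$otu)), 2L)
  # at 5% the merged OTU holds exactly the a1 and a2 reads
  merged <- cl5$id[cl5$otu == "OTU1"]
  expect_setequal(merged, c(sprintf("a1_%d", 1:4), sprintf("a2_%d", 1:4)))
})

test_that("every requested threshold yields a partition of the input", {
  withr::local_seed(55)
  for (s in c(101, 202, 303)) {
    com <- generate_community(community_spec(
      n_species = 3, ancestor_length = 120, abundances = c(4L, 6L, 2L),
      within_divergence = 0.02, seed = s))
    fit <- clustom(com$seqs, alphas = c(0.03, 0.07),
                   sample_size = 12, seed = s)
    for (cl in fit$clusterings) {
      expect_equal(sort(cl$id), sort(com$seqs$id))
      expect_false(anyDuplicated(cl$id) > 0)
      # each OTU's seed is one of its members
      by_otu <- split(cl$id, cl$otu)
      seeds <- vapply(split(cl$seed_id, cl$otu), `[`, "", 1)
      expect_true(all(mapply(`%in%`, seeds, by_otu)))
    }
  }
})

test_that("the pipeline is deterministic for fixed arguments", {
  com <- two_species_community(seed = 61, reads = 6, len = 150)
  f1 <- clustom(com$seqs, alphas = c(0.03, 0.05), sample_size = 10, seed = 7)
  f2 <- clustom(com$seqs, alphas = c(0.03, 0.05), sample_size = 10, seed = 7)
  expect_equal(f1$calibration$beta, f2$calibration$beta)
  for (nm in names(f1$clusterings)) {
    expect_identical(tibble::as_tibble(f1$clusterings[[nm]]),
                     tibble::as_tibble(f2$clusterings[[nm]]))
  }
})

test_that("thresholds outside the supported range are flagged", {
  com <- two_species_community(seed = 71, reads = 4, len = 100)
  w <- capture_warnings(clustom(com$seqs, alphas = 0.2,
                                sample_size = 8, seed = 1))
  expect_match(w, "outside the supported range", all = FALSE)
  expect_error(clustom(com$seqs, alphas = numeric(0)))
})

test_that("tidy, glance and OTU labelling expose the fit consistently", {
  com <- two_species_community(seed = 81, reads = 5, len = 150)
  fit <- clustom(com$seqs, alphas = c(0.03, 0.05), sample_size = 10, seed = 3)
  td <- tidy(fit)
  expect_setequal(names(td), c("alpha", "otu", "seed_id", "id"))
  expect_equal(nrow(td), 2 * nrow(com$seqs))
  gl <- glance(fit)
  expect_equal(gl$alpha, c(0.03, 0.05))
  expect_true(all(gl$n_otus >= 1))
  # OTU labels are ordered by decreasing size
  for (cl in fit$clusterings) {
    sizes <- table(cl$otu)[unique(cl$otu)]
    expect_true(all(diff(as.integer(sizes)) <= 0))
  }
})
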