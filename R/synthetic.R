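# Synthetic amplicon communities with planted cluster structure:
# homogeneous within species, divergent between species.

#' Specification of a synthetic amplicon community
#'
#' Describes a planted-partition read set: one random ancestor,
#' `n_species` centroids mutated away from it at the between-species
#' level, and reads mutated away from each centroid at the much smaller
#' within-species level. This emulates the premise the clustering
#' algorithm rests on -- 16S sequences homogeneous within species,
#' divergent between species -- with defaults sized like 454 amplicon
#' data (reads around 450 nt).
#'
#' @param n_species Number of planted species (default 3).
#' @param ancestor_length Ancestor length in nt (default 450).
#' @param between_divergence Expected substitutions/site from ancestor
#'   to each species centroid (default 0.15).
#' @param within_divergence Expected substitutions/site from centroid to
#'   each read (default 0.01).
#' @param abundances Integer reads per species, length `n_species`
#'   (default 50 each).
#' @param indel_rate Per-site insertion and deletion probability applied
#'   to reads (default 0).
#' @param max_truncation Maximum random 3' truncation in nt, mimicking
#'   variable 454 read lengths (default 0).
#' @param seed Integer RNG seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_species = 3, ancestor_length = 450,
                           between_divergence = 0.15,
                           within_divergence = 0.01,
                           abundances = rep(50L, n_species),
                           indel_rate = 0, max_truncation = 0, seed = 1) {
  stopifnot(n_species >= 1, ancestor_length >= 1,
            between_divergence >= 0, between_divergence <= 1,
            within_divergence >= 0, within_divergence <= 1,
            indel_rate >= 0, indel_rate < 1, max_truncation >= 0)
  if (length(abundances) != n_species) {
    stop("need one abundance per species", call. = FALSE)
  }
  if (any(abundances < 1)) stop("abundances must be positive", call. = FALSE)
  if (n_species > 1 && within_divergence >= between_divergence) {
    warning("within-species divergence >= between-species divergence: ",
            "planted clusters will not be separable", call. = FALSE)
  }
  structure(list(n_species = n_species,
                 ancestor_length = as.integer(ancestor_length),
                 between_divergence = between_divergence,
                 within_divergence = within_divergence,
                 abundances = as.integer(abundances),
                 indel_rate = indel_rate,
                 max_truncation = as.integer(max_truncation),
                 seed = as.integer(seed)),
            class = "community_spec")
}

# substitute each site independently with probability p, drawing
# uniformly among the three alternative bases (Jukes-Cantor-like)
mutate_bases <- function(bases, p) {
  if (p <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < p)
  for (ix in hit) {
    bases[ix] <- sample(setdiff(c("A", "C", "G", "T"), bases[ix]), 1)
  }
  bases
}

apply_indels <- function(bases, rate) {
  if (rate <= 0) return(bases)
  keep <- stats::runif(length(bases)) >= rate
  bases <- bases[keep]
  ins <- which(stats::runif(length(bases)) < rate)
  if (length(ins) > 0) {
    pieces <- as.list(bases)
    for (ix in ins) {
      pieces[[ix]] <- c(pieces[[ix]], sample(c("A", "C", "G", "T"), 1))
    }
    bases <- unlist(pieces)
  }
  bases
}

#' Generate a synthetic community with known species labels
#'
#' Draws the ancestor, centroids and reads described by a
#' [community_spec()]. Read
#' ids are assigned after shuffling, so they encode nothing about the
#' planted species; the ground truth comes back as a separate tibble.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec A [community_spec()].
#' @return List with `seqs` (sequence tibble) and `truth` (tibble `id`,
#'   `label` with labels `sp1`, `sp2`, ...).
#' @examples
#' com <- generate_community(community_spec(
#'   n_species = 2, ancestor_length = 100, abundances = c(4, 4), seed = 7))
#' table(com$truth$label)
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    ancestor <- sample(c("A", "C", "G", "T"), spec$ancestor_length,
                       replace = TRUE)
    centroids <- lapply(seq_len(spec$n_species), function(s) {
      mutate_bases(ancestor, spec$between_divergence)
    })
    labels <- rep(paste0("sp", seq_len(spec$n_species)), spec$abundances)
    reads <- unlist(lapply(seq_len(spec$n_species), function(s) {
      vapply(seq_len(spec$abundances[s]), function(r) {
        b <- mutate_bases(centroids[[s]], spec$within_divergence)
        b <- apply_indels(b, spec$indel_rate)
        if (spec$max_truncation > 0) {
          cut <- sample.int(spec$max_truncation + 1, 1) - 1
          if (cut > 0 && cut < length(b)) b <- b[seq_len(length(b) - cut)]
        }
        paste(b, collapse = "")
      }, "")
    }))
    ord <- sample.int(length(reads))
    ids <- sprintf("read_%04d", seq_along(reads))
    seqs <- amplicon_tbl(ids, reads[ord])
    truth <- tibble::tibble(id = ids, label = labels[ord])
  })
  list(seqs = seqs, truth = truth)
}

#' The printed three-OTU toy confusion instance
#'
#' An abstract 40-sequence example used to illustrate the
#' taxonomy-based scoring: species A, B and C (15, 8 and 17 sequences)
#' spread over three OTUs as OTU1 = (10, 5, 2), OTU2 = (2, 1, 10),
#' OTU3 = (3, 2, 5). Labels and assignments only -- no bases are needed
#' to exercise [assign_representatives()] and [taxon_confusion()].
#'
#' @return List with `clustering` (an `otu_clustering`) and `taxonomy`
#'   (tibble `id`, `label`).
#' @export
generate_toy_confusion <- function() {
  layout <- list(OTU1 = c(A = 10, B = 5, C = 2),
                 OTU2 = c(A = 2, B = 1, C = 10),
                 OTU3 = c(A = 3, B = 2, C = 5))
  counter <- c(A = 0L, B = 0L, C = 0L)
  rows <- list()
  for (otu in names(layout)) {
    for (sp in names(layout[[otu]])) {
      n <- layout[[otu]][[sp]]
      ids <- sprintf("%s%02d", sp, counter[[sp]] + seq_len(n))
      counter[[sp]] <- counter[[sp]] + n
      rows[[length(rows) + 1]] <- tibble::tibble(otu = otu, id = ids,
                                                 label = sp)
    }
  }
  flat <- dplyr::bind_rows(rows)
  clusters <- lapply(split(flat$id, flat$otu), function(ids) {
    list(seed_id = lex_min(ids), member_ids = lex_sort(ids))
  })
  clustering <- new_otu_clustering(unname(clusters), alpha = NA_real_,
                                   provenance = list(source = "toy"))
  list(clustering = clustering,
       taxonomy = flat[c("id", "label")])
}
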