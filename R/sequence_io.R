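# FASTA input, validation, and the three OTU output files.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Build a validated amplicon sequence table
#'
#' Normalises raw sequences into the tibble used throughout the package:
#' one row per read with columns `id`, `seq` and `length`. Bases are
#' uppercased and `U` is mapped to `T` so RNA-style input shares one
#' alphabet with DNA; IUPAC ambiguity codes are accepted (see
#' [kmer_profile()] for how they are treated in distances).
#'
#' @param ids Character vector of unique, non-empty sequence ids.
#' @param seqs Character vector of bases, same length as `ids`.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @examples
#' amplicon_tbl(c("s1", "s2"), c("acgu", "ACGT"))
#' @export
amplicon_tbl <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  stopifnot(length(ids) == length(seqs))
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop("sequence ids must be non-empty", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  seqs <- gsub("[[:space:]]", "", toupper(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (length(seqs) == 0) stop("no sequences", call. = FALSE)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(head(ids[!nzchar(seqs)], 5), collapse = ", "), call. = FALSE)
  }
  bad_chr <- gsub(paste0("[", paste(IUPAC_CODES, collapse = ""), "]"), "", seqs)
  if (any(nzchar(bad_chr))) {
    w <- which(nzchar(bad_chr))[1]
    stop("sequence '", ids[w], "' contains non-IUPAC character '",
         substr(bad_chr[w], 1, 1), "'", call. = FALSE)
  }
  tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Read amplicon reads from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file and returns the validated
#' sequence tibble. The id is the header token up to the first
#' whitespace. Sequences are uppercased with `U` mapped to `T`; duplicate
#' ids and characters outside the IUPAC nucleotide alphabet are errors.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`, in file order.
#' @seealso [write_otu_files()]
#' @export
read_amplicon_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  amplicon_tbl(ids, as.character(set))
}

#' Write the three OTU output files
#'
#' Writes the clustering result in the tool's standard layout:
#' `membership.tsv` (`otu` TAB `id`, one line per sequence),
#' `representatives.fasta` (seed sequence per OTU, headers
#' `otu|seed_id`), and `abundance.tsv` (`otu` TAB `count`). OTUs are
#' already labelled by decreasing size with ties broken by the
#' lexicographically smallest seed id.
#'
#' @param clustering An `otu_clustering` tibble (see [clustom()]).
#' @param seqs The sequence tibble the clustering was computed from.
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_otu_files <- function(clustering, seqs, out_dir) {
  stopifnot(inherits(clustering, "otu_clustering"))
  unknown <- setdiff(clustering$id, seqs$id)
  if (length(unknown) > 0) {
    stop("clustering references unknown id(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    membership = file.path(out_dir, "membership.tsv"),
    representatives = file.path(out_dir, "representatives.fasta"),
    abundance = file.path(out_dir, "abundance.tsv")
  )

  memb <- dplyr::arrange(tibble::as_tibble(clustering)[c("otu", "id")],
                         .data$otu, .data$id)
  utils::write.table(memb, paths[["membership"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  reps <- dplyr::distinct(tibble::as_tibble(clustering)[c("otu", "seed_id")])
  reps <- reps[order(otu_rank(reps$otu)), ]
  rep_seq <- seqs$seq[match(reps$seed_id, seqs$id)]
  set <- Biostrings::BStringSet(setNames(rep_seq,
                                         paste0(reps$otu, "|", reps$seed_id)))
  Biostrings::writeXStringSet(set, paths[["representatives"]])

  ab <- dplyr::count(tibble::as_tibble(clustering), .data$otu, name = "count")
  ab <- ab[order(otu_rank(ab$otu)), ]
  utils::write.table(ab, paths[["abundance"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  invisible(paths)
}

# numeric rank of labels "OTU1", "OTU2", ... for stable file ordering
otu_rank <- function(otu) as.integer(sub("^OTU", "", otu))
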