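# broom-style accessors and plots for fitted objects.

#' Tidy a clustering result
#'
#' @param x A `clustom_result` from [clustom()].
#' @param ... Unused.
#' @return A tibble with one row per (alpha, sequence): `alpha`, `otu`,
#'   `seed_id`, `id`.
#' @export
tidy.clustom_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$params$alphas, function(a) {
    cl <- x$clusterings[[format(a, trim = TRUE)]]
    dplyr::mutate(tibble::as_tibble(cl), alpha = a, .before = 1)
  }))
}

#' One-row-per-threshold summary of a clustering result
#'
#' @inheritParams tidy.clustom_result
#' @return A tibble with `alpha`, `n_otus`, `n_singleton_otus`,
#'   `largest_otu`, `beta`, `n_seeds`, `n_singletons`, `r2`.
#' @export
glance.clustom_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$params$alphas, function(a) {
    cl <- x$clusterings[[format(a, trim = TRUE)]]
    sizes <- table(cl$otu)
    tibble::tibble(alpha = a,
                   n_otus = length(sizes),
                   n_singleton_otus = sum(sizes == 1),
                   largest_otu = max(sizes),
                   beta = x$calibration$beta,
                   n_seeds = length(x$initial$clusters),
                   n_singletons = length(x$initial$singletons),
                   r2 = x$calibration$r2)
  }))
}

#' @rdname tidy.clustom_result
#' @export
tidy.otu_clustering <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a single clustering
#'
#' @param x An `otu_clustering`.
#' @param ... Unused.
#' @return A tibble with `alpha`, `n_otus`, `n_singleton_otus`,
#'   `largest_otu`, `n`.
#' @export
glance.otu_clustering <- function(x, ...) {
  sizes <- table(x$otu)
  tibble::tibble(alpha = attr(x, "alpha"),
                 n_otus = length(sizes),
                 n_singleton_otus = sum(sizes == 1),
                 largest_otu = max(sizes),
                 n = nrow(x))
}

#' Tidy a calibration result
#'
#' @param x A `clustom_calibration` from [calibrate()].
#' @param ... Unused.
#' @return The sampled pair table: `id_i`, `id_j`, `kmer_dist`,
#'   `nw_dist`, plus the pair's confusion `category` at (alpha, beta).
#' @export
tidy.clustom_calibration <- function(x, ...) {
  p <- x$pairs
  d_ok <- p$nw_dist <= x$alpha
  k_ok <- p$kmer_dist <= x$beta
  p$category <- dplyr::case_when(d_ok & k_ok ~ "TP", !d_ok & k_ok ~ "FP",
                                 d_ok & !k_ok ~ "FN", TRUE ~ "TN")
  p
}

#' @rdname tidy.clustom_calibration
#' @return For `glance()`: one row with `alpha`, `beta`, `TP`, `FP`,
#'   `FN`, `TN`, `r2`, `n_sample`, `n_pairs`, `seed`.
#' @export
glance.clustom_calibration <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(alpha = x$alpha, beta = x$beta),
                   x$confusion,
                   tibble::tibble(r2 = x$r2,
                                  n_sample = length(x$sample_ids),
                                  n_pairs = nrow(x$pairs),
                                  seed = x$seed))
}

#' Plot the calibration scatter
#'
#' k-mer distance against NW distance for every sampled pair, with the
#' alpha and beta thresholds; the lower-right quadrant (k-mer below
#' beta, NW above alpha) is empty by construction.
#'
#' @param object A `clustom_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clustom_calibration <- function(object, ...) {
  p <- tidy(object)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$nw_dist, y = .data$kmer_dist,
                                  colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$beta, linetype = "dashed") +
    ggplot2::labs(x = "NW distance", y = "k-mer distance",
                  colour = NULL,
                  title = sprintf("Calibration: alpha = %g, beta = %.4g",
                                  object$alpha, object$beta)) +
    ggplot2::theme_minimal()
}

#' Plot OTU size distributions per threshold
#'
#' Number of OTUs per OTU size (sequences per cluster), one panel per
#' requested threshold -- the standard way to compare how granular the
#' clusterings are.
#'
#' @param object A `clustom_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clustom_result <- function(object, ...) {
  sizes <- dplyr::count(tidy(object), .data$alpha, .data$otu,
                        name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~alpha, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "OTU size (sequences)", y = "number of OTUs") +
    ggplot2::theme_minimal()
}
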