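#' Similarity of a library to a reference compound
#'
#' Computes the Tanimoto coefficient of every library member against a
#' reference molecule's 2D fingerprint and bins the coefficients. Bins are
#' left-open/right-closed intervals `(lower, upper]`, so every coefficient
#' falls in exactly one bin and the bin counts partition the library.
#'
#' @param library Molecule tibble (fingerprints computed with
#'   [compute_fingerprint()] if absent).
#' @param reference A one-row molecule tibble (or the id of a library member).
#' @param bin_edges Increasing numeric vector of bin edges spanning `[0, 1]`;
#'   the first bin additionally includes its lower edge so 0 is covered.
#' @return A `similarity_report`: list with `reference` (id), `ligands`
#'   (tibble `id`, `coefficient`), and `bins` (tibble `lower`, `upper`,
#'   `count`, `fraction`).
#' @export
similarity_report <- function(library, reference,
                              bin_edges = c(0, 0.4, 0.5, 0.7, 0.8, 0.9, 1.0)) {
  if (nrow(library) == 0) stop("empty library", call. = FALSE)
  if (is.character(reference)) {
    ref_row <- library[library$id == reference, ]
    if (nrow(ref_row) != 1) stop("reference id not found in library", call. = FALSE)
    reference <- ref_row
  }
  if (!"fingerprint" %in% names(library)) {
    library <- compute_fingerprint(library)
  }
  if (!"fingerprint" %in% names(reference)) {
    reference <- compute_fingerprint(reference)
  }
  ref_fp <- reference$fingerprint[[1]]
  coef <- vapply(library$fingerprint, tanimoto, 0, b = ref_fp)
  ligands <- tibble::tibble(id = library$id, coefficient = coef) |>
    dplyr::arrange(dplyr::desc(.data$coefficient), .data$id)
  bins <- bin_coefficients(coef, bin_edges)
  structure(
    list(reference = reference$id[[1]], ligands = ligands, bins = bins),
    class = "similarity_report"
  )
}

# Left-open bins (lower, upper]; the first bin is closed on both ends.
bin_coefficients <- function(coef, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  idx <- findInterval(coef, bin_edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[coef <= bin_edges[1] + 1e-12] <- 1L  # include the lower boundary
  nb <- length(bin_edges) - 1L
  if (any(idx < 1 | idx > nb)) {
    stop("coefficients fall outside the bin edges", call. = FALSE)
  }
  count <- tabulate(idx, nbins = nb)
  tibble::tibble(
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1],
    count = count,
    fraction = count / length(coef)
  )
}

#' Fraction of ligands above a similarity threshold
#'
#' @param report A `similarity_report`, or a bin-count tibble with columns
#'   `lower`, `upper`, `count` (in which case `threshold` must coincide with a
#'   bin edge).
#' @param threshold Tanimoto coefficient cutoff (exclusive).
#' @return Percentage (0-100) of ligands with coefficient strictly above
#'   `threshold`.
#' @export
fraction_above <- function(report, threshold = 0.7) {
  if (inherits(report, "similarity_report")) {
    return(100 * mean(report$ligands$coefficient > threshold))
  }
  bins <- report
  if (!all(c("lower", "upper", "count") %in% names(bins))) {
    stop("need a similarity_report or a lower/upper/count bin table", call. = FALSE)
  }
  if (!any(abs(bins$lower - threshold) < 1e-9)) {
    stop("threshold must fall on a bin edge when only counts are given",
      call. = FALSE
    )
  }
  100 * sum(bins$count[bins$lower >= threshold - 1e-9]) / sum(bins$count)
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> reference:", x$reference,
      "|", nrow(x$ligands), "ligands\n")
  print(x$bins)
  invisible(x)
}
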