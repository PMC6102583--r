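#' Compute 2D fingerprints
#'
#' Hashed path-based binary fingerprints (OpenBabel FP2, 1024 bits) computed
#' from the molecular graph. Deterministic: identical structures give
#' identical bit vectors. The scheme is configurable via `type`.
#'
#' @param molecules Molecule tibble with an `sdf` column.
#' @param type OpenBabel fingerprint name (default `"FP2"`).
#' @return The tibble with a `fingerprint` list-column of logical bit vectors
#'   (equal length across the table).
#' @export
compute_fingerprint <- function(molecules, type = "FP2") {
  has_sdf <- !purrr::map_lgl(molecules$sdf, is.null)
  if (!all(has_sdf)) {
    stop("fingerprints need parsed structures; molecules without chemistry: ",
      paste(molecules$id[!has_sdf], collapse = ", "),
      call. = FALSE
    )
  }
  sdfset <- methods::new("SDFset", SDF = molecules$sdf, ID = molecules$id)
  fp <- ChemmineR::fingerprintOB(sdfset, type)
  m <- fp@fpma
  molecules$fingerprint <- lapply(seq_len(nrow(m)), function(i) m[i, ] > 0)
  molecules
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`, the standard 2D-similarity measure, in `[0, 1]`.
#' Two all-zero fingerprints are defined to have similarity 0 (with a
#' warning), since the ratio is 0/0.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 shared / 4 union = 0.5
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("fingerprint lengths differ (", length(a), " vs ", length(b), ")",
      call. = FALSE
    )
  }
  un <- sum(a | b)
  if (un == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0", call. = FALSE)
    return(0)
  }
  sum(a & b) / un
}
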