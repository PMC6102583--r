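#' Hypothesis-evaluation indices from a labeled screen
#'
#' Given active/inactive labels for a test set and the set of ids a
#' pharmacophore hypothesis retrieved, computes the confusion counts and the
#' three screening-enrichment indices:
#' \describe{
#'   \item{HRA}{hit rate of actives, `100 * Ha / A` (percent) -- the fraction
#'     of actives retrieved.}
#'   \item{IEI}{identify effective index, `(Ha / Ht) / (A / D)` -- enrichment
#'     of actives among the hits relative to the test-set base rate
#'     (1 for a random classifier).}
#'   \item{CAI}{comprehensive appraisal index, `(HRA / 100) * IEI`.}
#' }
#' `D` is the test-set size, `A` the number of actives, `Ht` the number of
#' hits, `Ha` the number of active hits.
#'
#' @param labels Tibble with columns `id` and `label`
#'   (`"active"`/`"inactive"`).
#' @param hits Character vector of hit ids (or a tibble with an `id` column).
#'   Every hit must be labeled.
#' @return One-row tibble: `D`, `A`, `Ha`, `Ht`, `HRA`, `IEI`, `CAI`,
#'   `undefined` (TRUE when `Ht = 0`, in which case IEI and CAI are `NA`).
#'   Indices are kept at full precision; round only for presentation.
#' @examples
#' labels <- tibble::tibble(
#'   id = as.character(1:10),
#'   label = rep(c("active", "inactive"), each = 5)
#' )
#' evaluate_model(labels, as.character(1:5))  # HRA 100, IEI 2
#' @export
evaluate_model <- function(labels, hits) {
  if (is.data.frame(hits)) hits <- hits$id
  hits <- unique(as.character(hits))
  stray <- setdiff(hits, labels$id)
  if (length(stray) > 0) {
    stop("hit id(s) not in the labeled set: ",
      paste(utils::head(stray, 5), collapse = ", "),
      call. = FALSE
    )
  }
  is_active <- labels$label == "active"
  A <- sum(is_active)
  if (A < 1) stop("test set has no active compounds", call. = FALSE)
  D <- nrow(labels)
  Ht <- length(hits)
  Ha <- sum(labels$id[is_active] %in% hits)
  validation_from_counts(D, A, Ha, Ht)
}

#' Indices from confusion counts
#'
#' Vectorized computation of HRA, IEI and CAI directly from counts; see
#' [evaluate_model()] for definitions.
#'
#' @param D,A,Ha,Ht Integer vectors (recycled): test-set size, actives, active
#'   hits, total hits.
#' @return Tibble with one row per input row.
#' @export
validation_from_counts <- function(D, A, Ha, Ht) {
  n <- max(length(D), length(A), length(Ha), length(Ht))
  D <- rep_len(D, n); A <- rep_len(A, n)
  Ha <- rep_len(Ha, n); Ht <- rep_len(Ht, n)
  if (any(Ha > pmin(A, Ht)) || any(Ht > D) || any(A > D) ||
    any(c(D, A, Ha, Ht) < 0)) {
    stop("infeasible counts: need 0 <= Ha <= min(A, Ht), Ht <= D, A <= D",
      call. = FALSE
    )
  }
  HRA <- 100 * Ha / A
  IEI <- ifelse(Ht > 0, (Ha / Ht) / (A / D), NA_real_)
  tibble::tibble(
    D = D, A = A, Ha = Ha, Ht = Ht,
    HRA = HRA, IEI = IEI, CAI = (HRA / 100) * IEI,
    undefined = Ht == 0
  )
}

#' Recompute a validation table
#'
#' Applies [validation_from_counts()] to a table of per-hypothesis counts, as
#' when re-deriving the printed validation table of a set of hypotheses from
#' its counts.
#'
#' @param rows Tibble with columns `D`, `A`, `Ha`, `Ht` (extra columns such as
#'   `Hypo` or `rank_score` are carried through).
#' @return Input columns plus `HRA`, `IEI`, `CAI`, `undefined`.
#' @export
recompute_table <- function(rows) {
  stats <- validation_from_counts(rows$D, rows$A, rows$Ha, rows$Ht)
  dplyr::bind_cols(
    rows[, setdiff(names(rows), names(stats)), drop = FALSE],
    stats
  )
}

#' Select the best hypothesis
#'
#' Among hypotheses whose HRA, IEI and CAI all meet the quality thresholds
#' (conventionally 80%, 2 and 2), returns the one with the highest rank
#' score. If none meets all thresholds, falls back to the highest CAI with a
#' warning. Ties break by row order.
#'
#' @param stats Tibble with columns `HRA`, `IEI`, `CAI` and `rank_score`.
#' @param thresholds Named vector `c(HRA = , IEI = , CAI = )`.
#' @return Integer row index of the chosen hypothesis, with attribute
#'   `meets_thresholds`.
#' @export
select_best <- function(stats, thresholds = c(HRA = 80, IEI = 2, CAI = 2)) {
  if (nrow(stats) == 0) stop("no hypotheses to select from", call. = FALSE)
  ok <- stats$HRA >= thresholds[["HRA"]] &
    stats$IEI >= thresholds[["IEI"]] &
    stats$CAI >= thresholds[["CAI"]]
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    idx <- which(ok)[which.max(stats$rank_score[ok])]
    meets <- TRUE
  } else {
    warning("no hypothesis meets all thresholds; falling back to highest CAI",
      call. = FALSE
    )
    idx <- which.max(stats$CAI)
    meets <- FALSE
  }
  structure(as.integer(idx), meets_thresholds = meets)
}
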