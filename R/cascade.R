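#' Read / write docking tables
#'
#' Tab-separated docking results: columns `id`, `score_energy`,
#' `score_interaction` (both unitless, higher is better) and `interactions`,
#' a semicolon-separated list of `RESIDUE:kind` tokens (kind `hydrophobic` or
#' `hbond`), e.g. `PHE54:hydrophobic;SER51:hbond`.
#'
#' @param path File path.
#' @return `read_docking_table()` returns a tibble with an `interactions`
#'   list-column of tibbles (`residue`, `kind`).
#' @export
read_docking_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    score_energy = readr::col_double(),
    score_interaction = readr::col_double(),
    interactions = readr::col_character()
  ))
  raw$interactions <- purrr::map(raw$interactions, parse_interactions)
  raw
}

#' @rdname read_docking_table
#' @param records Docking tibble.
#' @export
write_docking_table <- function(records, path) {
  out <- records
  out$interactions <- purrr::map_chr(records$interactions, function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return("")
    }
    paste0(x$residue, ":", x$kind, collapse = ";")
  })
  readr::write_tsv(out, path)
  invisible(path)
}

parse_interactions <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble::tibble(residue = character(), kind = character()))
  }
  tok <- strsplit(strsplit(s, ";")[[1]], ":")
  tb <- tibble::tibble(
    residue = vapply(tok, `[[`, "", 1),
    kind = vapply(tok, `[[`, "", 2)
  )
  bad <- !grepl("^[A-Z]{3}[0-9]+$", tb$residue)
  if (any(bad)) {
    stop("malformed residue label(s): ", paste(tb$residue[bad], collapse = ", "),
      call. = FALSE
    )
  }
  tb
}

#' Docking-score threshold filter
#'
#' Keeps the records whose scores reach a stated fraction (conventionally
#' 80%) of a reference ligand's scores. By default both score columns must
#' pass; `mode = "either"` relaxes this to one.
#'
#' @param records Docking tibble (`id`, `score_energy`, `score_interaction`,
#'   optional `interactions`).
#' @param reference One-row docking record, or a named vector with
#'   `score_energy` and `score_interaction`.
#' @param fraction Fraction of the reference scores used as thresholds
#'   (`0 < fraction <= 1`, default 0.8).
#' @param mode `"both"` (default) or `"either"`.
#' @return The surviving rows of `records`.
#' @examples
#' recs <- tibble::tibble(
#'   id = "cand", score_energy = 42.08, score_interaction = 52.92
#' )
#' docking_threshold_filter(
#'   recs, c(score_energy = 51.30, score_interaction = 61.78)
#' )
#' @export
docking_threshold_filter <- function(records, reference, fraction = 0.8,
                                     mode = c("both", "either")) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction <= 1)
  if (is.data.frame(reference)) {
    reference <- c(
      score_energy = reference$score_energy[[1]],
      score_interaction = reference$score_interaction[[1]]
    )
  }
  if (!all(is.finite(reference[c("score_energy", "score_interaction")]))) {
    stop("reference scores must be finite", call. = FALSE)
  }
  te <- fraction * reference[["score_energy"]]
  ti <- fraction * reference[["score_interaction"]]
  pass_e <- records$score_energy >= te
  pass_i <- records$score_interaction >= ti
  keep <- if (mode == "both") pass_e & pass_i else pass_e | pass_i
  records[keep & !is.na(keep), , drop = FALSE]
}

#' Residue interaction frequency
#'
#' Counts, for each residue, how many docking records (compounds, not raw
#' interaction events) form an interaction of the requested kind with it --
#' the quantity plotted in a key-residue frequency column diagram.
#'
#' @param records Docking tibble with an `interactions` list-column.
#' @param kind Optional filter: `"hydrophobic"` or `"hbond"` (default: all).
#' @return Tibble (`residue`, `count`), count descending then residue.
#' @export
interaction_frequency <- function(records, kind = NULL) {
  per_record <- purrr::map(records$interactions, function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return(character())
    }
    if (!is.null(kind)) x <- x[x$kind == kind, , drop = FALSE]
    unique(x$residue)
  })
  res <- unlist(per_record)
  if (length(res) == 0) {
    return(tibble::tibble(residue = character(), count = integer()))
  }
  tibble::tibble(residue = res) |>
    dplyr::count(.data$residue, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$residue)
}

#' Key-residue interaction overlap
#'
#' Intersection of each record's interacting residues (optionally filtered by
#' interaction kind) with a reference set of key binding residues.
#'
#' @param records Docking tibble with an `interactions` list-column.
#' @param key_residues Non-empty character vector of residue labels (e.g.
#'   `c("PHE54", "VAL179", "LEU183", "LEU211", "PRO292")`).
#' @param kind Optional interaction-kind filter.
#' @return Tibble (`id`, `overlap` list-column, `n_overlap`).
#' @export
key_residue_overlap <- function(records, key_residues, kind = NULL) {
  if (length(key_residues) == 0) stop("key residue set is empty", call. = FALSE)
  ov <- purrr::map(records$interactions, function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return(character())
    }
    if (!is.null(kind)) x <- x[x$kind == kind, , drop = FALSE]
    sort(intersect(unique(x$residue), key_residues))
  })
  tibble::tibble(
    id = records$id,
    overlap = ov,
    n_overlap = lengths(ov)
  )
}

#' Cascade configuration
#'
#' Stage toggles and thresholds for [run_cascade()].
#'
#' @param lipinski,pharmacophore,docking,overlap Logical stage toggles.
#' @param fraction Docking-score fraction threshold (default 0.8).
#' @param score_mode `"both"` or `"either"` (see
#'   [docking_threshold_filter()]).
#' @param min_overlap Minimum key-residue overlap count (default 3).
#' @param kind Interaction-kind filter for the overlap stage (default
#'   `"hydrophobic"`).
#' @param allow_omit Features the pharmacophore stage may omit (default 0).
#' @param max_violations Lipinski violations tolerated (default 0).
#' @return A named list of class `cascade_config`.
#' @export
cascade_config <- function(lipinski = TRUE, pharmacophore = TRUE,
                           docking = TRUE, overlap = TRUE,
                           fraction = 0.8, score_mode = "both",
                           min_overlap = 3, kind = "hydrophobic",
                           allow_omit = 0, max_violations = 0) {
  structure(
    list(
      lipinski = lipinski, pharmacophore = pharmacophore, docking = docking,
      overlap = overlap, fraction = fraction, score_mode = score_mode,
      min_overlap = min_overlap, kind = kind, allow_omit = allow_omit,
      max_violations = max_violations
    ),
    class = "cascade_config"
  )
}

#' Run the consensus screening cascade
#'
#' Applies, in order: Lipinski drug-likeness filter, pharmacophore screen,
#' docking-score threshold relative to the reference ligand, and minimum
#' key-residue interaction overlap. Survivor sets are nested by construction;
#' each stage only removes compounds. Pharmacophore hits lacking a docking
#' record are dropped at the docking stage with a warning.
#'
#' @param molecules Molecule tibble (the library).
#' @param model A `phore_model` (required when the pharmacophore stage is on).
#' @param docking Docking tibble keyed by `id` (required when the docking or
#'   overlap stage is on).
#' @param reference Reference docking record for the threshold stage.
#' @param key_residues Key binding residues for the overlap stage.
#' @param config A [cascade_config()].
#' @return A `cascade_result`: list with `stages` (tibble `stage`, `n`,
#'   `survivors` list-column) and `candidates` (final ranked tibble: id,
#'   fitvalue, scores, `n_overlap`; ranked by overlap count, then
#'   `score_energy`, then fitvalue, descending, ties by id).
#' @export
run_cascade <- function(molecules, model = NULL, docking = NULL,
                        reference = NULL, key_residues = NULL,
                        config = cascade_config()) {
  if (nrow(molecules) == 0) stop("empty library", call. = FALSE)
  survivors <- molecules$id
  stages <- tibble::tibble(
    stage = "library", n = length(survivors), survivors = list(survivors)
  )
  add_stage <- function(name, ids) {
    stages <<- dplyr::bind_rows(
      stages,
      tibble::tibble(stage = name, n = length(ids), survivors = list(ids))
    )
  }
  hit_info <- NULL

  if (isTRUE(config$lipinski)) {
    lp <- lipinski_pass(molecules, max_violations = config$max_violations)
    survivors <- intersect(survivors, lp$id[lp$lipinski_pass])
    add_stage("lipinski", survivors)
  }
  if (isTRUE(config$pharmacophore)) {
    if (is.null(model)) stop("pharmacophore stage needs a model", call. = FALSE)
    hits <- screen_library(
      molecules[molecules$id %in% survivors, ],
      model,
      allow_omit = config$allow_omit
    )
    hit_info <- hits
    survivors <- intersect(survivors, hits$id)
    add_stage("pharmacophore", survivors)
  }
  if (isTRUE(config$docking)) {
    if (is.null(docking) || is.null(reference)) {
      stop("docking stage needs docking records and a reference", call. = FALSE)
    }
    missing <- setdiff(survivors, docking$id)
    if (length(missing) > 0) {
      warning(length(missing), " survivor(s) lack docking records; dropped",
        call. = FALSE
      )
    }
    dk <- docking[docking$id %in% survivors, , drop = FALSE]
    kept <- docking_threshold_filter(dk, reference,
      fraction = config$fraction, mode = config$score_mode
    )
    survivors <- intersect(survivors, kept$id)
    add_stage("docking", survivors)
  }
  if (isTRUE(config$overlap)) {
    if (is.null(docking) || is.null(key_residues)) {
      stop("overlap stage needs docking records and key residues", call. = FALSE)
    }
    dk <- docking[docking$id %in% survivors, , drop = FALSE]
    ov <- key_residue_overlap(dk, key_residues, kind = config$kind)
    survivors <- intersect(survivors, ov$id[ov$n_overlap >= config$min_overlap])
    add_stage("key_residues", survivors)
  }

  candidates <- tibble::tibble(id = survivors)
  if (!is.null(hit_info)) {
    candidates <- dplyr::left_join(
      candidates, hit_info[, c("id", "fitvalue")],
      by = "id"
    )
  } else {
    candidates$fitvalue <- NA_real_
  }
  if (!is.null(docking)) {
    candidates <- dplyr::left_join(
      candidates,
      docking[, c("id", "score_energy", "score_interaction")],
      by = "id"
    )
  } else {
    candidates$score_energy <- NA_real_
    candidates$score_interaction <- NA_real_
  }
  if (!is.null(docking) && !is.null(key_residues)) {
    dk <- docking[docking$id %in% survivors, , drop = FALSE]
    candidates <- dplyr::left_join(
      candidates,
      key_residue_overlap(dk, key_residues, kind = config$kind)[
        , c("id", "n_overlap")
      ],
      by = "id"
    )
  } else {
    candidates$n_overlap <- NA_integer_
  }
  candidates <- dplyr::arrange(
    candidates,
    dplyr::desc(dplyr::coalesce(.data$n_overlap, -1L)),
    dplyr::desc(dplyr::coalesce(.data$score_energy, -Inf)),
    dplyr::desc(dplyr::coalesce(.data$fitvalue, -Inf)),
    .data$id
  )
  structure(
    list(stages = stages, candidates = candidates, config = config),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  print(x$stages[, c("stage", "n")])
  cat("final candidates:", nrow(x$candidates), "\n")
  invisible(x)
}
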