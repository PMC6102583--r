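#' Reverse target profiling of one ligand
#'
#' Screens a single ligand's conformer ensemble against a database of
#' pharmacophore models (one per putative target) and reports, per model,
#' whether the ligand maps and the best fitvalue. A ligand counts as mapped
#' when the geometric constraints (tolerances and excluded volumes) are
#' satisfied; no fitvalue cutoff is applied.
#'
#' @param molecule One-row molecule tibble. If it has no conformer ensemble
#'   yet and carries chemistry, conformers are generated with
#'   [generate_conformers()] (flexible-search settings: up to `max_conf`
#'   conformers within `energy_window` kcal/mol).
#' @param models List of `phore_model` objects, or a directory of model YAML
#'   files (read with [read_phore_model()]).
#' @param allow_omit Model features that may be omitted (default 0).
#' @param max_conf,energy_window,seed Conformer-generation settings
#'   (defaults 255, 20, 1).
#' @return A `profile_report` tibble: `ligand`, `model`, `mapped`,
#'   `fitvalue` (NA when unmapped), one row per model in database order.
#' @export
profile_ligand <- function(molecule, models, allow_omit = 0,
                           max_conf = 255, energy_window = 20, seed = 1) {
  if (is.character(models)) {
    paths <- sort(list.files(models, pattern = "\\.ya?ml$", full.names = TRUE))
    if (length(paths) == 0) stop("no model YAML files in ", models, call. = FALSE)
    models <- lapply(paths, read_phore_model)
  }
  if (length(models) == 0) stop("empty model database", call. = FALSE)
  if (nrow(molecule) != 1) stop("profile one ligand at a time", call. = FALSE)
  conf_err <- NULL
  if (is.null(molecule$features[[1]]) && length(molecule$conformers[[1]]) <= 1) {
    gen <- tryCatch(
      generate_conformers(molecule,
        max_count = max_conf,
        energy_window = energy_window, seed = seed
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(gen)) {
      conf_err <- gen  # flagged per entry, molecule screened on base geometry
    } else {
      molecule <- gen
    }
  }
  rows <- purrr::map(models, function(m) {
    res <- map_ligand(molecule, m, allow_omit = allow_omit)
    tibble::tibble(
      ligand = molecule$id[[1]],
      model = m$name,
      mapped = res$mapped,
      fitvalue = dplyr::if_else(res$mapped, res$fitvalue, NA_real_),
      note = if (!is.null(conf_err)) conf_err else res$reason
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("profile_report", class(out))
  out
}
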