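#' Per-frame MM-PBSA binding energy
#'
#' The single-snapshot binding free energy is the sum of the molecular
#' mechanics terms (van der Waals `E_vdW` and electrostatic `E_ele`) and the
#' solvation terms (Poisson-Boltzmann polar `G_polar` and SASA-based nonpolar
#' `G_nonpolar`), all in kJ/mol. The entropy term is omitted by default,
#' following common end-point MM-PBSA practice; supply `entropy` (a `-TdS`
#' value in kJ/mol) to include an external estimate.
#'
#' @param frames Tibble of snapshots with columns `E_vdW`, `E_ele`,
#'   `G_polar`, `G_nonpolar`.
#' @param entropy Optional `-TdS` term added to every frame (default 0).
#' @return The tibble with a `total` column (kJ/mol) added.
#' @examples
#' frame_total(tibble::tibble(
#'   E_vdW = -310.59, E_ele = -36.47, G_polar = 118.63, G_nonpolar = -24.60
#' ))$total  # -253.03
#' @export
frame_total <- function(frames, entropy = 0) {
  comp <- c("E_vdW", "E_ele", "G_polar", "G_nonpolar")
  if (!all(comp %in% names(frames))) {
    stop("frames need columns ", paste(comp, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(frames[, comp])
  if (any(!is.finite(m))) stop("non-finite energy component", call. = FALSE)
  frames$total <- rowSums(m) + entropy
  frames
}

#' Summarize MM-PBSA frames
#'
#' Component-wise mean and sample standard deviation over snapshots, plus the
#' total binding energy computed from per-frame totals. By construction the
#' total mean equals the sum of the component means.
#'
#' @inheritParams frame_total
#' @return An `energy_summary`: tibble (`component`, `mean`, `sd`, kJ/mol)
#'   with the `total` row last and attribute `n_frames`.
#' @export
summarize_frames <- function(frames, entropy = 0) {
  if (nrow(frames) == 0) stop("no frames to summarize", call. = FALSE)
  frames <- frame_total(frames, entropy = entropy)
  comp <- c("E_vdW", "E_ele", "G_polar", "G_nonpolar", "total")
  long <- tidyr::pivot_longer(frames[, comp],
    cols = dplyr::all_of(comp),
    names_to = "component", values_to = "energy"
  )
  out <- long |>
    dplyr::group_by(component = factor(.data$component, levels = comp)) |>
    dplyr::summarise(
      mean = mean(.data$energy),
      sd = if (dplyr::n() > 1) stats::sd(.data$energy) else 0,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$component) |>
    dplyr::mutate(component = as.character(.data$component))
  structure(out, class = c("energy_summary", class(out)), n_frames = nrow(frames))
}

#' Three-species binding energy
#'
#' When separate complex, protein and ligand frame sets are available, the
#' binding energy is `G_complex - (G_protein + G_ligand)` applied per
#' component; the single-trajectory approximation (complex frames only) is
#' the common default handled by [summarize_frames()].
#'
#' @param complex,protein,ligand Frame tibbles (see [frame_total()]).
#' @param entropy Optional `-TdS` term (kJ/mol) added to the complex frames.
#' @return An `energy_summary` of the per-component differences of means,
#'   with sds combined in quadrature.
#' @export
binding_energy <- function(complex, protein, ligand, entropy = 0) {
  sc <- summarize_frames(complex, entropy = entropy)
  sp <- summarize_frames(protein)
  sl <- summarize_frames(ligand)
  out <- tibble::tibble(
    component = sc$component,
    mean = sc$mean - sp$mean - sl$mean,
    sd = sqrt(sc$sd^2 + sp$sd^2 + sl$sd^2)
  )
  structure(out,
    class = c("energy_summary", class(out)),
    n_frames = attr(sc, "n_frames")
  )
}

#' Nonpolar solvation energy from SASA
#'
#' Linear surface-area model `gamma * SASA + beta`.
#'
#' @param sasa Solvent-accessible surface area (Angstrom^2), vectorized.
#' @param gamma Surface tension coefficient (kJ/mol/Angstrom^2, default
#'   0.0227).
#' @param beta Offset (kJ/mol, default 0).
#' @return Nonpolar solvation energy (kJ/mol).
#' @export
nonpolar_from_sasa <- function(sasa, gamma = 0.0227, beta = 0) {
  stopifnot(all(sasa >= 0))
  gamma * sasa + beta
}

#' Per-residue energy decomposition
#'
#' Mean and sample standard deviation of each residue's contribution to the
#' binding energy over snapshots, optionally restricted to residues of
#' interest.
#'
#' @param residue_frames Tibble with columns `frame`, `residue`, `energy`
#'   (kJ/mol); every frame must report the same residue set.
#' @param residues Optional character vector restricting (and ordering) the
#'   output.
#' @return Tibble (`residue`, `mean`, `sd`) with attribute `range`
#'   (min/max of the means).
#' @export
residue_decomposition <- function(residue_frames, residues = NULL) {
  keysets <- residue_frames |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(k = paste(sort(.data$residue), collapse = "|"), .groups = "drop")
  if (length(unique(keysets$k)) > 1) {
    stop("frames report inconsistent residue sets", call. = FALSE)
  }
  out <- residue_frames |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      mean = mean(.data$energy),
      sd = if (dplyr::n() > 1) stats::sd(.data$energy) else 0,
      .groups = "drop"
    )
  if (!is.null(residues)) {
    missing <- setdiff(residues, out$residue)
    if (length(missing) > 0) {
      stop("residue(s) absent from the decomposition: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    out <- out[match(residues, out$residue), ]
  }
  attr(out, "range") <- range(out$mean)
  out
}

#' Read MM-PBSA component tables
#'
#' Reads whitespace- or tab-delimited per-snapshot energy tables with a
#' header naming the four components (`E_vdW`, `E_ele`, `G_polar`,
#' `G_nonpolar`; a leading `frame` column is optional), the dialect written
#' by g_mmpbsa-style tools.
#'
#' @param path File path.
#' @return Frame tibble suitable for [summarize_frames()].
#' @export
read_energy_frames <- function(path) {
  out <- readr::read_table(path, col_types = readr::cols(.default = readr::col_double()))
  comp <- c("E_vdW", "E_ele", "G_polar", "G_nonpolar")
  if (!all(comp %in% names(out))) {
    stop("energy table must name columns ", paste(comp, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Read a per-residue contribution table
#'
#' Long-format TSV with columns `frame`, `residue`, `energy` (kJ/mol).
#'
#' @param path File path.
#' @return Tibble for [residue_decomposition()].
#' @export
read_residue_frames <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    frame = readr::col_integer(),
    residue = readr::col_character(),
    energy = readr::col_double()
  ))
}
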