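#' Trajectory tables
#'
#' A trajectory is a tidy table of coordinate snapshots: columns `frame`
#' (integer), `atom` (atom id, constant set across frames), `residue`
#' (label such as `PHE54`), `x`, `y`, `z` (Angstrom).
#' `read_trajectory_xyz()` reads the TSV dialect of that table.
#'
#' @param path File path.
#' @return Trajectory tibble.
#' @export
read_trajectory_xyz <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    frame = readr::col_integer(),
    atom = readr::col_character(),
    residue = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(), z = readr::col_double()
  ))
}

# Split a trajectory into per-frame coordinate matrices with consistent atom
# order; errors if the atom set varies.
traj_matrices <- function(traj, selection = NULL) {
  if (!is.null(selection)) {
    traj <- traj[traj$residue %in% selection | traj$atom %in% selection, ]
  }
  if (nrow(traj) == 0) stop("empty atom selection", call. = FALSE)
  frames <- sort(unique(traj$frame))
  first <- traj[traj$frame == frames[1], ]
  atom_order <- first$atom
  mats <- lapply(frames, function(f) {
    fr <- traj[traj$frame == f, ]
    if (nrow(fr) != length(atom_order) || !setequal(fr$atom, atom_order)) {
      stop("atom count/identity differs between frames", call. = FALSE)
    }
    fr <- fr[match(atom_order, fr$atom), ]
    as_coord_matrix(fr)
  })
  list(frames = frames, atoms = atom_order, residues = first$residue, mats = mats)
}

#' Backbone RMSD time series
#'
#' Root-mean-square deviation of each snapshot from a reference snapshot
#' after least-squares rigid superposition, the standard stability summary of
#' a molecular-dynamics trajectory.
#'
#' @param traj Trajectory tibble (see [read_trajectory_xyz()]).
#' @param reference Frame number used as reference (default: first frame).
#' @param selection Optional character vector of residue labels (or atom ids)
#'   to restrict the fit and the deviation to.
#' @param fit Superpose each snapshot onto the reference before measuring
#'   (default TRUE). With `fit = FALSE` the deviation is taken in the frame's
#'   own coordinates, which is the convention under which a single atom
#'   displaced by `d` among N gives exactly `d / sqrt(N)`; the fitted value
#'   is never larger.
#' @return Tibble (`frame`, `rmsd`) in Angstrom.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL, fit = TRUE) {
  tm <- traj_matrices(traj, selection)
  if (is.null(reference)) reference <- tm$frames[1]
  ri <- match(reference, tm$frames)
  if (is.na(ri)) stop("reference frame not in trajectory", call. = FALSE)
  ref <- tm$mats[[ri]]
  rmsd <- vapply(tm$mats, function(m) {
    if (fit) {
      kabsch_fit(m, ref)$rmsd
    } else {
      sqrt(sum((m - ref)^2) / nrow(ref))
    }
  }, 0)
  tibble::tibble(frame = tm$frames, rmsd = rmsd)
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of each atom about its mean position, after
#' superposing every snapshot onto the first, averaged within residues
#' (root-mean of the atomic mean-square fluctuations) -- the standard
#' flexibility profile of a simulation.
#'
#' @inheritParams rmsd_series
#' @param fit Superpose snapshots onto the first before measuring
#'   fluctuations (default TRUE); `fit = FALSE` measures in raw coordinates
#'   (global-translation closed forms hold exactly there).
#' @return Tibble (`residue`, `rmsf`) in Angstrom, one row per residue of the
#'   selection, in order of first appearance.
#' @export
rmsf_per_residue <- function(traj, selection = NULL, fit = TRUE) {
  tm <- traj_matrices(traj, selection)
  if (length(tm$mats) < 2) {
    stop("RMSF needs at least two snapshots", call. = FALSE)
  }
  ref <- tm$mats[[1]]
  fitted <- lapply(tm$mats, function(m) {
    if (fit) transform_points(m, kabsch_fit(m, ref)) else m
  })
  arr <- simplify2array(fitted)  # atoms x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  msf <- rowMeans(apply(arr, 3, function(m) rowSums((m - mean_pos)^2)))
  tibble::tibble(residue = tm$residues, msf = msf) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(rmsf = sqrt(mean(.data$msf)), .groups = "drop") |>
    dplyr::arrange(match(.data$residue, unique(tm$residues)))
}
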