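#' Build a molecule table
#'
#' The package represents a compound library as a tibble with one row per
#' molecule: `id`, an `atoms` list-column (tibbles with `elem`, `x`, `y`, `z`,
#' `charge`), a `bonds` list-column (tibbles with `from`, `to`, `order`), an
#' optional `sdf` list-column holding the underlying ChemmineR `SDF` object
#' (present for molecules parsed from SMILES/SDF; needed for fingerprints and
#' drug-likeness properties), a `conformers` list-column (each element a list
#' of n_atoms x 3 coordinate matrices), and an optional `features` list-column
#' of pre-assigned pharmacophoric points (used by the synthetic generator).
#'
#' @param id Character vector of molecule ids.
#' @param atoms,bonds,sdf,conformers,features Parallel lists (or NULL).
#' @return A `tbl_df` of molecules.
#' @export
molecule_tbl <- function(id, atoms, bonds = NULL, sdf = NULL,
                         conformers = NULL, features = NULL) {
  n <- length(id)
  empty_bonds <- tibble::tibble(from = integer(), to = integer(), order = integer())
  out <- tibble::tibble(
    id = as.character(id),
    atoms = atoms,
    bonds = if (is.null(bonds)) rep(list(empty_bonds), n) else bonds,
    sdf = if (is.null(sdf)) rep(list(NULL), n) else sdf,
    conformers = if (is.null(conformers)) {
      purrr::map(atoms, ~ list(as_coord_matrix(.x)))
    } else {
      conformers
    },
    features = if (is.null(features)) rep(list(NULL), n) else features
  )
  if (anyDuplicated(out$id)) stop("molecule ids must be unique", call. = FALSE)
  out
}

#' Parse a compound library from SMILES or SDF
#'
#' Invalid records are skipped with a warning and counted in the
#' `skipped` attribute; an input with zero valid records is an error.
#' Coordinates found in the source (2D or 3D) become the molecule's first
#' conformer; use [generate_conformers()] to grow an ensemble.
#'
#' @param source Path to a file, or (for `format = "smiles"`) a character
#'   vector of SMILES strings, optionally named by id.
#' @param format `"smiles"` (one SMILES per line, optional whitespace-separated
#'   id) or `"sdf"` (V2000).
#' @return Molecule tibble (see [molecule_tbl()]) with attribute `skipped`
#'   (number of invalid records dropped).
#' @examples
#' mols <- parse_molecules(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' mols$id
#' @export
parse_molecules <- function(source, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    if (length(source) == 1 && !grepl("[^A-Za-z0-9_./\\\\:~-]", source) &&
        file.exists(source)) {
      lines <- readr::read_lines(source)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "\\s+")
      smi <- vapply(parts, `[[`, "", 1)
      ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
      names(smi) <- ids
    } else {
      smi <- source
      if (is.null(names(smi))) names(smi) <- rep(NA_character_, length(smi))
    }
    if (length(smi) == 0) stop("empty library: no SMILES records", call. = FALSE)
    auto <- is.na(names(smi)) | !nzchar(names(smi))
    names(smi)[auto] <- paste0("mol", which(auto))
    sdfs <- vector("list", length(smi))
    ok <- logical(length(smi))
    for (i in seq_along(smi)) {
      res <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi[i], names(smi)[i]))),
        error = function(e) NULL
      )
      if (!is.null(res) && length(res) == 1 && ChemmineR::validSDF(res)) {
        sdfs[[i]] <- res[[1]]
        ok[i] <- TRUE
      }
    }
    n_skip <- sum(!ok)
    if (n_skip > 0) {
      warning(n_skip, " invalid SMILES record(s) skipped", call. = FALSE)
    }
    if (!any(ok)) stop("empty library: no valid SMILES records", call. = FALSE)
    out <- sdf_list_to_tbl(sdfs[ok], names(smi)[ok], smiles = unname(smi[ok]))
  } else {
    if (!file.exists(source)) stop("unreadable source: ", source, call. = FALSE)
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(source, skipErrors = TRUE)),
      error = function(e) stop("unreadable SDF source: ", conditionMessage(e), call. = FALSE)
    )
    if (length(sdfset) == 0) stop("empty library: no SDF records", call. = FALSE)
    valid <- ChemmineR::validSDF(sdfset)
    n_skip <- sum(!valid)
    if (n_skip > 0) {
      warning(n_skip, " corrupt SDF record(s) skipped", call. = FALSE)
      sdfset <- sdfset[valid]
    }
    if (length(sdfset) == 0) stop("empty library: no valid SDF records", call. = FALSE)
    ids <- vapply(seq_along(sdfset), function(i) {
      h <- ChemmineR::header(sdfset[[i]])[1]
      h <- trimws(h)
      if (nzchar(h)) h else paste0("mol", i)
    }, "")
    ids <- make.unique(ids, sep = "_")
    out <- sdf_list_to_tbl(lapply(seq_along(sdfset), function(i) sdfset[[i]]), ids)
  }
  attr(out, "skipped") <- n_skip
  out
}

# Convert a list of ChemmineR SDF objects into the molecule tibble.
sdf_list_to_tbl <- function(sdfs, ids, smiles = NULL) {
  atoms <- purrr::map(sdfs, function(s) {
    ab <- ChemmineR::atomblock(s)
    elem <- sub("_.*$", "", rownames(ab))
    tibble::tibble(
      elem = elem,
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      charge = charge_from_atomblock(ab)
    )
  })
  bonds <- purrr::map(sdfs, function(s) {
    bb <- ChemmineR::bondblock(s)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    tibble::tibble(
      from = as.integer(bb[, 1]),
      to = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  })
  out <- molecule_tbl(ids, atoms, bonds, sdf = sdfs)
  if (!is.null(smiles)) out$smiles <- smiles
  out
}

# MDL ctab charge codes: column 5 of the atom block holds 0 or code 1..7
# (3 -> +1, 5 -> -1 etc.); ChemmineR keeps the raw code.
charge_from_atomblock <- function(ab) {
  if (ncol(ab) < 5) {
    return(rep(0L, nrow(ab)))
  }
  code <- ab[, 5]
  chg <- integer(length(code))
  map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  hit <- as.character(code) %in% names(map)
  chg[hit] <- map[as.character(code[hit])]
  chg
}

#' Compute drug-likeness properties
#'
#' Adds molecular weight (Da), an octanol/water logP estimate, and hydrogen
#' bond donor/acceptor counts to a molecule table. Properties are always
#' recomputed from structure via OpenBabel descriptors (ChemmineOB), never
#' trusted from the input file; the logP estimator is recorded in the
#' `prop_method` attribute.
#'
#' @param molecules Molecule tibble with an `sdf` column (from
#'   [parse_molecules()]).
#' @return The tibble with columns `mw`, `logp`, `hbd`, `hba` added; rows
#'   whose properties could not be computed carry `NA`.
#' @export
mol_properties <- function(molecules) {
  has_sdf <- !purrr::map_lgl(molecules$sdf, is.null)
  mw <- logp <- hbd <- hba <- rep(NA_real_, nrow(molecules))
  if (any(has_sdf)) {
    sdfset <- methods::new("SDFset",
      SDF = molecules$sdf[has_sdf], ID = molecules$id[has_sdf]
    )
    props <- tryCatch(ChemmineR::propOB(sdfset), error = function(e) NULL)
    if (!is.null(props)) {
      mw[has_sdf] <- props$MW
      logp[has_sdf] <- props$logP
      hbd[has_sdf] <- props$HBD
      hba[has_sdf] <- props$HBA1  # N+O count, the classic rule-of-five flavor
    }
  }
  molecules$mw <- mw
  molecules$logp <- logp
  molecules$hbd <- hbd
  molecules$hba <- hba
  attr(molecules, "prop_method") <-
    "OpenBabel 3.1 descriptors (logP: Wildman-Crippen atom contributions)"
  molecules
}

#' Lipinski rule-of-five filter
#'
#' Classic drug-likeness screen: molecular weight <= 500 Da, logP <= 5,
#' hydrogen-bond donors <= 5, acceptors <= 10. The default is strict
#' (zero violations tolerated); `max_violations` relaxes it.
#'
#' @param molecules Molecule tibble; properties are computed with
#'   [mol_properties()] if the columns are absent.
#' @param max_violations Number of rule violations tolerated (default 0).
#' @param thresholds Named numeric vector overriding the four cutoffs
#'   (`mw`, `logp`, `hbd`, `hba`).
#' @return The tibble with `lipinski_violations` (NA-property molecules count
#'   as failing, with the reason in `lipinski_reason`) and `lipinski_pass`
#'   columns added.
#' @examples
#' parse_molecules(c(ethanol = "CCO")) |> lipinski_pass()
#' @export
lipinski_pass <- function(molecules, max_violations = 0,
                          thresholds = c(mw = 500, logp = 5, hbd = 5, hba = 10)) {
  if (!all(c("mw", "logp", "hbd", "hba") %in% names(molecules))) {
    molecules <- mol_properties(molecules)
  }
  viol <- (molecules$mw > thresholds[["mw"]]) +
    (molecules$logp > thresholds[["logp"]]) +
    (molecules$hbd > thresholds[["hbd"]]) +
    (molecules$hba > thresholds[["hba"]])
  bad <- is.na(viol)
  molecules$lipinski_violations <- viol
  molecules$lipinski_reason <- dplyr::if_else(
    bad, "property computation failed", NA_character_
  )
  molecules$lipinski_pass <- !bad & viol <= max_violations
  molecules
}

# Number of heavy (non-hydrogen) atoms.
n_heavy_atoms <- function(atoms) sum(atoms$elem != "H")

# Implicit hydrogen count per atom from standard valences minus bond orders.
implicit_h <- function(atoms, bonds) {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3)
  deg <- rep(0, nrow(atoms))
  if (nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      o <- bonds$order[i]
      # MDL aromatic bond code 4 counts as 1.5
      o <- if (o == 4) 1.5 else o
      deg[bonds$from[i]] <- deg[bonds$from[i]] + o
      deg[bonds$to[i]] <- deg[bonds$to[i]] + o
    }
  }
  v <- valence[atoms$elem]
  v[is.na(v)] <- 0
  # protonation raises the H count on N+, deprotonation lowers it on O-
  h <- v - deg + atoms$charge
  pmax(0, round(h))
}
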