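#' Pharmacophoric feature perception rules
#'
#' The curated rule set used by [perceive_features()], exposed (with a version
#' string) so analyses can pin it. Kinds follow the common four-letter
#' vocabulary: `A` hydrogen-bond acceptor, `D` hydrogen-bond donor,
#' `H` hydrophobe, `R` aromatic ring.
#'
#' @return A list describing each rule and the rule-set `version`.
#' @export
feature_rules <- function() {
  list(
    version = "1.0",
    A = "N or O atom with formal charge <= 0 and open coordination (degree + implicit H <= 3 for N); feature at the atom position",
    D = "N or O atom bearing at least one (implicit or explicit) hydrogen; feature at the atom position",
    H = "maximal connected cluster of >= 3 non-aromatic carbons, none adjacent to N/O/S; feature at the cluster centroid",
    R = "aromatic ring (graph/aromaticity perception of the parsed structure); feature at the ring centroid, ring normal kept as auxiliary direction"
  )
}

# Feature definitions (kind + defining atom indices) from connectivity.
# Coordinates are not consulted here, so definitions are conformer-independent.
feature_defs <- function(atoms, bonds, sdf = NULL) {
  heavy <- which(atoms$elem != "H")
  nh <- implicit_h(atoms, bonds)
  # explicit hydrogens add to the donor count
  if (nrow(bonds) > 0 && any(atoms$elem == "H")) {
    hidx <- which(atoms$elem == "H")
    for (h in hidx) {
      nbr <- c(bonds$to[bonds$from == h], bonds$from[bonds$to == h])
      nh[nbr] <- nh[nbr] + 1
    }
  }
  deg <- tabulate(c(bonds$from, bonds$to), nbins = nrow(atoms))

  aromatic_atoms <- integer(0)
  ring_defs <- list()
  if (!is.null(sdf)) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rg) && length(rg$RINGS) > 0) {
      arom <- rg$AROMATIC
      for (i in seq_along(rg$RINGS)) {
        if (isTRUE(arom[[i]])) {
          idx <- as.integer(sub("^.*_", "", rg$RINGS[[i]]))
          ring_defs[[length(ring_defs) + 1]] <- idx
          aromatic_atoms <- union(aromatic_atoms, idx)
        }
      }
    }
  }

  defs <- list()
  add <- function(kind, idx) {
    defs[[length(defs) + 1]] <<- list(kind = kind, atom_idx = idx)
  }
  # acceptors / donors
  for (i in heavy) {
    el <- atoms$elem[i]
    if (el %in% c("N", "O") && atoms$charge[i] <= 0) {
      if (el == "O" || (deg[i] + nh[i]) <= 3) add("A", i)
    }
    if (el %in% c("N", "O") && nh[i] >= 1) add("D", i)
  }
  # aromatic rings
  for (idx in ring_defs) add("R", idx)
  # hydrophobic carbon clusters
  hetero_adj <- rep(FALSE, nrow(atoms))
  if (nrow(bonds) > 0) {
    het <- atoms$elem %in% c("N", "O", "S")
    hetero_adj[bonds$from[het[bonds$to]]] <- TRUE
    hetero_adj[bonds$to[het[bonds$from]]] <- TRUE
  }
  eligible <- atoms$elem == "C" & !hetero_adj &
    !(seq_len(nrow(atoms)) %in% aromatic_atoms)
  comps <- connected_components(which(eligible), bonds)
  for (cmp in comps) {
    if (length(cmp) >= 3) add("H", cmp)
  }
  defs
}

# Connected components of the bond graph restricted to `nodes`.
connected_components <- function(nodes, bonds) {
  if (length(nodes) == 0) {
    return(list())
  }
  adj <- split(
    c(bonds$to, bonds$from),
    c(bonds$from, bonds$to)
  )
  seen <- logical(max(c(nodes, 1)))
  comps <- list()
  nodeset <- logical(length(seen))
  nodeset[nodes] <- TRUE
  for (s in nodes) {
    if (seen[s]) next
    comp <- integer(0)
    stack <- s
    seen[s] <- TRUE
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- adj[[as.character(v)]]
      nb <- nb[!is.na(nb) & nb <= length(nodeset) & nodeset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Evaluate feature definitions at one conformer's coordinates.
features_for_conformer <- function(defs, coords, atoms) {
  if (length(defs) == 0) {
    return(tibble::tibble(
      kind = character(), x = double(), y = double(), z = double()
    ))
  }
  rows <- purrr::map(defs, function(d) {
    ctr <- colMeans(coords[d$atom_idx, , drop = FALSE])
    tibble::tibble(kind = d$kind, x = ctr[1], y = ctr[2], z = ctr[3])
  })
  dplyr::bind_rows(rows)
}

#' Perceive pharmacophoric feature points
#'
#' Locates hydrogen-bond acceptors (`A`) and donors (`D`) at heteroatom
#' positions, hydrophobes (`H`) at carbon-cluster centroids, and aromatic
#' rings (`R`) at ring centroids, on the coordinates of the requested
#' conformer. The rule set is documented in [feature_rules()]. Molecules whose
#' `features` column was pre-assigned (synthetic feature clouds) keep those
#' features untouched.
#'
#' @param molecules Molecule tibble.
#' @param conformer Conformer index to evaluate (default 1).
#' @return The tibble with the `features` list-column filled; each element is
#'   a tibble with `kind`, `x`, `y`, `z`.
#' @examples
#' parse_molecules(c(benzene = "c1ccccc1")) |>
#'   perceive_features() |>
#'   dplyr::pull(features)
#' @export
perceive_features <- function(molecules, conformer = 1) {
  molecules$features <- purrr::pmap(
    list(molecules$atoms, molecules$bonds, molecules$sdf,
         molecules$conformers, molecules$features),
    function(atoms, bonds, sdf, conformers, feats) {
      if (!is.null(feats)) {
        return(feats)
      }
      if (length(conformers) < conformer) {
        stop("conformer ", conformer, " does not exist", call. = FALSE)
      }
      defs <- feature_defs(atoms, bonds, sdf)
      features_for_conformer(defs, conformers[[conformer]], atoms)
    }
  )
  molecules
}
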