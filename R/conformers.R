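#' Generate a conformer ensemble
#'
#' Deterministic conformer ensemble generation: starting from the molecule's
#' base geometry (coordinates from the input file, or an internal-coordinate
#' embedding when none are present), torsions about every rotatable bond are
#' enumerated systematically in 120-degree steps; each conformer is scored
#' with a soft steric-clash energy and the ensemble is pruned to the
#' `energy_window` above the best conformer found, then truncated to
#' `max_count` lowest-strain members. When the torsion grid exceeds
#' `max_count` combinations, a seeded subsample (always containing the base
#' geometry) is evaluated, so results are reproducible for a fixed seed.
#'
#' Defaults (at most 255 conformers within a 20 kcal/mol strain window) follow
#' common flexible-search practice for pharmacophore screening.
#'
#' @param molecules Molecule tibble.
#' @param max_count Maximum conformers retained per molecule (default 255).
#' @param energy_window Strain window above the minimum, kcal/mol (default 20).
#' @param seed Integer seed for the torsion-grid subsample.
#' @return The tibble with the `conformers` list-column replaced by the
#'   generated ensemble (each element a list of n_atoms x 3 matrices, strain
#'   energies in the `strain` attribute of each element).
#' @examples
#' parse_molecules(c(benzene = "c1ccccc1")) |>
#'   generate_conformers() |>
#'   dplyr::mutate(n_conf = lengths(conformers))
#' @export
generate_conformers <- function(molecules, max_count = 255,
                                energy_window = 20, seed = 1) {
  molecules$conformers <- purrr::pmap(
    list(molecules$atoms, molecules$bonds, molecules$id, seq_len(nrow(molecules))),
    function(atoms, bonds, id, i) {
      base <- base_geometry(atoms, bonds, id)
      confs <- tryCatch(
        enumerate_conformers(base, atoms, bonds, max_count, energy_window,
          seed = seed + i
        ),
        error = function(e) {
          stop("conformer generation failed for molecule '", id, "': ",
            conditionMessage(e),
            call. = FALSE
          )
        }
      )
      confs
    }
  )
  molecules
}

# Base 3D geometry: input coordinates if any are non-degenerate, else a
# spanning-tree embedding with standard bond lengths and tetrahedral angles.
base_geometry <- function(atoms, bonds, id) {
  coords <- as_coord_matrix(atoms)
  if (nrow(coords) >= 2 && max(stats::dist(coords)) > 1e-6) {
    return(coords)
  }
  embed_from_graph(atoms, bonds, id)
}

# Minimal internal-coordinate embedding over a BFS spanning tree: standard
# bond lengths, 109.47-degree angles, anti torsions. Ring closure is not
# enforced; supply explicit coordinates for ring systems.
embed_from_graph <- function(atoms, bonds, id) {
  n <- nrow(atoms)
  if (n == 0) stop("no atoms to embed")
  if (n == 1) {
    return(matrix(0, 1, 3))
  }
  if (nrow(bonds) == 0) {
    stop("cannot embed molecule '", id, "': atoms without bonds")
  }
  blen <- function(e1, e2) {
    key <- paste(sort(c(e1, e2)), collapse = "-")
    lens <- c(`C-C` = 1.54, `C-O` = 1.43, `C-N` = 1.47, `C-H` = 1.09,
              `H-O` = 0.96, `H-N` = 1.01, `C-S` = 1.81)
    if (key %in% names(lens)) lens[[key]] else 1.5
  }
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$from[i]]] <- c(adj[[bonds$from[i]]], bonds$to[i])
    adj[[bonds$to[i]]] <- c(adj[[bonds$to[i]]], bonds$from[i])
  }
  coords <- matrix(NA_real_, n, 3)
  placed <- logical(n)
  # BFS from atom 1; zig-zag backbone in the xz plane, branches alternate
  coords[1, ] <- c(0, 0, 0)
  placed[1] <- TRUE
  queue <- 1L
  theta <- (180 - 109.47) * pi / 180
  k <- 0L
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in sort(adj[[v]])) {
      if (placed[w]) next
      k <- k + 1L
      l <- blen(atoms$elem[v], atoms$elem[w])
      dir <- c(cos(theta * (-1)^k), 0.12 * k, sin(theta) * (-1)^(k %/% 2))
      dir <- dir / sqrt(sum(dir^2))
      coords[w, ] <- coords[v, ] + l * dir
      placed[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  if (any(!placed)) {
    stop("cannot embed molecule '", id, "': disconnected structure")
  }
  coords
}

# Rotatable bonds: acyclic single bonds between two non-terminal heavy atoms.
rotatable_bonds <- function(atoms, bonds) {
  if (nrow(bonds) == 0) {
    return(bonds[0, ])
  }
  deg <- tabulate(c(bonds$from, bonds$to), nbins = nrow(atoms))
  in_ring <- ring_edges(nrow(atoms), bonds)
  keep <- bonds$order == 1 &
    !in_ring &
    deg[bonds$from] >= 2 & deg[bonds$to] >= 2 &
    atoms$elem[bonds$from] != "H" & atoms$elem[bonds$to] != "H"
  bonds[keep, , drop = FALSE]
}

# TRUE for each bond that lies on a cycle (endpoints stay connected with the
# edge removed).
ring_edges <- function(n_atoms, bonds) {
  vapply(seq_len(nrow(bonds)), function(i) {
    rest <- bonds[-i, , drop = FALSE]
    comp <- connected_components(seq_len(n_atoms), rest)
    a <- bonds$from[i]
    b <- bonds$to[i]
    any(vapply(comp, function(cmp) a %in% cmp && b %in% cmp, TRUE))
  }, TRUE)
}

# Atoms on the `to` side of a bond once the bond is cut.
side_atoms <- function(n_atoms, bonds, cut) {
  rest <- bonds[!(bonds$from == cut[1] & bonds$to == cut[2]) &
    !(bonds$from == cut[2] & bonds$to == cut[1]), , drop = FALSE]
  comp <- connected_components(seq_len(n_atoms), rest)
  for (cmp in comp) {
    if (cut[2] %in% cmp) {
      return(cmp)
    }
  }
  cut[2]
}

# Soft steric-clash strain (kcal/mol): quadratic penalty for heavy-atom pairs
# separated by >= 3 bonds that approach within 3.0 Angstrom.
clash_energy <- function(coords, atoms, path3) {
  if (nrow(path3) == 0) {
    return(0)
  }
  d <- sqrt(rowSums((coords[path3[, 1], , drop = FALSE] -
    coords[path3[, 2], , drop = FALSE])^2))
  sum(10 * pmax(0, 3.0 - d)^2)
}

# Heavy-atom pairs at graph distance >= 3 (the nonbonded pairs a torsion can
# move relative to each other).
nonbonded_pairs <- function(atoms, bonds) {
  n <- nrow(atoms)
  heavy <- which(atoms$elem != "H")
  if (length(heavy) < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  for (i in seq_len(nrow(bonds))) {
    dmat[bonds$from[i], bonds$to[i]] <- 1
    dmat[bonds$to[i], bonds$from[i]] <- 1
  }
  for (k in seq_len(n)) {
    dmat <- pmin(dmat, outer(dmat[, k], dmat[k, ], `+`))
  }
  pr <- t(utils::combn(heavy, 2))
  pr[dmat[pr] >= 3, , drop = FALSE]
}

enumerate_conformers <- function(base, atoms, bonds, max_count, energy_window,
                                 seed) {
  rot <- rotatable_bonds(atoms, bonds)
  pairs <- nonbonded_pairs(atoms, bonds)
  if (nrow(rot) == 0) {
    out <- list(base)
    attr(out[[1]], "strain") <- 0
    return(out)
  }
  angles <- c(0, 2 * pi / 3, -2 * pi / 3)
  grid <- as.matrix(expand.grid(rep(list(seq_along(angles)), nrow(rot))))
  if (nrow(grid) > max_count) {
    set.seed(seed %% .Machine$integer.max)
    keep <- c(1L, sample(2:nrow(grid), max_count - 1L))
    grid <- grid[keep, , drop = FALSE]
  }
  sides <- lapply(seq_len(nrow(rot)), function(i) {
    side_atoms(nrow(atoms), bonds, c(rot$from[i], rot$to[i]))
  })
  confs <- vector("list", nrow(grid))
  energies <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    coords <- base
    for (bi in seq_len(nrow(rot))) {
      ang <- angles[grid[g, bi]]
      if (ang != 0) {
        coords <- rotate_about_axis(
          coords,
          coords[rot$from[bi], ], coords[rot$to[bi], ],
          ang, sides[[bi]]
        )
      }
    }
    confs[[g]] <- coords
    energies[g] <- clash_energy(coords, atoms, pairs)
  }
  emin <- min(energies)
  keep <- which(energies <= emin + energy_window)
  keep <- keep[order(energies[keep], keep)]
  if (length(keep) > max_count) keep <- keep[seq_len(max_count)]
  out <- confs[keep]
  for (i in seq_along(out)) attr(out[[i]], "strain") <- energies[keep[i]] - emin
  out
}
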