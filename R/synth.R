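#' Synthetic benchmark specification
#'
#' Describes a planted-signal screening benchmark: actives embed a known
#' 3D feature arrangement (up to positional jitter and a random rigid
#' motion), decoys carry the same feature-kind multiset at scrambled
#' positions. Defaults mirror a typical hypothesis-validation test set:
#' 154 actives and 462 decoys, a four-point acceptor/hydrophobe/hydrophobe/
#' aromatic arrangement with inter-feature distances in the 3-5 Angstrom
#' range.
#'
#' @param n_actives,n_decoys Library composition (default 154 / 462).
#' @param kinds Feature kinds of the planted arrangement (default
#'   `c("A", "H", "H", "R")`).
#' @param distances Pairwise distance matrix (Angstrom) of the planted
#'   points; default realizes the canonical arrangement below. Must be
#'   embeddable in 3D.
#' @param jitter_sd Positional jitter of planted points in actives
#'   (Angstrom, default 0.3).
#' @param n_extra_features Additional random feature points per molecule
#'   (default 2), so assignment search is non-trivial.
#' @param seed Integer seed; every generated artifact records it.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_actives = 154, n_decoys = 462,
                           kinds = c("A", "H", "H", "R"),
                           distances = NULL,
                           jitter_sd = 0.3, n_extra_features = 2,
                           seed = 1) {
  stopifnot(n_actives >= 0, n_decoys >= 0, jitter_sd >= 0)
  if (is.null(distances)) {
    canon <- matrix(c(
      0, 0, 0,
      4.0, 0, 0,
      2.0, 3.5, 0,
      2.0, 1.2, 3.0
    ), ncol = 3, byrow = TRUE)
    canon <- canon[seq_along(kinds), , drop = FALSE]
    distances <- as.matrix(stats::dist(canon))
  }
  structure(
    list(
      n_actives = n_actives, n_decoys = n_decoys, kinds = kinds,
      distances = as.matrix(distances), jitter_sd = jitter_sd,
      n_extra_features = n_extra_features, seed = as.integer(seed)
    ),
    class = "benchmark_spec"
  )
}

#' The pharmacophore model a benchmark plants
#'
#' @param spec A [benchmark_spec()].
#' @param tolerance,weight Feature sphere parameters.
#' @return A `phore_model` whose feature centers realize the planted
#'   arrangement (canonical orientation).
#' @export
planted_phore_model <- function(spec, tolerance = 1.6, weight = 1) {
  coords <- embed_distances(spec$distances, tol = 1e-4)
  pharmacophore_model(
    "planted",
    tibble::tibble(
      kind = spec$kinds,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      tolerance = tolerance, weight = weight
    )
  )
}

#' Generate a planted-signal screening library
#'
#' Actives carry feature points realizing the planted arrangement (jittered,
#' randomly rotated and translated); decoys carry the same kinds at uniform
#' random positions. Both get `n_extra_features` random additional feature
#' points and a minimal heavy-atom scaffold (one carbon per feature point).
#' Fully reproducible from the spec's seed; the manifest records labels and
#' the planted (post-jitter, pre-rotation) coordinates of every active.
#'
#' @param spec A [benchmark_spec()].
#' @return Molecule tibble with `label` column (`"active"`/`"inactive"`) and
#'   attributes `manifest` (tibble id, label, planted list-column) and `spec`.
#' @export
make_library <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  planted <- embed_distances(spec$distances, tol = 1e-4)
  k <- nrow(planted)
  set.seed(spec$seed)
  n <- spec$n_actives + spec$n_decoys
  label <- rep(c("active", "inactive"), c(spec$n_actives, spec$n_decoys))
  ids <- sprintf("mol%04d", seq_len(n))
  extra_kind_pool <- c("A", "D", "H", "R")

  rows <- purrr::map(seq_len(n), function(i) {
    if (label[i] == "active") {
      pts <- planted + matrix(stats::rnorm(3 * k, sd = spec$jitter_sd), k, 3)
      record <- pts
    } else {
      pts <- matrix(stats::runif(3 * k, -5, 5), k, 3)
      record <- NULL
    }
    n_extra <- spec$n_extra_features
    if (n_extra > 0) {
      extra <- matrix(stats::runif(3 * n_extra, -6, 6), n_extra, 3)
      kinds <- c(spec$kinds, sample(extra_kind_pool, n_extra, replace = TRUE))
      pts <- rbind(pts, extra)
    } else {
      kinds <- spec$kinds
    }
    # random rigid placement of the whole cloud
    R <- random_rotation()
    t <- stats::runif(3, -10, 10)
    pts <- sweep(pts %*% t(R), 2, t, "+")
    feats <- tibble::tibble(
      kind = kinds, x = pts[, 1], y = pts[, 2], z = pts[, 3]
    )
    atoms <- tibble::tibble(
      elem = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3], charge = 0L
    )
    list(feats = feats, atoms = atoms, planted = record)
  })

  mols <- molecule_tbl(
    ids,
    atoms = purrr::map(rows, "atoms"),
    features = purrr::map(rows, "feats")
  )
  mols$label <- label
  manifest <- tibble::tibble(
    id = ids, label = label,
    planted = purrr::map(rows, "planted"),
    seed = spec$seed
  )
  attr(mols, "manifest") <- manifest
  attr(mols, "spec") <- spec
  mols
}

#' Generate a small chemistry library (SMILES)
#'
#' Drug-like and deliberately rule-breaking molecules assembled from a fixed
#' SMILES pool, for exercising parsing, property and fingerprint stages with
#' real chemistry. Deterministic for a given seed.
#'
#' @param n Library size.
#' @param seed Integer seed.
#' @return Molecule tibble with a `label` column marking the intended
#'   Lipinski outcome (`"pass"`/`"fail"`, by construction of the pool).
#' @export
make_chem_library <- function(n = 20, seed = 1) {
  pool_pass <- c(
    "CCO", "CC(=O)OC1=CC=CC=C1C(=O)O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    "C1=CC=C(C=C1)C(=O)O", "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",
    "C1=CC=C2C(=C1)C=CC=C2", "CCN(CC)CC", "OCC1OC(O)C(O)C(O)C1O"
  )
  pool_fail <- c(
    strrep("C", 40),                       # logP far above 5
    paste0("C(", strrep("C(O)", 12), ")O") # donor count above 5
  )
  set.seed(seed)
  pick_pass <- sample(pool_pass, ceiling(0.8 * n), replace = TRUE)
  pick_fail <- sample(pool_fail, n - length(pick_pass), replace = TRUE)
  smi <- c(pick_pass, pick_fail)
  ids <- sprintf("chem%03d", seq_along(smi))
  mols <- parse_molecules(stats::setNames(smi, ids))
  mols$label <- rep(c("pass", "fail"), c(length(pick_pass), length(pick_fail)))
  mols
}

#' Construct a labeling and hit set with exact confusion counts
#'
#' Builds a labeled test set of `D` compounds (`A` active) and a hit set of
#' size `Ht` containing exactly `Ha` actives, so [evaluate_model()]
#' reproduces the requested counts. Infeasible counts error.
#'
#' @param D,A,Ha,Ht Target counts.
#' @param seed Integer seed (which ids end up as hits is randomized).
#' @return List with `labels` (tibble id, label) and `hits` (character).
#' @export
make_hit_set <- function(D, A, Ha, Ht, seed = 1) {
  if (A > D || Ha > min(A, Ht) || Ht > D || (Ht - Ha) > (D - A) ||
    any(c(D, A, Ha, Ht) < 0)) {
    stop("infeasible counts: need Ha <= min(A, Ht), Ht - Ha <= D - A, A <= D",
      call. = FALSE
    )
  }
  set.seed(seed)
  ids <- sprintf("t%05d", seq_len(D))
  labels <- tibble::tibble(
    id = ids, label = rep(c("active", "inactive"), c(A, D - A))
  )
  hits <- c(
    sample(ids[seq_len(A)], Ha),
    if (Ht - Ha > 0) sample(ids[A + seq_len(D - A)], Ht - Ha)
  )
  list(labels = labels, hits = hits)
}

#' Simulate a docking-score table with a planted active-vs-decoy effect
#'
#' Scores are Gaussian around a base level (a fixed fraction of the reference
#' ligand's scores), with actives shifted upward by `effect`; actives also
#' receive key-residue hydrophobic interactions with higher probability.
#'
#' @param labels Tibble (`id`, `label`).
#' @param reference_scores Named vector `c(score_energy =, score_interaction =)`
#'   echoed into the returned reference record.
#' @param effect Additive score shift for actives (score units, default 10).
#' @param noise_sd Score noise standard deviation (default 3).
#' @param key_residues Residue labels used as the key set.
#' @param p_key_active,p_key_decoy Per-residue probability of a key
#'   hydrophobic interaction (default 0.85 / 0.25).
#' @param base_fraction Base score level as a fraction of the reference
#'   (default 0.7, i.e. decoys sit just under an 80% threshold).
#' @param seed Integer seed.
#' @return List with `records` (docking tibble) and `reference` (one-row
#'   docking record, id `"REF"`); generative parameters in the `params`
#'   attribute.
#' @export
simulate_docking <- function(labels,
                             reference_scores = c(
                               score_energy = 51.30, score_interaction = 61.78
                             ),
                             effect = 10, noise_sd = 3,
                             key_residues = c(
                               "PHE54", "VAL179", "LEU183", "LEU211", "PRO292"
                             ),
                             p_key_active = 0.85, p_key_decoy = 0.25,
                             base_fraction = 0.7, seed = 1) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  n <- nrow(labels)
  shift <- ifelse(labels$label == "active", effect, 0)
  decoy_pool <- c("TYR73", "ALA176", "MET207", "GLN212", "SER51", "ARG52")
  records <- tibble::tibble(
    id = labels$id,
    score_energy = base_fraction * reference_scores[["score_energy"]] +
      shift + stats::rnorm(n, sd = noise_sd),
    score_interaction = base_fraction * reference_scores[["score_interaction"]] +
      shift + stats::rnorm(n, sd = noise_sd),
    interactions = purrr::map(seq_len(n), function(i) {
      p <- if (labels$label[i] == "active") p_key_active else p_key_decoy
      keys <- key_residues[stats::runif(length(key_residues)) < p]
      extra <- sample(decoy_pool, min(stats::rpois(1, 1), length(decoy_pool)))
      tibble::tibble(
        residue = c(keys, extra),
        kind = c(
          rep("hydrophobic", length(keys)),
          sample(c("hydrophobic", "hbond"), length(extra), replace = TRUE)
        )
      )
    })
  )
  reference <- tibble::tibble(
    id = "REF",
    score_energy = reference_scores[["score_energy"]],
    score_interaction = reference_scores[["score_interaction"]],
    interactions = list(tibble::tibble(
      residue = key_residues, kind = "hydrophobic"
    ))
  )
  out <- list(records = records, reference = reference)
  attr(out, "params") <- list(
    effect = effect, noise_sd = noise_sd, base_fraction = base_fraction,
    p_key_active = p_key_active, p_key_decoy = p_key_decoy, seed = seed
  )
  out
}

#' Simulate Gaussian MM-PBSA frames
#'
#' Independent Gaussian draws per component per snapshot; at large frame
#' counts [summarize_frames()] recovers the requested means.
#'
#' @param means,sds Named numeric vectors over `E_vdW`, `E_ele`, `G_polar`,
#'   `G_nonpolar` (kJ/mol).
#' @param n_frames Number of snapshots (default 10).
#' @param seed Integer seed.
#' @return Frame tibble (with a `frame` column) for [summarize_frames()].
#' @export
simulate_energy_frames <- function(means = c(
                                     E_vdW = -310.59, E_ele = -36.47,
                                     G_polar = 118.63, G_nonpolar = -24.60
                                   ),
                                   sds = c(
                                     E_vdW = 13.49, E_ele = 1.89,
                                     G_polar = 6.81, G_nonpolar = 0.20
                                   ),
                                   n_frames = 10, seed = 1) {
  stopifnot(n_frames >= 1, all(sds >= 0))
  comp <- c("E_vdW", "E_ele", "G_polar", "G_nonpolar")
  set.seed(seed)
  draws <- lapply(comp, function(cn) {
    stats::rnorm(n_frames, mean = means[[cn]], sd = sds[[cn]])
  })
  names(draws) <- comp
  tibble::as_tibble(c(list(frame = seq_len(n_frames)), draws))
}

#' Simulate per-residue contribution frames
#'
#' @param residue_means Named numeric vector of per-residue mean
#'   contributions (kJ/mol).
#' @param residue_sds Standard deviation(s), recycled over residues
#'   (default 0.5).
#' @param n_frames Number of snapshots.
#' @param seed Integer seed.
#' @return Long tibble (`frame`, `residue`, `energy`) for
#'   [residue_decomposition()].
#' @export
simulate_residue_frames <- function(residue_means, residue_sds = 0.5,
                                    n_frames = 10, seed = 1) {
  set.seed(seed)
  residue_sds <- rep_len(residue_sds, length(residue_means))
  tidyr::expand_grid(
    frame = seq_len(n_frames),
    residue = names(residue_means)
  ) |>
    dplyr::mutate(
      energy = stats::rnorm(
        dplyr::n(),
        mean = residue_means[.data$residue],
        sd = residue_sds[match(.data$residue, names(residue_means))]
      )
    )
}
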