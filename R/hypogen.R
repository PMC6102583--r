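#' Generate common-feature pharmacophore hypotheses from a training set
#'
#' A simplified common-feature (qualitative) hypothesis generator. A reference
#' compound is taken from the highly active (`principal = 2`) training
#' members; every 3- to 5-point subset of its perceived feature points becomes
#' a candidate hypothesis, and a candidate is kept only if every
#' `principal = 2`, `max_omit = 0` training compound maps onto it with no
#' feature omitted. Compounds with `principal = 0` / `max_omit = 2` carry no
#' constraint (their features may all be ignored) but still contribute their
#' fitvalue when they happen to map. Up to `max_ev` excluded-volume spheres
#' are then placed at consensus void positions -- points near the model that
#' no mapped training conformer's heavy atoms approach. Candidates are ranked
#' by `rank_score`, the sum of training-set fitvalues.
#'
#' @param training Molecule tibble with columns `principal` (0 or 2) and
#'   `max_omit` (0 or 2). Features must be available (pre-assigned or
#'   perceivable).
#' @param max_ev Maximum excluded volumes per model (default 5).
#' @param n_models Maximum number of ranked models returned (default 10).
#' @param tolerance,weight Feature tolerance radius (Angstrom) and weight
#'   given to every candidate feature sphere.
#' @param ev_radius Excluded-volume radius (Angstrom, default 1.2).
#' @param subset_sizes Feature-subset sizes to enumerate (default 3:5).
#' @param seed Integer seed (used for the excluded-volume candidate shell).
#' @return List of `phore_model` objects, rank score non-increasing; empty
#'   list (with a message) if no common subset exists.
#' @export
generate_common_feature_models <- function(training, max_ev = 5, n_models = 10,
                                           tolerance = 1.6, weight = 1,
                                           ev_radius = 1.2,
                                           subset_sizes = 3:5, seed = 1) {
  if (!all(c("principal", "max_omit") %in% names(training))) {
    stop("training table needs 'principal' and 'max_omit' columns", call. = FALSE)
  }
  principal <- which(training$principal == 2)
  if (length(principal) < 2) {
    stop("need at least two principal (principal = 2) training compounds",
      call. = FALSE
    )
  }
  training <- perceive_features(training)
  must_map <- which(training$principal == 2 & training$max_omit == 0)

  ref_idx <- principal[1]
  ref_feats <- training$features[[ref_idx]]
  nf <- nrow(ref_feats)
  sizes <- subset_sizes[subset_sizes <= nf & subset_sizes >= 1]
  if (length(sizes) == 0) {
    message("reference compound has too few features (", nf, ")")
    return(list())
  }

  candidates <- list()
  for (s in sizes) {
    for (sub in asplit(utils::combn(nf, s), 2)) {
      feats <- ref_feats[sub, , drop = FALSE]
      model <- pharmacophore_model(
        paste0("Hypo_", paste(sub, collapse = ".")),
        tibble::tibble(
          kind = feats$kind, x = feats$x, y = feats$y, z = feats$z,
          tolerance = tolerance, weight = weight
        )
      )
      maps <- map_ligand(training, model, allow_omit = 0)
      if (!all(maps$mapped[must_map])) next
      rank_score <- sum(maps$fitvalue[maps$mapped])
      candidates[[length(candidates) + 1]] <- list(
        model = model, rank_score = rank_score, maps = maps
      )
    }
  }
  if (length(candidates) == 0) {
    message("no common feature subset maps every constrained training compound")
    return(list())
  }
  ord <- order(-vapply(candidates, `[[`, 0, "rank_score"))
  candidates <- candidates[ord[seq_len(min(n_models, length(candidates)))]]

  purrr::imap(candidates, function(cand, i) {
    ev <- consensus_excluded_volumes(
      cand$model, cand$maps, training, max_ev, ev_radius,
      seed = seed + i
    )
    pharmacophore_model(
      paste0("Hypo", i),
      cand$model$features,
      excluded_volumes = ev,
      rank_score = cand$rank_score
    )
  })
}

# Excluded volumes at consensus voids: sample a deterministic shell of points
# around the feature centroid, keep those clear of every mapped training
# conformer's transformed heavy atoms, pick a spread-out subset.
consensus_excluded_volumes <- function(model, maps, training, max_ev,
                                       ev_radius, seed, clearance = 1.0) {
  if (max_ev <= 0) {
    return(NULL)
  }
  centers <- as_coord_matrix(model$features[, c("x", "y", "z")])
  centroid <- colMeans(centers)
  shell_r <- max(sqrt(rowSums(sweep(centers, 2, centroid)^2))) + 2.5
  set.seed(seed %% .Machine$integer.max)
  n_cand <- 200
  u <- matrix(stats::rnorm(3 * n_cand), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  cand <- sweep(u * shell_r, 2, centroid, "+")

  # collect heavy atoms of every mapped training molecule in the model frame
  atoms <- list()
  for (i in seq_len(nrow(maps))) {
    if (!maps$mapped[i]) next
    heavy <- training$atoms[[i]]$elem != "H"
    coords <- training$conformers[[i]][[maps$conformer[i]]]
    atoms[[length(atoms) + 1]] <-
      transform_points(coords[heavy, , drop = FALSE], maps$transform[[i]])
  }
  occ <- do.call(rbind, atoms)
  min_clear <- ev_radius + clearance
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    d2 <- rowSums(sweep(occ, 2, cand[i, ])^2)
    min(d2) >= min_clear^2
  }, TRUE)
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  # greedy farthest-point selection for spatial spread
  sel <- 1L
  while (length(sel) < min(max_ev, nrow(cand))) {
    dmin <- apply(cand, 1, function(p) {
      min(sqrt(rowSums(sweep(cand[sel, , drop = FALSE], 2, p)^2)))
    })
    dmin[sel] <- -Inf
    sel <- c(sel, which.max(dmin))
  }
  tibble::tibble(
    x = cand[sel, 1], y = cand[sel, 2], z = cand[sel, 3], radius = ev_radius
  )
}
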