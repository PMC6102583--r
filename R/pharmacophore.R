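#' Construct a pharmacophore model
#'
#' A pharmacophore hypothesis is a named set of typed feature spheres
#' (hydrogen-bond acceptor `A`, donor `D`, hydrophobe `H`, aromatic ring `R`;
#' each with a 3D center, a tolerance radius and a weight) plus optional
#' excluded-volume spheres that no ligand heavy atom may occupy.
#'
#' @param name Model name.
#' @param features Tibble/data frame with columns `kind`, `x`, `y`, `z` and
#'   optionally `tolerance` (Angstrom, default 1.6) and `weight` (default 1).
#' @param excluded_volumes Optional tibble with `x`, `y`, `z` and `radius`
#'   (default 1.2 Angstrom).
#' @param rank_score Optional unitless rank score (sum of training-set
#'   fitvalues for generated hypotheses).
#' @return An object of class `phore_model`.
#' @examples
#' pharmacophore_model(
#'   "toy",
#'   tibble::tibble(kind = c("A", "H"), x = c(0, 3), y = 0, z = 0)
#' )
#' @export
pharmacophore_model <- function(name, features, excluded_volumes = NULL,
                                rank_score = NA_real_) {
  features <- tibble::as_tibble(features)
  if (!"tolerance" %in% names(features)) features$tolerance <- 1.6
  if (!"weight" %in% names(features)) features$weight <- 1
  features <- features[, c("kind", "x", "y", "z", "tolerance", "weight")]
  if (is.null(excluded_volumes)) {
    excluded_volumes <- tibble::tibble(
      x = double(), y = double(), z = double(), radius = double()
    )
  } else {
    excluded_volumes <- tibble::as_tibble(excluded_volumes)
    if (!"radius" %in% names(excluded_volumes)) excluded_volumes$radius <- 1.2
    excluded_volumes <- excluded_volumes[, c("x", "y", "z", "radius")]
  }
  model <- structure(
    list(
      name = as.character(name),
      features = features,
      excluded_volumes = excluded_volumes,
      rank_score = as.numeric(rank_score)
    ),
    class = "phore_model"
  )
  validate_phore_model(model)
  model
}

#' Validate a pharmacophore model
#'
#' Checks the schema used by [pharmacophore_model()] and the YAML reader:
#' feature kinds drawn from `A`/`D`/`H`/`R`, strictly positive tolerance and
#' excluded-volume radii, finite coordinates.
#'
#' @param model A `phore_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_phore_model <- function(model) {
  f <- model$features
  if (nrow(f) == 0) stop("model has no features", call. = FALSE)
  bad_kind <- setdiff(unique(f$kind), c("A", "D", "H", "R"))
  if (length(bad_kind) > 0) {
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(as.matrix(f[, c("x", "y", "z")])))) {
    stop("non-finite feature coordinates", call. = FALSE)
  }
  if (any(f$tolerance <= 0)) stop("tolerance radii must be > 0", call. = FALSE)
  if (any(f$weight < 0)) stop("feature weights must be >= 0", call. = FALSE)
  ev <- model$excluded_volumes
  if (nrow(ev) > 0 && any(ev$radius <= 0)) {
    stop("excluded-volume radii must be > 0", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.phore_model <- function(x, ...) {
  comp <- table(x$features$kind)
  cat(
    "<phore_model> ", x$name, ": ",
    paste0(comp, "x", names(comp), collapse = ", "),
    ", ", nrow(x$excluded_volumes), " excluded volume(s)",
    if (!is.na(x$rank_score)) paste0(", rank score ", round(x$rank_score, 2)),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write pharmacophore models as YAML
#'
#' The on-disk schema is
#' `name`, `features: [{kind, center: [x, y, z], tolerance, weight}]`,
#' `excluded_volumes: [{center: [x, y, z], radius}]`, optional `rank_score`.
#'
#' @param path File path.
#' @return `read_phore_model()` returns a validated `phore_model`;
#'   `write_phore_model()` returns `path` invisibly.
#' @export
read_phore_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$features)) {
    stop("model file must have 'name' and 'features'", call. = FALSE)
  }
  feats <- purrr::map_dfr(y$features, function(f) {
    tibble::tibble(
      kind = f$kind,
      x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
      tolerance = f$tolerance %||% 1.6,
      weight = f$weight %||% 1
    )
  })
  ev <- NULL
  if (!is.null(y$excluded_volumes) && length(y$excluded_volumes) > 0) {
    ev <- purrr::map_dfr(y$excluded_volumes, function(e) {
      tibble::tibble(
        x = e$center[[1]], y = e$center[[2]], z = e$center[[3]],
        radius = e$radius %||% 1.2
      )
    })
  }
  pharmacophore_model(y$name, feats, ev, y$rank_score %||% NA_real_)
}

#' @rdname read_phore_model
#' @param model A `phore_model`.
#' @export
write_phore_model <- function(model, path) {
  y <- list(
    name = model$name,
    features = purrr::pmap(model$features, function(kind, x, y, z, tolerance, weight) {
      list(kind = kind, center = c(x, y, z), tolerance = tolerance, weight = weight)
    }),
    excluded_volumes = purrr::pmap(model$excluded_volumes, function(x, y, z, radius) {
      list(center = c(x, y, z), radius = radius)
    })
  )
  if (!is.na(model$rank_score)) y$rank_score <- model$rank_score
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Map ligands onto a pharmacophore model
#'
#' For every molecule, searches over all conformers and all kind-compatible
#' injective assignments of model features to perceived ligand feature points
#' (omitting at most `allow_omit` model features) for the least-squares rigid
#' superposition that places every matched ligand feature inside its model
#' feature's tolerance sphere while keeping all ligand heavy atoms out of the
#' excluded volumes. Among valid placements the one with maximal fitvalue
#' wins; ties break deterministically toward fewer omitted features, lower
#' conformer index, then lexicographically earliest assignment.
#'
#' The search is an exhaustive enumeration, intended for the small feature
#' counts (3-8 per side) typical of pharmacophore hypotheses.
#'
#' @param molecules Molecule tibble. Features are taken from the `features`
#'   column when pre-assigned (synthetic feature clouds) and perceived with
#'   [perceive_features()] rules per conformer otherwise.
#' @param model A `phore_model`.
#' @param allow_omit Maximum number of model features that may be left
#'   unmatched (default 0).
#' @return A tibble with one row per molecule: `id`, `mapped`, `conformer`,
#'   `fitvalue`, `n_omitted`, and list-columns `assignment` (model feature ->
#'   ligand feature row, NA = omitted), `displacements` (Angstrom) and
#'   `transform`; unmapped molecules carry the `reason`.
#' @export
map_ligand <- function(molecules, model, allow_omit = 0) {
  validate_phore_model(model)
  res <- purrr::pmap(
    list(molecules$id, molecules$atoms, molecules$bonds, molecules$sdf,
         molecules$conformers, molecules$features),
    function(id, atoms, bonds, sdf, conformers, feats) {
      map_one(id, atoms, bonds, sdf, conformers, feats, model, allow_omit)
    }
  )
  dplyr::bind_rows(res)
}

map_one <- function(id, atoms, bonds, sdf, conformers, feats, model,
                    allow_omit) {
  unmapped <- function(reason) {
    tibble::tibble(
      id = id, mapped = FALSE, conformer = NA_integer_,
      fitvalue = NA_real_, n_omitted = NA_integer_,
      assignment = list(NULL), displacements = list(NULL),
      transform = list(NULL), reason = reason
    )
  }
  if (length(conformers) == 0) {
    return(unmapped("no conformers"))
  }
  precomputed <- !is.null(feats)
  defs <- if (precomputed) NULL else feature_defs(atoms, bonds, sdf)
  heavy <- atoms$elem != "H"
  n_conf <- if (precomputed) 1L else length(conformers)

  best <- NULL
  for (ci in seq_len(n_conf)) {
    coords <- conformers[[ci]]
    lig <- if (precomputed) feats else features_for_conformer(defs, coords, atoms)
    if (nrow(lig) == 0) next
    cand <- best_assignment(model, lig, coords[heavy, , drop = FALSE], allow_omit)
    if (!is.null(cand) && (is.null(best) || cand$fitvalue > best$fitvalue ||
      (cand$fitvalue == best$fitvalue && cand$n_omitted < best$n_omitted))) {
      cand$conformer <- ci
      best <- cand
    }
  }
  if (is.null(best)) {
    has_any <- if (precomputed) nrow(feats) > 0 else length(defs) > 0
    return(unmapped(if (!has_any) "no features perceived" else "no valid placement"))
  }
  tibble::tibble(
    id = id, mapped = TRUE, conformer = best$conformer,
    fitvalue = best$fitvalue, n_omitted = best$n_omitted,
    assignment = list(best$assignment),
    displacements = list(best$displacements),
    transform = list(best$transform), reason = NA_character_
  )
}

# Exhaustive search over omission subsets and kind-compatible injective
# assignments for one conformer. Returns the best valid placement or NULL.
best_assignment <- function(model, lig_feats, heavy_coords, allow_omit) {
  mf <- model$features
  k <- nrow(mf)
  ev <- model$excluded_volumes
  lig_xyz <- as_coord_matrix(lig_feats)
  best <- NULL

  for (n_omit in 0:min(allow_omit, k - 1)) {
    omit_sets <- if (n_omit == 0) list(integer(0)) else {
      asplit(utils::combn(k, n_omit), 2)
    }
    for (omit in omit_sets) {
      matched <- setdiff(seq_len(k), omit)
      cands <- lapply(matched, function(i) which(lig_feats$kind == mf$kind[i]))
      if (any(lengths(cands) == 0)) next
      assigns <- injective_assignments(cands)
      for (a in assigns) {
        L <- lig_xyz[a, , drop = FALSE]
        Tm <- as_coord_matrix(mf[matched, c("x", "y", "z")])
        fit <- kabsch_fit(L, Tm)
        disp <- sqrt(rowSums((transform_points(L, fit) - Tm)^2))
        if (any(disp > mf$tolerance[matched])) next
        if (nrow(ev) > 0 && nrow(heavy_coords) > 0) {
          ha <- transform_points(heavy_coords, fit)
          viol <- FALSE
          for (e in seq_len(nrow(ev))) {
            d2 <- rowSums((ha - matrix(as.numeric(ev[e, c("x", "y", "z")]),
              nrow(ha), 3,
              byrow = TRUE
            ))^2)
            if (any(d2 < ev$radius[e]^2)) {
              viol <- TRUE
              break
            }
          }
          if (viol) next
        }
        fv <- sum(mf$weight[matched] *
          pmax(0, 1 - (disp / mf$tolerance[matched])^2))
        if (is.null(best) || fv > best$fitvalue) {
          assignment <- rep(NA_integer_, k)
          assignment[matched] <- a
          displacements <- rep(NA_real_, k)
          displacements[matched] <- disp
          best <- list(
            fitvalue = fv, n_omitted = n_omit,
            assignment = assignment, displacements = displacements,
            transform = fit
          )
        }
      }
    }
  }
  best
}

# All injective choices, one element from each candidate set, in
# lexicographic order.
injective_assignments <- function(cands) {
  out <- list()
  rec <- function(i, chosen) {
    if (i > length(cands)) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    for (c_ in cands[[i]]) {
      if (!(c_ %in% chosen)) rec(i + 1, c(chosen, c_))
    }
  }
  rec(1, integer(0))
  out
}

#' Fitvalue of a mapping
#'
#' The overlay score of a mapped ligand: the weighted sum over matched
#' features of `1 - (displacement / tolerance)^2`, floored at zero per
#' feature. It equals the sum of feature weights exactly when every
#' displacement is zero and decreases monotonically as any displacement
#' grows.
#'
#' @param result One row of a [map_ligand()] result (or a tibble of rows).
#' @param model The `phore_model` the mapping was made against.
#' @return Numeric vector of fitvalues.
#' @export
fitvalue <- function(result, model) {
  if (any(!result$mapped)) {
    stop("fitvalue is undefined for unmapped results", call. = FALSE)
  }
  purrr::map2_dbl(result$displacements, result$assignment, function(d, a) {
    m <- !is.na(a)
    sum(model$features$weight[m] *
      pmax(0, 1 - (d[m] / model$features$tolerance[m])^2))
  })
}

#' Screen a library against a pharmacophore model
#'
#' Maps every molecule with [map_ligand()] and returns the hit list (mapped
#' molecules only), sorted by fitvalue descending.
#'
#' @inheritParams map_ligand
#' @return Tibble with `id`, `fitvalue`, `conformer`, sorted by fitvalue
#'   descending (ties by id).
#' @export
screen_library <- function(molecules, model, allow_omit = 0) {
  if (nrow(molecules) == 0) {
    return(tibble::tibble(
      id = character(), fitvalue = double(), conformer = integer()
    ))
  }
  map_ligand(molecules, model, allow_omit) |>
    dplyr::filter(.data$mapped) |>
    dplyr::select("id", "fitvalue", "conformer") |>
    dplyr::arrange(dplyr::desc(.data$fitvalue), .data$id)
}
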