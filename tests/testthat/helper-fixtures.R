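# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

# Canonical four-point arrangement used by toy models and feature clouds.
toy_feats <- function() {
  tibble::tibble(
    kind = c("A", "H", "H", "R"),
    x = c(0, 4, 2, 2), y = c(0, 0, 3.5, 1.2), z = c(0, 0, 0, 3)
  )
}

toy_model <- function(tolerance = 1.6, weight = 1, ev = NULL) {
  f <- toy_feats()
  f$tolerance <- tolerance
  f$weight <- weight
  pharmacophore_model("toy", f, excluded_volumes = ev)
}

# A feature-cloud molecule whose scaffold carbons sit at the feature points.
feature_cloud <- function(id, feats, extra_atoms = NULL) {
  atoms <- tibble::tibble(
    elem = "C", x = feats$x, y = feats$y, z = feats$z, charge = 0L
  )
  if (!is.null(extra_atoms)) atoms <- dplyr::bind_rows(atoms, extra_atoms)
  molecule_tbl(id, atoms = list(atoms), features = list(feats))
}

# Apply one rigid motion to a molecule's conformers and stored features.
rigid_move <- function(mol, R, t) {
  mol$conformers <- lapply(mol$conformers, function(confs) {
    lapply(confs, function(m) sweep(m %*% t(R), 2, t, "+"))
  })
  mol$features <- lapply(mol$features, function(f) {
    if (is.null(f)) return(NULL)
    xyz <- sweep(as.matrix(f[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
    f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
    f
  })
  mol$atoms <- lapply(mol$atoms, function(a) {
    xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a
  })
  mol
}

rot_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# --- independent superposition oracle: Horn's quaternion method -----------
# (different algorithm from the SVD-based fit in the package)
horn_fit <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  P <- sweep(source, 2, cs); Q <- sweep(target, 2, ct)
  S <- crossprod(P, Q)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
  fitted <- sweep(P %*% t(R), 2, ct, "+")
  list(fitted = fitted, rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

# --- brute-force mapping oracle -------------------------------------------
# Exhaustive enumeration over conformers, omission subsets and assignments,
# using the Horn superposition; independent of map_ligand's search code.
# Excluded volumes are not supported: use Ev-free models with this oracle.
oracle_map_one <- function(mol_row, model, allow_omit = 0) {
  mf <- model$features
  ev <- model$excluded_volumes
  stopifnot(nrow(ev) == 0)
  k <- nrow(mf)
  feats <- mol_row$features[[1]]
  stopifnot(!is.null(feats))  # oracle works on feature-cloud molecules
  confs <- list(mol_row$conformers[[1]][[1]])
  best <- NULL
  for (ci in seq_along(confs)) {
    lf <- feats
    lig_xyz <- as.matrix(lf[, c("x", "y", "z")])
    for (n_omit in 0:min(allow_omit, k - 1)) {
      omits <- if (n_omit == 0) list(integer(0)) else {
        asplit(utils::combn(k, n_omit), 2)
      }
      for (om in omits) {
        matched <- setdiff(seq_len(k), om)
        idx_sets <- lapply(matched, function(i) which(lf$kind == mf$kind[i]))
        grid <- expand.grid(idx_sets, stringsAsFactors = FALSE)
        if (nrow(grid) == 0) next
        for (g in seq_len(nrow(grid))) {
          a <- as.integer(grid[g, ])
          if (anyDuplicated(a)) next
          L <- lig_xyz[a, , drop = FALSE]
          Tm <- as.matrix(mf[matched, c("x", "y", "z")])
          hf <- horn_fit(L, Tm)
          disp <- sqrt(rowSums((hf$fitted - Tm)^2))
          if (any(disp > mf$tolerance[matched] + 1e-9)) next
          fv <- sum(mf$weight[matched] * pmax(0, 1 - (disp / mf$tolerance[matched])^2))
          if (is.null(best) || fv > best$fitvalue + 1e-12) {
            best <- list(fitvalue = fv, mapped = TRUE)
          }
        }
      }
    }
  }
  if (is.null(best)) list(mapped = FALSE, fitvalue = NA_real_) else best
}

# Scalar index oracle for validation statistics.
oracle_indices <- function(D, A, Ha, Ht) {
  HRA <- 100 * Ha / A
  IEI <- if (Ht == 0) NA_real_ else (Ha / Ht) / (A / D)
  c(HRA = HRA, IEI = IEI, CAI = (HRA / 100) * IEI)
}

# The printed ten-hypothesis validation table used as input counts
# (columns: rank score, D, A, Ha, Ht and the printed index values).
printed_validation_table <- function() {
  tibble::tribble(
    ~Hypo, ~rank_score, ~D, ~A, ~Ha, ~Ht, ~HRA_printed, ~IEI_printed, ~CAI_printed,
    1L, 157.40, 616L, 154L, 145L, 256L, 94.16, 2.26, 2.12,
    2L, 156.97, 616L, 154L, 147L, 290L, 95.45, 2.03, 1.93,
    3L, 156.45, 616L, 154L, 138L, 271L, 89.61, 2.04, 1.83,
    4L, 155.73, 616L, 154L, 138L, 278L, 89.61, 1.99, 1.78,
    5L, 155.62, 616L, 154L, 147L, 265L, 95.45, 2.22, 2.12,
    6L, 155.54, 616L, 154L, 151L, 268L, 98.05, 2.25, 2.21,
    7L, 154.89, 616L, 154L, 106L, 247L, 68.83, 1.72, 1.18,
    8L, 154.67, 616L, 154L, 126L, 219L, 81.81, 2.30, 1.88,
    9L, 154.43, 616L, 154L, 144L, 267L, 93.50, 2.16, 2.02,
    10L, 154.43, 616L, 154L, 143L, 254L, 92.86, 2.25, 2.09
  )
}
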