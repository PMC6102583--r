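#' Least-squares rigid superposition of two point sets
#'
#' Finds the rotation and translation that superpose `source` onto `target`
#' with minimal root-mean-square deviation (the Kabsch algorithm). Used for
#' overlaying ligand feature points onto pharmacophore feature centers and for
#' trajectory RMSD/RMSF fitting.
#'
#' @param source Numeric matrix (n x 3) of coordinates to move.
#' @param target Numeric matrix (n x 3) of reference coordinates, row-paired
#'   with `source`.
#' @return A list with `rotation` (3 x 3 matrix), `translation` (length-3
#'   vector), and `rmsd` (Angstrom). The fitted coordinates of any point set
#'   `X` are `transform_points(X, fit)`.
#' @examples
#' p <- matrix(rnorm(12), ncol = 3)
#' th <- 0.7
#' rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- kabsch_fit(p %*% rot + 5, p)
#' fit$rmsd  # ~0
#' @export
kabsch_fit <- function(source, target) {
  source <- as_coord_matrix(source)
  target <- as_coord_matrix(target)
  stopifnot(nrow(source) == nrow(target))
  n <- nrow(source)
  cs <- colMeans(source)
  ct <- colMeans(target)
  P <- sweep(source, 2, cs)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)  # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum((fitted - Q)^2) / n)
  list(
    rotation = R,
    translation = as.numeric(ct - cs %*% t(R)),
    rmsd = rmsd
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param x Numeric matrix (n x 3).
#' @param fit A transform as returned by [kabsch_fit()].
#' @return Transformed n x 3 matrix.
#' @export
transform_points <- function(x, fit) {
  x <- as_coord_matrix(x)
  sweep(x %*% t(fit$rotation), 2, fit$translation, "+")
}

# Coerce tibble/data.frame with x,y,z columns or matrix to an n x 3 matrix.
as_coord_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, c("x", "y", "z")])
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  x
}

#' Embed points from a pairwise distance matrix
#'
#' Classical multidimensional scaling into three dimensions. Used to realize a
#' planted pharmacophore feature arrangement specified by its pairwise
#' distances. Distances that violate the triangle inequality (or are otherwise
#' not embeddable in 3D within tolerance) raise an error.
#'
#' @param d Symmetric matrix of pairwise distances (Angstrom).
#' @param tol Maximum allowed absolute deviation between requested and
#'   realized distances (Angstrom).
#' @return An n x 3 coordinate matrix reproducing `d` within `tol`.
#' @export
embed_distances <- function(d, tol = 1e-6) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n == 1) {
    return(matrix(0, 1, 3))
  }
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = min(3L, n - 1L)))
  coords <- matrix(0, n, 3)
  coords[, seq_len(ncol(xy))] <- xy
  realized <- as.matrix(stats::dist(coords))
  if (max(abs(realized - d)) > tol) {
    stop(
      "distance matrix is not embeddable in 3D (max deviation ",
      format(max(abs(realized - d)), digits = 3), " Å); ",
      "check the planted feature distances for triangle-inequality violations",
      call. = FALSE
    )
  }
  coords
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Rotate coordinates about the axis through points a, b by angle (radians);
# only rows in `idx` move. Used for torsion driving in conformer generation.
rotate_about_axis <- function(coords, a, b, angle, idx) {
  axis <- b - a
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, axis[3], -axis[2],
    -axis[3], 0, axis[1],
    axis[2], -axis[1], 0
  ), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  moved <- sweep(coords[idx, , drop = FALSE], 2, a)
  coords[idx, ] <- sweep(moved %*% t(R), 2, a, "+")
  coords
}
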