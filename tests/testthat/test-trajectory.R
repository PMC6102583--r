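# Build a trajectory tibble from a list of coordinate matrices.
traj_from_mats <- function(mats, residues = NULL) {
  n <- nrow(mats[[1]])
  if (is.null(residues)) residues <- sprintf("GLY%d", seq_len(n))
  purrr::imap_dfr(mats, function(m, f) {
    tibble::tibble(
      frame = f, atom = sprintf("a%03d", seq_len(n)), residue = residues,
      x = m[, 1], y = m[, 2], z = m[, 3]
    )
  })
}

test_that("RMSD of a frame against itself and a rotated copy is zero", {
  set.seed(2)
  base <- matrix(rnorm(300), ncol = 3)
  moved <- sweep(base %*% t(rot_z(1.3)), 2, c(5, -3, 2), "+")
  traj <- traj_from_mats(list(base, base, moved))
  r <- rmsd_series(traj)
  expect_equal(r$rmsd, c(0, 0, 0), tolerance = 1e-8)
})

test_that("single displaced atom gives the closed-form RMSD", {
  set.seed(5)
  base <- matrix(rnorm(300), ncol = 3)  # 100 atoms
  disp <- base
  disp[7, 1] <- disp[7, 1] + 1
  traj <- traj_from_mats(list(base, disp))
  raw <- rmsd_series(traj, fit = FALSE)
  expect_equal(raw$rmsd[2], sqrt(1 / 100), tolerance = 1e-12)
  fitted <- rmsd_series(traj, fit = TRUE)
  expect_lte(fitted$rmsd[2], raw$rmsd[2] + 1e-12)
  expect_gt(fitted$rmsd[2], 0.9 * raw$rmsd[2])
})

test_that("RMSD agrees with bio3d superposition on a random trajectory", {
  skip_if_not_installed("bio3d")
  set.seed(31)
  base <- matrix(rnorm(90), ncol = 3)
  mats <- lapply(1:4, function(i) base + matrix(rnorm(90, sd = 0.3), ncol = 3))
  traj <- traj_from_mats(mats)
  ours <- rmsd_series(traj)$rmsd
  ref_xyz <- as.vector(t(mats[[1]]))
  theirs <- vapply(mats, function(m) {
    bio3d::rmsd(ref_xyz, as.vector(t(m)), fit = TRUE)
  }, 0)
  expect_equal(ours, theirs, tolerance = 2e-3)  # bio3d prints 3 decimals
})

test_that("constant trajectories have zero RMSF everywhere", {
  base <- matrix(rnorm(60), ncol = 3)
  traj <- traj_from_mats(list(base, base, base))
  r <- rmsf_per_residue(traj)
  expect_true(all(abs(r$rmsf) < 1e-10))
  expect_equal(nrow(r), 20)  # one row per residue
  expect_error(rmsf_per_residue(traj_from_mats(list(base))), "two snapshots")
})

test_that("two-point oscillation gives RMSF = d for the moving residue only", {
  set.seed(9)
  base <- matrix(rnorm(150), ncol = 3)  # 50 atoms
  d <- 0.8
  up <- base; up[11, 3] <- up[11, 3] + d
  down <- base; down[11, 3] <- down[11, 3] - d
  traj <- traj_from_mats(list(up, down, up, down))
  r <- rmsf_per_residue(traj, fit = FALSE)
  expect_equal(r$rmsf[r$residue == "GLY11"], d, tolerance = 1e-12)
  expect_true(all(r$rmsf[r$residue != "GLY11"] < 1e-12))
  # with superposition the contamination of fixed residues stays small
  rf <- rmsf_per_residue(traj, fit = TRUE)
  expect_equal(rf$rmsf[rf$residue == "GLY11"], d, tolerance = 0.05)
})

test_that("trajectory reader round-trips and selections filter residues", {
  base <- matrix(rnorm(30), ncol = 3)
  traj <- traj_from_mats(list(base, base + 0.1),
    residues = rep(c("PHE54", "LEU183"), each = 5)
  )
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(traj, tf)
  back <- read_trajectory_xyz(tf)
  expect_equal(back$x, traj$x, tolerance = 1e-9)
  sel <- rmsf_per_residue(dplyr::bind_rows(traj), selection = "PHE54")
  expect_equal(sel$residue, "PHE54")
  mism <- traj[-1, ]
  expect_error(rmsd_series(mism), "differs between frames")
})
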