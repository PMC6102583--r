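# Component means of the complexes' published MM-PBSA rows (kJ/mol), used as
# generator inputs and identity checks.
d99_row <- tibble::tibble(
  E_vdW = -310.59, E_ele = -36.47, G_polar = 118.63, G_nonpolar = -24.60
)
tak_row <- tibble::tibble(
  E_vdW = -374.76, E_ele = -32.18, G_polar = 149.79, G_nonpolar = -28.20
)

test_that("frame totals are the component sums", {
  expect_equal(frame_total(d99_row)$total, -253.03, tolerance = 1e-9)
  expect_equal(frame_total(tak_row)$total, -285.36, tolerance = 0.011)
  zeros <- tibble::tibble(E_vdW = 0, E_ele = 0, G_polar = 0, G_nonpolar = 0)
  expect_equal(frame_total(zeros)$total, 0)
  expect_equal(frame_total(zeros, entropy = 5)$total, 5)
  expect_error(frame_total(dplyr::mutate(zeros, E_vdW = NaN)), "non-finite")
})

test_that("frame summaries: identities and degenerate cases", {
  frames <- dplyr::bind_rows(rep(list(d99_row), 10))
  s <- summarize_frames(frames)
  expect_true(all(s$sd == 0))
  expect_equal(attr(s, "n_frames"), 10)
  # total mean equals the sum of component means
  expect_equal(
    s$mean[s$component == "total"],
    sum(s$mean[s$component != "total"]),
    tolerance = 1e-9
  )
  two <- dplyr::bind_rows(d99_row, tak_row)
  s2 <- summarize_frames(two)
  expect_equal(
    s2$mean[s2$component == "E_vdW"], (-310.59 + -374.76) / 2
  )
  expect_error(summarize_frames(two[0, ]), "no frames")
})

test_that("summaries recover planted Gaussian component means", {
  frames <- simulate_energy_frames(n_frames = 10000, seed = 42)
  s <- summarize_frames(frames)
  comp <- c(E_vdW = -310.59, E_ele = -36.47, G_polar = 118.63, G_nonpolar = -24.60)
  sds <- c(E_vdW = 13.49, E_ele = 1.89, G_polar = 6.81, G_nonpolar = 0.20)
  for (cn in names(comp)) {
    se <- sds[[cn]] / sqrt(10000)
    expect_lt(abs(s$mean[s$component == cn] - comp[[cn]]), 3 * se)
  }
  total_se <- sqrt(sum(sds^2)) / sqrt(10000)
  expect_lt(abs(s$mean[s$component == "total"] - (-253.03)), 3 * total_se)
})

test_that("three-species binding energy subtracts per component", {
  cpx <- dplyr::bind_rows(rep(list(d99_row), 3))
  prot <- dplyr::bind_rows(rep(list(dplyr::mutate(d99_row, E_vdW = -100)), 3))
  lig <- dplyr::bind_rows(rep(list(
    tibble::tibble(E_vdW = -10, E_ele = 0, G_polar = 0, G_nonpolar = 0)
  ), 3))
  be <- binding_energy(cpx, prot, lig)
  expect_equal(be$mean[be$component == "E_vdW"], -310.59 - (-100) - (-10))
})

test_that("nonpolar solvation follows the linear SASA model", {
  expect_equal(nonpolar_from_sasa(0, beta = 2.5), 2.5)
  expect_equal(nonpolar_from_sasa(1000, gamma = 0.0227, beta = 0), 22.7)
  expect_equal(
    nonpolar_from_sasa(2000, beta = 0),
    2 * nonpolar_from_sasa(1000, beta = 0)
  )
  expect_error(nonpolar_from_sasa(-1), "sasa")
})

test_that("per-residue decomposition: shape, recovery, and errors", {
  one <- tibble::tibble(
    frame = 1L, residue = c("PHE54", "LEU183"), energy = c(-10.5, -2.3)
  )
  d1 <- residue_decomposition(one)
  expect_equal(d1$sd, c(0, 0))
  expect_equal(d1$mean[d1$residue == "PHE54"], -10.5)

  means <- c(PHE54 = -10.56, LEU183 = -2.32, LEU211 = -11.55, PRO292 = -5.40)
  frames <- simulate_residue_frames(means, residue_sds = 0.5,
                                    n_frames = 4000, seed = 13)
  dec <- residue_decomposition(frames, residues = names(means))
  expect_equal(dec$residue, names(means))  # 4-row table, requested order
  se <- 0.5 / sqrt(4000)
  for (r in names(means)) {
    expect_lt(abs(dec$mean[dec$residue == r] - means[[r]]), 3 * se)
  }
  rng <- attr(dec, "range")
  expect_true(rng[1] <= min(dec$mean) + 1e-12 && rng[2] >= max(dec$mean) - 1e-12)

  bad <- dplyr::bind_rows(one, tibble::tibble(
    frame = 2L, residue = "PHE54", energy = -9
  ))
  expect_error(residue_decomposition(bad), "inconsistent")
  expect_error(residue_decomposition(frames, residues = "XXX1"), "absent")
})

test_that("energy tables round-trip through the text readers", {
  frames <- simulate_energy_frames(n_frames = 5, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(frames, tf)
  back <- read_energy_frames(tf)
  expect_equal(back$E_vdW, frames$E_vdW, tolerance = 1e-9)

  rf <- simulate_residue_frames(c(PHE54 = -10), n_frames = 3, seed = 1)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rf, tf2)
  expect_equal(read_residue_frames(tf2)$energy, rf$energy, tolerance = 1e-9)
})
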