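test_that("library generation is a pure function of spec and seed", {
  spec <- benchmark_spec(n_actives = 8, n_decoys = 12, seed = 42)
  a <- make_library(spec)
  b <- make_library(spec)
  expect_identical(attr(a, "manifest"), attr(b, "manifest"))
  expect_equal(a$features, b$features)
  c_ <- make_library(benchmark_spec(n_actives = 8, n_decoys = 12, seed = 43))
  expect_false(identical(attr(a, "manifest")$planted, attr(c_, "manifest")$planted))
})

test_that("zero-jitter actives map the planted model with maximal fitvalue", {
  spec <- benchmark_spec(n_actives = 12, n_decoys = 0, jitter_sd = 0, seed = 7)
  lib <- make_library(spec)
  model <- planted_phore_model(spec)
  res <- map_ligand(lib, model)
  expect_true(all(res$mapped))
  expect_equal(res$fitvalue, rep(sum(model$features$weight), 12),
    tolerance = 1e-6
  )
})

test_that("active hit rate decays monotonically with jitter", {
  rate <- vapply(c(0, 0.5, 1, 2), function(j) {
    spec <- benchmark_spec(n_actives = 25, n_decoys = 0, jitter_sd = j, seed = 19)
    lib <- make_library(spec)
    nrow(screen_library(lib, planted_phore_model(spec))) / 25
  }, 0)
  expect_true(all(diff(rate) <= 0))
  expect_equal(rate[1], 1)
})

test_that("infeasible planted distances are rejected", {
  d <- matrix(c(0, 1, 10, 1, 0, 1, 10, 1, 0), 3, 3)
  spec <- benchmark_spec(kinds = c("A", "H", "R"), distances = d, seed = 1)
  expect_error(make_library(spec), "not embeddable")
})

test_that("hit sets realize exact confusion counts", {
  hs <- make_hit_set(616, 154, 145, 256, seed = 5)
  s <- evaluate_model(hs$labels, hs$hits)
  expect_equal(c(s$D, s$A, s$Ha, s$Ht), c(616, 154, 145, 256))
  expect_equal(round(s$HRA, 2), 94.16)

  s2 <- evaluate_model(
    make_hit_set(10, 5, 5, 5, seed = 1)$labels,
    make_hit_set(10, 5, 5, 5, seed = 1)$hits
  )
  expect_equal(s2$HRA, 100)
  expect_equal(s2$IEI, 2)
  expect_error(make_hit_set(10, 5, 6, 6), "infeasible")
})

test_that("docking simulation plants the stated effect", {
  labels <- tibble::tibble(
    id = sprintf("m%03d", 1:100),
    label = rep(c("active", "inactive"), 50)
  )
  # degenerate generator: no effect, no noise -> all scores identical
  sim0 <- simulate_docking(labels, effect = 0, noise_sd = 0, seed = 1)
  expect_equal(length(unique(sim0$records$score_energy)), 1)
  kept <- docking_threshold_filter(sim0$records, sim0$reference, fraction = 0.6)
  expect_equal(nrow(kept), 100)  # threshold below the base level keeps all

  # reference scores are echoed into the reference record
  expect_equal(sim0$reference$score_energy, 51.30)
  expect_equal(sim0$reference$score_interaction, 61.78)

  sim <- simulate_docking(labels, effect = 10, noise_sd = 3, seed = 8)
  by_label <- split(sim$records$score_energy, labels$label)
  expect_gt(mean(by_label$active), mean(by_label$inactive))
  sim_b <- simulate_docking(labels, effect = 10, noise_sd = 3, seed = 8)
  expect_equal(sim$records, sim_b$records)
})

test_that("energy-frame simulation is seed-stable with recoverable means", {
  f0 <- simulate_energy_frames(sds = c(
    E_vdW = 0, E_ele = 0, G_polar = 0, G_nonpolar = 0
  ), n_frames = 6, seed = 2)
  expect_equal(length(unique(frame_total(f0)$total)), 1)

  a <- simulate_energy_frames(n_frames = 50, seed = 3)
  b <- simulate_energy_frames(n_frames = 50, seed = 3)
  expect_identical(a, b)
  c_ <- simulate_energy_frames(n_frames = 5000, seed = 4)
  d_ <- simulate_energy_frames(n_frames = 5000, seed = 5)
  expect_false(identical(c_, d_))
  # two seeds, same recovered totals within Monte-Carlo tolerance
  expect_equal(
    mean(frame_total(c_)$total), mean(frame_total(d_)$total),
    tolerance = 0.01
  )
})
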