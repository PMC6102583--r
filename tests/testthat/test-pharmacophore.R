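test_that("a ligand matching the model exactly maps with maximal fitvalue", {
  model <- toy_model()
  mol <- feature_cloud("exact", toy_feats())
  res <- map_ligand(mol, model)
  expect_true(res$mapped)
  expect_equal(res$fitvalue, sum(model$features$weight))
  expect_equal(max(res$displacements[[1]], na.rm = TRUE), 0, tolerance = 1e-8)
})

test_that("an atom inside an excluded volume blocks the mapping", {
  ev <- tibble::tibble(x = 1, y = 1, z = 1, radius = 1.2)
  model <- toy_model(ev = ev)
  clean <- feature_cloud("clean", toy_feats())
  expect_true(map_ligand(clean, model)$mapped)
  blocked <- feature_cloud(
    "blocked", toy_feats(),
    extra_atoms = tibble::tibble(elem = "C", x = 1, y = 1, z = 1, charge = 0L)
  )
  res <- map_ligand(blocked, model)
  expect_false(res$mapped)
})

test_that("fitvalue follows the quadratic-falloff formula", {
  model <- toy_model()
  tol <- model$features$tolerance[1]
  # fix the mapping frame with an exact cloud, then evaluate the formula at
  # hand-set displacements
  res <- map_ligand(feature_cloud("m", toy_feats()), model)
  res$displacements[[1]] <- c(0.5 * tol, 0.5 * tol, 0.5 * tol, 0)
  expect_equal(fitvalue(res, model), 3 * (1 - 0.25) + 1)  # 3.25
  res$displacements[[1]] <- c(tol, 0, 0, 0)  # boundary contributes zero
  expect_equal(fitvalue(res, model), 3)
  res$displacements[[1]] <- rep(0, 4)
  expect_equal(fitvalue(res, model), 4)
})

test_that("fitvalue errors on unmapped results", {
  model <- toy_model()
  far <- toy_feats()
  far$x <- far$x + c(0, 20, -20, 40)  # unmatchable geometry
  res <- map_ligand(feature_cloud("far", far), model)
  expect_false(res$mapped)
  expect_error(fitvalue(res, model), "unmapped")
})

test_that("mapping is invariant under rigid motion of the ligand", {
  model <- toy_model()
  f <- toy_feats()
  f$x <- f$x + c(0.3, -0.2, 0.1, 0)  # small distortions, still mappable
  mol <- feature_cloud("lig", f)
  res0 <- map_ligand(mol, model)
  moved <- rigid_move(mol, rot_z(2.2), c(-4, 7, 1))
  res1 <- map_ligand(moved, model)
  expect_true(res0$mapped && res1$mapped)
  expect_equal(res0$fitvalue, res1$fitvalue, tolerance = 1e-6)
  expect_equal(res0$displacements[[1]], res1$displacements[[1]], tolerance = 1e-6)
})

test_that("map_ligand agrees with exhaustive enumeration on a micro-benchmark", {
  model <- toy_model()
  set.seed(21)
  spec <- benchmark_spec(n_actives = 3, n_decoys = 2, jitter_sd = 0.4, seed = 21)
  lib <- make_library(spec)
  res <- map_ligand(lib, model, allow_omit = 1)
  for (i in seq_len(nrow(lib))) {
    oracle <- oracle_map_one(lib[i, ], model, allow_omit = 1)
    expect_equal(res$mapped[i], oracle$mapped, info = lib$id[i])
    if (oracle$mapped) {
      expect_equal(res$fitvalue[i], oracle$fitvalue,
        tolerance = 1e-6, info = lib$id[i]
      )
    }
  }
})

test_that("screen_library equals element-wise mapping, sorted by fitvalue", {
  model <- toy_model()
  lib <- make_library(benchmark_spec(n_actives = 10, n_decoys = 30, seed = 5))
  hits <- screen_library(lib, model)
  per_mol <- map_ligand(lib, model)
  expect_setequal(hits$id, per_mol$id[per_mol$mapped])
  expect_equal(hits$fitvalue, sort(hits$fitvalue, decreasing = TRUE))
  expect_equal(
    hits$fitvalue,
    per_mol$fitvalue[match(hits$id, per_mol$id)]
  )
  empty <- screen_library(lib[0, ], model)
  expect_equal(nrow(empty), 0)
})

test_that("model YAML round-trips and the validator rejects bad models", {
  ev <- tibble::tibble(x = 8, y = 0, z = 0, radius = 1.2)
  model <- pharmacophore_model("Hypo1", toy_feats(), ev, rank_score = 157.40)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_phore_model(model, tf)
  back <- read_phore_model(tf)
  expect_equal(back$name, model$name)
  expect_equal(back$features, model$features, tolerance = 1e-9)
  expect_equal(back$excluded_volumes, model$excluded_volumes, tolerance = 1e-9)
  expect_equal(back$rank_score, model$rank_score)

  f <- toy_feats()
  f$kind[1] <- "Q"
  expect_error(pharmacophore_model("bad", f), "unknown feature kind")
  f <- toy_feats()
  expect_error(
    pharmacophore_model("bad", dplyr::mutate(f, tolerance = 0)),
    "tolerance"
  )
})
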