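ref_record <- function() {
  tibble::tibble(
    id = "REF", score_energy = 51.30, score_interaction = 61.78,
    interactions = list(tibble::tibble(
      residue = c("PHE54", "SER51", "ARG52", "SER53"),
      kind = c("hbond", "hbond", "hbond", "hbond")
    ))
  )
}

test_that("the 80% docking-score rule reproduces the reference decisions", {
  ref <- ref_record()
  cands <- tibble::tibble(
    id = c("near_miss_pass", "boundary", "low_energy"),
    score_energy = c(42.08, 51.30, 40.00),
    score_interaction = c(52.92, 61.78, 70.00),
    interactions = list(NULL, NULL, NULL)
  )
  kept <- docking_threshold_filter(cands, ref, fraction = 0.8)
  expect_setequal(kept$id, c("near_miss_pass", "boundary"))
  # thresholds are 41.04 and 49.424; (40, 70) fails on the first score
  expect_false("low_energy" %in% kept$id)
  # both-columns rule: either-mode would keep it
  either <- docking_threshold_filter(cands, ref, fraction = 0.8, mode = "either")
  expect_true("low_energy" %in% either$id)
})

test_that("threshold limiting cases", {
  ref <- ref_record()
  set.seed(3)
  recs <- tibble::tibble(
    id = sprintf("r%02d", 1:20),
    score_energy = runif(20, 10, 60),
    score_interaction = runif(20, 10, 70),
    interactions = rep(list(NULL), 20)
  )
  expect_equal(nrow(docking_threshold_filter(recs, ref, fraction = 1e-9)), 20)
  at1 <- docking_threshold_filter(recs, ref, fraction = 1)
  expect_true(all(at1$score_energy >= 51.30 & at1$score_interaction >= 61.78))
  expect_error(
    docking_threshold_filter(recs, c(score_energy = Inf, score_interaction = 1)),
    "finite"
  )
})

test_that("interaction frequency counts compounds, not events", {
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    score_energy = 1, score_interaction = 1,
    interactions = list(
      tibble::tibble(residue = c("LEU211", "LEU211"), kind = "hydrophobic"),
      tibble::tibble(residue = c("LEU211", "PHE54"), kind = "hydrophobic"),
      tibble::tibble(residue = "LEU211", kind = "hydrophobic")
    )
  )
  freq <- interaction_frequency(recs, kind = "hydrophobic")
  # compound a lists LEU211 twice but counts once
  expect_equal(freq$count[freq$residue == "LEU211"], 3L)
  expect_equal(freq$count[freq$residue == "PHE54"], 1L)
  expect_equal(nrow(interaction_frequency(recs[0, ])), 0)
})

test_that("interaction frequency is additive over disjoint record subsets", {
  labels <- tibble::tibble(
    id = sprintf("m%03d", 1:60),
    label = rep(c("active", "inactive"), 30)
  )
  sim <- simulate_docking(labels, seed = 17)
  recs <- sim$records
  f_all <- interaction_frequency(recs, kind = "hydrophobic")
  f1 <- interaction_frequency(recs[1:30, ], kind = "hydrophobic")
  f2 <- interaction_frequency(recs[31:60, ], kind = "hydrophobic")
  merged <- dplyr::full_join(f1, f2, by = "residue") |>
    dplyr::mutate(total = dplyr::coalesce(.data$count.x, 0L) +
      dplyr::coalesce(.data$count.y, 0L))
  expect_equal(
    f_all$count[order(f_all$residue)],
    merged$total[order(merged$residue)]
  )
})

test_that("key-residue overlap matches set intersection", {
  keys <- c("PHE54", "VAL179", "LEU183", "LEU211", "PRO292")
  rec <- tibble::tibble(
    id = "candidate",
    score_energy = 42.08, score_interaction = 52.92,
    interactions = list(tibble::tibble(
      residue = c("PHE54", "LEU183", "LEU211", "PRO292", "GLN212"),
      kind = c(rep("hydrophobic", 4), "hbond")
    ))
  )
  ov <- key_residue_overlap(rec, keys, kind = "hydrophobic")
  expect_equal(ov$n_overlap, 4L)
  expect_setequal(ov$overlap[[1]], c("PHE54", "LEU183", "LEU211", "PRO292"))

  none <- rec
  none$interactions <- list(tibble::tibble(residue = "TYR73", kind = "hydrophobic"))
  expect_equal(key_residue_overlap(none, keys)$n_overlap, 0L)
  full <- rec
  full$interactions <- list(tibble::tibble(residue = keys, kind = "hydrophobic"))
  expect_equal(key_residue_overlap(full, keys)$n_overlap, length(keys))
  expect_error(key_residue_overlap(rec, character(0)), "empty")
})

test_that("docking table round-trips through TSV", {
  labels <- tibble::tibble(id = c("a", "b"), label = c("active", "inactive"))
  sim <- simulate_docking(labels, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_docking_table(sim$records, tf)
  back <- read_docking_table(tf)
  expect_equal(back$id, sim$records$id)
  expect_equal(back$score_energy, sim$records$score_energy, tolerance = 1e-9)
  expect_equal(back$interactions, sim$records$interactions)
})

test_that("cascade survivor sets are nested for random configurations", {
  lib <- make_library(benchmark_spec(n_actives = 15, n_decoys = 45, seed = 4))
  labels <- tibble::tibble(id = lib$id, label = lib$label)
  sim <- simulate_docking(labels, seed = 4)
  model <- planted_phore_model(attr(lib, "spec"))
  set.seed(12)
  for (rep in 1:100) {
    cfg <- cascade_config(
      lipinski = FALSE,
      pharmacophore = rep <= 10,  # mapping is the slow stage; sample it
      docking = runif(1) < 0.8,
      overlap = runif(1) < 0.8,
      fraction = runif(1, 0.5, 1),
      min_overlap = sample(0:5, 1),
      score_mode = sample(c("both", "either"), 1)
    )
    res <- suppressWarnings(run_cascade(
      lib,
      model = model, docking = sim$records, reference = sim$reference,
      key_residues = sim$reference$interactions[[1]]$residue, config = cfg
    ))
    surv <- res$stages$survivors
    for (i in seq_along(surv)[-1]) {
      expect_true(all(surv[[i]] %in% surv[[i - 1]]))
    }
    expect_equal(res$stages$n, vapply(surv, length, 0L))
  }
})

test_that("disabling downstream stages leaves the pharmacophore hits", {
  lib <- make_library(benchmark_spec(n_actives = 10, n_decoys = 20, seed = 9))
  model <- planted_phore_model(attr(lib, "spec"))
  res <- run_cascade(
    lib,
    model = model,
    config = cascade_config(lipinski = FALSE, docking = FALSE, overlap = FALSE)
  )
  hits <- screen_library(lib, model)
  expect_setequal(res$candidates$id, hits$id)
})

test_that("the cascade enriches planted actives above the base rate", {
  spec <- benchmark_spec(n_actives = 30, n_decoys = 90, seed = 23)
  lib <- make_library(spec)
  labels <- tibble::tibble(id = lib$id, label = lib$label)
  sim <- simulate_docking(labels, effect = 10, noise_sd = 3, seed = 23)
  model <- planted_phore_model(spec)
  res <- suppressWarnings(run_cascade(
    lib,
    model = model, docking = sim$records, reference = sim$reference,
    key_residues = sim$reference$interactions[[1]]$residue,
    config = cascade_config(lipinski = FALSE, min_overlap = 3)
  ))
  final <- res$candidates$id
  n_active <- sum(labels$label[match(final, labels$id)] == "active")
  expect_gt(length(final), 0)
  bt <- binom.test(n_active, length(final), p = 30 / 120, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})
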