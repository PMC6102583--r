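#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Accepts a YAML file path or
#' a nested list; unknown keys error before any stage runs. Defaults mirror
#' the screening protocol the package implements end to end: conformer
#' search capped at 255 conformers in a 20 kcal/mol window, hypothesis
#' quality thresholds HRA 80% / IEI 2 / CAI 2, docking threshold at 80% of
#' the reference scores, and a 154-active / 462-decoy benchmark.
#'
#' @param config YAML path or list overriding any defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L,
    output_dir = NULL,
    benchmark = list(
      n_actives = 154L, n_decoys = 462L, jitter_sd = 0.3,
      n_extra_features = 2L, n_training = 6L
    ),
    hypotheses = list(
      n_models = 5L, max_ev = 5L, tolerance = 1.6, subset_min = 3L,
      subset_max = 5L
    ),
    thresholds = list(HRA = 80, IEI = 2, CAI = 2),
    conformers = list(max_count = 255L, energy_window = 20),
    docking = list(effect = 10, noise_sd = 3, base_fraction = 0.7),
    cascade = list(
      lipinski = FALSE, fraction = 0.8, score_mode = "both",
      min_overlap = 3L, kind = "hydrophobic", allow_omit = 0L
    ),
    energetics = list(enabled = TRUE, n_frames = 10L),
    profile = list(enabled = TRUE)
  )
  merged <- utils::modifyList(defaults, config)
  check_keys <- function(given, allowed, where) {
    extra <- setdiff(names(given), allowed)
    if (length(extra) > 0) {
      stop("unknown config key(s) in ", where, ": ",
        paste(extra, collapse = ", "),
        call. = FALSE
      )
    }
  }
  check_keys(config, names(defaults), "config")
  for (sec in setdiff(names(defaults), c("seed", "output_dir"))) {
    if (!is.null(config[[sec]])) {
      check_keys(config[[sec]], names(defaults[[sec]]), sec)
    }
  }
  structure(merged, class = "pipeline_config")
}

#' Run the full screening pipeline on a synthetic benchmark
#'
#' End-to-end deterministic run: generate a planted-signal training set and
#' test library, derive common-feature hypotheses, validate them (HRA / IEI /
#' CAI) and select the best, screen the library, refine hits through the
#' docking-consensus cascade on a simulated docking table, summarize
#' synthetic MM-PBSA frames, and reverse-profile the top candidate against
#' the generated hypothesis database. Identical config and seed give
#' identical results.
#'
#' @param config A [pipeline_config()], YAML path, or list.
#' @return Invisibly, a named list of stage results (`library`, `models`,
#'   `validation`, `best`, `hits`, `cascade`, `energy`, `profile`,
#'   `summary`). When `output_dir` is set, per-stage TSVs and a JSON summary
#'   (carrying the config hash, seed and package version) are written there.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  seed <- as.integer(cfg$seed)

  # --- synthetic inputs -------------------------------------------------
  train_spec <- benchmark_spec(
    n_actives = cfg$benchmark$n_training, n_decoys = 0,
    jitter_sd = cfg$benchmark$jitter_sd,
    n_extra_features = cfg$benchmark$n_extra_features,
    seed = seed + 1000L
  )
  training <- make_library(train_spec)
  training$principal <- 2
  training$max_omit <- 0

  test_spec <- benchmark_spec(
    n_actives = cfg$benchmark$n_actives, n_decoys = cfg$benchmark$n_decoys,
    jitter_sd = cfg$benchmark$jitter_sd,
    n_extra_features = cfg$benchmark$n_extra_features,
    seed = seed
  )
  library_tbl <- make_library(test_spec)
  labels <- tibble::tibble(id = library_tbl$id, label = library_tbl$label)

  # --- hypothesis generation and validation -----------------------------
  models <- generate_common_feature_models(
    training,
    max_ev = cfg$hypotheses$max_ev, n_models = cfg$hypotheses$n_models,
    tolerance = cfg$hypotheses$tolerance,
    subset_sizes = cfg$hypotheses$subset_min:cfg$hypotheses$subset_max,
    seed = seed
  )
  if (length(models) == 0) stop("hypothesis generation found no models", call. = FALSE)
  screens <- purrr::map(models, function(m) screen_library(library_tbl, m))
  validation <- purrr::imap(screens, function(h, i) {
    evaluate_model(labels, h$id) |>
      dplyr::mutate(
        Hypo = models[[i]]$name, rank_score = models[[i]]$rank_score,
        .before = 1
      )
  }) |> dplyr::bind_rows()
  best_idx <- select_best(
    validation,
    thresholds = unlist(cfg$thresholds)[c("HRA", "IEI", "CAI")]
  )
  best_model <- models[[best_idx]]
  hits <- screens[[best_idx]]

  # --- docking + cascade ------------------------------------------------
  dock <- simulate_docking(
    labels,
    effect = cfg$docking$effect, noise_sd = cfg$docking$noise_sd,
    base_fraction = cfg$docking$base_fraction, seed = seed + 2000L
  )
  key_res <- dock$reference$interactions[[1]]$residue
  cascade <- run_cascade(
    library_tbl,
    model = best_model, docking = dock$records,
    reference = dock$reference, key_residues = key_res,
    config = cascade_config(
      lipinski = cfg$cascade$lipinski,
      fraction = cfg$cascade$fraction, score_mode = cfg$cascade$score_mode,
      min_overlap = cfg$cascade$min_overlap, kind = cfg$cascade$kind,
      allow_omit = cfg$cascade$allow_omit
    )
  )

  # --- energetics (synthetic frames) ------------------------------------
  energy <- NULL
  if (isTRUE(cfg$energetics$enabled)) {
    frames <- simulate_energy_frames(
      n_frames = cfg$energetics$n_frames, seed = seed + 3000L
    )
    energy <- summarize_frames(frames)
  }

  # --- reverse profiling of the top candidate ---------------------------
  profile <- NULL
  if (isTRUE(cfg$profile$enabled) && nrow(cascade$candidates) > 0) {
    top <- library_tbl[library_tbl$id == cascade$candidates$id[1], ]
    profile <- profile_ligand(top, models)
  }

  summary <- list(
    package = "phorescreen",
    version = as.character(utils::packageVersion("phorescreen")),
    seed = seed,
    config_hash = rlang::hash(unclass(cfg)),
    stages = stats::setNames(
      as.list(cascade$stages$n), cascade$stages$stage
    ),
    n_models = length(models),
    best_model = best_model$name,
    best_HRA = validation$HRA[best_idx],
    best_IEI = validation$IEI[best_idx],
    best_CAI = validation$CAI[best_idx],
    n_final_candidates = nrow(cascade$candidates)
  )

  out <- list(
    library = library_tbl, models = models, validation = validation,
    best = best_model, hits = hits, cascade = cascade, energy = energy,
    profile = profile, summary = summary
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_tsv(x, file.path(cfg$output_dir, f))
    w(validation, "validation.tsv")
    w(hits, "hits.tsv")
    w(cascade$stages[, c("stage", "n")], "cascade_stages.tsv")
    w(cascade$candidates, "cascade_candidates.tsv")
    if (!is.null(energy)) w(tibble::as_tibble(energy), "energy_summary.tsv")
    if (!is.null(profile)) w(tibble::as_tibble(profile), "profile.tsv")
    for (m in models) {
      write_phore_model(m, file.path(cfg$output_dir, paste0(m$name, ".yaml")))
    }
    jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out)
}
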