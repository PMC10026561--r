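#' Build a pipeline configuration
#'
#' Collects everything a full analysis run needs: input paths (or a
#' synthetic-screen regime when no measured table is supplied), the
#' train/test split size, ensemble settings, the master seed that drives
#' every stochastic stage, and the design-rule query. The config is echoed
#' verbatim into the run manifest so any artifact can be traced to its
#' settings.
#'
#' @param screen_path Path to a measured screen table, or `NULL` to simulate.
#' @param parts_path Optional custom parts fixture path.
#' @param out_dir Output directory for artifacts.
#' @param simulate_regime [ground_truth_regime()] name used when
#'   `screen_path` is `NULL`.
#' @param n_records Synthetic screen size (ignored when reading a file).
#' @param n_test Test-set size for the split.
#' @param variants Ensemble hyperparameter tibble.
#' @param master_seed Master seed for split, training, and simulation.
#' @param include_spacer Include the spacer part in enrichment reports.
#' @param addition_motif Motif appended in the design-rule query.
#' @param addition_copies Copies appended.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(screen_path = NULL, parts_path = NULL,
                            out_dir = tempfile("cargrammar_run_"),
                            simulate_regime = "default", n_records = 246,
                            n_test = 25, variants = default_variants(),
                            master_seed = 1, include_spacer = FALSE,
                            addition_motif = "M1", addition_copies = 1) {
  structure(list(
    screen_path = screen_path, parts_path = parts_path, out_dir = out_dir,
    simulate_regime = simulate_regime, n_records = n_records, n_test = n_test,
    variants = variants, master_seed = as.integer(master_seed),
    include_spacer = include_spacer, addition_motif = addition_motif,
    addition_copies = addition_copies
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error so typos cannot silently revert to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$variants)) raw$variants <- tibble::as_tibble(raw$variants)
  do.call(pipeline_config, raw)
}

write_tsv_artifact <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: load (or simulate) and normalize the
#' screen, split, train one ensemble per phenotype on the training split and
#' evaluate on both splits, refit on all records, predict the full
#' enumerated library, run the motif/pair/position distribution analyses,
#' rank pairs by combined phenotype, and run the motif-addition design-rule
#' query on the receptor-like subsets. Every artifact is written as TSV or
#' JSON together with a manifest recording the config, seeds and package
#' version; a rerun with the same config and seed is byte-identical.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # fail on unreadable inputs before any stage runs
  if (!is.null(config$screen_path) && !file.exists(config$screen_path)) {
    abort(paste0("stage load: screen table not found: ", config$screen_path))
  }
  if (!is.null(config$parts_path) && !file.exists(config$parts_path)) {
    abort(paste0("stage load: parts fixture not found: ", config$parts_path))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  library <- motif_library(motif_parts(config$parts_path))
  domains <- enumerate_domains(library)

  if (is.null(config$screen_path)) {
    gt <- ground_truth_regime(config$simulate_regime)
    screen <- generate_screen(gt, domains, n_records = config$n_records,
                              seed = config$master_seed, library = library)
  } else {
    gt <- NULL
    screen <- read_screen_table(config$screen_path, library)
  }
  records <- average_replicates(normalize_phenotypes(screen))
  split <- split_screen(records, n_test = config$n_test,
                        seed = config$master_seed)

  models <- list(); evaluation <- list(); predictions <- list()
  for (ph in c("cytotoxicity", "stemness")) {
    fit <- train_ensemble(split$train, ph, library, config$variants,
                          master_seed = config$master_seed)
    evaluation[[ph]] <- dplyr::bind_rows(
      dplyr::mutate(evaluate_ensemble(fit, split$train), split = "train"),
      if (nrow(split$test) > 0) {
        dplyr::mutate(evaluate_ensemble(fit, split$test), split = "test")
      }
    )
    # refit on all records for library-wide prediction (recorded in manifest)
    refit <- train_ensemble(records, ph, library, config$variants,
                            master_seed = config$master_seed)
    models[[ph]] <- refit
    predictions[[ph]] <- predict(refit, domains)
  }
  evaluation <- dplyr::bind_rows(evaluation)

  ranked <- purrr::map(predictions, percentile_rank)
  enrich <- purrr::map(ranked, motif_enrichment, library = library,
                       include_spacer = config$include_spacer)
  pairs <- purrr::map(ranked, pair_enrichment, library = library)
  positions <- purrr::map(ranked, position_enrichment, library = library)
  pair_ranking <- rank_pairs_combined(pairs$cytotoxicity, pairs$stemness)

  sigs <- default_signatures()
  rules <- purrr::map(sigs, function(sig) {
    base <- select_like(domains, library, sig)
    free <- base[base$n_motifs + config$addition_copies <= library$slot_count, ]
    eff <- motif_addition_effect(models$cytotoxicity, models$stemness, free,
                                 config$addition_motif, config$addition_copies)
    list(effects = eff, summary = addition_effect_summary(eff))
  })

  pred_table <- tibble::tibble(
    domain_label = domains$domain_label,
    cytotoxicity_mean = predictions$cytotoxicity$mean,
    cytotoxicity_sem = predictions$cytotoxicity$sem,
    stemness_mean = predictions$stemness$mean,
    stemness_sem = predictions$stemness$sem
  )

  out <- config$out_dir
  paths <- list(
    screen = write_tsv_artifact(screen, out, "screen.tsv"),
    evaluation = write_tsv_artifact(evaluation, out, "evaluation.tsv"),
    predictions = write_tsv_artifact(pred_table, out, "library_predictions.tsv"),
    motif_enrichment = write_tsv_artifact(
      dplyr::bind_rows(enrich, .id = "phenotype"), out, "motif_enrichment.tsv"),
    pair_enrichment = write_tsv_artifact(
      dplyr::bind_rows(pairs, .id = "phenotype"), out, "pair_enrichment.tsv"),
    position_enrichment = write_tsv_artifact(
      dplyr::bind_rows(positions, .id = "phenotype"), out,
      "position_enrichment.tsv"),
    pair_ranking = write_tsv_artifact(pair_ranking, out, "pair_ranking.tsv"),
    design_rules = write_tsv_artifact(
      dplyr::bind_rows(purrr::map(rules, "effects"), .id = "subset"), out,
      "design_rule_effects.tsv")
  )
  summary_json <- list(
    top_pairs = pair_label(head(pair_ranking, 4)),
    bottom_pairs = pair_label(utils::tail(pair_ranking, 4)),
    design_rules = purrr::map(rules, "summary")
  )
  paths$summary <- file.path(out, "summary.json")
  jsonlite::write_json(summary_json, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cargrammar")),
    master_seed = config$master_seed,
    config = config[setdiff(names(config), "variants")],
    variants = config$variants,
    n_records = nrow(records),
    n_train = nrow(split$train), n_test = nrow(split$test),
    data_fingerprint = rlang::hash(screen)
  )
  paths$manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(
    library = library, domains = domains, ground_truth = gt,
    records = records, split = split, models = models,
    evaluation = evaluation, predictions = predictions, ranked = ranked,
    motif_enrichment = enrich, pair_enrichment = pairs,
    position_enrichment = positions, pair_ranking = pair_ranking,
    design_rules = rules, paths = paths
  ))
}
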