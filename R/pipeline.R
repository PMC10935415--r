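# Pipeline orchestration: a configuration object carrying every
# threshold at its published default, composable stages that write
# their artifacts plus a JSON manifest, and an end-to-end runner used
# by the command-line script.

#' Default pipeline configuration
#'
#' Every threshold defaults to its published value: lg(Ki) merge
#' spread 1, class cut-offs 2 and 3, MACCS pruning threshold 0.75,
#' cascade thresholds 0.15 and 0.8, modeling fraction 165/208,
#' 7:3 inner split, 10x10 cross-validation, gate multiplier 1.96.
#'
#' @param seed root seed.
#' @return Nested list of class `znbf_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(n_ligands = 208L, high_fraction = 131 / 208,
                     effect_size = 1.5, n_informative = 8L, n_noise = 42L),
    curation = list(similarity_threshold = 0.75, merge_spread = 1,
                    modeling_fraction = 165 / 208, train_fraction = 0.7),
    descriptors = list(r_min = 0.15, r_pair = 0.8, provider = "synthetic"),
    selection = list(method = "cfs_wrapper"),
    model = list(algorithm = "nb",
                 grid = list(ibk_k = c(1L, 5L, 25L),
                             j48_min_obj = c(2L, 4L, 8L))),
    evaluation = list(folds = 10L, repeats = 10L, n_replicates = 10L),
    screening = list(gate_multiplier = 1.96, n_molecules = 2000L,
                     active_fraction = 0.05)),
    class = "znbf_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_config()]; overrides are recorded in the run manifest.
#'
#' @param path YAML file.
#' @return A `znbf_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1L)
  overrides <- list()
  for (section in intersect(names(user), names(cfg))) {
    if (is.list(user[[section]])) {
      for (key in names(user[[section]])) {
        cfg[[section]][[key]] <- user[[section]][[key]]
        overrides[[paste(section, key, sep = ".")]] <- user[[section]][[key]]
      }
    } else cfg[[section]] <- user[[section]]
  }
  attr(cfg, "overrides") <- overrides
  cfg
}

# 32-bit FNV-1a over a canonical JSON rendering, for manifests
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

write_manifest <- function(dir, stage, cfg, inputs = character(0),
                           outputs = character(0)) {
  manifest <- list(stage = stage, config_hash = config_hash(unclass(cfg)),
                   seed = cfg$seed,
                   overrides = attr(cfg, "overrides") %||% list(),
                   inputs = inputs, outputs = outputs,
                   package_version =
                     as.character(utils::packageVersion("znscreen")))
  jsonlite::write_json(manifest, file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> curate -> describe -> select -> train -> evaluate ->
#' gate -> screen -> search, writing per-stage artifacts and manifests
#' under `out_dir`.  With the `"synthetic"` descriptor provider the
#' modeling descriptors come from the planted-signal generator; the
#' `"graph2d"` provider computes them from the generated structures.
#'
#' @param config a `znbf_config` (default [default_config()]).
#' @param out_dir output directory; `NULL` (default) keeps everything
#'   in memory and writes nothing.
#' @return List with the main artifacts: `spec`, `dataset` (curated),
#'   `descriptors`, `profiles`, `subset`, `cv`, `replicates`, `gate`,
#'   `screen`, `search`, and `summary` (named numeric headline
#'   quantities).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "znbf_config"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_csv <- function(df, name) {
    if (!is.null(out_dir))
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  # simulate
  spec <- synthetic_spec(seed = config$seed,
                         n_ligands = config$synthetic$n_ligands,
                         high_fraction = config$synthetic$high_fraction,
                         effect_size = config$synthetic$effect_size,
                         n_informative = config$synthetic$n_informative,
                         n_noise = config$synthetic$n_noise)
  lig <- generate_ligand_set(spec)
  if (!is.null(out_dir))
    write_synthetic_set(lig, dir = file.path(out_dir, "synthetic"))

  # curate (structure-level pruning on MACCS fingerprints)
  desc_all <- if (config$descriptors$provider == "graph2d")
    compute_descriptors(setNames(lig$ligands$smiles, lig$ligands$ligand_id))
  else generate_descriptor_table(spec, lig$ligands)
  dataset <- curate_dataset(lig$records, lig$ligands,
                            threshold = config$curation$similarity_threshold,
                            modeling_fraction = config$curation$modeling_fraction,
                            descriptors = desc_all, seed = config$seed)
  entries <- dataset$entries
  save_csv(entries, "curated_entries.csv")

  # describe: align descriptors with retained entries, run the cascade
  desc <- desc_all[match(entries$ligand_id, desc_all$ligand_id), ]
  casc <- filter_cascade(desc, entries$lg_ki,
                         r_min = config$descriptors$r_min,
                         r_pair = config$descriptors$r_pair)
  save_csv(casc$matrix, "descriptors_filtered.csv")
  save_csv(casc$log, "cascade_log.csv")
  profiles <- profile_descriptors(desc, entries$activity_class)
  save_csv(profiles, "descriptor_profiles.csv")

  # select + train + evaluate on the modeling set
  y <- setNames(entries$activity_class, entries$ligand_id)
  model_ids <- names(dataset$split_assignment)[
    dataset$split_assignment == "modeling"]
  xm <- as_descriptor_matrix(casc$matrix)[model_ids, , drop = FALSE]
  subset <- switch(config$selection$method,
                   cfs = cfs_select(xm, y[model_ids]),
                   gr = gain_ratio_rank(xm, y[model_ids]),
                   wrapper = wrapper_select(xm, y[model_ids],
                                            seed = config$seed),
                   cfs_wrapper = cfs_then_wrapper(xm, y[model_ids],
                                                  seed = config$seed))
  feat <- if (length(subset$names)) subset$names else colnames(xm)
  cv <- cross_validate(config$model$algorithm, xm[, feat, drop = FALSE],
                       y[model_ids], folds = config$evaluation$folds,
                       repeats = config$evaluation$repeats,
                       seed = config$seed)
  reps <- replicate_splits(dataset, casc$matrix,
                           algorithm = config$model$algorithm,
                           selector = config$selection$method,
                           n_replicates = config$evaluation$n_replicates,
                           seed = config$seed)
  save_csv(reps$table, "replicate_table.csv")

  # gate + screen + search on a fresh fragment library
  gate <- build_gate(profiles,
                     gated_names = intersect(electronic_descriptor_names(),
                                             profiles$name),
                     multiplier = config$screening$gate_multiplier)
  lib <- generate_fragment_library(
    spec, n_molecules = config$screening$n_molecules,
    n_actives = round(config$screening$active_fraction *
                        config$screening$n_molecules))
  hits <- screen_library(lib$descriptors, reps$best_model, gate)
  save_csv(hits, "screen_hits.csv")
  retained <- hits$molecule_id[hits$overall_pass]
  truth <- setNames(lib$molecules$is_active, lib$molecules$molecule_id)
  tp <- sum(truth[retained])
  search <- substructure_search(
    lib$molecules[lib$molecules$molecule_id %in% retained, ],
    znbf_patterns(),
    scores = setNames(hits$model_score, hits$molecule_id))
  save_csv(search, "substructure_hits.csv")

  prevalence <- mean(lib$molecules$is_active)
  summary <- c(
    n_curated = nrow(entries),
    high_fraction = mean(entries$activity_class == "high"),
    cv_accuracy = cv$cv_mean,
    best_external_accuracy = reps$table$external_acc[reps$best],
    best_external_auc = reps$table$external_auc[reps$best],
    n_screen_retained = length(retained),
    screen_precision = if (length(retained))
      active_detected_pct(tp, length(retained) - tp) else NA_real_,
    screen_hit_rate = hit_rate_pct(tp, sum(truth)),
    enrichment_fold = if (length(retained))
      (tp / length(retained)) / prevalence else NA_real_)

  if (!is.null(out_dir)) {
    jsonlite::write_json(as.list(summary), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "pipeline", config)
  }
  list(spec = spec, dataset = dataset, descriptors = casc$matrix,
       cascade_log = casc$log, profiles = profiles, subset = subset,
       cv = cv, replicates = reps, gate = gate, library = lib,
       screen = hits, search = search, summary = summary)
}
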