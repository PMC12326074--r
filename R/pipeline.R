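# End-to-end orchestration: synth/ingest -> panel -> pretrain -> embed ->
# train -> matrix -> screen, from one validated config, with a
# machine-readable run manifest (config echo + per-stage file checksums)
# sufficient to re-run bit-identically.

#' Build and validate a pipeline run configuration
#'
#' @param out_dir output directory (created; all outputs live under it).
#' @param seed master seed; every stage derives its seed from it.
#' @param synthetic a [synthetic_config()] to generate inputs, or `NULL` to
#'   read existing files.
#' @param activity_paths character vector of activity-table paths (ignored
#'   when `synthetic` is given).
#' @param corpus_path SMILES corpus path (ignored when `synthetic` is given).
#' @param ppi_path PPI edge-list path (ignored when `synthetic` is given).
#' @param seed_proteins seed protein names for panel assembly (defaults to
#'   the synthetic hubs when `synthetic` is given).
#' @param query_smiles named character vector of screening queries; `NULL`
#'   skips the screening stage.
#' @param positive_control optional query id flagged in the screening report.
#' @param min_dataset_size inclusive dataset-inclusion threshold (also the
#'   minimum training size).
#' @param encoder an [encoder_config()].
#' @param pretrain a [pretrain_config()].
#' @param tree a [tree_params()].
#' @param model_seeds five distinct seeds for the per-target ensembles.
#' @param dialect an [activity_dialect()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 0L, synthetic = NULL,
                       activity_paths = NULL, corpus_path = NULL,
                       ppi_path = NULL, seed_proteins = NULL,
                       query_smiles = NULL, positive_control = NULL,
                       min_dataset_size = 100L,
                       encoder = encoder_config(),
                       pretrain = pretrain_config(),
                       tree = tree_params(), model_seeds = 0:4,
                       dialect = activity_dialect()) {
  if (missing(out_dir) || !nzchar(out_dir)) stop("out_dir is required")
  if (is.null(synthetic)) {
    for (fld in c("activity_paths", "corpus_path", "ppi_path")) {
      v <- get(fld)
      if (is.null(v)) {
        stop("config invalid: '", fld, "' is required when no synthetic ",
             "stage is enabled")
      }
    }
    if (is.null(seed_proteins)) {
      stop("config invalid: 'seed_proteins' is required when no synthetic ",
           "stage is enabled")
    }
  } else {
    stopifnot(inherits(synthetic, "synthetic_config"))
  }
  stopifnot(inherits(encoder, "encoder_config"),
            inherits(pretrain, "pretrain_config"),
            inherits(tree, "tree_params"),
            length(model_seeds) == 5, !anyDuplicated(model_seeds),
            min_dataset_size >= 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, activity_paths = activity_paths,
                 corpus_path = corpus_path, ppi_path = ppi_path,
                 seed_proteins = seed_proteins, query_smiles = query_smiles,
                 positive_control = positive_control,
                 min_dataset_size = as.integer(min_dataset_size),
                 encoder = encoder, pretrain = pretrain, tree = tree,
                 model_seeds = as.integer(model_seeds), dialect = dialect),
            class = "run_config")
}

.md5 <- function(paths) {
  as.list(tools::md5sum(paths))
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full screening pipeline
#'
#' Executes the stages in dependency order, writing all outputs (synthetic
#' inputs, model bundle, cross-target matrix TSV, screening table, manifest)
#' under `cfg$out_dir`. Deterministic for a fixed config: re-running yields
#' byte-identical tables.
#'
#' @param cfg a [run_config()].
#' @return a `run_manifest` (also written as `manifest.json` in the output
#'   directory): config echo, per-stage file checksums, per-target CV
#'   summaries, output paths, stage order.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  incomplete <- file.path(out, "INCOMPLETE")
  file.create(incomplete)
  stages <- character(0)
  checksums <- list()

  # --- synth / input resolution ------------------------------------------
  if (!is.null(cfg$synthetic)) {
    scfg <- cfg$synthetic
    oracle <- affinity_oracle(scfg)
    synth <- make_activity_tables(scfg, oracle)
    net <- make_ppi(scfg)
    sdir <- file.path(out, "synth")
    dir.create(sdir, showWarnings = FALSE)
    activity_paths <- vapply(names(synth$tables), function(tid) {
      p <- file.path(sdir, paste0("activity_", tid, ".csv"))
      write_activity_table(synth$tables[[tid]], p, cfg$dialect)
      p
    }, character(1))
    corpus_path <- file.path(sdir, "corpus.smi")
    writeLines(unname(synth$pool), corpus_path)
    ppi_path <- file.path(sdir, "ppi_edges.tsv")
    utils::write.table(net$edges, ppi_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    seed_proteins <- net$seeds
    stages <- c(stages, "synth")
    checksums$synth <- .md5(c(activity_paths, corpus_path, ppi_path))
    .stage_log("synth", sprintf("%d activity tables, %d corpus SMILES, %d PPI edges",
                                length(activity_paths), length(synth$pool),
                                nrow(net$edges)))
  } else {
    activity_paths <- cfg$activity_paths
    corpus_path <- cfg$corpus_path
    ppi_path <- cfg$ppi_path
    seed_proteins <- cfg$seed_proteins
    missing_in <- c(activity_paths, corpus_path, ppi_path)
    missing_in <- missing_in[!file.exists(missing_in)]
    if (length(missing_in) > 0) {
      stop("input file(s) not found: ", paste(missing_in, collapse = ", "))
    }
  }

  # --- ingest -------------------------------------------------------------
  records <- do.call(rbind, lapply(activity_paths, function(p)
    read_activity_table(p, cfg$dialect)$records))
  datasets <- lapply(split(records, records$target_id), aggregate_replicates)
  stages <- c(stages, "ingest")
  checksums$ingest <- .md5(activity_paths)
  .stage_log("ingest", sprintf("%d records in, %d per-target datasets out",
                               nrow(records), length(datasets)))

  # --- panel --------------------------------------------------------------
  net <- read_ppi(ppi_path, seeds = seed_proteins)
  panel <- assemble_panel(net, datasets, cfg$min_dataset_size)
  panel_datasets <- datasets[panel$global_targets]
  stages <- c(stages, "panel")
  checksums$panel <- .md5(ppi_path)
  .stage_log("panel", sprintf("%d datasets in, %d panel targets out",
                              length(datasets), length(panel$global_targets)))

  # --- pretrain -----------------------------------------------------------
  corpus <- read_smiles_corpus(corpus_path)
  pre <- cfg$pretrain
  pre$seed <- pre$seed + cfg$seed
  enc <- cfg$encoder
  enc$seed <- enc$seed + cfg$seed
  embedder <- pretrain_autoencoder(corpus, enc, pre)
  embedder_path <- file.path(out, "embedder.rds")
  saveRDS(embedder, embedder_path)
  stages <- c(stages, "pretrain")
  checksums$pretrain <- .md5(corpus_path)
  .stage_log("pretrain", sprintf("%d corpus SMILES in, final loss %.4f",
                                 length(corpus), utils::tail(embedder$loss_trace, 1)))

  # --- embed --------------------------------------------------------------
  emb <- lapply(panel_datasets, function(d) embed_dataset(embedder, d))
  stages <- c(stages, "embed")
  .stage_log("embed", sprintf("%d datasets in, %s fingerprint rows out",
                              length(emb),
                              paste(vapply(emb, nrow, integer(1)), collapse = "+")))

  # --- train --------------------------------------------------------------
  fits <- lapply(panel$global_targets, function(tid) {
    d <- panel_datasets[[tid]]
    train_target_model(emb[[tid]], ba_from_ic50(d$records$ic50_molar), tid,
                       seeds = cfg$model_seeds + cfg$seed, params = cfg$tree,
                       min_train = cfg$min_dataset_size)
  })
  names(fits) <- panel$global_targets
  models <- lapply(fits, `[[`, "model")
  cv_summaries <- lapply(fits, function(f)
    list(target_id = f$cv$target_id, mean_r = f$cv$mean_r,
         mean_rmse = f$cv$mean_rmse))
  models_path <- file.path(out, "models.rds")
  saveRDS(models, models_path)
  metrics_path <- file.path(out, "cv_metrics.json")
  jsonlite::write_json(cv_summaries, metrics_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stages <- c(stages, "train")
  checksums$train <- .md5(metrics_path)
  .stage_log("train", sprintf("%d targets trained, mean CV R %.3f",
                              length(models),
                              mean(vapply(cv_summaries, `[[`, numeric(1), "mean_r"))))

  # --- matrix -------------------------------------------------------------
  mat <- build_matrix(unname(models), unname(panel_datasets), embedder)
  matrix_path <- file.path(out, "cross_target_matrix.tsv")
  export_matrix(mat, matrix_path)
  stages <- c(stages, "matrix")
  checksums$matrix <- .md5(matrix_path)
  .stage_log("matrix", sprintf("%dx%d cells out", length(mat$model_ids),
                               length(mat$dataset_ids)))

  # --- screen -------------------------------------------------------------
  screening_path <- NULL
  if (!is.null(cfg$query_smiles) && length(cfg$query_smiles) > 0) {
    scr <- screen_candidates(unname(models), cfg$query_smiles, embedder,
                             positive_control = cfg$positive_control)
    screening_path <- file.path(out, "screening.tsv")
    tab <- data.frame(compound_id = rownames(scr$table), scr$table,
                      best_target = scr$best_target, best_ba = scr$best_ba,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, screening_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages <- c(stages, "screen")
    checksums$screen <- .md5(screening_path)
    .stage_log("screen", sprintf("%d queries in, ranked table out",
                                 length(cfg$query_smiles)))
  }

  manifest <- structure(list(
    config = .echo_config(cfg),
    stages = stages,
    checksums = checksums,
    cv_summaries = cv_summaries,
    panel = list(core_targets = panel$core_targets,
                 global_targets = panel$global_targets),
    paths = list(out_dir = out, embedder = embedder_path,
                 models = models_path, metrics = metrics_path,
                 matrix = matrix_path, screening = screening_path)),
    class = "run_manifest")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  unlink(incomplete)
  manifest
}

# config echoed verbatim into the manifest (functions/classes flattened)
.echo_config <- function(cfg) {
  rapply(unclass(cfg), f = function(x) x, how = "list")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run:", paste(x$stages, collapse = " -> "), "\n")
  cat("outputs under:", x$paths$out_dir, "\n")
  invisible(x)
}
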