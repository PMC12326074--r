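# Cross-target affinity matrix and candidate screening.
#
# The matrix mirrors the panel heatmap: the diagonal cell of a model/dataset
# pair with the same id holds that model's self five-fold-CV Pearson R; an
# off-diagonal cell (i, j) holds the strongest binding affinity (most
# negative kcal/mol) predicted by model i over dataset j's compounds.
# cell_kind tags keep the two unit systems separate for downstream use.

#' Build the cross-target binding-affinity matrix
#'
#' @param models list of `target_model` objects.
#' @param datasets list of `target_dataset` objects; every model's target id
#'   must own a dataset with the same id.
#' @param embedder an `st_model` used to fingerprint dataset compounds.
#' @return a `cross_target_matrix`: list with `model_ids`, `dataset_ids`,
#'   `cells` (numeric matrix), `cell_kind` (character matrix with entries
#'   `"self_cv_r"` or `"cross_max_ba"`).
#' @export
build_matrix <- function(models, datasets, embedder) {
  model_ids <- vapply(models, function(m) m$target_id, character(1))
  dataset_ids <- vapply(datasets, function(d) d$target_id, character(1))
  orphans <- setdiff(model_ids, dataset_ids)
  if (length(orphans) > 0) {
    stop("model target(s) without a matching dataset: ",
         paste(orphans, collapse = ", "))
  }
  emb <- lapply(datasets, function(d) embed_dataset(embedder, d))
  cells <- matrix(NA_real_, length(models), length(datasets),
                  dimnames = list(model_ids, dataset_ids))
  kind <- matrix("cross_max_ba", length(models), length(datasets),
                 dimnames = dimnames(cells))
  for (i in seq_along(models)) {
    for (j in seq_along(datasets)) {
      if (model_ids[i] == dataset_ids[j]) {
        cells[i, j] <- models[[i]]$cv_pearson_r
        kind[i, j] <- "self_cv_r"
      } else {
        # strongest binding = most negative predicted BA over the column set
        cells[i, j] <- min(predict_ba(models[[i]], emb[[j]]))
      }
    }
  }
  structure(list(model_ids = model_ids, dataset_ids = dataset_ids,
                 cells = cells, cell_kind = kind),
            class = "cross_target_matrix")
}

#' @export
print.cross_target_matrix <- function(x, ...) {
  cat(sprintf("cross-target matrix: %d model(s) x %d dataset(s)\n",
              length(x$model_ids), length(x$dataset_ids)))
  print(round(x$cells, 3))
  invisible(x)
}

#' Screen candidate compounds across the model panel
#'
#' Predicts a full compounds-by-targets binding-affinity table, assigns each
#' compound its best (most negative) target, and ranks compounds by their
#' best affinity; ties break lexicographically by compound id. A supplied
#' positive control is flagged in the result for manual inspection, with no
#' automatic pass/fail.
#'
#' @param models list of `target_model` objects.
#' @param query_smiles named character vector (names = compound ids) or bare
#'   character vector of SMILES.
#' @param embedder an `st_model`.
#' @param positive_control optional compound id present among the queries.
#' @return a `screening_result`: list with `table` (compounds x targets BA
#'   matrix, kcal/mol), `best_target`, `best_ba`, `ranking` (data.frame) and
#'   `positive_control`.
#' @export
screen_candidates <- function(models, query_smiles, embedder,
                              positive_control = NULL) {
  if (length(query_smiles) == 0) stop("empty query list")
  if (length(models) == 0) stop("need at least one model")
  ids <- names(query_smiles)
  if (is.null(ids)) ids <- sprintf("query_%03d", seq_along(query_smiles))
  target_ids <- vapply(models, function(m) m$target_id, character(1))
  recs <- data.frame(compound_id = ids, smiles = unname(query_smiles),
                     stringsAsFactors = FALSE)
  X <- embed_dataset(embedder, recs)
  tab <- vapply(models, function(m) predict_ba(m, X),
                numeric(length(query_smiles)))
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1)
  dimnames(tab) <- list(ids, target_ids)
  best_j <- apply(tab, 1, which.min)
  best_ba <- tab[cbind(seq_along(ids), best_j)]
  ord <- order(best_ba, ids)   # strongest first, then lexicographic id
  ranking <- data.frame(rank = seq_along(ids), compound_id = ids[ord],
                        best_target = target_ids[best_j][ord],
                        best_ba = best_ba[ord], stringsAsFactors = FALSE,
                        row.names = NULL)
  if (!is.null(positive_control) && !(positive_control %in% ids)) {
    warning("positive control '", positive_control,
            "' is not among the queries")
    positive_control <- NULL
  }
  structure(list(table = tab,
                 best_target = stats::setNames(target_ids[best_j], ids),
                 best_ba = stats::setNames(best_ba, ids),
                 ranking = ranking, positive_control = positive_control),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening: %d compound(s) x %d target(s)\n",
              nrow(x$table), ncol(x$table)))
  print(x$ranking)
  if (!is.null(x$positive_control)) {
    cat(sprintf("positive control '%s': best %s at %.3f kcal/mol (inspect manually)\n",
                x$positive_control, x$best_target[x$positive_control],
                x$best_ba[x$positive_control]))
  }
  invisible(x)
}

#' Export the cross-target matrix as TSV and heatmap
#'
#' The TSV (`model_id  dataset_id  value  kind`) is lossless and
#' round-trips through [read_matrix_tsv()]. The heatmap (written when
#' `image_path` is given and the pheatmap package is available) colours
#' stronger binding darker-to-lighter consistent with the affinity sign
#' convention.
#'
#' @param matrix a `cross_target_matrix`.
#' @param tsv_path output TSV path.
#' @param image_path optional PNG path for the heatmap.
#' @return `tsv_path`, invisibly.
#' @export
export_matrix <- function(matrix, tsv_path, image_path = NULL) {
  stopifnot(inherits(matrix, "cross_target_matrix"))
  if (length(matrix$model_ids) == 0) stop("empty matrix")
  long <- expand.grid(model_id = matrix$model_ids,
                      dataset_id = matrix$dataset_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- as.vector(matrix$cells)
  long$kind <- as.vector(matrix$cell_kind)
  ok <- tryCatch({
    utils::write.table(format(long, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write TSV to ", tsv_path)
  if (!is.null(image_path)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(image_path, width = 900, height = 800)
      on.exit(grDevices::dev.off(), add = TRUE)
      pheatmap::pheatmap(matrix$cells, cluster_rows = FALSE,
                         cluster_cols = FALSE,
                         color = grDevices::colorRampPalette(
                           c("#08306b", "#6baed6", "#f7fbff"))(100),
                         main = "cross-target binding affinity")
    } else {
      warning("pheatmap not installed; heatmap skipped, TSV written")
    }
  }
  invisible(tsv_path)
}

#' @rdname export_matrix
#' @param path a TSV previously written by [export_matrix()].
#' @return `read_matrix_tsv`: the reconstructed `cross_target_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  model_ids <- unique(long$model_id)
  dataset_ids <- unique(long$dataset_id)
  cells <- matrix(NA_real_, length(model_ids), length(dataset_ids),
                  dimnames = list(model_ids, dataset_ids))
  kind <- matrix(NA_character_, length(model_ids), length(dataset_ids),
                 dimnames = dimnames(cells))
  cells[cbind(long$model_id, long$dataset_id)] <- as.numeric(long$value)
  kind[cbind(long$model_id, long$dataset_id)] <- long$kind
  structure(list(model_ids = model_ids, dataset_ids = dataset_ids,
                 cells = cells, cell_kind = kind),
            class = "cross_target_matrix")
}
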