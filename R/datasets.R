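# Activity-table and PPI ingestion, unit normalisation, replicate
# aggregation, the dataset-inclusion filter, and panel assembly from
# protein-interaction neighborhoods.

# molar scale factors for the allowed concentration units
.UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Dialect for delimited activity tables
#'
#' Column-name mapping and unit aliases so that both ChEMBL-style exports and
#' locally generated tables parse through one reader.
#'
#' @param sep field separator (`","` or `"\t"`).
#' @param col_map named character vector mapping the five logical columns
#'   (`compound_id`, `smiles`, `ic50_value`, `ic50_unit`, `target_id`) to the
#'   header names used in the file.
#' @param unit_aliases named character vector mapping unit spellings found in
#'   files to the canonical symbols `M`, `mM`, `uM`, `nM`, `pM` (the
#'   micro-sign spellings are pre-mapped to `uM`).
#' @return an `activity_dialect` list.
#' @export
activity_dialect <- function(sep = ",",
                             col_map = c(compound_id = "compound_id",
                                         smiles = "smiles",
                                         ic50_value = "ic50_value",
                                         ic50_unit = "ic50_unit",
                                         target_id = "target_id"),
                             unit_aliases = c("µM" = "uM",
                                              "μM" = "uM")) {
  req <- c("compound_id", "smiles", "ic50_value", "ic50_unit", "target_id")
  if (!all(req %in% names(col_map))) {
    stop("col_map must name all of: ", paste(req, collapse = ", "))
  }
  structure(list(sep = sep, col_map = col_map, unit_aliases = unit_aliases),
            class = "activity_dialect")
}

#' Read an activity table
#'
#' Reads a delimited text file of compound-target potency measurements.
#' Rows with a missing or non-positive IC50, an empty SMILES, or an unit
#' outside \{M, mM, uM, nM, pM\} (after alias mapping) are dropped and
#' tallied in the skip report; unknown units additionally raise a warning,
#' never a silent coercion.
#'
#' @param path file path.
#' @param dialect an [activity_dialect()].
#' @return list with `records` (data.frame: compound_id, smiles, ic50_value,
#'   ic50_unit, target_id) and `skip_report` (data.frame: reason, n).
#' @export
read_activity_table <- function(path, dialect = activity_dialect()) {
  if (!file.exists(path)) stop("activity table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  cm <- dialect$col_map
  missing_cols <- cm[!(cm %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop("columns missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(compound_id = raw[[cm["compound_id"]]],
                   smiles = raw[[cm["smiles"]]],
                   ic50_value = suppressWarnings(as.numeric(raw[[cm["ic50_value"]]])),
                   ic50_unit = raw[[cm["ic50_unit"]]],
                   target_id = raw[[cm["target_id"]]],
                   stringsAsFactors = FALSE)
  al <- dialect$unit_aliases
  hit <- df$ic50_unit %in% names(al)
  df$ic50_unit[hit] <- unname(al[df$ic50_unit[hit]])

  skip <- c("missing or non-numeric IC50" = 0L, "non-positive IC50" = 0L,
            "empty SMILES" = 0L, "unknown unit" = 0L)
  bad_na <- is.na(df$ic50_value)
  bad_pos <- !bad_na & df$ic50_value <= 0
  bad_smi <- !nzchar(trimws(df$smiles))
  bad_unit <- !(df$ic50_unit %in% names(.UNIT_FACTORS))
  if (any(bad_unit)) {
    warning("skipping rows with unknown IC50 unit(s): ",
            paste(unique(df$ic50_unit[bad_unit]), collapse = ", "))
  }
  drop <- bad_na | bad_pos | bad_smi | bad_unit
  # a row is counted once, under its first failing rule
  first <- function(m, earlier) m & !earlier
  skip["missing or non-numeric IC50"] <- sum(bad_na)
  skip["non-positive IC50"] <- sum(first(bad_pos, bad_na))
  skip["empty SMILES"] <- sum(first(bad_smi, bad_na | bad_pos))
  skip["unknown unit"] <- sum(first(bad_unit, bad_na | bad_pos | bad_smi))
  list(records = df[!drop, , drop = FALSE],
       skip_report = data.frame(reason = names(skip), n = unname(skip),
                                stringsAsFactors = FALSE))
}

#' Write an activity table
#'
#' Inverse of [read_activity_table()]; writing then reading reproduces the
#' record list exactly.
#'
#' @param records data.frame with the five logical columns.
#' @param path output file path.
#' @param dialect an [activity_dialect()].
#' @export
write_activity_table <- function(records, path, dialect = activity_dialect()) {
  cm <- dialect$col_map
  out <- records[, c("compound_id", "smiles", "ic50_value", "ic50_unit",
                     "target_id")]
  names(out) <- unname(cm[names(out)])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a concentration to molar units
#'
#' @param value positive numeric vector.
#' @param unit unit symbol(s): one of `M`, `mM`, `uM`, `nM`, `pM` (recycled).
#' @return numeric vector in molar.
#' @examples
#' to_molar(10, "uM")   # 1e-5
#' @export
to_molar <- function(value, unit) {
  bad <- setdiff(unique(unit), names(.UNIT_FACTORS))
  if (length(bad) > 0) {
    stop("unknown concentration unit(s): ", paste(bad, collapse = ", "))
  }
  value * unname(.UNIT_FACTORS[unit])
}

#' Aggregate replicate measurements into a per-target dataset
#'
#' Collapses repeated measurements of the same compound by the geometric
#' mean of the IC50 in molar units (potency errors are log-normal, so the
#' mean is taken in log space). SMILES is taken from the compound's first
#' record.
#'
#' @param records data.frame of activity records for one target (columns
#'   compound_id, smiles, ic50_value, ic50_unit, target_id).
#' @param target_id optional target id for an empty record set.
#' @return a `target_dataset`: list with `target_id`, `records` (data.frame:
#'   compound_id, smiles, ic50_molar) and `size`.
#' @export
aggregate_replicates <- function(records, target_id = NULL) {
  if (nrow(records) == 0) {
    return(structure(list(target_id = target_id %||% NA_character_,
                          records = data.frame(compound_id = character(0),
                                               smiles = character(0),
                                               ic50_molar = numeric(0),
                                               stringsAsFactors = FALSE),
                          size = 0L),
                     class = "target_dataset"))
  }
  tid <- unique(records$target_id)
  if (length(tid) != 1) {
    stop("records span multiple targets: ", paste(tid, collapse = ", "))
  }
  molar <- to_molar(records$ic50_value, records$ic50_unit)
  # sorted compound order => output independent of input row permutation
  ids <- unique(sort(records$compound_id))
  gm <- vapply(ids, function(cid) {
    exp(mean(log(molar[records$compound_id == cid])))
  }, numeric(1))
  smi <- vapply(ids, function(cid) {
    records$smiles[records$compound_id == cid][1]
  }, character(1))
  structure(list(target_id = tid,
                 records = data.frame(compound_id = ids, smiles = unname(smi),
                                      ic50_molar = unname(gm),
                                      stringsAsFactors = FALSE),
                 size = length(ids)),
            class = "target_dataset")
}

#' @export
print.target_dataset <- function(x, ...) {
  cat(sprintf("target dataset '%s': %d compounds\n", x$target_id, x$size))
  invisible(x)
}

#' Apply the dataset-inclusion filter
#'
#' Datasets must reach a minimum number of training points to support a
#' per-target model; the default threshold of 100 is inclusive (a dataset of
#' exactly 100 compounds is kept).
#'
#' @param datasets list of `target_dataset` objects.
#' @param min_size inclusive minimum size.
#' @return list with `kept` and `dropped` (both lists, input order
#'   preserved; together a partition of the input).
#' @export
filter_datasets <- function(datasets, min_size = 100L) {
  stopifnot(min_size >= 1L)
  sizes <- vapply(datasets, function(d) d$size, integer(1))
  keep <- sizes >= min_size
  list(kept = datasets[keep], dropped = datasets[!keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- PPI networks --------------------------------------------------------

#' Construct a protein-protein interaction network
#'
#' Edges are undirected: duplicate and reversed pairs are collapsed and
#' self-loops dropped. Confidence scores are stored but not filtered on.
#'
#' @param edges data.frame with columns `a`, `b` and optionally `score`
#'   (confidence in \[0, 1\]).
#' @param seeds character vector of seed protein names; must be nodes.
#' @return a `ppi_network`: list with `nodes`, `edges`, `seeds`.
#' @export
ppi_network <- function(edges, seeds = character(0)) {
  stopifnot(all(c("a", "b") %in% names(edges)))
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  edges <- data.frame(a = lo[first], b = hi[first],
                      score = edges$score[first], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$a, edges$b)))
  missing_seeds <- setdiff(seeds, nodes)
  if (length(missing_seeds) > 0) {
    stop("seed(s) not present in network: ",
         paste(missing_seeds, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges, seeds = seeds),
            class = "ppi_network")
}

#' Read a STRING-style edge list
#'
#' Tab-separated 2- or 3-column file: protein-A, protein-B, optional
#' confidence score.
#'
#' @param path file path.
#' @param seeds seed protein names.
#' @param header whether the file has a header row.
#' @return a `ppi_network`.
#' @export
read_ppi <- function(path, seeds = character(0), header = TRUE) {
  if (!file.exists(path)) stop("PPI edge list not found: ", path)
  raw <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (ncol(raw) < 2) stop("PPI edge list needs at least 2 columns")
  edges <- data.frame(a = as.character(raw[[1]]), b = as.character(raw[[2]]),
                      stringsAsFactors = FALSE)
  if (ncol(raw) >= 3) edges$score <- as.numeric(raw[[3]])
  ppi_network(edges, seeds)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges, %d seed(s)\n",
              length(x$nodes), nrow(x$edges), length(x$seeds)))
  invisible(x)
}

.ppi_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("a", "b")], directed = FALSE,
                                vertices = net$nodes)
}

#' Core subnetwork of a seed protein
#'
#' The seed plus its direct interaction partners (first shell only).
#'
#' @param net a `ppi_network`.
#' @param seed a protein name present in the network.
#' @return sorted character vector of protein names including the seed.
#' @export
core_subnetwork <- function(net, seed) {
  stopifnot(inherits(net, "ppi_network"))
  if (!(seed %in% net$nodes)) {
    stop("seed protein not in network: ", seed)
  }
  g <- .ppi_igraph(net)
  nb <- names(igraph::neighbors(g, seed))
  sort(unique(c(seed, nb)))
}

#' Assemble the target panel from PPI neighborhoods and passing datasets
#'
#' The panel is the union over seed proteins of their core subnetworks,
#' intersected with the targets that own a dataset passing the inclusion
#' filter. Core targets are the seeds themselves that own a passing dataset.
#'
#' @param net a `ppi_network` with non-empty `seeds`.
#' @param datasets list of `target_dataset` objects keyed by their
#'   `target_id` matching protein names.
#' @param min_size inclusive minimum dataset size.
#' @return a `panel_spec`: list with `seed_proteins`, `min_dataset_size`,
#'   `core_targets`, `global_targets` (both sorted).
#' @export
assemble_panel <- function(net, datasets, min_size = 100L) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$seeds) == 0) stop("network has no seed proteins")
  kept <- filter_datasets(datasets, min_size)$kept
  kept_ids <- vapply(kept, function(d) d$target_id, character(1))
  members <- unique(unlist(lapply(net$seeds, core_subnetwork, net = net)))
  global_targets <- sort(intersect(members, kept_ids))
  core_targets <- sort(intersect(net$seeds, kept_ids))
  if (length(global_targets) == 0) {
    stop("empty target panel: no PPI-neighborhood protein owns a dataset of ",
         "size >= ", min_size, "; review min_size or the network")
  }
  structure(list(seed_proteins = net$seeds,
                 min_dataset_size = as.integer(min_size),
                 core_targets = core_targets,
                 global_targets = global_targets),
            class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("target panel: %d global target(s), %d core, min dataset size %d\n",
              length(x$global_targets), length(x$core_targets),
              x$min_dataset_size))
  invisible(x)
}
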