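# Synthetic world: grammar-valid SMILES, latent-structure activity tables
# with a known affinity oracle, and hub-and-periphery PPI networks. Every
# artifact is written/consumed through the same readers as real data.
#
# SMILES are built constructively (linear/branched skeletons, optional
# single ring from valence-safe templates), never by rejection-sampling an
# external validator, so each string tokenizes and is valence-plausible by
# construction.

#' Synthetic-world configuration
#'
#' Defaults state the testing world: a few targets whose dataset sizes
#' straddle the 100-record inclusion threshold, assay noise of 0.5 kcal/mol
#' applied in log (binding-affinity) space matching log-normal potency
#' error, and a small organic atom vocabulary.
#'
#' @param seed integer master seed; identical configs give identical outputs.
#' @param n_compounds size of the generated compound pool.
#' @param atom_vocab atom symbols available to the generator.
#' @param max_length maximum token length of a generated SMILES.
#' @param n_targets number of protein targets.
#' @param dataset_sizes per-target dataset sizes (length `n_targets`).
#' @param noise_sd label noise SD in kcal/mol, applied to the oracle
#'   affinity before conversion back to IC50.
#' @param weight_scale SD of the oracle's substructure weights (kcal/mol per
#'   feature unit).
#' @param n_neighbors first-shell interactors per hub in the synthetic PPI.
#' @param n_periphery second-shell proteins per first-shell interactor.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 0L, n_compounds = 500L,
                             atom_vocab = c("C", "N", "O", "S", "Cl", "Br",
                                            "c", "n", "o"),
                             max_length = 40L, n_targets = 3L,
                             dataset_sizes = c(150L, 120L, 99L),
                             noise_sd = 0.5, weight_scale = 0.5,
                             n_neighbors = 3L, n_periphery = 2L) {
  known <- c("C", "N", "O", "S", "Cl", "Br", "c", "n", "o")
  bad <- setdiff(atom_vocab, known)
  if (length(bad) > 0) {
    stop("unsupported atom vocabulary symbol(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(n_compounds >= 1L, max_length >= 3L, n_targets >= 1L,
            length(dataset_sizes) == n_targets, all(dataset_sizes >= 1L),
            noise_sd >= 0, weight_scale > 0)
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 atom_vocab = atom_vocab, max_length = as.integer(max_length),
                 n_targets = as.integer(n_targets),
                 dataset_sizes = as.integer(dataset_sizes),
                 noise_sd = noise_sd, weight_scale = weight_scale,
                 n_neighbors = as.integer(n_neighbors),
                 n_periphery = as.integer(n_periphery)),
            class = "synthetic_config")
}

.synthetic_target_ids <- function(cfg) sprintf("T%02d", seq_len(cfg$n_targets))

# one valence-plausible SMILES; caller owns the RNG state
.one_smiles <- function(cfg) {
  chain_atoms <- intersect(c("C", "N", "O", "S"), cfg$atom_vocab)
  halogens <- intersect(c("Cl", "Br"), cfg$atom_vocab)
  # aromatic ring templates restricted to the vocabulary
  rings <- character(0)
  if (all(c("c") %in% cfg$atom_vocab)) rings <- c(rings, "c1ccccc1")
  if (all(c("c", "n") %in% cfg$atom_vocab)) rings <- c(rings, "c1ccncc1")
  if (all(c("c", "o") %in% cfg$atom_vocab)) rings <- c(rings, "c1cocc1")
  if ("C" %in% cfg$atom_vocab) rings <- c(rings, "C1CCCCC1", "C1CCCC1")

  budget <- cfg$max_length
  parts <- character(0)
  if (length(rings) > 0 && stats::runif(1) < 0.4) {
    ring <- rings[sample.int(length(rings), 1)]
    parts <- ring
    budget <- budget - nchar(ring)  # ring templates are 1 char per token
  }
  n_chain <- sample(2:max(2, min(8, budget - 4)), 1)
  for (k in seq_len(n_chain)) {
    # O/S are divalent: only C (or N) may carry a branch
    atom <- chain_atoms[sample.int(length(chain_atoms), 1)]
    parts <- c(parts, atom)
    if (atom == "C" && budget > 6 && stats::runif(1) < 0.3) {
      br <- if (length(halogens) > 0 && stats::runif(1) < 0.4) {
        halogens[sample.int(length(halogens), 1)]
      } else {
        paste(rep("C", sample(1:2, 1)), collapse = "")
      }
      parts <- c(parts, "(", br, ")")
      budget <- budget - nchar(br) - 2
    }
    budget <- budget - 1
    if (budget <= 2) break
  }
  if (length(parts) == 0) parts <- "C"
  paste(parts, collapse = "")
}

#' Generate a deterministic pool of grammar-valid SMILES
#'
#' @param cfg a [synthetic_config()].
#' @return character vector of length `cfg$n_compounds`; every string
#'   round-trips through [tokenize()]/[detokenize()].
#' @export
generate_smiles <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  vapply(seq_len(cfg$n_compounds), function(i) .one_smiles(cfg), character(1))
}

# ---- affinity oracle -----------------------------------------------------

# substructure-count features visible to a sequence model
.oracle_feature_names <- function(cfg) {
  c(paste0("count_", cfg$atom_vocab), "ring_closures", "halogens",
    "len_le10", "len_11_20", "len_gt20")
}

#' Substructure-count features of a SMILES string
#'
#' Counts of each vocabulary atom token, ring-closure pairs, halogens, and
#' one-hot token-length bins; the closed-form basis of the synthetic
#' affinity oracle.
#'
#' @param smiles a SMILES string.
#' @param cfg a [synthetic_config()].
#' @return named numeric feature vector.
#' @export
oracle_features <- function(smiles, cfg) {
  toks <- tokenize(smiles)$tokens
  counts <- vapply(cfg$atom_vocab, function(a) sum(toks == a), numeric(1))
  ndig <- sum(toks %in% as.character(0:9))
  L <- length(toks)
  stats::setNames(
    c(counts, ndig / 2, sum(toks %in% c("Cl", "Br")),
      as.numeric(L <= 10), as.numeric(L > 10 && L <= 20), as.numeric(L > 20)),
    .oracle_feature_names(cfg))
}

#' Construct the latent affinity oracle
#'
#' Per-target linear weights over substructure counts plus an intercept at a
#' realistic potency level (-7.5 kcal/mol, i.e. a few micromolar); the
#' noiseless ground-truth affinity of any SMILES is computable in closed
#' form.
#'
#' @param cfg a [synthetic_config()].
#' @param intercept baseline affinity in kcal/mol.
#' @return an `affinity_oracle`: list with `weights` (targets x features),
#'   `intercept`, `noise_sd`, `cfg`.
#' @export
affinity_oracle <- function(cfg, intercept = -7.5) {
  stopifnot(inherits(cfg, "synthetic_config"))
  fn <- .oracle_feature_names(cfg)
  set.seed(cfg$seed + 1000L)
  W <- matrix(stats::rnorm(cfg$n_targets * length(fn), sd = cfg$weight_scale),
              cfg$n_targets, length(fn),
              dimnames = list(.synthetic_target_ids(cfg), fn))
  structure(list(weights = W, intercept = intercept, noise_sd = cfg$noise_sd,
                 cfg = cfg),
            class = "affinity_oracle")
}

#' @rdname affinity_oracle
#' @param oracle an `affinity_oracle`.
#' @param smiles character vector of SMILES.
#' @param target_id a target id among the oracle's rows.
#' @return `oracle_ba`: noiseless ground-truth affinities (kcal/mol).
#' @export
oracle_ba <- function(oracle, smiles, target_id) {
  stopifnot(inherits(oracle, "affinity_oracle"))
  if (!(target_id %in% rownames(oracle$weights))) {
    stop("unknown oracle target: ", target_id)
  }
  F <- t(vapply(smiles, oracle_features, cfg = oracle$cfg,
                numeric(ncol(oracle$weights))))
  as.numeric(F %*% oracle$weights[target_id, ] + oracle$intercept)
}

#' Generate per-target activity tables with known ground truth
#'
#' Samples compounds from the generated pool for each target, assigns the
#' oracle affinity plus Gaussian noise in log (affinity) space, converts
#' back to IC50 via the exact inverse of the affinity formula, and writes
#' rows in micromolar or nanomolar units.
#'
#' @param cfg a [synthetic_config()] with `n_compounds >= max(dataset_sizes)`.
#' @param oracle an [affinity_oracle()] built from the same config.
#' @return list with `tables` (named list of activity-record data.frames,
#'   readable by [read_activity_table()] after [write_activity_table()]),
#'   `truth` (named list of data.frames: compound_id, smiles, ba_true) and
#'   `pool` (the compound pool).
#' @export
make_activity_tables <- function(cfg, oracle) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(oracle, "affinity_oracle"))
  if (nrow(oracle$weights) != cfg$n_targets) {
    stop("oracle target count does not match cfg$n_targets")
  }
  if (cfg$n_compounds < max(cfg$dataset_sizes)) {
    stop("n_compounds must be >= max(dataset_sizes)")
  }
  pool <- generate_smiles(cfg)
  pool_ids <- sprintf("CPD%05d", seq_along(pool))
  tids <- .synthetic_target_ids(cfg)
  set.seed(cfg$seed + 2000L)
  tables <- truth <- stats::setNames(vector("list", cfg$n_targets), tids)
  for (t in seq_len(cfg$n_targets)) {
    n <- cfg$dataset_sizes[t]
    pick <- sort(sample.int(length(pool), n))
    ba_true <- oracle_ba(oracle, pool[pick], tids[t])
    ba_noisy <- ba_true + stats::rnorm(n, sd = cfg$noise_sd)
    molar <- ic50_from_ba(ba_noisy)
    unit <- sample(c("uM", "nM"), n, replace = TRUE)
    value <- molar / .UNIT_FACTORS[unit]
    tables[[t]] <- data.frame(compound_id = pool_ids[pick],
                              smiles = pool[pick],
                              ic50_value = unname(value),
                              ic50_unit = unname(unit),
                              target_id = tids[t],
                              stringsAsFactors = FALSE)
    truth[[t]] <- data.frame(compound_id = pool_ids[pick],
                             smiles = pool[pick], ba_true = ba_true,
                             stringsAsFactors = FALSE)
  }
  list(tables = tables, truth = truth, pool = stats::setNames(pool, pool_ids))
}

#' Generate a synthetic hub-and-periphery PPI network
#'
#' One hub per target, each with `n_neighbors` direct interactors and
#' `n_periphery` second-shell proteins per interactor, so each hub's core
#' subnetwork has `1 + n_neighbors` members and the global network adds the
#' periphery.
#'
#' @param cfg a [synthetic_config()].
#' @return a `ppi_network` whose seeds are the hub target ids.
#' @export
make_ppi <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  tids <- .synthetic_target_ids(cfg)
  set.seed(cfg$seed + 3000L)
  a <- character(0); b <- character(0)
  for (t in seq_len(cfg$n_targets)) {
    hubs <- tids[t]
    for (k in seq_len(cfg$n_neighbors)) {
      nb <- sprintf("%s_N%d", hubs, k)
      a <- c(a, hubs); b <- c(b, nb)
      for (p in seq_len(cfg$n_periphery)) {
        a <- c(a, nb); b <- c(b, sprintf("%s_P%d", nb, p))
      }
    }
  }
  edges <- data.frame(a = a, b = b,
                      score = round(stats::runif(length(a), 0.4, 0.999), 3),
                      stringsAsFactors = FALSE)
  ppi_network(edges, seeds = tids)
}
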