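# two tiny models over distinct targets, shared embedder
cross_fixture <- function() {
  fixture("cross_fixture", function() {
    scfg <- synthetic_config(seed = 11, n_compounds = 300L, n_targets = 2L,
                             dataset_sizes = c(60L, 50L), noise_sd = 0.2)
    orc <- affinity_oracle(scfg)
    synth <- make_activity_tables(scfg, orc)
    emb <- tiny_embedder()
    datasets <- lapply(synth$tables, aggregate_replicates)
    models <- lapply(names(datasets), function(tid) {
      d <- datasets[[tid]]
      train_target_model(embed_dataset(emb, d),
                         ba_from_ic50(d$records$ic50_molar), tid,
                         params = tree_params(n_trees = 40, max_depth = 2,
                                              learning_rate = 0.1),
                         min_train = 10L)$model
    })
    list(models = models, datasets = unname(datasets), embedder = emb)
  })
}

test_that("matrix diagonal holds self-CV R and off-diagonals the strongest BA", {
  fx <- cross_fixture()
  mat <- build_matrix(fx$models, fx$datasets, fx$embedder)
  expect_equal(dim(mat$cells), c(2L, 2L))
  expect_equal(diag(mat$cells),
               setNames(vapply(fx$models, `[[`, numeric(1), "cv_pearson_r"),
                        mat$model_ids))
  expect_equal(diag(mat$cell_kind), setNames(rep("self_cv_r", 2), mat$model_ids))
  expect_true(all(mat$cell_kind[row(mat$cells) != col(mat$cells)] ==
                    "cross_max_ba"))
  expect_true(all(diag(mat$cells) >= -1 & diag(mat$cells) <= 1))

  # brute-force oracle: re-predict every compound of dataset j under model i
  for (i in 1:2) for (j in 1:2) {
    if (i == j) next
    X <- embed_dataset(fx$embedder, fx$datasets[[j]])
    expect_equal(mat$cells[i, j], min(predict_ba(fx$models[[i]], X)))
  }
})

test_that("a 1x1 matrix is just the model's CV R", {
  fx <- cross_fixture()
  mat <- build_matrix(fx$models[1], fx$datasets[1], fx$embedder)
  expect_equal(dim(mat$cells), c(1L, 1L))
  expect_equal(mat$cells[1, 1], fx$models[[1]]$cv_pearson_r)
  expect_equal(mat$cell_kind[1, 1], "self_cv_r")
})

test_that("permuting dataset order permutes columns and kinds consistently", {
  fx <- cross_fixture()
  m12 <- build_matrix(fx$models, fx$datasets, fx$embedder)
  m21 <- build_matrix(fx$models, rev(fx$datasets), fx$embedder)
  expect_equal(m21$cells, m12$cells[, 2:1])
  expect_equal(m21$cell_kind, m12$cell_kind[, 2:1])
})

test_that("orphan models are rejected with their ids", {
  fx <- cross_fixture()
  expect_error(build_matrix(fx$models, fx$datasets[1], fx$embedder),
               fx$models[[2]]$target_id)
})

test_that("screening ranks by strongest affinity with lexicographic ties", {
  fx <- cross_fixture()
  q <- c(a2 = "CCOC", a1 = "CCOC", b = "c1ccccc1CC")   # a1/a2 tie exactly
  res <- screen_candidates(fx$models, q, fx$embedder)
  expect_equal(dim(res$table), c(3L, 2L))
  expect_true(all(is.finite(res$table)))
  # per-compound best target is the most negative row entry
  for (id in rownames(res$table)) {
    expect_equal(res$best_ba[[id]], min(res$table[id, ]))
    expect_equal(res$best_target[[id]],
                 colnames(res$table)[which.min(res$table[id, ])])
  }
  # ranking sorted by best BA, the a1/a2 tie broken lexicographically
  expect_false(is.unsorted(res$ranking$best_ba))
  pos <- match(c("a1", "a2"), res$ranking$compound_id)
  expect_lt(pos[1], pos[2])
  # invariance to query order
  res2 <- screen_candidates(fx$models, q[c(3, 1, 2)], fx$embedder)
  expect_equal(res2$ranking, res$ranking)
})

test_that("screening validates inputs and flags the positive control", {
  fx <- cross_fixture()
  expect_error(screen_candidates(fx$models, character(0), fx$embedder),
               "empty query")
  expect_error(screen_candidates(list(), c(a = "CCO"), fx$embedder),
               "at least one model")
  one <- screen_candidates(fx$models[1], c(ctrl = "CCSCC"), fx$embedder,
                           positive_control = "ctrl")
  expect_equal(dim(one$table), c(1L, 1L))
  expect_equal(one$best_target[["ctrl"]], fx$models[[1]]$target_id)
  expect_equal(one$positive_control, "ctrl")
  expect_warning(
    screen_candidates(fx$models, c(a = "CCO"), fx$embedder,
                      positive_control = "missing"),
    "not among")
})

test_that("matrix TSV export is lossless and complete", {
  fx <- cross_fixture()
  mat <- build_matrix(fx$models, fx$datasets, fx$embedder)
  tsv <- tempfile(fileext = ".tsv")
  export_matrix(mat, tsv)
  lines <- readLines(tsv)
  expect_equal(lines[1], "model_id\tdataset_id\tvalue\tkind")
  expect_length(lines, 5)                    # header + 4 cells
  expect_false(any(grepl("\t\t|\t$", lines)))  # no empty cells
  back <- read_matrix_tsv(tsv)
  expect_equal(back$cells[mat$model_ids, mat$dataset_ids], mat$cells)
  expect_equal(back$cell_kind[mat$model_ids, mat$dataset_ids], mat$cell_kind)
})
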