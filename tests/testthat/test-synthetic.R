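test_that("SMILES generation is deterministic per seed and seed-sensitive", {
  cfg1 <- synthetic_config(seed = 5, n_compounds = 1)
  expect_identical(generate_smiles(cfg1), generate_smiles(cfg1))
  a <- generate_smiles(synthetic_config(seed = 5, n_compounds = 50))
  b <- generate_smiles(synthetic_config(seed = 6, n_compounds = 50))
  expect_length(a, 50)
  expect_true(any(a != b))
})

test_that("generated SMILES respect the vocabulary and length budget", {
  cfg <- synthetic_config(seed = 2, n_compounds = 200, max_length = 30)
  sm <- generate_smiles(cfg)
  allowed <- c(cfg$atom_vocab, "(", ")", as.character(0:9))
  for (s in sm) {
    toks <- tokenize(s)$tokens
    expect_lte(length(toks), 30L)
    expect_true(all(toks %in% allowed))
  }
  # restricted vocabulary is honoured; unknown symbols rejected
  sm_c <- generate_smiles(synthetic_config(seed = 2, n_compounds = 50,
                                           atom_vocab = c("C", "O")))
  expect_false(any(grepl("[NSnos]|Cl|Br", sm_c)))
  expect_error(synthetic_config(atom_vocab = c("C", "Xx")), "Xx")
})

test_that("the affinity oracle is a closed-form function of substructure counts", {
  cfg <- synthetic_config(seed = 4)
  orc <- affinity_oracle(cfg)
  expect_equal(dim(orc$weights), c(3L, length(cfg$atom_vocab) + 5L))
  f <- oracle_features("CC(Cl)c1ccccc1", cfg)
  expect_equal(unname(f["count_Cl"]), 1)
  expect_equal(unname(f["ring_closures"]), 1)
  expect_equal(unname(f["halogens"]), 1)
  expect_equal(unname(f["len_11_20"]), 1)
  # manual dot product reproduces oracle_ba
  manual <- sum(orc$weights["T02", ] * f) + orc$intercept
  expect_equal(oracle_ba(orc, "CC(Cl)c1ccccc1", "T02"), manual)
  expect_identical(oracle_ba(orc, "CCO", "T01"), oracle_ba(orc, "CCO", "T01"))
  expect_error(oracle_ba(orc, "CCO", "T99"), "unknown oracle target")
})

test_that("noiseless tables invert exactly back to the oracle affinity", {
  cfg <- synthetic_config(seed = 7, n_compounds = 120, n_targets = 2,
                          dataset_sizes = c(40L, 30L), noise_sd = 0)
  out <- make_activity_tables(cfg, affinity_oracle(cfg))
  for (tid in names(out$tables)) {
    tab <- out$tables[[tid]]
    ba_back <- ba_from_ic50(to_molar(tab$ic50_value, tab$ic50_unit))
    expect_equal(ba_back, out$truth[[tid]]$ba_true, tolerance = 1e-9)
    expect_true(all(tab$ic50_unit %in% c("uM", "nM")))
    expect_equal(nrow(tab), cfg$dataset_sizes[match(tid, names(out$tables))])
  }
})

test_that("label noise has the configured spread in affinity space", {
  cfg <- synthetic_config(seed = 9, n_compounds = 250, n_targets = 1,
                          dataset_sizes = 200L, noise_sd = 0.5)
  out <- make_activity_tables(cfg, affinity_oracle(cfg))
  tab <- out$tables[[1]]
  resid <- ba_from_ic50(to_molar(tab$ic50_value, tab$ic50_unit)) -
    out$truth[[1]]$ba_true
  expect_gt(stats::sd(resid), 0.35)
  expect_lt(stats::sd(resid), 0.65)
})

test_that("synthetic tables pass through the standard reader and filter", {
  cfg <- synthetic_config(seed = 12, n_compounds = 200, n_targets = 2,
                          dataset_sizes = c(99L, 150L))
  out <- make_activity_tables(cfg, affinity_oracle(cfg))
  datasets <- lapply(out$tables, function(tab) {
    p <- tempfile(fileext = ".csv")
    write_activity_table(tab, p)
    aggregate_replicates(read_activity_table(p)$records)
  })
  kept <- filter_datasets(unname(datasets), 100)$kept
  expect_length(kept, 1)                       # only the size-150 dataset
  expect_equal(kept[[1]]$size, 150L)
  # filter composition matches the dataset_sizes construction in general
  for (sz in list(c(100L, 99L), c(150L, 120L, 99L))) {
    cfg2 <- synthetic_config(seed = 1, n_compounds = 200,
                             n_targets = length(sz), dataset_sizes = sz)
    out2 <- make_activity_tables(cfg2, affinity_oracle(cfg2))
    ds2 <- lapply(out2$tables, aggregate_replicates)
    expect_length(filter_datasets(unname(ds2), 100)$kept, sum(sz >= 100))
  }
})

test_that("synthetic PPI has hub-and-periphery topology with exact core sizes", {
  cfg <- synthetic_config(seed = 3, n_targets = 2, dataset_sizes = c(10L, 10L),
                          n_neighbors = 3, n_periphery = 2)
  net <- make_ppi(cfg)
  expect_identical(net, make_ppi(cfg))         # deterministic
  expect_equal(net$seeds, c("T01", "T02"))
  for (hub in net$seeds) {
    expect_length(core_subnetwork(net, hub), 1 + 3)
  }
  # no self loops, all scores in range
  expect_true(all(net$edges$a != net$edges$b))
  expect_true(all(net$edges$score > 0 & net$edges$score < 1))
  # zero periphery: the global network is exactly the union of cores
  cfg0 <- synthetic_config(seed = 3, n_targets = 2, dataset_sizes = c(10L, 10L),
                           n_neighbors = 2, n_periphery = 0)
  net0 <- make_ppi(cfg0)
  cores <- unique(unlist(lapply(net0$seeds, core_subnetwork, net = net0)))
  expect_setequal(net0$nodes, cores)
})
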