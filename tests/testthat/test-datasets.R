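test_that("reader returns one record per well-formed row with empty skip report", {
  p <- write_temp_table(make_records(c("a", "b", "c"), c("CCO", "CCN", "CCS"),
                                     c(1, 2, 3), c("uM", "nM", "uM")))
  out <- read_activity_table(p)
  expect_equal(nrow(out$records), 3)
  expect_equal(sum(out$skip_report$n), 0)
})

test_that("reader drops and tallies bad rows instead of coercing them", {
  df <- make_records(c("a", "b", "c", "d"), c("CCO", "CCN", "", "CCS"),
                     c(1, 0, 2, 3), c("uM", "uM", "uM", "furlongs"))
  p <- write_temp_table(df)
  expect_warning(out <- read_activity_table(p), "furlongs")
  expect_equal(nrow(out$records), 1)
  rep <- setNames(out$skip_report$n, out$skip_report$reason)
  expect_equal(unname(rep["non-positive IC50"]), 1)
  expect_equal(unname(rep["empty SMILES"]), 1)
  expect_equal(unname(rep["unknown unit"]), 1)
})

test_that("unit aliases map micro-sign spellings to uM via the dialect", {
  df <- make_records("a", "CCO", 10, "µM")
  p <- write_temp_table(df)
  out <- read_activity_table(p)
  expect_equal(out$records$ic50_unit, "uM")
  expect_equal(to_molar(out$records$ic50_value, out$records$ic50_unit), 1e-5)
})

test_that("reader honours a custom column mapping", {
  d <- activity_dialect(sep = "\t",
                        col_map = c(compound_id = "molecule_chembl_id",
                                    smiles = "canonical_smiles",
                                    ic50_value = "standard_value",
                                    ic50_unit = "standard_units",
                                    target_id = "target_chembl_id"))
  p <- write_temp_table(make_records("CHEMBL1", "CCO", 250, "nM"), d)
  out <- read_activity_table(p, d)
  expect_equal(out$records$compound_id, "CHEMBL1")
  expect_error(read_activity_table(p), "columns missing")
})

test_that("writing then reading an activity table is the identity", {
  df <- make_records(sprintf("c%02d", 1:8),
                     rep(c("CCO", "c1ccccc1CC", "CC(Cl)C", "NCCS"), 2),
                     c(0.5, 12, 3.25, 100, 7, 0.125, 44, 9.5),
                     rep(c("uM", "nM"), 4))
  p <- tempfile(fileext = ".csv")
  write_activity_table(df, p)
  expect_equal(read_activity_table(p)$records, df,
               ignore_attr = "row.names")
})

test_that("to_molar applies exact scale factors and rejects unknown units", {
  expect_equal(to_molar(1, "M"), 1.0)
  expect_equal(to_molar(10, "uM"), 1e-5)
  expect_equal(to_molar(250, "nM"), 2.5e-7)
  expect_equal(to_molar(c(1, 1), c("mM", "pM")), c(1e-3, 1e-12))
  expect_error(to_molar(1, "kM"), "kM")
  # multiplicative in the value
  set.seed(1)
  v <- stats::runif(20, 0.1, 100)
  a <- stats::runif(20, 0.5, 2)
  expect_equal(to_molar(a * v, "nM"), a * to_molar(v, "nM"))
})

test_that("replicates aggregate by geometric mean in molar units", {
  one <- aggregate_replicates(make_records("a", "CCO", 1, "uM"))
  expect_equal(one$records$ic50_molar, 1e-6)
  expect_equal(one$size, 1L)

  # {1e-6, 1e-8} M -> 1e-7 M
  two <- aggregate_replicates(make_records(c("a", "a"), c("CCO", "CCO"),
                                           c(1, 0.01), c("uM", "uM")))
  expect_equal(two$records$ic50_molar, 1e-7)
  expect_equal(two$size, 1L)

  distinct <- aggregate_replicates(make_records(c("a", "b"), c("CCO", "CCN"),
                                                c(1, 2), c("uM", "uM")))
  expect_equal(distinct$size, 2L)
})

test_that("aggregation is permutation-invariant and guards target identity", {
  df <- make_records(c("b", "a", "b", "c"), c("CCN", "CCO", "CCN", "CCS"),
                     c(4, 1, 9, 2), "uM")
  perm <- df[c(3, 1, 4, 2), ]
  expect_equal(aggregate_replicates(df), aggregate_replicates(perm))
  expect_equal(aggregate_replicates(df)$records$ic50_molar[2], 6e-6) # gm(4,9)
  mixed <- rbind(df, make_records("z", "CC", 1, "uM", target_id = "T02"))
  expect_error(aggregate_replicates(mixed), "multiple targets")
  empty <- aggregate_replicates(df[0, ], target_id = "T09")
  expect_equal(empty$size, 0L)
  expect_equal(empty$target_id, "T09")
})

test_that("inclusion filter keeps size >= threshold and partitions the input", {
  mk <- function(n) {
    aggregate_replicates(make_records(sprintf("c%03d", seq_len(n)),
                                      rep("CCO", n), seq_len(n), "uM"))
  }
  ds <- lapply(c(50, 99, 100, 150), mk)
  out <- filter_datasets(ds, 100)
  expect_length(out$kept, 2)                       # 100 and 150
  expect_length(out$dropped, 2)
  expect_equal(vapply(out$kept, `[[`, integer(1), "size"), c(100L, 150L))
  # the boundary case: exactly 100 passes (inclusive threshold)
  expect_length(filter_datasets(ds[3], 100)$kept, 1)
  expect_length(filter_datasets(ds[2], 100)$kept, 0)
  # partition property across random thresholds
  for (m in c(1, 60, 100, 151)) {
    f <- filter_datasets(ds, m)
    expect_equal(length(f$kept) + length(f$dropped), length(ds))
  }
})

test_that("core subnetwork is the seed plus direct neighbors only", {
  net <- ppi_network(data.frame(a = c("S", "S", "A"), b = c("A", "B", "C")),
                     seeds = "S")
  expect_setequal(core_subnetwork(net, "S"), c("S", "A", "B"))  # not C
  expect_true(all(core_subnetwork(net, "S") %in% net$nodes))
  expect_error(core_subnetwork(net, "Z"), "Z")

  # duplicate/reversed undirected edges collapse
  dup <- ppi_network(data.frame(a = c("S", "A", "S"), b = c("A", "S", "A")))
  expect_equal(nrow(dup$edges), 1)
  expect_setequal(core_subnetwork(dup, "S"), c("S", "A"))

  # isolated seed
  iso <- ppi_network(data.frame(a = "X", b = "Y"), seeds = character(0))
  iso$nodes <- c(iso$nodes, "S")
  expect_equal(core_subnetwork(iso, "S"), "S")
})

test_that("self-loops are dropped and absent seeds rejected", {
  net <- ppi_network(data.frame(a = c("A", "B"), b = c("A", "C")))
  expect_equal(nrow(net$edges), 1)
  expect_error(ppi_network(data.frame(a = "A", b = "B"), seeds = "Q"), "Q")
})

test_that("panel assembly intersects PPI neighborhoods with passing datasets", {
  mk <- function(tid, n) {
    aggregate_replicates(make_records(sprintf("c%03d", seq_len(n)),
                                      rep("CCO", n), seq_len(n), "uM",
                                      target_id = tid))
  }
  net <- ppi_network(data.frame(a = c("S", "S"), b = c("A", "B")), seeds = "S")

  # all three with passing datasets -> 3 global targets
  ds <- list(mk("S", 150), mk("A", 150), mk("B", 150))
  panel <- assemble_panel(net, ds, 100)
  expect_equal(panel$global_targets, c("A", "B", "S"))
  expect_equal(panel$core_targets, "S")

  # a small neighbor dataset is excluded
  ds2 <- list(mk("S", 150), mk("A", 50), mk("B", 150))
  expect_equal(assemble_panel(net, ds2, 100)$global_targets, c("B", "S"))

  # seed without a dataset: absent from core, neighbors remain
  ds3 <- list(mk("A", 150), mk("B", 120))
  p3 <- assemble_panel(net, ds3, 100)
  expect_equal(p3$core_targets, character(0))
  expect_equal(p3$global_targets, c("A", "B"))

  # nothing passes -> advisory error
  expect_error(assemble_panel(net, ds3, 1000), "min_size")
})

test_that("STRING-style edge lists round-trip through read_ppi", {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(a = c("S", "S", "A"), b = c("A", "B", "C"),
                                score = c(0.9, 0.4, 0.7)),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  net <- read_ppi(p, seeds = "S")
  expect_equal(length(net$nodes), 4)
  expect_equal(net$edges$score[net$edges$a == "A" & net$edges$b == "S"], 0.9)
  expect_error(read_ppi(tempfile(), seeds = "S"), "not found")
})
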