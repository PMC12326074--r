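# Shared fixtures, built once per test run and cached in this environment.
# All encoders here are desk-scale (narrow width); the fingerprint-dimension
# contract at the full default architecture is exercised separately.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small trained autoencoder over a deterministic synthetic corpus
tiny_embedder <- function() {
  fixture("tiny_embedder", function() {
    corpus <- tiny_corpus()
    pretrain_autoencoder(
      corpus,
      encoder_config(n_blocks = 4, n_heads = 4, embed_dim = 16,
                     max_sequence_length = 48, seed = 1),
      pretrain_config(n_samples = length(corpus), epochs = 3,
                      batch_size = 16, seed = 2))
  })
}

# covers the pools of every tiny_training_set variant (same generator seed)
tiny_corpus <- function() {
  fixture("tiny_corpus", function() {
    generate_smiles(synthetic_config(seed = 11, n_compounds = 300))
  })
}

# an untrained encoder sharing the tiny embedder's vocabulary
tiny_random_model <- function(seed = 5) {
  cfg <- encoder_config(n_blocks = 4, n_heads = 4, embed_dim = 16,
                        max_sequence_length = 48, seed = seed,
                        vocab = tiny_embedder()$vocab)
  st_model(cfg)
}

# write an activity data.frame to a temp csv and return the path
write_temp_table <- function(df, dialect = activity_dialect()) {
  p <- tempfile(fileext = ".csv")
  write_activity_table(df, p, dialect)
  p
}

make_records <- function(compound_id, smiles, ic50_value, ic50_unit,
                         target_id = "T01") {
  data.frame(compound_id = compound_id, smiles = smiles,
             ic50_value = ic50_value, ic50_unit = ic50_unit,
             target_id = target_id, stringsAsFactors = FALSE)
}

# a synthetic dataset with fingerprints and labels for model tests
tiny_training_set <- function(n = 150, noise_sd = 0, seed = 11) {
  key <- sprintf("train_%d_%g_%d", n, noise_sd, seed)
  fixture(key, function() {
    scfg <- synthetic_config(seed = seed, n_compounds = 300L,
                             n_targets = 1L, dataset_sizes = as.integer(n),
                             noise_sd = noise_sd)
    orc <- affinity_oracle(scfg)
    synth <- make_activity_tables(scfg, orc)
    ds <- aggregate_replicates(synth$tables[[1]])
    emb <- tiny_embedder()
    X <- embed_dataset(emb, ds)
    list(X = X, y = ba_from_ic50(ds$records$ic50_molar),
         truth = synth$truth[[1]]$ba_true, dataset = ds, embedder = emb)
  })
}
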