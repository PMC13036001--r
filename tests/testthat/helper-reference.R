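# Shared fixtures, built lazily and cached for the whole test session.
#
# reference_fixture() is the reference desk-scale run: the default synthetic
# repertoire, a 20,000-pair dataset, its curation and 80/10/10 split, and a
# 2+2-layer d=64 model trained for 4 epochs (batch 64, cosine schedule with
# 5% warm-up to max LR 3e-3).  Training takes several minutes and happens at
# most once per session, the first time a test asks for it.

reference_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      repertoire <- build_default_repertoire()
      ds <- make_dataset(20000, seed = 2026, repertoire = repertoire)
      cur <- curate_pairs(ds$pairs)
      splits <- split_dataset(cur$pairs, seed = 42)
      cfg <- model_config(n_encoder_layers = 2, n_decoder_layers = 2,
                          n_heads = 4, d_model = 64, d_feedforward = 256,
                          dropout = 0.1)
      trained <- train_model(build_model(cfg, 1), splits$train,
                             splits$validation,
                             train_config(epochs = 4, batch_size = 64,
                                          max_lr = 3e-3, seed = 11),
                             quiet = TRUE)
      cache <<- list(
        repertoire = repertoire, dataset = ds, curation = cur$report,
        splits = splits, model = trained$model, log = trained$log,
        test_truth = ds$truth[match(splits$test$id, ds$truth$id), ])
    }
    cache
  }
})

# small 5,000-pair dataset for statistical property tests (no model needed)
stats_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_dataset(5000, seed = 77,
                             repertoire = build_default_repertoire())
    cache
  }
})

# untrained micro model: cheap deterministic network for contract tests
micro_model <- function(seed = 3L, dropout = 0) {
  build_model(model_config(n_encoder_layers = 1, n_decoder_layers = 1,
                           n_heads = 4, d_model = 32, d_feedforward = 32,
                           dropout = dropout, max_len = 200), seed)
}

random_aa <- function(n, len = 110) {
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = ""), "")
}

# 10-pair curation toy set: one anchor-less light, one unknown residue, one
# exact duplicate -> 7 pairs survive
make_toy_curation_set <- function() {
  ds <- make_dataset(9, seed = 5)
  pairs <- ds$pairs[, c("id", "heavy", "light")]
  pairs$light[2] <- gsub("C", "A", pairs$light[2])
  substr(pairs$light[3], 50, 50) <- "X"
  dup <- pairs[1, ]; dup$id <- "dup_of_1"
  rbind(pairs, dup)
}

# ground-truth-assisted annotation for synthetic pairs (always succeeds on
# indel-free chains because the germline hint fixes the boundaries)
truth_annotation <- function(seq, germ) {
  annotate_regions(seq, germline_hint = annotate_regions(germ))
}
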