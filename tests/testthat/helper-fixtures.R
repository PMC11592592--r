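# Shared fixtures. Expensive objects (trained models) are built once per
# test run and memoized; all seeds are fixed study conditions.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small mixed dataset for codec / feature tests
small_dataset <- function(n = 60L, seed = 42L) {
  memo(sprintf("ds_%d_%d", n, seed), function() {
    generate_dataset(generator_config(n_samples = n, seed = seed))
  })
}

# planted-rule study: 2000 records, desk training, the regime used by the
# rule-recovery and conditional-generation checks
planted_fixture <- function() {
  memo("planted", function() {
    records <- generate_planted_rule_dataset(2000L, seed = 21L)
    tensors <- dataset_tensors(records)
    model <- diva_train(tensors, diva_config("desk", epochs = 60L, tol = 1e-4),
                        seed = 7L)
    list(records = records, tensors = tensors, model = model,
         train_idx = 1:1500, test_idx = 1501:2000)
  })
}

# tiny untrained model for loss-algebra tests
tiny_model <- function(seed = 11L) {
  memo(sprintf("tiny_%d", seed), function() {
    cfg <- diva_config("desk", latent_dim = 2L, iaf_blocks = 2L,
                       iaf_context = 4L, iaf_hidden = 8L, enc_hidden = 12L,
                       enc_blocks = 1L, dec_hidden = 16L, prior_hidden = 8L,
                       aux_hidden = 8L)
    set.seed(seed)
    diva_init(cfg)
  })
}

expect_same_record <- function(a, b) {
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$structure, b$structure)
}
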