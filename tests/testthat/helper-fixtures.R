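# Shared fixtures: a small architecture and cached synthetic data so
# individual test files stay fast.

test_config <- function(...) {
  ddg_config_tiny(n_max = 16L, embed_dim = 8L, pos_enc_dim = 4L,
                  rbf_centers = 8L, head_hidden = c(16L, 16L, 8L),
                  d_model = 16L, ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture_complex <- function(seed = 7L, n_per_chain = 10L) {
  key <- paste0("cx", seed, "_", n_per_chain)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      make_toy_complex(toy_spec(n_per_chain = n_per_chain, seed = seed))
  }
  .fixture_env[[key]]
}

fixture_samples <- function(n = 6L, seed = 11L, n_per_chain = 10L) {
  key <- paste0("ds", n, "_", seed, "_", n_per_chain)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <-
      make_dataset(n, toy_spec(n_per_chain = n_per_chain, seed = 1L),
                   seed = seed)
  }
  .fixture_env[[key]]
}

# Feature bundle + selection for one sample under a config.
fixture_feats <- function(sample, config = test_config()) {
  provider <- mock_embedding_provider(config$embed_dim, 0L)
  sel <- select_residues(sample$wt, sample$mutations, config$n_max)
  list(feats = ddgatt:::build_features(sample$wt, sel, provider, config),
       sel = sel, provider = provider)
}

# A valid mutation spec for a residue of a toy complex (picks a target type
# different from the wild type).
fixture_mutation <- function(x, i = 5L, to = NULL) {
  if (is.null(to)) to <- if (x$aa[i] == "C") "S" else "C"
  parse_mutation_code(paste0(x$aa[i], x$chain[i], x$resseq[i], to))
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(unlist(x))))
}
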