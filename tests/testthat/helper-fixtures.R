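# Shared desk-scale fixtures, built once per test run.
# The 2000-molecule corpus and its pre-trained policy back the
# learning-behaviour tests; smaller corpora back the unit tests.

.molahc_test_env <- new.env(parent = emptyenv())

small_corpus <- function(n = 120L, seed = 7L) {
  key <- paste0("corpus_", n, "_", seed)
  if (is.null(.molahc_test_env[[key]])) {
    .molahc_test_env[[key]] <-
      generate_fixture_corpus(fixture_spec(n_molecules = n, seed = seed))
  }
  .molahc_test_env[[key]]
}

# desk-scale model: compact two-layer GRU, enough for the fixture
# grammar; trained at the desk-scale learning rate (see the methods
# vignette for the scaling rationale)
desk_model_config <- function() {
  clm_config(embedding_dim = 64L, n_layers = 2L, hidden_dim = 128L,
             max_sequence_length = 100L)
}

desk_learning_rate <- function() 0.005

full_corpus <- function() {
  if (is.null(.molahc_test_env$full_corpus)) {
    .molahc_test_env$full_corpus <-
      generate_fixture_corpus(fixture_spec(n_molecules = 2000L, seed = 42L))
  }
  .molahc_test_env$full_corpus
}

pretrained_policy <- function() {
  if (is.null(.molahc_test_env$policy)) {
    .molahc_test_env$policy <- pretrain(
      full_corpus(), model_config = desk_model_config(),
      tc = train_config(epochs = 5L, batch_size = 128L,
                        learning_rate = desk_learning_rate(), seed = 1L,
                        augment_n = 10L),
      holdout_fraction = 0.05)
  }
  .molahc_test_env$policy
}

# tiny untrained policy over a minimal vocabulary, for plumbing tests
tiny_policy <- function(seed = 5L) {
  vocab <- build_vocabulary(c("CCO", "c1ccccc1N", "CCl"))
  init_policy(vocab, clm_config(8L, 1L, 16L, max_sequence_length = 30L),
              seed = seed)
}

# independent leader-clustering oracle: plain double loop
brute_force_leader <- function(fps, threshold) {
  n <- nrow(fps)
  assign <- integer(n)
  leaders <- integer(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (j in seq_along(leaders)) {
      a <- fps[i, ] > 0
      b <- fps[leaders[j], ] > 0
      un <- sum(a | b)
      sim <- if (un == 0) 1 else sum(a & b) / un
      if (sim >= threshold) {
        assign[i] <- j
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      assign[i] <- length(leaders)
    }
  }
  list(leaders = leaders, assign = assign)
}
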