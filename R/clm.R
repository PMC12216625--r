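# The chemical language model: a GRU network over SMILES tokens trained
# by next-token prediction with teacher forcing, plus autoregressive
# sampling and sequence log-likelihood evaluation.

#' Model and training configuration
#'
#' `clm_config()` holds the network architecture (defaults: embedding
#' 256, three GRU layers of hidden size 512, maximum sequence length 128
#' tokens; sequences hitting the cap are marked truncated and score as
#' invalid). `train_config()` holds the optimisation settings (defaults:
#' 5 epochs, batch size 128, Adam at learning rate 0.001, 10-fold
#' restricted-randomisation augmentation).
#'
#' @param embedding_dim,hidden_dim,n_layers integers; network sizes.
#' @param max_sequence_length cap on encoded sequence length (tokens,
#'   including GO/EOS framing).
#' @return a `clm_config` list.
#' @export
clm_config <- function(embedding_dim = 256L, n_layers = 3L,
                       hidden_dim = 512L, max_sequence_length = 128L) {
  stopifnot(embedding_dim > 0L, n_layers > 0L, hidden_dim > 0L,
            max_sequence_length > 2L)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 max_sequence_length = as.integer(max_sequence_length)),
            class = "clm_config")
}

#' @rdname clm_config
#' @param epochs,batch_size,learning_rate,seed training settings.
#' @param augment_n restricted-randomisation variants per molecule added
#'   to the training set (0 disables augmentation).
#' @export
train_config <- function(epochs = 5L, batch_size = 128L,
                         learning_rate = 0.001, seed = 1L,
                         augment_n = 10L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment_n = as.integer(augment_n)),
            class = "train_config")
}

# --- parameter trees -------------------------------------------------------

.init_params <- function(vocab_size, config, seed) {
  set.seed(seed)
  d <- config$embedding_dim
  h <- config$hidden_dim
  L <- config$n_layers
  V <- vocab_size
  rnd <- function(r, c, scale) matrix(rnorm(r * c, 0, scale), r, c)
  params <- list(
    E = rnd(V, d, 0.1),
    W = lapply(seq_len(L), function(l) {
      ind <- if (l == 1L) d else h
      rnd(3L * h, ind, 1 / sqrt(ind))
    }),
    U = lapply(seq_len(L), function(l) rnd(3L * h, h, 1 / sqrt(h))),
    bx = lapply(seq_len(L), function(l) numeric(3L * h)),
    bh = lapply(seq_len(L), function(l) numeric(3L * h)),
    Wo = rnd(V, h, 1 / sqrt(h)),
    bo = numeric(V))
  params
}

# elementwise map over (possibly nested) parameter trees
.tree_map <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- .tree_map(f, a[[i]],
                            if (!is.null(b)) b[[i]],
                            if (!is.null(c)) c[[i]])
    }
    out
  } else {
    f(a, b, c)
  }
}

.tree_zeros <- function(a) .tree_map(function(x, ...) x * 0, a)

# Adam optimiser state and update (minimisation)
.adam_init <- function(params) {
  list(m = .tree_zeros(params), v = .tree_zeros(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- .tree_map(function(v, g, ...) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' Initialize an untrained policy
#'
#' @param vocab a `clm_vocabulary`.
#' @param config a [clm_config()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `clm_policy`.
#' @export
init_policy <- function(vocab, config = clm_config(), seed = 1L) {
  structure(list(params = .init_params(length(vocab$tokens), config, seed),
                 vocab = vocab, config = config),
            class = "clm_policy")
}

#' @export
print.clm_policy <- function(x, ...) {
  cfg <- x$config
  np <- sum(unlist(.tree_map(function(p, ...) length(p), x$params)))
  cat(sprintf(paste0("GRU chemical language model: |V|=%d, embedding %d, ",
                     "%d layer(s) x hidden %d (%s parameters)\n"),
              length(x$vocab$tokens), cfg$embedding_dim, cfg$n_layers,
              cfg$hidden_dim, format(np, big.mark = ",")))
  invisible(x)
}

# encode a corpus, dropping sequences beyond the length cap
.encode_corpus <- function(smiles, vocab, max_len) {
  seqs <- lapply(smiles, function(s)
    tryCatch(encode_smiles(s, vocab), error = function(e) NULL))
  seqs <- seqs[!vapply(seqs, is.null, logical(1))]
  seqs[lengths(seqs) <= max_len]
}

#' Pre-train the chemical language model
#'
#' Maximum-likelihood training with teacher forcing: minimizes the mean
#' per-token negative log-likelihood of the next token given all
#' previous tokens. Optionally augments the corpus with restricted
#' SMILES randomisation (`augment_n` variants per molecule, drawn once
#' under the training seed and reshuffled every epoch). Aborts with a
#' diagnostic if the loss diverges.
#'
#' @param corpus `molecule_record` data frame or character vector of
#'   SMILES.
#' @param vocab vocabulary; built from the corpus when `NULL`.
#' @param model_config a [clm_config()].
#' @param tc a [train_config()].
#' @param holdout_fraction fraction of molecules held out for the
#'   per-epoch validation loss trace (0 disables).
#' @param verbose print per-epoch losses.
#' @return a `clm_policy` with attribute `loss_trace`: data frame of
#'   epoch, training loss, and held-out loss (mean per-token NLL, nats).
#' @export
pretrain <- function(corpus, vocab = NULL, model_config = clm_config(),
                     tc = train_config(), holdout_fraction = 0.05,
                     verbose = FALSE) {
  smiles <- if (is.data.frame(corpus)) corpus$canonical_smiles else corpus
  smiles <- smiles[!is.na(smiles)]
  if (is.null(vocab)) vocab <- build_vocabulary(smiles)

  set.seed(tc$seed)
  n_hold <- floor(holdout_fraction * length(smiles))
  hold_idx <- if (n_hold > 0L) sample(length(smiles), n_hold) else integer(0)
  train_smiles <- if (length(hold_idx)) smiles[-hold_idx] else smiles
  hold_smiles <- smiles[hold_idx]

  if (tc$augment_n > 0L) {
    aug <- randomized_smiles(train_smiles, n = tc$augment_n,
                             seed = tc$seed)
    train_smiles <- c(train_smiles, unlist(aug))
    # augmented spellings can contain tokens absent from the canonical
    # corpus; keep only in-vocabulary variants
  }
  max_len <- model_config$max_sequence_length
  seqs <- .encode_corpus(train_smiles, vocab, max_len)
  hold_seqs <- .encode_corpus(hold_smiles, vocab, max_len)
  if (!length(seqs)) stop("no encodable training sequences")

  policy <- init_policy(vocab, model_config, seed = tc$seed)
  params <- policy$params
  # initialize the output bias at the corpus unigram log-frequencies:
  # the untrained model then already emits the marginal token
  # distribution, which speeds early convergence
  tok_counts <- tabulate(unlist(lapply(seqs, function(s) s[-1L])),
                         nbins = length(vocab$tokens))
  params$bo <- log((tok_counts + 1) / sum(tok_counts + 1))
  opt <- .adam_init(params)

  eval_nll <- function(p, ss) {
    if (!length(ss)) return(NA_real_)
    tot_ll <- 0; tot_tok <- 0
    bs <- 256L
    for (b in seq(1L, length(ss), by = bs)) {
      batch <- ss[b:min(b + bs - 1L, length(ss))]
      pk <- .pack_sequences(batch, policy$vocab$pad)
      r <- .cpp_clm_grad(p, pk$X, pk$lengths, rep(0, nrow(pk$X)), FALSE)
      tot_ll <- tot_ll + sum(r$loglik)
      tot_tok <- tot_tok + r$n_tokens
    }
    -tot_ll / tot_tok
  }

  trace <- data.frame(epoch = integer(0), train_nll = numeric(0),
                      holdout_nll = numeric(0))
  for (ep in seq_len(tc$epochs)) {
    ord <- sample(length(seqs))
    ep_ll <- 0; ep_tok <- 0
    for (b in seq(1L, length(seqs), by = tc$batch_size)) {
      idx <- ord[b:min(b + tc$batch_size - 1L, length(seqs))]
      pk <- .pack_sequences(seqs[idx], vocab$pad)
      # minimise batch mean per-token NLL: G = -(1/T) * sum loglik
      r <- .cpp_clm_grad(params, pk$X, pk$lengths,
                         rep(-1 / 1, nrow(pk$X)), TRUE)
      Tb <- r$n_tokens
      grads <- .tree_map(function(g, ...) g / Tb, r$grad)
      loss <- -sum(r$loglik) / Tb
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d (loss %g)", ep, loss))
      }
      st <- .adam_step(params, grads, opt, tc$learning_rate)
      params <- st$params
      opt <- st$state
      ep_ll <- ep_ll + sum(r$loglik)
      ep_tok <- ep_tok + Tb
    }
    hnll <- eval_nll(params, hold_seqs)
    trace <- rbind(trace, data.frame(epoch = ep,
                                     train_nll = -ep_ll / ep_tok,
                                     holdout_nll = hnll))
    if (verbose) {
      message(sprintf("epoch %d: train NLL/token %.4f, holdout %.4f",
                      ep, -ep_ll / ep_tok, hnll))
    }
  }
  policy$params <- params
  attr(policy, "loss_trace") <- trace
  policy
}

#' Per-token negative log-likelihood of a SMILES set under a policy
#'
#' @param policy a `clm_policy`.
#' @param smiles character vector.
#' @return mean per-token NLL in nats.
#' @export
evaluate_nll <- function(policy, smiles) {
  seqs <- .encode_corpus(smiles, policy$vocab,
                         policy$config$max_sequence_length)
  if (!length(seqs)) return(NA_real_)
  pk <- .pack_sequences(seqs, policy$vocab$pad)
  r <- .cpp_clm_grad(policy$params, pk$X, pk$lengths,
                     rep(0, nrow(pk$X)), FALSE)
  -sum(r$loglik) / r$n_tokens
}

#' Sample molecules from the policy
#'
#' Autoregressive multinomial sampling at temperature 1: a GO token is
#' fed in and tokens are drawn from the predicted next-token
#' distribution until EOS or the sequence-length cap (capped sequences
#' are flagged `truncated` and treated as invalid downstream). Each
#' sample carries its sequence log-likelihood under the sampling policy.
#'
#' @param policy a `clm_policy`.
#' @param n number of sequences.
#' @param seed integer seed.
#' @return data frame with columns `smiles`, `agent_ll`, `truncated`;
#'   the encoded sequences are kept in the list column `tokens`.
#' @export
sample_batch <- function(policy, n, seed = 1L) {
  stopifnot(n >= 1L)
  max_emit <- policy$config$max_sequence_length - 1L  # after GO
  r <- .cpp_clm_sample(policy$params, n, max_emit, seed,
                       policy$vocab$go, policy$vocab$eos)
  smiles <- character(n)
  toks <- vector("list", n)
  for (i in seq_len(n)) {
    L <- r$lengths[i]
    emitted <- if (L > 0L) r$tokens[i, seq_len(L)] else integer(0)
    toks[[i]] <- c(policy$vocab$go, emitted)
    smiles[i] <- decode_smiles(emitted, policy$vocab)
  }
  out <- data.frame(smiles = smiles, agent_ll = r$loglik,
                    truncated = r$truncated, stringsAsFactors = FALSE)
  out$tokens <- toks
  out
}

#' Sequence log-likelihood under a policy
#'
#' Sum over the sequence of log P(x_i | x_<i); always <= 0. Supplies the
#' prior and agent likelihoods of the augmented-likelihood update.
#'
#' @param policy a `clm_policy`.
#' @param sequences list of integer token sequences (GO ... EOS framing,
#'   as produced by [encode_smiles()] or [sample_batch()]).
#' @return numeric vector of log-likelihoods.
#' @export
sequence_log_likelihood <- function(policy, sequences) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (any(lengths(sequences) > policy$config$max_sequence_length)) {
    stop("sequence exceeds max_sequence_length")
  }
  pk <- .pack_sequences(sequences, policy$vocab$pad)
  r <- .cpp_clm_grad(policy$params, pk$X, pk$lengths,
                     rep(0, nrow(pk$X)), FALSE)
  as.numeric(r$loglik)
}

#' Save / load a policy checkpoint
#'
#' Checkpoints embed the weights, vocabulary and architecture config.
#'
#' @param policy a `clm_policy`.
#' @param path file path.
#' @export
save_policy <- function(policy, path) {
  saveRDS(policy, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  p <- readRDS(path)
  stopifnot(inherits(p, "clm_policy"))
  p
}
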