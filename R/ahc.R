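# Augmented Hill-Climb: regress the agent's sequence log-likelihood
# toward the frozen prior's log-likelihood augmented by sigma * reward,
# using only the top-k-rewarded molecules of each sampled batch.

#' Reinforcement-learning configuration
#'
#' Defaults are the reference settings: sigma 60, top-k fraction 0.5,
#' batch size 64, 200 steps (so 12,800 molecules sampled per run), and a
#' scaffold diversity-filter bucket of 25.
#'
#' @param sigma reward scaling of the augmented likelihood.
#' @param topk_fraction fraction k of the batch used for the update.
#' @param batch_size molecules sampled per step.
#' @param n_steps optimisation steps.
#' @param seed integer seed (drives sampling and all stochastic parts).
#' @param diversity_bucket scaffold occurrences tolerated before the
#'   diversity filter zeroes the reward (`Inf` disables the filter).
#' @param learning_rate Adam learning rate for the policy update.
#' @return object of class `rl_config`.
#' @export
rl_config <- function(sigma = 60, topk_fraction = 0.5, batch_size = 64L,
                      n_steps = 200L, seed = 1L, diversity_bucket = 25,
                      learning_rate = 0.001) {
  stopifnot(topk_fraction > 0, topk_fraction <= 1, sigma >= 0,
            batch_size >= 1L, n_steps >= 1L)
  structure(list(sigma = sigma, topk_fraction = topk_fraction,
                 batch_size = as.integer(batch_size),
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 diversity_bucket = diversity_bucket,
                 learning_rate = learning_rate),
            class = "rl_config")
}

#' Augmented likelihood
#'
#' `prior_ll + sigma * reward`: the prior sequence log-likelihood raised
#' in proportion to the reward, so that high-reward molecules define a
#' higher likelihood target for the agent. (In the customary
#' negative-log-likelihood notation this is written as a subtraction;
#' here `prior_ll` is a log-likelihood, so the reward term is added.)
#'
#' @param prior_ll sequence log-likelihood under the frozen prior.
#' @param reward reward in `[0, 1]`.
#' @param sigma scaling factor.
#' @return augmented sequence log-likelihood.
#' @export
#' @examples
#' augmented_likelihood(-10, 0.5, 60)  # 20
augmented_likelihood <- function(prior_ll, reward, sigma) {
  prior_ll + sigma * reward
}

#' Augmented Hill-Climb loss
#'
#' Mean squared difference between the augmented and the agent sequence
#' log-likelihoods over the selected molecules.
#'
#' @param augmented_ll,agent_ll numeric vectors (selected molecules).
#' @return non-negative scalar.
#' @export
ahc_loss <- function(augmented_ll, agent_ll) {
  stopifnot(length(augmented_ll) == length(agent_ll))
  if (!length(augmented_ll)) stop("empty selection")
  mean((augmented_ll - agent_ll)^2)
}

#' Top-k selection by reward
#'
#' Returns the indices of the `ceiling(n * topk_fraction)` molecules
#' with the highest reward; ties are broken stably by original batch
#' order.
#'
#' @param rewards numeric vector.
#' @param topk_fraction fraction k in (0, 1].
#' @return integer vector of selected indices.
#' @export
select_topk <- function(rewards, topk_fraction) {
  stopifnot(length(rewards) > 0L, topk_fraction > 0, topk_fraction <= 1)
  k <- ceiling(length(rewards) * topk_fraction)
  ord <- order(-rewards)  # radix order is stable: ties keep batch order
  ord[seq_len(k)]
}

#' Scaffold diversity filter
#'
#' Run-level memory penalising repeated sampling of the same
#' Bemis-Murcko scaffold: each valid molecule increments its scaffold's
#' count, and once a scaffold has been seen more than `bucket_size`
#' times the molecule's reward is zeroed before top-k selection.
#' `new_diversity_filter(Inf)` is inert.
#'
#' @param bucket_size occurrences tolerated per scaffold.
#' @return `new_diversity_filter()`: an environment holding
#'   `scaffold_counts` and `bucket_size`.
#' @export
new_diversity_filter <- function(bucket_size = 25) {
  st <- new.env(parent = emptyenv())
  st$counts <- new.env(parent = emptyenv())
  st$bucket_size <- bucket_size
  class(st) <- "diversity_filter"
  st
}

#' @rdname new_diversity_filter
#' @param state a `diversity_filter` (mutated in place).
#' @param scaffolds character vector of Bemis-Murcko scaffolds (NA for
#'   invalid molecules, which pass through untouched).
#' @param rewards numeric vector of rewards.
#' @return adjusted rewards.
#' @export
diversity_penalty <- function(state, scaffolds, rewards) {
  stopifnot(inherits(state, "diversity_filter"),
            length(scaffolds) == length(rewards))
  if (!is.finite(state$bucket_size)) return(rewards)
  out <- rewards
  for (i in seq_along(scaffolds)) {
    sc <- scaffolds[i]
    if (is.na(sc)) next
    key <- if (nzchar(sc)) sc else "<acyclic>"
    cnt <- if (!is.null(state$counts[[key]])) state$counts[[key]] else 0L
    cnt <- cnt + 1L
    state$counts[[key]] <- cnt
    if (cnt > state$bucket_size) out[i] <- 0
  }
  out
}

#' Run Augmented Hill-Climb optimisation
#'
#' Per step: sample `batch_size` molecules from the agent, score them
#' with the multi-parameter scorer (which updates its running extrema
#' with the batch before normalising it), apply the scaffold diversity
#' filter, compute augmented likelihoods from the frozen prior, select
#' the top-k molecules by reward, and apply one Adam update on the
#' squared augmented-minus-agent likelihood loss. The prior is never
#' modified.
#'
#' @param prior a pre-trained `clm_policy` (the frozen regularizer).
#' @param scorer an [make_scorer()] object, or any
#'   `function(smiles, invalid)` returning a score-record data frame
#'   with at least `canonical_smiles`, `valid`, `ds`, the five
#'   component columns and `reward` (e.g. a stub for plumbing tests).
#' @param config an [rl_config()].
#' @param agent optional starting agent; defaults to a copy of the
#'   prior.
#' @param verbose print per-step summaries every 10 steps.
#' @return list with `agent` (final policy), `steps` (per-step log:
#'   mean reward and components, validity, uniqueness, loss), and
#'   `archive` (every sampled molecule with likelihoods and scores;
#'   exactly `n_steps * batch_size` rows).
#' @export
run_ahc <- function(prior, scorer, config = rl_config(), agent = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(prior, "clm_policy"),
            inherits(scorer, "mpo_scorer") || is.function(scorer))
  if (is.null(agent)) agent <- prior
  opt <- .adam_init(agent$params)
  dfilter <- new_diversity_filter(config$diversity_bucket)
  steps <- vector("list", config$n_steps)
  archive <- vector("list", config$n_steps)

  for (step in seq_len(config$n_steps)) {
    step_seed <- as.integer((config$seed * 7919 + step * 104729) %% 2147483647)
    batch <- sample_batch(agent, config$batch_size, seed = step_seed)
    sc <- if (is.function(scorer)) scorer(batch$smiles, batch$truncated) else
      score_molecules(scorer, batch$smiles, invalid = batch$truncated)
    scaff <- rep(NA_character_, nrow(sc))
    if (any(sc$valid) && is.finite(config$diversity_bucket)) {
      scaff[sc$valid] <- murcko_scaffold(sc$canonical_smiles[sc$valid])
    }
    reward_adj <- diversity_penalty(dfilter, scaff, sc$reward)
    prior_ll <- sequence_log_likelihood(prior, batch$tokens)
    aug_ll <- augmented_likelihood(prior_ll, reward_adj, config$sigma)
    sel <- select_topk(reward_adj, config$topk_fraction)

    pk <- .pack_sequences(batch$tokens[sel], agent$vocab$pad)
    # d/dtheta mean((aug - agent_ll)^2) via per-sequence weights
    w <- 2 * (batch$agent_ll[sel] - aug_ll[sel]) / length(sel)
    r <- .cpp_clm_grad(agent$params, pk$X, pk$lengths, w, TRUE)
    loss <- ahc_loss(aug_ll[sel], batch$agent_ll[sel])
    if (!is.finite(loss)) {
      stop(sprintf("non-finite AHC loss at step %d (rewards %s)", step,
                   paste(round(range(reward_adj), 3), collapse = "..")))
    }
    st <- .adam_step(agent$params, r$grad, opt, config$learning_rate)
    agent$params <- st$params
    opt <- st$state

    steps[[step]] <- data.frame(
      step = step, mean_reward = mean(reward_adj),
      mean_s_dock = mean(sc$s_dock), mean_s_synth = mean(sc$s_synth),
      mean_s_logp = mean(sc$s_logp), mean_s_crot = mean(sc$s_crot),
      mean_s_hbd = mean(sc$s_hbd),
      n_valid = sum(sc$valid),
      n_unique = length(unique(sc$canonical_smiles[sc$valid])),
      loss = loss)
    arch <- data.frame(step = step, smiles = batch$smiles,
                       canonical_smiles = sc$canonical_smiles,
                       agent_ll = batch$agent_ll, prior_ll = prior_ll,
                       augmented_ll = aug_ll, reward = reward_adj,
                       ds = sc$ds, s_dock = sc$s_dock,
                       s_synth = sc$s_synth, s_logp = sc$s_logp,
                       s_crot = sc$s_crot, s_hbd = sc$s_hbd,
                       valid = sc$valid, stringsAsFactors = FALSE)
    archive[[step]] <- arch
    if (verbose && step %% 10L == 0L) {
      message(sprintf("step %3d: mean reward %.3f, valid %d/%d, loss %.1f",
                      step, mean(reward_adj), sum(sc$valid),
                      config$batch_size, loss))
    }
  }
  list(agent = agent, steps = do.call(rbind, steps),
       archive = do.call(rbind, archive))
}
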