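# Workflow commands: each stage reads/writes documented formats into a
# self-describing run directory (config snapshot + seeds + package
# versions), and `replay()` re-executes a recorded run and verifies the
# artifacts checksum-identically.

.write_run_meta <- function(out_dir, stage, params, artifacts) {
  meta <- list(stage = stage, params = params,
               artifacts = as.list(artifacts),
               versions = list(
                 molahc = as.character(utils::packageVersion("molahc")),
                 ChemmineOB = as.character(utils::packageVersion("ChemmineOB")),
                 R = paste(R.version$major, R.version$minor, sep = ".")))
  yaml::write_yaml(meta, file.path(out_dir, "config.yaml"))
  invisible(meta)
}

#' Workflow stage commands
#'
#' Thin, file-oriented wrappers over the package functions, one per
#' workflow stage; these are what the shipped command-line script
#' (`system.file("cli", "molahc.R", package = "molahc")`) dispatches to.
#' Each writes its artifacts plus a `config.yaml` snapshot (stage,
#' parameters, seeds, package versions) into `out_dir` and never
#' modifies its inputs.
#'
#' @param out_dir output run directory (created if missing).
#' @param n,seed fixture size and seed.
#' @return invisibly, the run directory.
#' @export
cmd_fixtures <- function(out_dir, n = 2000L, seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_fixture_corpus(fixture_spec(n_molecules = n, seed = seed))
  write_smi(corpus$canonical_smiles, file.path(out_dir, "corpus.smi"),
            id = paste0("fx", seq_len(nrow(corpus))))
  .write_run_meta(out_dir, "fixtures", list(n = n, seed = seed),
                  "corpus.smi")
  invisible(out_dir)
}

#' @rdname cmd_fixtures
#' @param input input `.smi`/CSV path.
#' @export
cmd_curate <- function(input, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smi <- read_smi(input)
  rec <- passes_curation(standardize_molecules(smi$smiles))
  write_curation_report(rec, file.path(out_dir, "curation_report.csv"))
  write_smi(rec$canonical_smiles[rec$pass],
            file.path(out_dir, "curated.smi"),
            id = smi$id[rec$pass])
  .write_run_meta(out_dir, "curate", list(input = basename(input)),
                  c("curation_report.csv", "curated.smi"))
  invisible(out_dir)
}

#' @rdname cmd_fixtures
#' @param epochs,batch_size,learning_rate,augment_n training settings.
#' @param embedding_dim,n_layers,hidden_dim architecture settings.
#' @export
cmd_pretrain <- function(input, out_dir, epochs = 5L, batch_size = 128L,
                         learning_rate = 0.001, augment_n = 10L,
                         embedding_dim = 256L, n_layers = 3L,
                         hidden_dim = 512L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smi <- read_smi(input)
  policy <- pretrain(smi$smiles,
                     model_config = clm_config(embedding_dim, n_layers,
                                               hidden_dim),
                     tc = train_config(epochs, batch_size, learning_rate,
                                       seed, augment_n))
  write.csv(attr(policy, "loss_trace"),
            file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
  save_policy(policy, file.path(out_dir, "policy.rds"))
  .write_run_meta(out_dir, "pretrain",
                  list(input = basename(input), epochs = epochs,
                       batch_size = batch_size,
                       learning_rate = learning_rate,
                       augment_n = augment_n, seed = seed,
                       embedding_dim = embedding_dim, n_layers = n_layers,
                       hidden_dim = hidden_dim),
                  c("loss_trace.csv"))
  invisible(out_dir)
}

#' @rdname cmd_fixtures
#' @param checkpoint a policy checkpoint path (from [cmd_pretrain()]).
#' @export
cmd_sample <- function(checkpoint, out_dir, n = 128L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  policy <- load_policy(checkpoint)
  s <- sample_batch(policy, n, seed = seed)
  write.csv(s[, c("smiles", "agent_ll", "truncated")],
            file.path(out_dir, "samples.csv"), row.names = FALSE)
  .write_run_meta(out_dir, "sample",
                  list(checkpoint = basename(checkpoint), n = n,
                       seed = seed),
                  "samples.csv")
  invisible(out_dir)
}

#' @rdname cmd_fixtures
#' @param sigma,topk_fraction,n_steps RL settings, see [rl_config()].
#' @param diversity_bucket scaffold bucket size.
#' @export
cmd_optimize <- function(checkpoint, out_dir, sigma = 60,
                         topk_fraction = 0.5, batch_size = 64L,
                         n_steps = 200L, seed = 1L,
                         diversity_bucket = 25) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prior <- load_policy(checkpoint)
  scorer <- make_scorer()
  res <- run_ahc(prior, scorer,
                 rl_config(sigma = sigma, topk_fraction = topk_fraction,
                           batch_size = batch_size, n_steps = n_steps,
                           seed = seed,
                           diversity_bucket = diversity_bucket))
  write.csv(res$steps, file.path(out_dir, "step_log.csv"),
            row.names = FALSE)
  write.csv(res$archive, file.path(out_dir, "archive.csv"),
            row.names = FALSE)
  save_policy(res$agent, file.path(out_dir, "agent.rds"))
  .write_run_meta(out_dir, "optimize",
                  list(checkpoint = basename(checkpoint), sigma = sigma,
                       topk_fraction = topk_fraction,
                       batch_size = batch_size, n_steps = n_steps,
                       seed = seed, diversity_bucket = diversity_bucket),
                  c("step_log.csv", "archive.csv"))
  invisible(out_dir)
}

#' @rdname cmd_fixtures
#' @param actives,vendor,chemotypes optional reference `.smi` /
#'   pattern-file paths for the novelty funnel.
#' @export
cmd_analyze <- function(input, out_dir, actives = NULL, vendor = NULL,
                        chemotypes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smi <- read_smi(input)
  lib <- if (is.null(chemotypes)) list() else
    as.list(read_pattern_file(chemotypes))
  rep_ <- rediscovery_report(
    smi$smiles,
    reference_actives = if (is.null(actives)) character(0) else
      read_smi(actives)$smiles,
    reference_vendor = if (is.null(vendor)) character(0) else
      read_smi(vendor)$smiles,
    chemotype_library = lib)
  jsonlite::write_json(
    rep_[c("n_total", "n_valid", "n_unique", "n_novel",
           "n_with_known_chemotype", "n_known_actives_rediscovered")],
    file.path(out_dir, "funnel.json"), auto_unbox = TRUE)
  write.csv(rep_$molecules, file.path(out_dir, "molecules.csv"),
            row.names = FALSE)
  .write_run_meta(out_dir, "analyze",
                  list(input = basename(input)),
                  c("funnel.json", "molecules.csv"))
  invisible(out_dir)
}

#' Replay a recorded run and verify its artifacts
#'
#' Re-executes the stage recorded in a run directory's `config.yaml`
#' (with its recorded seed and parameters) into a scratch directory and
#' compares every recorded artifact by MD5 checksum. Deterministic
#' stages must reproduce byte-identically; stochastic stages reproduce
#' exactly under the recorded seed.
#'
#' @param run_dir a directory produced by one of the stage commands.
#' @param input_dir directory in which the stage's input files are
#'   found, for stages that read inputs (defaults to `run_dir`'s
#'   parent).
#' @return data frame with columns `artifact`, `match`, invisible
#'   `FALSE`-free on success; mismatches are reported by name.
#' @export
replay <- function(run_dir, input_dir = dirname(run_dir)) {
  cfg <- yaml::read_yaml(file.path(run_dir, "config.yaml"))
  tmp <- tempfile("replay_")
  p <- cfg$params
  locate <- function(f) {
    for (cand in c(file.path(input_dir, f), file.path(run_dir, f), f)) {
      if (file.exists(cand)) return(cand)
    }
    stop("replay cannot locate input: ", f)
  }
  switch(cfg$stage,
    fixtures = cmd_fixtures(tmp, n = p$n, seed = p$seed),
    curate = cmd_curate(locate(p$input), tmp),
    pretrain = cmd_pretrain(locate(p$input), tmp, epochs = p$epochs,
                            batch_size = p$batch_size,
                            learning_rate = p$learning_rate,
                            augment_n = p$augment_n,
                            embedding_dim = p$embedding_dim,
                            n_layers = p$n_layers,
                            hidden_dim = p$hidden_dim, seed = p$seed),
    sample = cmd_sample(locate(p$checkpoint), tmp, n = p$n, seed = p$seed),
    optimize = cmd_optimize(locate(p$checkpoint), tmp, sigma = p$sigma,
                            topk_fraction = p$topk_fraction,
                            batch_size = p$batch_size,
                            n_steps = p$n_steps, seed = p$seed,
                            diversity_bucket = p$diversity_bucket),
    analyze = cmd_analyze(locate(p$input), tmp),
    stop("unknown stage: ", cfg$stage))
  arts <- unlist(cfg$artifacts)
  match_ <- vapply(arts, function(a) {
    old <- file.path(run_dir, a)
    new <- file.path(tmp, a)
    file.exists(old) && file.exists(new) &&
      unname(tools::md5sum(old)) == unname(tools::md5sum(new))
  }, logical(1))
  res <- data.frame(artifact = arts, match = unname(match_),
                    stringsAsFactors = FALSE)
  if (any(!res$match)) {
    warning("replay divergence in: ",
            paste(res$artifact[!res$match], collapse = ", "))
  }
  res
}
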