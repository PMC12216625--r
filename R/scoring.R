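# The five-component desirability reward: reversed max-min normalisation
# of the oracle (docking) score against running extrema, piecewise
# soft/hard-limit property transforms, a synthesisability plug-in
# contract, and arithmetic-mean aggregation.

#' Max-min normalisation
#'
#' `(x - x_min) / (x_max - x_min)`, clipped to `[0, 1]` outside the
#' range. When `x_min == x_max` (degenerate extrema) the neutral value
#' 0.5 is returned rather than dividing by zero.
#'
#' @param x,x_min,x_max numerics.
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' maxmin_normalize(5, 0, 10)  # 0.5
maxmin_normalize <- function(x, x_min, x_max) {
  out <- pmin(1, pmax(0, (x - x_min) / (x_max - x_min)))
  degenerate <- rep_len(x_max == x_min, length(out))
  out[degenerate] <- 0.5
  out
}

#' Running extrema of observed oracle scores
#'
#' Tracks the minimum and maximum oracle (docking) score observed so far
#' in a run; the docking-score component is normalized against these,
#' "at a given point in training". `update_extrema()` widens the record
#' with a new batch of scores (NA entries from invalid molecules are
#' ignored and never touch the extrema).
#'
#' @return `running_extrema()`: object with fields `ds_min`, `ds_max`,
#'   `n_observed`.
#' @export
running_extrema <- function() {
  structure(list(ds_min = Inf, ds_max = -Inf, n_observed = 0L),
            class = "running_extrema")
}

#' @rdname running_extrema
#' @param extrema a `running_extrema`.
#' @param ds numeric vector of newly observed oracle scores.
#' @export
update_extrema <- function(extrema, ds) {
  ds <- ds[is.finite(ds)]
  if (length(ds)) {
    extrema$ds_min <- min(extrema$ds_min, ds)
    extrema$ds_max <- max(extrema$ds_max, ds)
    extrema$n_observed <- extrema$n_observed + length(ds)
  }
  extrema
}

#' Reversed docking-score transform
#'
#' `(ds_max - ds) / (ds_max - ds_min)`, clipped to `[0, 1]`: the lowest
#' (best) observed docking score maps to 1 and the highest to 0. With
#' degenerate extrema (a single distinct observed value) every score
#' maps to the neutral 0.5.
#'
#' @param ds numeric vector of oracle scores.
#' @param extrema a [running_extrema()] already updated with the current
#'   batch.
#' @return numeric vector in `[0, 1]`.
#' @export
transform_docking_score <- function(ds, extrema) {
  if (extrema$n_observed == 0L) {
    stop("extrema not initialized: update_extrema() before transforming")
  }
  maxmin_normalize(extrema$ds_max - ds,
                   0, extrema$ds_max - extrema$ds_min)
}

#' Soft/hard desirability limits
#'
#' A property scores 1 inside `[soft_low, soft_high]`, 0 at or beyond
#' the hard limits, and linearly in between. Setting a soft limit equal
#' to its hard limit gives a step on that side; infinite bounds disable
#' a side.
#'
#' @param soft_low,soft_high,hard_low,hard_high numerics with
#'   `hard_low <= soft_low <= soft_high <= hard_high`.
#' @return object of class `desirability_limits`.
#' @export
desirability_limits <- function(soft_low, soft_high, hard_low, hard_high) {
  stopifnot(hard_low <= soft_low, soft_low <= soft_high,
            soft_high <= hard_high)
  structure(list(soft_low = soft_low, soft_high = soft_high,
                 hard_low = hard_low, hard_high = hard_high),
            class = "desirability_limits")
}

#' Piecewise desirability transform
#'
#' @param x numeric vector of property values.
#' @param limits a [desirability_limits()].
#' @return numeric vector in `[0, 1]`: 1 inside the soft window, 0 at or
#'   beyond the hard limits, linear interpolation between soft and hard
#'   on each side (a step when soft == hard).
#' @export
#' @examples
#' lim <- desirability_limits(1, 3, 0, 4)
#' desirability_transform(c(2, 4.5, 0.5), lim)  # 1, 0, 0.5
desirability_transform <- function(x, limits) {
  s <- numeric(length(x))
  inside <- x >= limits$soft_low & x <= limits$soft_high
  s[inside] <- 1
  low <- !inside & x < limits$soft_low
  if (any(low)) {
    s[low] <- if (!is.finite(limits$hard_low)) 1 else
      ifelse(x[low] <= limits$hard_low, 0,
             maxmin_normalize(x[low], limits$hard_low, limits$soft_low))
  }
  high <- !inside & x > limits$soft_high
  if (any(high)) {
    s[high] <- if (!is.finite(limits$hard_high)) 1 else
      ifelse(x[high] >= limits$hard_high, 0,
             maxmin_normalize(limits$hard_high - x[high], 0,
                              limits$hard_high - limits$soft_high))
  }
  s
}

# --- synthesisability plug-in ----------------------------------------------

#' Synthesisability score
#'
#' Plug-in contract: the plugin receives a `molecule_record` data frame
#' and must return one probability in `[0, 1]` per row ("probability the
#' molecule is synthesisable"); no further transformation is applied.
#' Values outside `[0, 1]` are a contract violation and raise an error;
#' a plugin that throws scores 0 with a warning.
#'
#' The default surrogate maps a molecular-complexity estimate (heavy
#' atoms plus a fused-ring-junction penalty) to `[0, 1]` through a
#' decreasing logistic; it is a structural-complexity heuristic, not a
#' retrosynthesis model.
#'
#' @param records `molecule_record` data frame.
#' @param plugin function(records) -> numeric in `[0, 1]`.
#' @return numeric vector in `[0, 1]`.
#' @export
synthesisability_score <- function(records, plugin = synth_surrogate) {
  val <- tryCatch(plugin(records), error = function(e) {
    warning("synthesisability plugin failed: ", conditionMessage(e),
            "; scoring 0")
    rep(0, nrow(records))
  })
  if (length(val) != nrow(records)) {
    stop("synthesisability plugin returned ", length(val),
         " values for ", nrow(records), " molecules")
  }
  bad <- is.finite(val) & (val < 0 | val > 1)
  if (any(bad)) {
    stop("synthesisability plugin violated its contract: value ",
         format(val[bad][1]), " outside [0, 1]")
  }
  val[!is.finite(val)] <- 0
  val
}

#' @rdname synthesisability_score
#' @export
synth_surrogate <- function(records) {
  graphs <- mol_graphs(records$canonical_smiles)
  cx <- vapply(graphs, function(g) {
    if (is.null(g)) return(NA_real_)
    # ring-junction atoms: atoms carrying 3+ ring bonds (fused systems)
    rb <- g$bonds[g$bonds$ring, , drop = FALSE]
    junc <- 0L
    if (nrow(rb)) {
      tb <- tabulate(c(rb$a1, rb$a2), nbins = g$n)
      junc <- sum(tb >= 3L)
    }
    g$n + 4 * junc
  }, numeric(1))
  out <- 1 / (1 + exp((cx - 32) / 6))
  out[!is.finite(out) | is.na(cx)] <- 0
  out
}

# --- the full scorer -------------------------------------------------------

#' Build a multi-parameter desirability scorer
#'
#' Bundles the five reward components with their configuration and the
#' run-level running extrema. The reward of a valid molecule is the
#' arithmetic mean of `s_dock`, `s_synth`, `s_logp`, `s_crot`, `s_hbd`;
#' invalid molecules receive reward 0 with all components 0 and never
#' update the extrema. Oracle values are cached by canonical SMILES.
#'
#' @param oracle function(`molecule_record`) -> numeric docking-like
#'   score per row (lower better), e.g. [mock_docking_oracle()].
#' @param synth_plugin synthesisability plug-in, see
#'   [synthesisability_score()].
#' @param logp_limits desirability limits for logP (default soft 1-3,
#'   hard 0-4).
#' @param crot_max,hbd_max step thresholds for the consecutive-rotatable
#'   -bond and hydrogen-bond-donor components (score 1 at or below, 0
#'   above).
#' @param cache logical; cache oracle calls by canonical SMILES.
#' @return object of class `mpo_scorer` (an environment).
#' @export
make_scorer <- function(oracle = mock_docking_oracle,
                        synth_plugin = synth_surrogate,
                        logp_limits = desirability_limits(1, 3, 0, 4),
                        crot_max = 3, hbd_max = 3,
                        cache = TRUE) {
  sc <- new.env(parent = emptyenv())
  sc$oracle <- oracle
  sc$synth_plugin <- synth_plugin
  sc$logp_limits <- logp_limits
  sc$crot_limits <- desirability_limits(-Inf, crot_max, -Inf, crot_max)
  sc$hbd_limits <- desirability_limits(-Inf, hbd_max, -Inf, hbd_max)
  sc$extrema <- running_extrema()
  sc$cache <- if (cache) new.env(parent = emptyenv()) else NULL
  class(sc) <- "mpo_scorer"
  sc
}

#' Score a batch of molecules
#'
#' Standardizes the SMILES, queries the oracle for valid molecules,
#' updates the scorer's running extrema with the new oracle values
#' *before* normalizing the batch, applies the property transforms, and
#' aggregates the reward as the arithmetic mean of the five components.
#'
#' @param scorer an [make_scorer()] object (its extrema are updated in
#'   place).
#' @param smiles character vector of SMILES.
#' @param invalid logical vector marking entries to force-invalidate
#'   (e.g. truncated samples); optional.
#' @return a score-record data frame: `smiles`, `canonical_smiles`,
#'   `valid`, `ds`, `s_dock`, `s_synth`, `s_logp`, `s_crot`, `s_hbd`,
#'   `reward`.
#' @export
score_molecules <- function(scorer, smiles, invalid = NULL) {
  stopifnot(inherits(scorer, "mpo_scorer"))
  n <- length(smiles)
  if (is.null(invalid)) invalid <- rep(FALSE, n)
  rec <- standardize_molecules(smiles)
  valid <- rec$valid & !invalid & !rec$charged
  out <- data.frame(smiles = smiles,
                    canonical_smiles = rec$canonical_smiles,
                    valid = valid, ds = NA_real_,
                    s_dock = 0, s_synth = 0, s_logp = 0,
                    s_crot = 0, s_hbd = 0, reward = 0,
                    stringsAsFactors = FALSE)
  if (any(valid)) {
    vrec <- rec[valid, , drop = FALSE]
    ds <- rep(NA_real_, nrow(vrec))
    if (!is.null(scorer$cache)) {
      key <- vrec$canonical_smiles
      cached <- vapply(key, function(k)
        if (!is.null(scorer$cache[[k]])) scorer$cache[[k]] else NA_real_,
        numeric(1))
      need <- is.na(cached)
      if (any(need)) {
        fresh <- scorer$oracle(vrec[need, , drop = FALSE])
        for (i in which(need)) scorer$cache[[key[i]]] <-
            fresh[match(i, which(need))]
        cached[need] <- fresh
      }
      ds <- cached
    } else {
      ds <- scorer$oracle(vrec)
    }
    # extrema updated with the current batch before normalisation
    scorer$extrema <- update_extrema(scorer$extrema, ds)
    s_dock <- transform_docking_score(ds, scorer$extrema)
    s_synth <- synthesisability_score(vrec, scorer$synth_plugin)
    s_logp <- desirability_transform(vrec$logp, scorer$logp_limits)
    s_crot <- desirability_transform(vrec$max_consec_rot, scorer$crot_limits)
    s_hbd <- desirability_transform(vrec$n_hbd, scorer$hbd_limits)
    reward <- (s_dock + s_synth + s_logp + s_crot + s_hbd) / 5
    out$ds[valid] <- ds
    out$s_dock[valid] <- s_dock
    out$s_synth[valid] <- s_synth
    out$s_logp[valid] <- s_logp
    out$s_crot[valid] <- s_crot
    out$s_hbd[valid] <- s_hbd
    out$reward[valid] <- reward
  }
  out
}
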