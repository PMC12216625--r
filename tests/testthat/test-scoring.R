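# Desirability components: normalisation, docking reversal, piecewise
# transforms, synthesisability contract, and aggregation.

test_that("max-min normalisation clips and handles degeneracy", {
  expect_equal(maxmin_normalize(5, 0, 10), 0.5)
  expect_equal(maxmin_normalize(0, 0, 10), 0)
  expect_equal(maxmin_normalize(10, 0, 10), 1)
  expect_equal(maxmin_normalize(c(-5, 15), 0, 10), c(0, 1))
  expect_equal(maxmin_normalize(3, 3, 3), 0.5)   # no division error
})

test_that("docking transform reverses: best (lowest) score maps to 1", {
  ext <- update_extrema(running_extrema(), c(-12, -4))
  expect_equal(transform_docking_score(c(-12, -4, -8), ext), c(1, 0, 0.5))
  expect_error(transform_docking_score(-5, running_extrema()),
               "not initialized")
  # degenerate extrema give the neutral signal
  ext1 <- update_extrema(running_extrema(), -7)
  expect_equal(transform_docking_score(-7, ext1), 0.5)
})

test_that("docking transform is monotone decreasing in ds", {
  ext <- update_extrema(running_extrema(), c(-11, -2.5))
  ds <- sort(runif(50, -15, 2))
  s <- transform_docking_score(ds, ext)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("widening extrema moves s_dock in the implied direction", {
  ext <- update_extrema(running_extrema(), c(-10, -5))
  s0 <- transform_docking_score(-7, ext)
  # a new, better (lower) minimum lowers the score of a fixed ds
  s_lower <- transform_docking_score(-7, update_extrema(ext, -14))
  expect_lt(s_lower, s0)
  # a new, worse maximum raises the score of a fixed ds
  s_higher <- transform_docking_score(-7, update_extrema(ext, 0))
  expect_gt(s_higher, s0)
})

test_that("desirability transform matches the piecewise definition", {
  lim <- desirability_limits(1, 3, 0, 4)
  expect_equal(desirability_transform(2, lim), 1)
  expect_equal(desirability_transform(4.5, lim), 0)
  expect_equal(desirability_transform(0.5, lim), 0.5)  # f_maxmin(0.5; 1, 0)
  expect_equal(desirability_transform(3.5, lim), 0.5)  # f_maxmin(3.5; 3, 4)
  expect_equal(desirability_transform(c(0, 4), lim), c(0, 0))
})

test_that("desirability transform is continuous and attains 1 exactly on the soft window", {
  lim <- desirability_limits(1, 3, 0, 4)
  x <- seq(-1, 5, by = 0.001)
  s <- desirability_transform(x, lim)
  expect_true(all(abs(diff(s)) < 0.0015))          # continuity
  expect_true(all((s == 1) == (x >= 1 & x <= 3)))  # exact plateau
})

test_that("soft == hard yields a step (consecutive rotors, donors)", {
  step3 <- desirability_limits(-Inf, 3, -Inf, 3)
  expect_equal(desirability_transform(c(0, 3, 4, 7), step3), c(1, 1, 0, 0))
})

test_that("synthesisability plug-in contract is enforced", {
  rec <- standardize_molecules(c("CCO", "c1ccccc1"))
  expect_equal(synthesisability_score(rec, function(r) rep(1, nrow(r))),
               c(1, 1))
  expect_error(
    synthesisability_score(rec, function(r) rep(1.2, nrow(r))),
    "contract")
  expect_warning(
    out <- synthesisability_score(rec, function(r) stop("backend down")),
    "failed")
  expect_equal(out, c(0, 0))
  # default surrogate: simple molecule scores at least as high as a cage
  cage <- standardize_molecules("C1C2CC3CC1CC(C2)C3")  # adamantane
  expect_gte(synth_surrogate(rec)[1], synth_surrogate(cage)[1])
})

test_that("reward is the arithmetic mean of five components", {
  sc <- make_scorer()
  out <- score_molecules(sc, c("c1ccc2nc(N)nc(N(C)C)c2c1", "not a smiles ((" ))
  v <- out[1, ]
  expect_true(v$valid)
  expect_equal(v$reward,
               (v$s_dock + v$s_synth + v$s_logp + v$s_crot + v$s_hbd) / 5)
  expect_false(out$valid[2])
  expect_equal(out$reward[2], 0)
  expect_true(all(out[2, c("s_dock", "s_synth", "s_logp", "s_crot",
                           "s_hbd")] == 0))
})

test_that("all components stay in [0,1] over random molecules and extrema", {
  corpus <- small_corpus()
  set.seed(4)
  sc <- make_scorer()
  for (batch in split(sample(corpus$canonical_smiles, 60),
                      rep(1:3, each = 20))) {
    out <- score_molecules(sc, batch)
    comp <- as.matrix(out[, c("s_dock", "s_synth", "s_logp", "s_crot",
                              "s_hbd", "reward")])
    expect_true(all(comp >= 0 & comp <= 1))
  }
  expect_gt(sc$extrema$n_observed, 0L)
  expect_lte(sc$extrema$ds_min, sc$extrema$ds_max)
})

test_that("consecutive rotatable bond counting matches enumeration", {
  expect_equal(max_consecutive_rotatable_bonds("c1ccccc1"), 0L)   # benzene
  expect_equal(max_consecutive_rotatable_bonds("CCCCCCC"), 4L)    # n-heptane
  expect_equal(max_consecutive_rotatable_bonds("Cc1ccccc1"), 0L)  # toluene
  # branched chain: longest rotor chain passes through the backbone
  expect_equal(max_consecutive_rotatable_bonds("CCC(CC)CC"), 3L)
  # amide bond is excluded under the strict convention
  expect_equal(max_consecutive_rotatable_bonds("CC(=O)NC"), 0L)
  expect_equal(max_consecutive_rotatable_bonds("CC(=O)NC",
                                               exclude_amide = FALSE), 1L)
})

test_that("hydrogen bond donor counts follow the Lipinski definition", {
  expect_equal(count_hydrogen_bond_donors("CO"), 1L)        # methanol
  expect_equal(count_hydrogen_bond_donors("c1ccccc1"), 0L)  # benzene
  expect_equal(count_hydrogen_bond_donors("OCC1OC(O)C(O)C(O)C1O"), 5L)
})

test_that("oracle caching returns identical scores for repeats", {
  sc <- make_scorer()
  calls <- 0L
  sc$oracle <- function(rec) {
    calls <<- calls + nrow(rec)
    mock_docking_oracle(rec)
  }
  out1 <- score_molecules(sc, c("c1ccccc1", "c1ccoc1"))
  out2 <- score_molecules(sc, c("c1ccccc1", "c1ccoc1"))
  expect_equal(out1$ds, out2$ds)
  expect_equal(calls, 2L)   # second batch fully served from cache
})
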