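# Scaffolds, clustering, MCS chemotypes, matching, rediscovery funnel.

test_that("Bemis-Murcko scaffolds prune substituents, keep frameworks", {
  expect_equal(murcko_scaffold("c1ccccc1"),
               canonicalize_smiles("c1ccccc1"))         # its own scaffold
  expect_equal(murcko_scaffold("Cc1ccccc1"),
               canonicalize_smiles("c1ccccc1"))         # methyl pruned
  expect_equal(murcko_scaffold("CCO"), "")              # acyclic
  # linker between two rings is retained
  expect_equal(murcko_scaffold("c1ccc(CCc2ccccc2)cc1"),
               canonicalize_smiles("c1ccc(CCc2ccccc2)cc1"))
  # whole acyl side chain pruned from a single ring system
  expect_equal(murcko_scaffold("CC(=O)Nc1ccccc1"),
               canonicalize_smiles("c1ccccc1"))
})

test_that("scaffold clustering is a partition with leader semantics", {
  # identical scaffolds collapse into one cluster
  cl <- cluster_scaffolds(rep("Cc1ccccc1", 4))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  # orthogonal scaffolds split
  cl2 <- cluster_scaffolds(c("Cc1ccccc1", "C1CNCCN1C"), sim_cutoff = 0.2)
  expect_equal(length(unique(cl2$cluster_id)), 2L)
  # three close analogues plus one unrelated scaffold -> sizes {3, 1}
  cl3 <- cluster_scaffolds(c("Cc1ccc2ncncc2c1", "CCc1ccc2ncncc2c1",
                             "c1cc2ncncc2cc1CCO", "CC1CCCCC1"),
                           sim_cutoff = 0.2)
  expect_equal(sort(as.vector(table(cl3$cluster_id))), c(1L, 3L))
  # acyclic molecules pool in the reserved bin 0
  cl4 <- cluster_scaffolds(c("CCO", "CCCN", "Cc1ccccc1"))
  expect_equal(cl4$cluster_id[1:2], c(0L, 0L))
  # every molecule lands in exactly one cluster
  expect_false(anyNA(cl4$cluster_id))
})

test_that("leader clustering agrees with the brute-force oracle", {
  corpus <- small_corpus()
  set.seed(9)
  for (rep_ in 1:3) {
    smi <- sample(corpus$canonical_smiles, 25)
    scaff <- murcko_scaffold(smi)
    keep <- nzchar(scaff)
    fps <- molahc:::ecfp4_fingerprints(scaff[keep])
    want <- brute_force_leader(fps, 0.4)
    got <- cluster_scaffolds(smi[keep], sim_cutoff = 0.4)
    expect_equal(got$cluster_id, want$assign)
  }
})

test_that("cluster MCS yields the shared core for 3+ members only", {
  ct <- extract_cluster_mcs(rep("c1ccccc1", 3), min_heavy_atoms = 6L)
  expect_s3_class(ct, "chemotype")
  expect_equal(ct$graph$n, 6L)
  expect_equal(canonicalize_smiles(ct$pattern),
               canonicalize_smiles("c1ccccc1"))
  # common core of homologous alkylbenzenes: ring + attachment carbon
  ct2 <- extract_cluster_mcs(c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"))
  expect_equal(ct2$graph$n, 7L)
  # a cluster of two is below the floor
  expect_null(extract_cluster_mcs(rep("c1ccccc1", 2)))
  # an MCS smaller than 6 heavy atoms is rejected
  expect_null(extract_cluster_mcs(c("CCO", "CCN", "CCC")))
})

test_that("derived chemotypes match all their own cluster members", {
  corpus <- small_corpus(60L, seed = 3L)
  cl <- cluster_scaffolds(corpus$canonical_smiles, sim_cutoff = 0.2)
  cts <- derive_chemotypes(cl, budget = 50000L)
  expect_gt(length(cts), 0L)
  for (ct in cts[seq_len(min(3, length(cts)))]) {
    expect_gte(ct$n_members, 3L)
    m <- match_chemotypes(ct$member_smiles, list(ct))
    expect_true(all(m))
  }
})

test_that("chemotype matching is substructure containment", {
  m <- match_chemotypes(c("Cc1ccccc1", "C1CCCCC1"),
                        list(benzene = "c1ccccc1"))
  expect_equal(as.vector(m), c(TRUE, FALSE))
  # empty library leaves everything unlabeled
  m0 <- match_chemotypes(c("CCO", "c1ccccc1"), list())
  expect_equal(ncol(m0), 0L)
  # unparsable pattern is skipped with a warning
  expect_warning(
    m2 <- match_chemotypes("c1ccccc1", list(bad = "q(((", ok = "c1ccccc1")),
    "unparsable")
  expect_equal(as.vector(m2), c(FALSE, TRUE))
})

test_that("rediscovery funnel is monotone and matches brute force", {
  samples <- c("CCO", "CCO", "c1ccccc1", "bad(((", "Cc1ccccc1",
               "CCN", "c1ccoc1")
  actives <- c("OCC")                       # same molecule as CCO
  vendor <- c("c1ccccc1", "CCN")
  rep_ <- rediscovery_report(samples, actives, vendor,
                             chemotype_library = list(benzene = "c1ccccc1"))
  expect_equal(rep_$n_valid, 6L)            # one unparsable
  expect_equal(rep_$n_unique, 5L)           # CCO duplicated
  expect_equal(rep_$n_novel, 3L)            # benzene, CCN in vendor set
  expect_equal(rep_$n_with_known_chemotype, 1L)  # toluene only
  expect_equal(rep_$n_known_actives_rediscovered, 1L)
  expect_true(rep_$n_valid >= rep_$n_unique &&
                rep_$n_unique >= rep_$n_novel &&
                rep_$n_novel >= rep_$n_with_known_chemotype)
})

test_that("funnel counts agree with an independent set-based oracle", {
  corpus <- small_corpus()
  set.seed(2)
  for (rep_ in 1:3) {
    samples <- sample(c(corpus$canonical_smiles[1:20], "((bad", "CCO"),
                      25, replace = TRUE)
    vendor <- sample(corpus$canonical_smiles[1:20], 8)
    got <- rediscovery_report(samples, character(0), vendor)
    canon <- canonicalize_smiles(samples)
    valid_oracle <- sum(!is.na(canon))
    uniq_oracle <- length(unique(canon[!is.na(canon)]))
    novel_oracle <- length(setdiff(unique(canon[!is.na(canon)]),
                                   canonicalize_smiles(vendor)))
    expect_equal(got$n_valid, valid_oracle)
    expect_equal(got$n_unique, uniq_oracle)
    expect_equal(got$n_novel, novel_oracle)
  }
})
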