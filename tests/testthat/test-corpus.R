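# Standardisation, curation filters, undersampling, randomisation,
# fixture generation, and the mock oracle.

test_that("standardisation canonicalizes, neutralizes and rejects", {
  rec <- standardize_molecules(c("OCC", "C1=CC=CC=C1", "C(",
                                 "[Na+].[O-]C(=O)c1ccccc1"))
  expect_equal(rec$canonical_smiles[1], "CCO")
  # Kekule benzene must standardize to the same form as aromatic input
  expect_equal(rec$canonical_smiles[2], canonicalize_smiles("c1ccccc1"))
  expect_false(rec$valid[3])
  expect_equal(rec$reason[3], "invalid")
  # salt: largest organic fragment kept, charge neutralized
  expect_equal(rec$canonical_smiles[4], canonicalize_smiles("OC(=O)c1ccccc1"))
  expect_false(rec$charged[4])
})

test_that("cached properties are recomputable from the canonical SMILES", {
  rec <- standardize_molecules(small_corpus()$canonical_smiles[1:25])
  rec2 <- standardize_molecules(rec$canonical_smiles)
  for (col in c("canonical_smiles", "mol_weight", "logp",
                "n_rotatable_bonds", "n_hbd", "n_hba",
                "n_aromatic_rings", "max_consec_rot")) {
    expect_equal(rec[[col]], rec2[[col]], info = col)
  }
})

test_that("curation applies the filter rules and names the first failure", {
  rec <- standardize_molecules(c(
    "CCO",                         # MW 46 -> below 150
    "NC(=O)c1ccc([Si](C)(C)C)cc1", # silicon (MW in range) -> elements
    "CC(=O)Oc1ccccc1C(=O)O"))      # aspirin -> passes
  out <- passes_curation(rec)
  expect_false(out$pass[1])
  expect_equal(out$fail_reason[1], "mw_min")
  expect_false(out$pass[2])
  # reason is elements unless silicon already trips an earlier rule
  expect_equal(out$fail_reason[2], "elements")
  # aspirin: MW ~180, logP ~1.3, <=3 rotatable bonds
  expect_true(out$pass[3])
  expect_equal(out$mol_weight[3], 180.16, tolerance = 0.01)
  expect_lte(out$n_rotatable_bonds[3], 3L)
})

test_that("curation is idempotent under re-standardisation", {
  rec <- passes_curation(standardize_molecules(
    c(small_corpus()$canonical_smiles[1:10], "CCO")))
  rec2 <- passes_curation(standardize_molecules(rec$canonical_smiles))
  expect_equal(rec$pass, rec2$pass)
  expect_equal(rec$fail_reason, rec2$fail_reason)
})

test_that("structural alerts are caught by the generic pattern engine", {
  rec <- standardize_molecules(c("O=C(Cl)c1ccc(-c2ccccc2)cc1",   # acyl chloride
                                 "OOc1ccc(-c2ccccc2)cc1"))       # peroxide
  out <- passes_curation(rec)
  expect_true(all(!out$pass))
  expect_true(all(grepl("^alert:", out$fail_reason)))
})

test_that("scaffold undersampling keeps one centroid per cluster", {
  # five copies collapse to one
  rec <- standardize_molecules(rep("Cc1ccccc1CCN", 5))
  expect_equal(nrow(undersample_by_scaffold(rec)), 1L)
  # dissimilar scaffolds are all retained
  rec2 <- standardize_molecules(c("Cc1ccccc1", "CC1CCNCC1", "CC1CCSC1"))
  expect_equal(nrow(undersample_by_scaffold(rec2, 0.8)), 3L)
  # toluene/ethylbenzene share the benzene scaffold; cyclohexane differs
  rec3 <- standardize_molecules(c("Cc1ccccc1", "CCc1ccccc1", "C1CCCCC1"))
  scaff <- murcko_scaffold(rec3$canonical_smiles)
  fps <- molahc:::ecfp4_fingerprints(scaff)
  sim <- molahc:::tanimoto(fps[1, , drop = FALSE], fps[2, , drop = FALSE])
  out <- undersample_by_scaffold(rec3, 0.8)
  expected_n <- if (sim[1, 1] >= 0.8) 2L else 3L
  expect_equal(nrow(out), expected_n)
  # output is always a subset of the input
  expect_true(all(out$canonical_smiles %in% rec3$canonical_smiles))
})

test_that("restricted randomisation is label-preserving and n-fold", {
  corpus <- small_corpus()
  smi <- corpus$canonical_smiles[1:100]
  aug <- randomized_smiles(smi, n = 10L, seed = 3L)   # 1000 spellings
  expect_true(all(lengths(aug) == 10L))
  recan <- canonicalize_smiles(unlist(aug))
  expect_identical(recan, rep(smi, each = 10L))
  # methane admits a single spelling
  expect_equal(unique(randomized_smiles("C", n = 10L, seed = 1L)[[1]]), "C")
  # deterministic under the seed
  expect_identical(aug, randomized_smiles(smi, n = 10L, seed = 3L))
})

test_that("fixture corpus generation is pure in (spec, seed)", {
  a <- generate_fixture_corpus(fixture_spec(n_molecules = 60L, seed = 1L))
  b <- generate_fixture_corpus(fixture_spec(n_molecules = 60L, seed = 1L))
  expect_identical(a$canonical_smiles, b$canonical_smiles)
  c_ <- generate_fixture_corpus(fixture_spec(n_molecules = 60L, seed = 2L))
  expect_false(identical(a$canonical_smiles, c_$canonical_smiles))
  expect_true(all(a$pass))
  expect_false(anyDuplicated(a$canonical_smiles) > 0L)
})

test_that("fixture generation errors when the space is exhausted", {
  sp <- fixture_spec(n_molecules = 500L, seed = 1L,
                     scaffold_library = "c1ccc2sc({R1})nc2c1",
                     decoration_library = c("CCO", "CCC", "N(C)C"))
  expect_error(generate_fixture_corpus(sp), "exhausted")
})

test_that("mock oracle follows its closed form", {
  # benzene: 1 aromatic ring, 0 acceptors, 0 consecutive rotors
  expect_equal(mock_docking_oracle("c1ccccc1"), -2)
  # furan: 1 aromatic ring, 1 N+O acceptor
  expect_equal(mock_docking_oracle("c1ccoc1"), -3)
  expect_equal(mock_docking_oracle("C"), 0)
  # closed form on records
  rec <- small_corpus()[1:20, ]
  expect_equal(mock_docking_oracle(rec),
               -(2 * rec$n_aromatic_rings + rec$n_hba) +
                 0.7 * rec$max_consec_rot)
})

test_that("smi/csv round trip preserves molecules", {
  smi <- c("CCO", "c1ccccc1", "CC(=O)N")
  p <- tempfile(fileext = ".smi")
  write_smi(smi, p, id = c("a", "b", "c"))
  rd <- read_smi(p)
  expect_equal(rd$smiles, smi)
  expect_equal(rd$id, c("a", "b", "c"))
  pc <- tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = smi), pc, row.names = FALSE)
  expect_equal(read_smi(pc)$smiles, smi)
})
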