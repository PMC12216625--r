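# Synthetic fixture corpora: combinatorial scaffold decoration emulating
# a curated drug-like training set, plus a deterministic mock
# structure-based oracle used as the reward plug-in in tests and
# examples.

.default_scaffold_library <- function() c(
  "c1cc({R1})ccc1Oc1ccc({R2})cc1",        # diaryl ether
  "c1cc({R1})ccc1-c1ccc({R2})cc1",        # biphenyl
  "c1ccc2nc({R1})nc({R2})c2c1",           # quinazoline
  "c1ccc(-c2nc({R1})nc({R2})n2)cc1",      # phenyl-1,3,5-triazine
  "c1ccc2sc({R1})nc2c1",                  # benzothiazole
  "c1ccc2[nH]c({R1})nc2c1",               # benzimidazole
  "O=C({R1})Nc1ccc({R2})cc1",             # anilide
  "c1cc({R1})nc(-c2ccc({R2})cc2)n1",      # 2-phenylpyrimidine
  "c1ccc(N2CCN({R1})CC2)cc1",             # phenylpiperazine
  "c1ccc2nc({R1})ccc2c1",                 # quinoline
  "c1ccc(-c2oc({R1})cc2)cc1",             # 2-phenylfuran
  "c1ccc(-c2nc({R1})cs2)cc1"              # 2-phenylthiazole
)

.default_decoration_library <- function() c(
  "C", "CC", "CCC", "C(C)C", "CC(C)C", "CCO", "OC", "OCC", "N", "NC",
  "N(C)C", "CCN", "F", "Cl", "C(F)(F)F", "C#N", "OCCO", "CO",
  "N1CCOCC1", "S(C)(=O)=O", "c1ccncc1", "CC(C)O", "NCC", "OCC(C)C"
)

#' Fixture corpus specification
#'
#' Defines a deterministic synthetic corpus built by combinatorial
#' scaffold decoration. Generation is a pure function of the spec
#' (including its seed): the full combination grid is shuffled with the
#' seed and combinations are standardized and filtered until
#' `n_molecules` unique curation-passing molecules are collected.
#'
#' @param n_molecules number of molecules to generate.
#' @param seed integer seed.
#' @param scaffold_library character vector of scaffold templates with
#'   `{R1}` (and optionally `{R2}`) decoration sites.
#' @param decoration_library character vector of substituent fragments.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 2000L, seed = 42L,
                         scaffold_library = .default_scaffold_library(),
                         decoration_library = .default_decoration_library()) {
  stopifnot(n_molecules >= 1L, length(scaffold_library) > 0L,
            length(decoration_library) > 0L)
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed),
                 scaffold_library = scaffold_library,
                 decoration_library = decoration_library),
            class = "fixture_spec")
}

#' Generate a synthetic fixture corpus
#'
#' Enumerates scaffold/decoration combinations in a seed-shuffled order,
#' standardizes each candidate, and keeps unique molecules passing the
#' curation filters until the requested count is reached. The result is
#' bit-identical across runs with the same spec.
#'
#' @param spec a [fixture_spec()].
#' @param config curation filters the corpus must satisfy.
#' @return a `molecule_record` data frame of `spec$n_molecules` rows.
#' @export
generate_fixture_corpus <- function(spec = fixture_spec(),
                                    config = curation_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  scaf <- spec$scaffold_library
  deco <- spec$decoration_library
  two_site <- grepl("{R2}", scaf, fixed = TRUE)
  combos <- list()
  for (s in seq_along(scaf)) {
    if (two_site[s]) {
      grid <- expand.grid(s = s, d1 = seq_along(deco), d2 = seq_along(deco))
    } else {
      grid <- expand.grid(s = s, d1 = seq_along(deco), d2 = NA_integer_)
    }
    combos[[s]] <- grid
  }
  combos <- do.call(rbind, combos)
  total <- nrow(combos)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  ord <- sample.int(total)

  build <- function(row) {
    smi <- gsub("{R1}", deco[row$d1], scaf[row$s], fixed = TRUE)
    if (!is.na(row$d2)) smi <- gsub("{R2}", deco[row$d2], smi, fixed = TRUE)
    smi
  }

  collected <- NULL
  seen <- character(0)
  pos <- 1L
  chunk <- 500L
  while (pos <= total &&
         (is.null(collected) || nrow(collected) < spec$n_molecules)) {
    take <- ord[pos:min(pos + chunk - 1L, total)]
    pos <- pos + chunk
    smi <- vapply(take, function(i) build(combos[i, ]), "")
    rec <- standardize_molecules(smi)
    rec <- passes_curation(rec, config)
    keep <- rec$pass & !(rec$canonical_smiles %in% seen) &
      !duplicated(rec$canonical_smiles)
    rec <- rec[keep, , drop = FALSE]
    seen <- c(seen, rec$canonical_smiles)
    collected <- if (is.null(collected)) rec else rbind(collected, rec)
  }
  if (is.null(collected) || nrow(collected) < spec$n_molecules) {
    stop(sprintf(paste0("fixture space exhausted: only %d unique ",
                        "curation-passing molecules available from %d ",
                        "combinations; requested %d"),
                 if (is.null(collected)) 0L else nrow(collected),
                 total, spec$n_molecules))
  }
  out <- collected[seq_len(spec$n_molecules), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("molecule_record", "data.frame"))
}

#' Mock structure-based oracle
#'
#' A deterministic, analytically checkable stand-in for a docking
#' engine, used as the reward oracle in tests and examples:
#' \deqn{ds = -(2 n_{arom} + n_{HBA}) + 0.7\, c_{rot}}
#' where \eqn{n_{arom}} is the aromatic ring count, \eqn{n_{HBA}} the
#' Lipinski acceptor (N+O) count, and \eqn{c_{rot}} the maximum
#' consecutive rotatable-bond count. Lower is better, mimicking a
#' docking score. It is explicitly a test double, not a docking
#' surrogate.
#'
#' @param records a `molecule_record` data frame (cached properties are
#'   used) or a character vector of SMILES (standardized first).
#' @return numeric vector of mock docking scores (NA for invalid rows).
#' @export
#' @examples
#' mock_docking_oracle("c1ccccc1")  # -2
#' mock_docking_oracle("c1ccoc1")   # -3
mock_docking_oracle <- function(records) {
  if (is.character(records)) records <- standardize_molecules(records)
  stopifnot(is.data.frame(records))
  ds <- -(2 * records$n_aromatic_rings + records$n_hba) +
    0.7 * records$max_consec_rot
  as.numeric(ds)
}

#' Toy known-chemotype library
#'
#' A small pattern library shipped for tests and examples of chemotype
#' rediscovery; patterns are SMILES substructures of the fixture
#' scaffolds. The real workflow takes an expert-curated library as
#' input data.
#'
#' @return named character vector of patterns.
#' @export
toy_chemotype_library <- function() {
  read_pattern_file(system.file("extdata", "chemotypes_toy.txt",
                                package = "molahc"))
}
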