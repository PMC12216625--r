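# Corpus curation: molecule standardization, drug-likeness filters,
# scaffold-cluster undersampling, and restricted SMILES randomisation.

#' Curation configuration
#'
#' Thresholds for the drug-like corpus filters: Crippen-type logP at most
#' 4.5, at most 7 rotatable bonds, molecular weight 150-650 Da, atoms
#' restricted to \{C, S, O, N, H, F, Cl, Br\}, and no structural-alert
#' match. `alert_patterns` is any character vector of SMARTS; the default
#' is the reactive-group alert set shipped with the package.
#'
#' @param logp_max,rotbond_max,mw_min,mw_max numeric thresholds.
#' @param allowed_elements character vector of element symbols.
#' @param alert_patterns character vector of SMARTS patterns (named or not).
#' @param cluster_sim_threshold Tanimoto threshold for scaffold-cluster
#'   undersampling.
#' @return object of class `curation_config`.
#' @export
curation_config <- function(logp_max = 4.5, rotbond_max = 7L,
                            mw_min = 150, mw_max = 650,
                            allowed_elements = c("C", "S", "O", "N", "H",
                                                 "F", "Cl", "Br"),
                            alert_patterns = default_alert_patterns(),
                            cluster_sim_threshold = 0.8) {
  stopifnot(mw_min < mw_max, is.finite(logp_max), is.finite(rotbond_max))
  structure(list(logp_max = logp_max, rotbond_max = as.integer(rotbond_max),
                 mw_min = mw_min, mw_max = mw_max,
                 allowed_elements = allowed_elements,
                 alert_patterns = alert_patterns,
                 cluster_sim_threshold = cluster_sim_threshold),
            class = "curation_config")
}

#' Default structural-alert SMARTS patterns
#'
#' A compact reactive-group alert set (acyl halides, anhydrides,
#' peroxides, azides, isocyanates, epoxides/aziridines, ...) read from
#' the pattern file shipped with the package. The curation engine is
#' generic over any pattern list; supply your own file to
#' [read_pattern_file()] to use a different alert collection.
#'
#' @return named character vector of SMARTS.
#' @export
default_alert_patterns <- function() {
  read_pattern_file(system.file("extdata", "alerts_default.txt",
                                package = "molahc"))
}

#' Read a pattern-list file
#'
#' One pattern per line, either `ID<TAB>pattern` or bare `pattern`;
#' empty lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return named character vector of patterns.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][1L] else paste0("p", i)
  }, "")
  pats <- vapply(parts, function(x) x[[length(x)]], "")
  setNames(pats, ids)
}

#' Standardize raw SMILES into molecule records
#'
#' Each input is lexically checked, reduced to its largest organic
#' fragment, charge-neutralized where valence permits, canonicalized, and
#' annotated with cached physicochemical properties. Unparsable inputs
#' yield a row with `valid = FALSE` and `reason = "invalid"`; molecules
#' whose charge cannot be neutralized (e.g. quaternary nitrogen) are
#' retained with `charged = TRUE`.
#'
#' @param raw_smiles character vector of SMILES.
#' @return a `molecule_record` data frame with one row per input:
#'   `raw_smiles`, `canonical_smiles`, `mol_weight`, `logp`,
#'   `n_rotatable_bonds`, `n_hbd`, `n_hba`, `n_aromatic_rings`,
#'   `n_heavy`, `max_consec_rot`, `elements` (list column), `charged`,
#'   `valid`, `reason`.
#' @export
#' @examples
#' standardize_molecules(c("OCC", "C1=CC=CC=C1", "C("))
standardize_molecules <- function(raw_smiles) {
  n <- length(raw_smiles)
  rec <- data.frame(raw_smiles = as.character(raw_smiles),
                    canonical_smiles = NA_character_,
                    mol_weight = NA_real_, logp = NA_real_,
                    n_rotatable_bonds = NA_integer_, n_hbd = NA_integer_,
                    n_hba = NA_integer_, n_aromatic_rings = NA_integer_,
                    n_heavy = NA_integer_, max_consec_rot = NA_integer_,
                    charged = FALSE, valid = FALSE, reason = "invalid",
                    stringsAsFactors = FALSE)
  rec$elements <- replicate(n, character(0), simplify = FALSE)
  if (n == 0L) return(structure(rec, class = c("molecule_record", "data.frame")))

  # largest organic fragment of each multi-fragment (salt) entry
  frag <- vapply(raw_smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) <= 1L) return(s)
    heavy <- vapply(parts, function(p) {
      toks <- tokenize_smiles(p)
      if (is.null(toks)) return(-1L)
      ats <- .atom_tokens(toks)
      length(ats)
    }, integer(1))
    has_c <- vapply(parts, function(p) grepl("[Cc]", gsub("Cl", "", p)), logical(1))
    score <- heavy + ifelse(has_c, 1000L, 0L)
    parts[which.max(score)]
  }, "", USE.NAMES = FALSE)

  canon <- canonicalize_smiles(frag, neutralize = TRUE)
  ok <- !is.na(canon)
  rec$canonical_smiles[ok] <- canon[ok]
  if (any(ok)) {
    props <- ob_properties(canon[ok])
    graphs <- mol_graphs(canon[ok])
    rec$mol_weight[ok] <- props$mol_weight
    rec$logp[ok] <- props$logp
    rec$n_hbd[ok] <- props$n_hbd
    rec$n_hba[ok] <- vapply(graphs, count_n_plus_o, integer(1))
    rec$n_aromatic_rings[ok] <- vapply(graphs, function(g) {
      if (is.null(g)) NA_integer_ else count_aromatic_rings(g)
    }, integer(1))
    rec$n_heavy[ok] <- vapply(graphs, function(g) {
      if (is.null(g)) NA_integer_ else g$n
    }, integer(1))
    rec$n_rotatable_bonds[ok] <- vapply(graphs, count_rotatable_bonds,
                                        integer(1))
    rec$max_consec_rot[ok] <- vapply(graphs, function(g) {
      if (is.null(g)) return(NA_integer_)
      as.integer(.longest_rotor_chain(g, .rotatable_bond_ids(g, TRUE)))
    }, integer(1))
    rec$elements[ok] <- smiles_elements(canon[ok])
    rec$charged[ok] <- smiles_net_charge(canon[ok]) != 0L
    parsed <- ok & !is.na(rec$mol_weight)
    rec$valid[parsed] <- TRUE
    rec$reason[parsed] <- ""
    rec$reason[ok & rec$charged] <- ifelse(rec$valid[ok & rec$charged],
                                           "charged", "invalid")
  }
  structure(rec, class = c("molecule_record", "data.frame"))
}

#' Apply the drug-likeness curation filters
#'
#' Checks each standardized record against the curation thresholds.
#' `reason` names the first failed rule among `mw_min`, `mw_max`,
#' `logp_max`, `rotbond_max`, `elements`, `alert:<id>`; records that
#' failed standardization fail with reason `invalid`.
#'
#' @param records a `molecule_record` data frame from
#'   [standardize_molecules()].
#' @param config a [curation_config()].
#' @return `records` with logical column `pass` and character column
#'   `fail_reason` appended.
#' @export
passes_curation <- function(records, config = curation_config()) {
  stopifnot(inherits(records, "data.frame"))
  n <- nrow(records)
  pass <- rep(TRUE, n)
  reason <- rep("", n)
  fail <- function(idx, why) {
    hit <- idx & pass
    pass[hit] <<- FALSE
    reason[hit] <<- why
  }
  fail(!records$valid, "invalid")
  fail(records$valid & records$mol_weight < config$mw_min, "mw_min")
  fail(records$valid & records$mol_weight > config$mw_max, "mw_max")
  fail(records$valid & records$logp > config$logp_max, "logp_max")
  fail(records$valid & records$n_rotatable_bonds > config$rotbond_max,
       "rotbond_max")
  bad_elem <- vapply(seq_len(n), function(i) {
    records$valid[i] &&
      length(setdiff(records$elements[[i]], config$allowed_elements)) > 0L
  }, logical(1))
  fail(bad_elem, "elements")
  if (length(config$alert_patterns)) {
    todo <- which(pass & records$valid)
    if (length(todo)) {
      smi <- records$canonical_smiles[todo]
      for (k in seq_along(config$alert_patterns)) {
        live <- pass[todo]
        if (!any(live)) break
        cnt <- smarts_counts(smi, config$alert_patterns[[k]])
        hitv <- rep(FALSE, n)
        hitv[todo[!is.na(cnt) & cnt > 0L]] <- TRUE
        fail(hitv, paste0("alert:", names(config$alert_patterns)[k]))
      }
    }
  }
  records$pass <- pass
  records$fail_reason <- reason
  records
}

#' Scaffold-cluster undersampling
#'
#' Leader-style sphere-exclusion clustering on the ECFP4 Tanimoto
#' similarity of Bemis-Murcko scaffolds: records are visited in input
#' order, each joining the first existing cluster whose leader scaffold
#' has similarity at least `sim_threshold`, otherwise founding a new
#' cluster. Only the leaders (centroids) are returned, evening out
#' densely sampled chemical series. Acyclic molecules (empty scaffold)
#' share one cluster.
#'
#' @param records `molecule_record` data frame.
#' @param sim_threshold Tanimoto threshold in (0, 1] (default 0.8).
#' @return the subset of `records` that are cluster leaders, with a
#'   `cluster_id` column.
#' @export
undersample_by_scaffold <- function(records, sim_threshold = 0.8) {
  stopifnot(sim_threshold > 0, sim_threshold <= 1)
  n <- nrow(records)
  if (n == 0L) return(records)
  scaff <- murcko_scaffold(records$canonical_smiles)
  fps <- ecfp4_fingerprints(scaff)
  leaders <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    if (length(leaders)) {
      sims <- tanimoto(fps[i, , drop = FALSE],
                       fps[leaders, , drop = FALSE])[1, ]
      j <- which(sims >= sim_threshold)
      if (length(j)) {
        assign[i] <- j[1]
        next
      }
    }
    leaders <- c(leaders, i)
    assign[i] <- length(leaders)
  }
  out <- records[leaders, , drop = FALSE]
  out$cluster_id <- seq_along(leaders)
  rownames(out) <- NULL
  out
}

#' Restricted SMILES randomisation
#'
#' Generates alternative SMILES spellings of the same molecule by random
#' atom reordering: the molecule's connection table is rewritten with a
#' random atom permutation and re-serialized (non-canonically), leaving
#' branching and ring-closure conventions to the SMILES writer. Every
#' output re-canonicalizes to the source molecule. Duplicates among the
#' `n` outputs are possible for small molecules.
#'
#' @param smiles character vector of (canonical) SMILES.
#' @param n number of randomized variants per molecule.
#' @param seed integer seed; output is deterministic given (input, n, seed).
#' @return a list with one character vector of length `n` per input
#'   molecule (entries fall back to the input spelling if a permutation
#'   fails to serialize).
#' @export
#' @examples
#' randomized_smiles("Cc1ccccc1CCN", n = 3, seed = 1)
randomized_smiles <- function(smiles, n = 10L, seed = 1L) {
  stopifnot(n >= 1L)
  nm <- length(smiles)
  out <- lapply(seq_len(nm), function(i) rep(smiles[i], n))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                 collapse = "\n")
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", input, options = .ob_options()),
                  error = function(e) "")
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[vapply(blocks, function(b)
    length(strsplit(b, "\n", fixed = TRUE)[[1]]) >= 4L, logical(1))]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  perm_blocks <- character(0)
  perm_titles <- character(0)
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    title <- trimws(lines[1])
    pos <- match(title, .mol_titles(length(idx)))
    if (is.na(pos)) next
    counts <- lines[4]
    na_ <- as.integer(substr(counts, 1, 3))
    nb_ <- as.integer(substr(counts, 4, 6))
    if (is.na(na_) || na_ < 1L) next
    atoms <- lines[5:(4 + na_)]
    bondl <- if (nb_ > 0L) lines[(5 + na_):(4 + na_ + nb_)] else character(0)
    for (k in seq_len(n)) {
      perm <- if (na_ > 1L) sample.int(na_) else 1L
      inv <- order(perm)
      newb <- vapply(bondl, function(l) {
        a1 <- as.integer(substr(l, 1, 3))
        a2 <- as.integer(substr(l, 4, 6))
        paste0(formatC(inv[a1], width = 3), formatC(inv[a2], width = 3),
               substr(l, 7, nchar(l)))
      }, "", USE.NAMES = FALSE)
      ttl <- paste0(title, "_", k)
      perm_blocks <- c(perm_blocks,
                       paste(c(ttl, lines[2:3], counts, atoms[perm], newb,
                               "M  END", "$$$$"), collapse = "\n"))
      perm_titles <- c(perm_titles, ttl)
    }
  }
  if (!length(perm_blocks)) return(out)
  res <- tryCatch(
    ChemmineOB::convertFormat("SDF", "SMI", paste(perm_blocks, collapse = "\n")),
    error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    m <- regmatches(p[2], regexec("^m([0-9]+)_([0-9]+)$", trimws(p[2])))[[1]]
    if (length(m) == 3L) {
      i <- idx[as.integer(m[2])]
      k <- as.integer(m[3])
      if (nzchar(p[1])) out[[i]][k] <- p[1]
    }
  }
  out
}

# --- file I/O --------------------------------------------------------------

#' Read and write SMILES files
#'
#' `read_smi()` reads a `.smi` file (one SMILES per line with an optional
#' tab-separated identifier) or a CSV with a `smiles` column.
#' `write_smi()` writes the complementary `.smi` format.
#'
#' @param path file path.
#' @return `read_smi()`: data frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    cn <- tolower(names(df))
    if (!"smiles" %in% cn) stop("CSV must contain a 'smiles' column")
    smiles <- df[[which(cn == "smiles")[1]]]
    id <- if ("id" %in% cn) as.character(df[[which(cn == "id")[1]]]) else
      as.character(seq_along(smiles))
    return(data.frame(smiles = smiles, id = id, stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  data.frame(
    smiles = vapply(parts, `[`, "", 1L),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2L) parts[[i]][2L] else as.character(i)
    }, ""),
    stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param smiles character vector of SMILES to write.
#' @param id optional identifiers.
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a curation report
#'
#' CSV with one row per molecule: input SMILES, canonical SMILES, pass
#' flag and failure reason.
#'
#' @param records output of [passes_curation()].
#' @param path output CSV path.
#' @export
write_curation_report <- function(records, path) {
  write.csv(records[, c("raw_smiles", "canonical_smiles", "pass",
                        "fail_reason")],
            path, row.names = FALSE)
  invisible(path)
}
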