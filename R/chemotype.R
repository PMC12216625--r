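# Chemistry assessment: Bemis-Murcko scaffolds, ECFP4 leader clustering,
# maximum-common-substructure chemotype mining, substructure matching,
# and the validity/uniqueness/novelty/rediscovery funnel.

# extract a sub-molecule molblock given kept atom indices (bonds induced)
.extract_submol <- function(lines, keep, bonds_keep = NULL, title = "sub") {
  counts <- lines[4]
  na_ <- as.integer(substr(counts, 1, 3))
  nb_ <- as.integer(substr(counts, 4, 6))
  atoms <- lines[5:(4 + na_)]
  bondl <- if (nb_ > 0L) lines[(5 + na_):(4 + na_ + nb_)] else character(0)
  newid <- match(seq_len(na_), keep)
  kept_bonds <- character(0)
  for (bi in seq_along(bondl)) {
    l <- bondl[bi]
    a1 <- as.integer(substr(l, 1, 3))
    a2 <- as.integer(substr(l, 4, 6))
    if (!is.na(newid[a1]) && !is.na(newid[a2]) &&
        (is.null(bonds_keep) || bi %in% bonds_keep)) {
      kept_bonds <- c(kept_bonds,
                      paste0(formatC(newid[a1], width = 3),
                             formatC(newid[a2], width = 3),
                             substr(l, 7, nchar(l))))
    }
  }
  cnt <- paste0(formatC(length(keep), width = 3),
                formatC(length(kept_bonds), width = 3),
                substr(counts, 7, nchar(counts)))
  paste(c(title, lines[2:3], cnt, atoms[keep], kept_bonds, "M  END", "$$$$"),
        collapse = "\n")
}

#' Bemis-Murcko scaffold
#'
#' Returns the molecular framework: all ring systems plus the linker
#' atoms connecting them, with substituents pruned (terminal atoms
#' attached by single bonds are removed iteratively; exocyclic
#' double-bonded atoms such as carbonyl oxygens are retained). Acyclic
#' molecules yield the empty string.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of scaffold SMILES ("" for acyclic, NA for
#'   unparsable input).
#' @export
#' @examples
#' murcko_scaffold(c("c1ccccc1", "Cc1ccccc1", "CCO"))
murcko_scaffold <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                 collapse = "\n")
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", input, options = .ob_options()),
                  error = function(e) "")
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  sub_blocks <- character(0)
  sub_titles <- character(0)
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    if (length(lines) < 4L) next
    title <- trimws(lines[1])
    pos <- match(title, .mol_titles(length(idx)))
    if (is.na(pos)) next
    g <- .parse_molblock(lines, smiles[idx[pos]])
    if (is.null(g)) next
    if (!any(g$ring_atom)) {
      out[idx[pos]] <- ""
      next
    }
    keep <- rep(TRUE, g$n)
    b <- g$bonds
    # iteratively prune terminal atoms: what remains is rings + linkers
    repeat {
      live <- keep[b$a1] & keep[b$a2]
      deg <- tabulate(c(b$a1[live], b$a2[live]), nbins = g$n)
      drop <- setdiff(which(keep & deg <= 1L), which(g$ring_atom))
      if (!length(drop)) break
      keep[drop] <- FALSE
    }
    # re-attach exocyclic double/triple-bonded atoms (e.g. carbonyl O)
    readd <- b$order >= 2L &
      (xor(keep[b$a1], keep[b$a2]))
    keep[c(b$a1[readd], b$a2[readd])] <- TRUE
    if (!any(keep)) {
      out[idx[pos]] <- ""
      next
    }
    ttl <- paste0("s", pos)
    sub_blocks <- c(sub_blocks,
                    .extract_submol(lines, which(keep), title = ttl))
    sub_titles <- c(sub_titles, ttl)
  }
  if (length(sub_blocks)) {
    res <- tryCatch(
      ChemmineOB::convertFormat(
        "SDF", "CAN", paste(sub_blocks, collapse = "\n")),
      error = function(e) "")
    lns <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lns <- lns[nzchar(lns)]
    for (p in strsplit(lns, "\t", fixed = TRUE)) {
      if (length(p) < 2L) next
      m <- regmatches(p[2], regexec("^s([0-9]+)$", trimws(p[2])))[[1]]
      if (length(m) == 2L) out[idx[as.integer(m[2])]] <- p[1]
    }
  }
  out
}

# --- labeled-graph utilities for MCS and matching --------------------------

# atom label: element + aromatic flag; bond label: aromatic or bond order
.graph_labels <- function(g) {
  atom <- paste0(g$element, ifelse(g$aromatic, ":a", ""))
  bond <- ifelse(g$bonds$aromatic, "ar", as.character(g$bonds$order))
  adj <- matrix("", g$n, g$n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      adj[g$bonds$a1[i], g$bonds$a2[i]] <- bond[i]
      adj[g$bonds$a2[i], g$bonds$a1[i]] <- bond[i]
    }
  }
  list(atom = atom, adj = adj, n = g$n)
}

# Maximum common connected induced subgraph of two labeled graphs,
# McGregor-style backtracking with a node-expansion budget.
# Returns list(map1, map2, timeout).
.mcs_pair <- function(l1, l2, budget = 200000L) {
  n1 <- l1$n; n2 <- l2$n
  compat <- outer(l1$atom, l2$atom, "==")
  env <- new.env()
  env$best1 <- integer(0); env$best2 <- integer(0)
  env$nodes <- 0L; env$timeout <- FALSE

  extend <- function(map1, map2, excluded) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > budget) { env$timeout <- TRUE; return(invisible()) }
    if (length(map1) > length(env$best1)) {
      env$best1 <- map1; env$best2 <- map2
    }
    free1 <- setdiff(seq_len(n1), c(map1, excluded))
    free2 <- setdiff(seq_len(n2), map2)
    # upper bound: even mapping every remaining atom cannot beat best
    if (length(map1) + min(length(free1), length(free2)) <=
        length(env$best1)) {
      return(invisible())
    }
    if (!length(free1) || !length(free2)) return(invisible())
    # candidates adjacent to the mapped core (connected growth)
    adj1 <- free1[vapply(free1, function(a)
      any(l1$adj[a, map1] != ""), logical(1))]
    if (!length(adj1)) return(invisible())
    a <- adj1[1]
    for (bq in free2) {
      if (env$timeout) return(invisible())
      if (!compat[a, bq]) next
      okv <- TRUE
      for (k in seq_along(map1)) {
        if (l1$adj[a, map1[k]] != l2$adj[bq, map2[k]]) { okv <- FALSE; break }
      }
      if (okv) extend(c(map1, a), c(map2, bq), excluded)
    }
    # branch where atom `a` is not part of the common subgraph
    extend(map1, map2, c(excluded, a))
    invisible()
  }

  ord1 <- order(vapply(seq_len(n1), function(a)
    sum(l1$atom == l1$atom[a]), numeric(1)))  # rare labels first
  roots_done <- integer(0)
  for (a in ord1) {
    if (env$timeout) break
    for (bq in seq_len(n2)) {
      if (env$timeout) break
      if (compat[a, bq]) extend(a, bq, roots_done)
    }
    # symmetry: later roots never re-map an already-tried root atom
    roots_done <- c(roots_done, a)
    if (length(env$best1) >= min(n1, n2)) break
  }
  list(map1 = env$best1, map2 = env$best2, timeout = env$timeout)
}

# induced labeled subgraph of g restricted to atom indices `keep`
.induced_subgraph <- function(g, keep) {
  newid <- match(seq_len(g$n), keep)
  b <- g$bonds
  sel <- !is.na(newid[b$a1]) & !is.na(newid[b$a2])
  bb <- b[sel, , drop = FALSE]
  bb$a1 <- newid[bb$a1]; bb$a2 <- newid[bb$a2]
  out <- list(n = length(keep), element = g$element[keep],
              aromatic = g$aromatic[keep], bonds = bb,
              smiles = NA_character_)
  deg <- tabulate(c(bb$a1, bb$a2), nbins = out$n)
  out$degree <- deg
  out$ring_atom <- g$ring_atom[keep]
  out
}

#' Cluster molecules by scaffold similarity
#'
#' Leader-style clustering on the ECFP4 Tanimoto similarity of
#' Bemis-Murcko scaffolds: molecules are visited in input order and join
#' the first cluster whose leader scaffold has similarity at least
#' `sim_cutoff`, otherwise founding a new cluster. Acyclic molecules
#' (empty scaffold) are pooled in the reserved cluster 0, which is
#' excluded from chemotype derivation.
#'
#' @param smiles character vector of canonical SMILES.
#' @param sim_cutoff minimum Tanimoto similarity to join a cluster
#'   (default 0.2, a deliberately permissive grouping).
#' @return data frame with columns `smiles`, `scaffold`, `cluster_id`.
#' @export
cluster_scaffolds <- function(smiles, sim_cutoff = 0.2) {
  stopifnot(sim_cutoff > 0, sim_cutoff <= 1)
  n <- length(smiles)
  scaff <- murcko_scaffold(smiles)
  cluster <- rep(NA_integer_, n)
  cyclic <- which(!is.na(scaff) & nzchar(scaff))
  cluster[!is.na(scaff) & !nzchar(scaff)] <- 0L
  if (length(cyclic)) {
    fps <- ecfp4_fingerprints(scaff[cyclic])
    leaders <- integer(0)
    for (k in seq_along(cyclic)) {
      if (length(leaders)) {
        sims <- tanimoto(fps[k, , drop = FALSE],
                         fps[leaders, , drop = FALSE])[1, ]
        j <- which(sims >= sim_cutoff)
        if (length(j)) {
          cluster[cyclic[k]] <- j[1]
          next
        }
      }
      leaders <- c(leaders, k)
      cluster[cyclic[k]] <- length(leaders)
    }
  }
  data.frame(smiles = smiles, scaffold = scaff, cluster_id = cluster,
             stringsAsFactors = FALSE)
}

#' Derive the chemotype of a cluster by maximum common substructure
#'
#' Computes the maximum common connected substructure of all cluster
#' members (iterated pairwise, labels: element + aromaticity, bond order)
#' and returns it as a chemotype when the cluster has at least
#' `min_members` molecules and the substructure has at least
#' `min_heavy_atoms` heavy atoms. The search is bounded; if the budget is
#' exhausted the result carries `timeout = TRUE` (and is dropped by
#' [derive_chemotypes()]).
#'
#' @param member_smiles character vector of cluster member SMILES.
#' @param cluster_id integer id recorded on the chemotype.
#' @param min_members minimum cluster size (default 3).
#' @param min_heavy_atoms minimum substructure size (default 6).
#' @param budget backtracking node budget per pairwise search.
#' @return object of class `chemotype`, or `NULL`.
#' @export
extract_cluster_mcs <- function(member_smiles, cluster_id = NA_integer_,
                                min_members = 3L, min_heavy_atoms = 6L,
                                budget = 200000L) {
  member_smiles <- member_smiles[!is.na(member_smiles)]
  if (length(member_smiles) < min_members) return(NULL)
  graphs <- mol_graphs(member_smiles)
  if (any(vapply(graphs, is.null, logical(1)))) return(NULL)
  # iterate pairwise: MCS(m1, m2), then MCS(result, m3), ...
  cur <- graphs[[1]]
  ids <- seq_len(cur$n)   # atom indices of `cur` within the first member
  timeout <- FALSE
  for (k in 2:length(graphs)) {
    r <- .mcs_pair(.graph_labels(cur), .graph_labels(graphs[[k]]), budget)
    timeout <- timeout || r$timeout
    if (length(r$map1) < min_heavy_atoms) return(NULL)
    cur <- .induced_subgraph(cur, r$map1)
    ids <- ids[r$map1]
  }
  if (cur$n < min_heavy_atoms) return(NULL)
  attr(cur, "atom_ids") <- ids
  pattern <- .subgraph_smiles(member_smiles[1], graphs[[1]], cur)
  structure(list(pattern = pattern, graph = cur,
                 member_smiles = member_smiles,
                 cluster_id = cluster_id, n_members = length(member_smiles),
                 timeout = timeout),
            class = "chemotype")
}

# serialize a common subgraph back to a SMILES-like pattern string via
# the connection table of the first member (best effort, for reporting;
# matching uses the labeled graph itself)
.subgraph_smiles <- function(smiles, full_graph, sub_graph) {
  # rebuild: find which atoms of the full graph the subgraph uses by
  # matching element sequence; we instead re-derive from an SDF block
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF",
                                            paste0(smiles, "\tp")),
                  error = function(e) "")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NA_character_)
  # locate subgraph atoms: the induced subgraph was built on indices of
  # the first member, recorded via attr if present
  keep <- attr(sub_graph, "atom_ids")
  if (is.null(keep)) return(NA_character_)
  blk <- .extract_submol(lines, keep, title = "p")
  res <- tryCatch(ChemmineOB::convertFormat("SDF", "SMI", blk),
                  error = function(e) "")
  p <- strsplit(strsplit(res, "\n")[[1]][1], "\t")[[1]][1]
  if (is.null(p) || !nzchar(p)) NA_character_ else p
}

#' Derive chemotypes from clustered molecules
#'
#' Runs [extract_cluster_mcs()] over every non-reserved cluster of a
#' [cluster_scaffolds()] result.
#'
#' @param clustered data frame from [cluster_scaffolds()].
#' @param ... passed to [extract_cluster_mcs()].
#' @return list of `chemotype` objects (clusters that time out or fall
#'   below the size floors are omitted).
#' @export
derive_chemotypes <- function(clustered, ...) {
  ids <- sort(unique(clustered$cluster_id[!is.na(clustered$cluster_id) &
                                            clustered$cluster_id > 0L]))
  out <- list()
  for (cid in ids) {
    mem <- clustered$smiles[!is.na(clustered$cluster_id) &
                              clustered$cluster_id == cid]
    ct <- extract_cluster_mcs(mem, cluster_id = cid, ...)
    if (!is.null(ct) && !isTRUE(ct$timeout)) out[[length(out) + 1L]] <- ct
  }
  out
}

# --- substructure matching -------------------------------------------------

# monomorphism test: does `pattern` (labeled graph) embed in `target`?
# igraph LAD with atom-label domains, then a bond-label post-check.
.match_graph <- function(pattern, target) {
  if (is.null(pattern) || is.null(target)) return(FALSE)
  if (pattern$n > target$n) return(FALSE)
  pl <- .graph_labels(pattern)
  tl <- .graph_labels(target)
  domains <- lapply(seq_len(pattern$n), function(i)
    which(tl$atom == pl$atom[i]))
  if (any(vapply(domains, length, integer(1)) == 0L)) return(FALSE)
  pg <- igraph::graph_from_data_frame(
    pattern$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(pattern$n)))
  tg <- igraph::graph_from_data_frame(
    target$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(target$n)))
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pg, tg, method = "lad",
                                  induced = FALSE, domains = domains),
    error = function(e) list())
  if (!length(maps)) return(FALSE)
  pb <- pattern$bonds
  pbond <- ifelse(pb$aromatic, "ar", as.character(pb$order))
  for (mp in maps) {
    m <- as.integer(mp)
    okb <- TRUE
    for (i in seq_len(nrow(pb))) {
      if (tl$adj[m[pb$a1[i]], m[pb$a2[i]]] != pbond[i]) { okb <- FALSE; break }
    }
    if (okb) return(TRUE)
  }
  FALSE
}

#' Match molecules against a chemotype library
#'
#' Labels every molecule with each chemotype whose pattern occurs as a
#' substructure (monomorphism on element/aromaticity atom labels and
#' bond orders). Library entries may be `chemotype` objects or SMILES/
#' SMARTS-as-SMILES pattern strings; unparsable patterns are skipped
#' with a warning.
#'
#' @param smiles character vector of molecule SMILES.
#' @param library list of `chemotype` objects and/or pattern strings
#'   (possibly named).
#' @return logical matrix, molecules x chemotypes, with a
#'   `counts` attribute giving per-chemotype match totals.
#' @export
match_chemotypes <- function(smiles, library) {
  n <- length(smiles)
  if (length(library) == 0L) {
    out <- matrix(FALSE, n, 0L)
    attr(out, "counts") <- integer(0)
    return(out)
  }
  pat_graphs <- vector("list", length(library))
  pat_names <- character(length(library))
  for (k in seq_along(library)) {
    entry <- library[[k]]
    if (inherits(entry, "chemotype")) {
      pat_graphs[[k]] <- entry$graph
      pat_names[k] <- if (!is.na(entry$pattern)) entry$pattern else
        paste0("chemotype_", entry$cluster_id)
    } else {
      g <- mol_graph(as.character(entry))
      if (is.null(g)) {
        warning("skipping unparsable pattern: ", entry)
      } else {
        pat_graphs[[k]] <- g
      }
      pat_names[k] <- as.character(entry)
    }
  }
  nm <- names(library)
  if (!is.null(nm)) pat_names[nzchar(nm)] <- nm[nzchar(nm)]
  tgt <- mol_graphs(smiles)
  out <- matrix(FALSE, n, length(library),
                dimnames = list(NULL, pat_names))
  for (k in seq_along(pat_graphs)) {
    if (is.null(pat_graphs[[k]])) next
    out[, k] <- vapply(tgt, function(g) .match_graph(pat_graphs[[k]], g),
                       logical(1))
  }
  attr(out, "counts") <- colSums(out)
  out
}

#' Validity / uniqueness / novelty / chemotype rediscovery report
#'
#' Computes the nested funnel over a set of generated SMILES: valid
#' (standardizes to a molecule), unique (first occurrence by canonical
#' SMILES), novel (canonical SMILES absent from the reference vendor
#' set), and possessing a known chemotype (matches the supplied
#' library). Known-active rediscovery counts exact canonical matches
#' against the actives set among the unique molecules.
#'
#' @param sample_smiles generated SMILES.
#' @param reference_actives SMILES of known active molecules.
#' @param reference_vendor SMILES of the purchasable reference set.
#' @param chemotype_library as in [match_chemotypes()].
#' @return object of class `rediscovery_report`: list with `n_total`,
#'   `n_valid`, `n_unique`, `n_novel`, `n_with_known_chemotype`,
#'   `n_known_actives_rediscovered`, `per_chemotype` counts, and the
#'   per-molecule annotation table `molecules`.
#' @export
rediscovery_report <- function(sample_smiles,
                               reference_actives = character(0),
                               reference_vendor = character(0),
                               chemotype_library = list()) {
  canon <- canonicalize_smiles(sample_smiles)
  valid <- !is.na(canon)
  uniq <- valid & !duplicated(canon)
  ref_act <- unique(canonicalize_smiles(reference_actives))
  ref_ven <- unique(canonicalize_smiles(reference_vendor))
  ref_act <- ref_act[!is.na(ref_act)]
  ref_ven <- ref_ven[!is.na(ref_ven)]
  novel <- uniq & !(canon %in% ref_ven)
  with_ct <- rep(FALSE, length(canon))
  per_ct <- integer(0)
  if (length(chemotype_library)) {
    idx <- which(novel)
    if (length(idx)) {
      mm <- match_chemotypes(canon[idx], chemotype_library)
      with_ct[idx] <- rowSums(mm) > 0L
      per_ct <- attr(mm, "counts")
    } else {
      per_ct <- setNames(integer(length(chemotype_library)),
                         names(chemotype_library))
    }
  }
  rediscovered <- sum(canon[uniq] %in% ref_act)
  mols <- data.frame(smiles = sample_smiles, canonical = canon,
                     valid = valid, unique = uniq, novel = novel,
                     known_chemotype = with_ct, stringsAsFactors = FALSE)
  structure(list(n_total = length(sample_smiles),
                 n_valid = sum(valid), n_unique = sum(uniq),
                 n_novel = sum(novel),
                 n_with_known_chemotype = sum(with_ct),
                 n_known_actives_rediscovered = rediscovered,
                 per_chemotype = per_ct, molecules = mols),
            class = "rediscovery_report")
}

#' @export
print.rediscovery_report <- function(x, ...) {
  cat("Generated molecules:", x$n_total, "\n")
  cat("  valid:                 ", x$n_valid, "\n")
  cat("  + unique:              ", x$n_unique, "\n")
  cat("  + novel:               ", x$n_novel, "\n")
  cat("  + known chemotype:     ", x$n_with_known_chemotype, "\n")
  cat("known actives rediscovered:", x$n_known_actives_rediscovered, "\n")
  invisible(x)
}

#' @export
print.chemotype <- function(x, ...) {
  cat("chemotype", if (!is.na(x$pattern)) x$pattern else "<graph>",
      "| cluster", x$cluster_id, "|", x$n_members, "members\n")
  invisible(x)
}
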