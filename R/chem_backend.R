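# OpenBabel-backed chemistry primitives (via ChemmineOB).
# All multi-molecule calls are batched through a single conversion and
# realigned by molecule title, so a single unparsable entry cannot shift
# the remaining results.

.mol_titles <- function(n) paste0("m", seq_len(n))

.ob_options <- function(ops = character(0)) {
  if (length(ops) == 0L) {
    data.frame(names = character(0), args = character(0))
  } else {
    data.frame(names = ops, args = rep("", length(ops)))
  }
}

#' Canonicalize SMILES strings
#'
#' Returns the canonical SMILES of each input, or `NA` where the string
#' is lexically malformed or fails the toolkit parse. This is the
#' validity test applied to generated molecules.
#'
#' @param smiles character vector.
#' @param neutralize apply +1/-1 charge neutralisation where valence
#'   permits.
#' @param lexical_gate reject lexically malformed strings before the
#'   toolkit parse (see [smiles_lexically_valid()]).
#' @return character vector with `NA` for invalid entries.
#' @export
#' @examples
#' canonicalize_smiles(c("OCC", "C("))  # "CCO", NA
canonicalize_smiles <- function(smiles, neutralize = FALSE, lexical_gate = TRUE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (lexical_gate) ok <- ok & smiles_lexically_valid(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                 collapse = "\n")
  ops <- if (neutralize) "neutralize" else character(0)
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", input, options = .ob_options(ops)),
    error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, "", 1L)
    ttl <- vapply(parts, function(x) if (length(x) >= 2L) x[2L] else "", "")
    pos <- match(ttl, .mol_titles(length(idx)))
    keep <- !is.na(pos) & nzchar(smi)
    out[idx[pos[keep]]] <- smi[keep]
  }
  out
}

# physicochemical properties straight from OpenBabel (logP is the
# atomic-contribution Crippen-type estimate; HBD is the Lipinski N-H/O-H
# donor count). Rows align with `smiles`; NA rows where parsing fails.
ob_properties <- function(smiles) {
  n <- length(smiles)
  empty <- data.frame(mol_weight = rep(NA_real_, n), logp = NA_real_,
                      n_hbd = NA_integer_)
  if (n == 0L) return(empty[0, ])
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(empty)
  idx <- which(ok)
  input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                 collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  pr <- ChemmineOB::prop_OB(mols)
  pos <- match(pr$title, .mol_titles(length(idx)))
  keep <- !is.na(pos)
  empty$mol_weight[idx[pos[keep]]] <- pr$MW[keep]
  empty$logp[idx[pos[keep]]] <- pr$logP[keep]
  empty$n_hbd[idx[pos[keep]]] <- as.integer(pr$HBD[keep])
  empty
}

# ECFP4 bit matrix (one row per molecule); all-zero rows for failures or
# empty SMILES (the empty Bemis-Murcko scaffold of an acyclic molecule).
ecfp4_fingerprints <- function(smiles) {
  n <- length(smiles)
  ok <- !is.na(smiles) & nzchar(smiles)
  fp <- NULL
  if (any(ok)) {
    idx <- which(ok)
    input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                   collapse = "\n")
    mols <- ChemmineOB::forEachMol("SMILES", input, identity)
    raw <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
    out <- matrix(0L, n, ncol(raw))
    # fingerprint_OB returns rows in molecule order of the parsed set
    out[idx[seq_len(nrow(raw))], ] <- as.integer(raw > 0)
    fp <- out
  } else {
    fp <- matrix(0L, n, 4096L)
  }
  fp
}

# Tanimoto similarity between rows of two binary matrices; pairs of
# all-zero fingerprints (two empty scaffolds) count as identical.
tanimoto <- function(a, b) {
  a <- matrix(as.numeric(a), nrow = if (is.matrix(a)) nrow(a) else 1L)
  b <- matrix(as.numeric(b), nrow = if (is.matrix(b)) nrow(b) else 1L)
  inter <- tcrossprod(a, b)
  na <- rowSums(a)
  nb <- rowSums(b)
  un <- outer(na, nb, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, .Machine$double.eps))
  sim
}

.ELEMENT_RE <- "^\\[([0-9]*)([A-Za-z][a-z]?|\\*)"

.atom_tokens <- function(tokens) {
  is_atom <- grepl("^\\[", tokens) | tokens %in% .ORGANIC_ATOMS
  tokens[is_atom]
}

.token_element <- function(tok) {
  if (grepl("^\\[", tok)) {
    m <- regmatches(tok, regexec(.ELEMENT_RE, tok))[[1]]
    el <- m[3]
  } else {
    el <- tok
  }
  aromatic <- el %in% c("b", "c", "n", "o", "p", "s")
  list(element = if (aromatic) toupper(el) else
         paste0(toupper(substr(el, 1, 1)), substr(el, 2, 10)),
       aromatic = aromatic)
}

# net formal charge read off bracket atoms of a SMILES string
smiles_net_charge <- function(smiles) {
  vapply(smiles, function(s) {
    toks <- tokenize_smiles(s)
    if (is.null(toks)) return(NA_integer_)
    br <- toks[grepl("^\\[", toks)]
    chg <- 0L
    for (tk in br) {
      m <- regmatches(tk, gregexpr("[+-][0-9]*", tk))[[1]]
      for (x in m) {
        sign <- if (substr(x, 1, 1) == "+") 1L else -1L
        mag <- if (nchar(x) > 1L) as.integer(substr(x, 2, nchar(x))) else 1L
        chg <- chg + sign * mag
      }
    }
    chg
  }, integer(1), USE.NAMES = FALSE)
}

# --- molecular graphs ------------------------------------------------------

# Parse one OpenBabel-written V2000 molblock into an annotated graph.
# Aromaticity is recovered from the SMILES atom tokens (OpenBabel writes
# SDF atoms in SMILES reading order and kekulizes aromatic bonds).
.parse_molblock <- function(sdf_lines, smiles) {
  counts <- sdf_lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na == 0L) return(NULL)
  atom_lines <- sdf_lines[5:(4 + na)]
  elem <- trimws(substr(atom_lines, 32, 34))
  toks <- .atom_tokens(tokenize_smiles(smiles))
  arom <- rep(FALSE, na)
  if (length(toks) == na) {
    info <- lapply(toks, .token_element)
    arom <- vapply(info, `[[`, logical(1), "aromatic")
  }
  bonds <- NULL
  if (nb > 0L) {
    bond_lines <- sdf_lines[(5 + na):(4 + na + nb)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    ord <- as.integer(substr(bond_lines, 7, 9))
    bonds <- data.frame(a1 = a1, a2 = a2, order = ord)
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  g <- list(n = na, element = elem, aromatic = arom, bonds = bonds,
            smiles = smiles)
  if (nrow(bonds)) {
    ig <- igraph::graph_from_data_frame(
      bonds[, c("a1", "a2")], directed = FALSE,
      vertices = data.frame(name = seq_len(na)))
    bridges <- igraph::bridges(ig)
    in_ring_bond <- rep(TRUE, nrow(bonds))
    in_ring_bond[as.integer(bridges)] <- FALSE
    g$bonds$ring <- in_ring_bond
    ring_atoms <- unique(c(bonds$a1[in_ring_bond], bonds$a2[in_ring_bond]))
    g$ring_atom <- seq_len(na) %in% ring_atoms
    g$bonds$aromatic <- g$bonds$ring & arom[bonds$a1] & arom[bonds$a2]
    deg <- tabulate(c(bonds$a1, bonds$a2), nbins = na)
    g$degree <- deg
  } else {
    g$bonds$ring <- logical(0)
    g$ring_atom <- rep(FALSE, na)
    g$bonds$aromatic <- logical(0)
    g$degree <- rep(0L, na)
  }
  g
}

# Batched SMILES -> annotated molecular graphs. Returns a list aligned
# with `smiles`; NULL where conversion fails.
mol_graphs <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                 collapse = "\n")
  sdf <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", input, options = .ob_options()),
                  error = function(e) "")
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    if (length(lines) < 4L) next
    title <- trimws(lines[1])
    pos <- match(title, .mol_titles(length(idx)))
    if (is.na(pos)) next
    out[[idx[pos]]] <- .parse_molblock(lines, smiles[idx[pos]])
  }
  out
}

mol_graph <- function(smiles) mol_graphs(smiles)[[1]]

# SMARTS match counts (unique matches) for each molecule
smarts_counts <- function(smiles, pattern) {
  n <- length(smiles)
  out <- rep(NA_integer_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste(paste0(smiles[idx], "\t", .mol_titles(length(idx))),
                 collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", input, identity)
  cnt <- tryCatch(ChemmineOB::smartsSearch_OB(mols, pattern,
                                              uniqueMatches = TRUE),
                  error = function(e) rep(NA_integer_, length(mols)))
  out[idx[seq_len(length(cnt))]] <- as.integer(cnt)
  out
}

# element multiset of a molecule (implicit hydrogens contribute "H")
smiles_elements <- function(smiles) {
  lapply(smiles, function(s) {
    if (is.na(s)) return(character(0))
    toks <- .atom_tokens(tokenize_smiles(s))
    els <- vapply(toks, function(t) .token_element(t)$element, "")
    unique(c(els, "H"))  # implicit hydrogens are always notionally present
  })
}

# count of aromatic rings = cycle-space dimension of the aromatic-bond
# subgraph (benzene 1, naphthalene 2, biphenyl 2)
count_aromatic_rings <- function(graph) {
  if (is.null(graph) || !nrow(graph$bonds)) return(0L)
  ab <- graph$bonds[graph$bonds$aromatic, , drop = FALSE]
  if (!nrow(ab)) return(0L)
  verts <- unique(c(ab$a1, ab$a2))
  comp <- igraph::components(igraph::graph_from_data_frame(
    ab[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = verts)))$no
  as.integer(nrow(ab) - length(verts) + comp)
}

# Lipinski acceptor count: nitrogen + oxygen atoms
count_n_plus_o <- function(graph) {
  if (is.null(graph)) return(NA_integer_)
  sum(graph$element %in% c("N", "O"))
}
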