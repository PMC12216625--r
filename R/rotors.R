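# Rotatable-bond machinery shared by corpus curation and the scoring
# component. A rotatable bond is an acyclic single bond between two
# non-terminal heavy atoms; amide C-N bonds are excluded by default
# (strict convention, configurable).

.rotatable_bond_ids <- function(graph, exclude_amide = TRUE) {
  b <- graph$bonds
  if (!nrow(b)) return(integer(0))
  deg <- graph$degree
  cand <- which(!b$ring & b$order == 1L & deg[b$a1] >= 2L & deg[b$a2] >= 2L)
  if (exclude_amide && length(cand)) {
    # carbonyl carbons: C double-bonded to O
    dbl_o <- b$order == 2L &
      ((graph$element[b$a1] == "C" & graph$element[b$a2] == "O") |
       (graph$element[b$a2] == "C" & graph$element[b$a1] == "O"))
    carbonyl_c <- unique(c(b$a1[dbl_o & graph$element[b$a1] == "C"],
                           b$a2[dbl_o & graph$element[b$a2] == "C"]))
    amide <- (b$a1[cand] %in% carbonyl_c & graph$element[b$a2[cand]] == "N") |
             (b$a2[cand] %in% carbonyl_c & graph$element[b$a1[cand]] == "N")
    cand <- cand[!amide]
  }
  cand
}

count_rotatable_bonds <- function(graph, exclude_amide = TRUE) {
  if (is.null(graph)) return(NA_integer_)
  length(.rotatable_bond_ids(graph, exclude_amide))
}

# longest chain of rotatable bonds in which successive bonds share an
# atom: longest path in the rotor-adjacency graph, found by exhaustive
# DFS (rotor graphs of drug-like molecules are tiny trees or near-trees)
.longest_rotor_chain <- function(graph, rot_ids) {
  k <- length(rot_ids)
  if (k == 0L) return(0L)
  if (k == 1L) return(1L)
  b <- graph$bonds[rot_ids, , drop = FALSE]
  adj <- vector("list", k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (length(intersect(c(b$a1[i], b$a2[i]), c(b$a1[j], b$a2[j])))) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  best <- 1L
  dfs <- function(node, visited) {
    best <<- max(best, length(visited))
    for (nb in adj[[node]]) {
      if (!(nb %in% visited)) dfs(nb, c(visited, nb))
    }
  }
  for (s in seq_len(k)) dfs(s, s)
  best
}

#' Maximum number of consecutive rotatable bonds
#'
#' Length of the longest chain of rotatable bonds in which successive
#' bonds share an atom. Rotatable means an acyclic single bond between
#' two non-terminal heavy atoms (amide C-N bonds excluded by default).
#' This is the flexibility measure scored during reinforcement learning.
#'
#' @param smiles character vector of SMILES.
#' @param exclude_amide logical; drop amide C-N bonds from the rotatable
#'   set (default `TRUE`).
#' @return integer vector (NA where the SMILES cannot be parsed).
#' @export
#' @examples
#' max_consecutive_rotatable_bonds(c("c1ccccc1", "CCCCCCC"))  # 0, 4
max_consecutive_rotatable_bonds <- function(smiles, exclude_amide = TRUE) {
  graphs <- mol_graphs(smiles)
  vapply(graphs, function(g) {
    if (is.null(g)) return(NA_integer_)
    as.integer(.longest_rotor_chain(g, .rotatable_bond_ids(g, exclude_amide)))
  }, integer(1))
}

#' Count Lipinski hydrogen-bond donors
#'
#' Number of N-H and O-H donor groups, as computed by the chemistry
#' toolkit's Lipinski donor definition.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector (NA where the SMILES cannot be parsed).
#' @export
#' @examples
#' count_hydrogen_bond_donors(c("CO", "c1ccccc1"))  # 1, 0
count_hydrogen_bond_donors <- function(smiles) {
  ob_properties(smiles)$n_hbd
}
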