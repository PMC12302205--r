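# Canonical atom ranking (iterative Morgan-style refinement with tie
# breaking), a canonical SMILES writer, and Bemis-Murcko framework
# extraction. Canonicity here means: isomorphic inputs (any atom order)
# produce the same output string, which is what scaffold grouping and
# deterministic node ordering require.

# dense integer ranks (1-based) from a character key vector, ordered by key
.dense_rank <- function(keys) {
  match(keys, sort(unique(keys)))
}

#' Canonical atom ranks of a molecule
#'
#' Iterative neighbourhood refinement seeded with (element, aromaticity,
#' charge, degree, hydrogen count), with deterministic tie breaking. Atoms
#' that remain tied after refinement are symmetry-equivalent in all molecules
#' this package targets, so the derived ordering is invariant to the input
#' atom order.
#'
#' @param mol An `sc_mol` object.
#' @returns An integer permutation: `rank[i]` is the canonical position
#'   (1-based) of input atom `i`.
#' @keywords internal
canonical_ranks <- function(mol) {
  n <- mol$n
  if (n == 1L) return(1L)
  adj <- .adjacency(mol)
  el_idx <- match(mol$element, ELEMENTS)
  keys <- sprintf("%02d|%d|%+03d|%d|%d", el_idx, as.integer(mol$aromatic),
                  mol$charge, mol$degree, mol$hcount)
  ranks <- .dense_rank(keys)

  refine <- function(ranks) {
    repeat {
      keys <- vapply(seq_len(n), function(i) {
        nb <- sort(ranks[adj[[i]]])
        sprintf("%04d|%s", ranks[i], paste(sprintf("%04d", nb), collapse = ","))
      }, character(1L))
      new_ranks <- .dense_rank(keys)
      if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
      ranks <- new_ranks
    }
  }
  ranks <- refine(ranks)
  # tie breaking: promote one member of the lowest tied class, re-refine
  while (length(unique(ranks)) < n) {
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    cls <- min(tied)
    pick <- which(ranks == cls)[1L]
    ranks <- ranks * 2L
    ranks[pick] <- ranks[pick] - 1L
    ranks <- refine(.dense_rank(sprintf("%06d", ranks)))
  }
  ranks
}

# implicit H count an unbracketed atom token would get, given the atom's
# total bond order sum; used to decide whether the writer needs brackets
.implied_hcount <- function(element, bondsum) {
  vals <- .VALENCES[[element]]
  need <- ceiling(bondsum - 1e-9)
  v <- vals[vals >= need]
  if (length(v) == 0L) 0L else as.integer(v[1L] - need)
}

#' Write a canonical SMILES string for a molecule
#'
#' Depth-first traversal rooted at the atom of lowest canonical rank, with
#' neighbours visited in canonical-rank order, so isomorphic molecules yield
#' identical strings. Aromatic atoms are written lowercase; brackets are used
#' only where charge or hydrogen count requires them.
#'
#' @param mol An `sc_mol` object.
#' @returns A SMILES string that re-parses to an isomorphic molecule.
#' @export
mol_to_smiles <- function(mol) {
  n <- mol$n
  ranks <- canonical_ranks(mol)
  nb <- nrow(mol$bonds)
  bond_id <- function(i, j) {
    which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
          (mol$bonds$a1 == j & mol$bonds$a2 == i))[1L]
  }
  adj <- .adjacency(mol)
  bondsum <- numeric(n)
  for (k in seq_len(nb)) {
    bondsum[mol$bonds$a1[k]] <- bondsum[mol$bonds$a1[k]] + mol$bonds$order[k]
    bondsum[mol$bonds$a2[k]] <- bondsum[mol$bonds$a2[k]] + mol$bonds$order[k]
  }

  root <- which.min(ranks)
  visited <- logical(n)
  bond_used <- logical(nb)
  ring_marks <- vector("list", n)   # per atom: list of (digit, bond index)
  next_digit <- 0L

  # pass 1: DFS to mark tree bonds and assign ring-closure digits
  dfs_order <- function(i) {
    visited[i] <<- TRUE
    nbrs <- adj[[i]][order(ranks[adj[[i]]])]
    for (j in nbrs) {
      k <- bond_id(i, j)
      if (bond_used[k]) next
      if (visited[j]) {
        bond_used[k] <<- TRUE
        next_digit <<- next_digit + 1L
        ring_marks[[i]] <<- c(ring_marks[[i]], list(list(d = next_digit, k = k)))
        ring_marks[[j]] <<- c(ring_marks[[j]], list(list(d = next_digit, k = k)))
      } else {
        bond_used[k] <<- TRUE
        dfs_order(j)
      }
    }
  }
  dfs_order(root)
  if (next_digit > 99L) stop("too many ring closures")

  bond_sym <- function(k, i, j) {
    o <- mol$bonds$order[k]
    if (o == 2) return("=")
    if (o == 3) return("#")
    if (o == 1.5) return("")            # aromatic default between lowercase atoms
    if (mol$aromatic[i] && mol$aromatic[j]) return("-")  # e.g. biphenyl link
    ""
  }

  atom_token <- function(i) {
    el <- mol$element[i]
    sym <- if (mol$aromatic[i]) tolower(el) else el
    implied <- .implied_hcount(el, bondsum[i])
    if (mol$charge[i] == 0L && mol$hcount[i] == implied) return(sym)
    h <- if (mol$hcount[i] == 0L) "" else if (mol$hcount[i] == 1L) "H"
         else paste0("H", mol$hcount[i])
    ch <- mol$charge[i]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else if (ch > 0L) paste0("+", ch) else as.character(ch)
    paste0("[", sym, h, cs, "]")
  }

  digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

  visited2 <- logical(n)
  bond_written <- logical(nb)
  emit <- function(i) {
    visited2[i] <<- TRUE
    out <- atom_token(i)
    for (rm in ring_marks[[i]]) {
      k <- rm$k
      sym <- if (!bond_written[k]) {
        bond_written[k] <<- TRUE
        bond_sym(k, mol$bonds$a1[k], mol$bonds$a2[k])
      } else ""
      out <- paste0(out, sym, digit_token(rm$d))
    }
    ring_ids <- vapply(ring_marks[[i]], function(rm) rm$k, 1L)
    nbrs <- adj[[i]][order(ranks[adj[[i]]])]
    children <- nbrs[!visited2[nbrs]]
    children <- children[!vapply(children, function(j) {
      bond_id(i, j) %in% ring_ids
    }, TRUE)]
    if (length(children) > 0L) {
      parts <- lapply(children, function(j) {
        k <- bond_id(i, j)
        paste0(bond_sym(k, i, j), emit(j))
      })
      if (length(parts) > 1L) {
        out <- paste0(out,
                      paste0("(", unlist(parts[-length(parts)]), ")", collapse = ""),
                      parts[[length(parts)]])
      } else {
        out <- paste0(out, parts[[1L]])
      }
    }
    out
  }
  emit(root)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Extracts the molecular framework: ring systems plus the linker atoms
#' connecting them, with side chains removed. Atoms attached to the framework
#' by a double or triple bond (e.g. exocyclic carbonyl oxygens) are retained,
#' following the usual Bemis-Murcko convention. The result is written as a
#' canonical SMILES string, so all molecules sharing a scaffold map to the
#' same string regardless of input atom order.
#'
#' @param smiles A SMILES string.
#' @returns The scaffold as a canonical SMILES string; `""` for acyclic
#'   molecules (no ring, hence no scaffold).
#' @examples
#' murcko_scaffold("CCO")          # "" (acyclic)
#' murcko_scaffold("Cc1ccccc1")    # benzene framework
#' @export
murcko_scaffold <- function(smiles) {
  mol <- parse_smiles(smiles)
  if (!any(mol$ring_bond)) return("")

  keep <- rep(TRUE, mol$n)
  repeat {
    deg <- integer(mol$n)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      if (keep[i] && keep[j]) {
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
    prune <- keep & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  # re-attach atoms multiply bonded to the framework (exocyclic =O, =N, ...)
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] < 2) next
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      if (keep[i] && !keep[j]) { keep[j] <- TRUE; added <- TRUE }
      else if (keep[j] && !keep[i]) { keep[i] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }

  sub <- .induced_submol(mol, which(keep))
  mol_to_smiles(sub)
}

# induced subgraph of a molecule on a set of atom indices, with hydrogen
# counts recomputed from remaining valence (severed single bonds become H)
.induced_submol <- function(mol, atoms) {
  atoms <- sort(atoms)
  map <- match(seq_len(mol$n), atoms)
  bk <- mol$bonds$a1 %in% atoms & mol$bonds$a2 %in% atoms
  bonds <- mol$bonds[bk, , drop = FALSE]
  b_sym <- ifelse(bonds$order == 2, "=",
           ifelse(bonds$order == 3, "#",
           ifelse(bonds$aromatic, ":", "-")))
  .finalize_mol(
    element = mol$element[atoms],
    aromatic = mol$aromatic[atoms],
    charge = mol$charge[atoms],
    hexp = ifelse(mol$element[atoms] == "N" & mol$aromatic[atoms],
                  mol$hcount[atoms], NA_integer_),
    b_a1 = map[bonds$a1], b_a2 = map[bonds$a2], b_sym = b_sym,
    smiles = NA_character_
  )
}
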