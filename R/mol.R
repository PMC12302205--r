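# Minimal molecule model over the 9-element vocabulary {C,N,O,F,P,S,Cl,Br,I}.
# SMILES support covers the dialect found in FreeSolv-style databases:
# organic-subset atoms, aromatic lowercase atoms, bracket atoms with charge /
# explicit H / isotope / stereo marks (stereo is parsed and discarded),
# branches, ring closures (including %nn), and explicit bond symbols.

ELEMENTS <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

# standard valence sets used for implicit hydrogen assignment
.VALENCES <- list(
  C = 4L, N = c(3L, 5L), O = 2L, F = 1L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  Cl = 1L, Br = 1L, I = 1L, H = 1L
)

#' Parse a SMILES string into a molecule object
#'
#' Builds a heavy-atom molecule over the element vocabulary
#' \{C, N, O, F, P, S, Cl, Br, I\}. Hydrogens never appear as atoms: explicit
#' `[H]` atoms and bracket H counts are condensed onto their heavy neighbour,
#' and remaining hydrogens are inferred from standard valences (aromatic bonds
#' count 3/2). Stereochemistry marks (`@`, `/`, `\`) are accepted and ignored.
#'
#' @param smiles A single SMILES string.
#' @returns An object of class `sc_mol`: a list with `n` (heavy-atom count),
#'   `element`, `aromatic`, `charge`, `hcount` (per-atom vectors) and `bonds`
#'   (data frame with columns `a1`, `a2`, `order` in \{1, 2, 3, 1.5\} and
#'   `aromatic`), plus derived fields `degree`, `ring_bond`, `ring_atom` and
#'   `hybridization` (one of `"sp"`, `"sp2"`, `"sp3"`, `"other"`).
#' @examples
#' m <- parse_smiles("c1ccccc1O")  # phenol
#' m$n
#' sum(m$aromatic)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("smiles must be a single string")
  }
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES")

  element <- character()
  aromatic <- logical()
  charge <- integer()
  hexp <- integer()      # bracket-specified H count, NA when implicit
  b_a1 <- integer(); b_a2 <- integer(); b_sym <- character()

  stack <- integer()     # branch stack of atom indices
  prev <- NA_integer_
  pending_bond <- ""     # explicit bond symbol awaiting the next atom
  ring <- list()         # open ring closures: digit -> c(atom, bond symbol)

  add_atom <- function(el, arom, chg, h) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hexp[length(hexp) + 1L] <<- h
    length(element)
  }
  add_bond <- function(i, j, sym) {
    if (i == j) stop("self-bond in SMILES: ", smiles)
    b_a1[length(b_a1) + 1L] <<- i
    b_a2[length(b_a2) + 1L] <<- j
    b_sym[length(b_sym) + 1L] <<- sym
  }

  i <- 1L
  n_char <- nchar(s)
  while (i <= n_char) {
    ch <- substr(s, i, i)
    two <- if (i < n_char) substr(s, i, i + 1L) else ""

    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in SMILES: ", smiles)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n_char) stop("truncated %nn ring closure in: ", smiles)
        key <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9][0-9]$", key)) stop("bad %nn ring closure in: ", smiles)
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.na(prev)) stop("ring closure before any atom in SMILES: ", smiles)
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, sym = pending_bond)
      } else {
        open <- ring[[key]]
        sym <- pending_bond
        if (sym == "" ) sym <- open$sym
        if (open$sym != "" && pending_bond != "" && open$sym != pending_bond) {
          stop("conflicting ring-closure bond symbols in: ", smiles)
        }
        add_bond(open$atom, prev, sym)
        ring[[key]] <- NULL
      }
      pending_bond <- ""
    } else if (ch == ".") {
      stop("disconnected (multi-fragment) SMILES are not supported: ", smiles)
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, i, n_char), fixed = TRUE)
      if (close < 0L) stop("unbalanced '[' in SMILES: ", smiles)
      body <- substr(s, i + 1L, i + close - 2L)
      at <- .parse_bracket_atom(body, smiles)
      i <- i + close
      if (at$element == "H") {
        # explicit hydrogen atom: condense onto the attaching heavy atom
        if (is.na(prev)) stop("leading [H] atom is not supported in: ", smiles)
        hexp[prev] <- ifelse(is.na(hexp[prev]), 1L, hexp[prev] + 1L)
        pending_bond <- ""
        next
      }
      idx <- add_atom(at$element, at$aromatic, at$charge, at$hcount)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      prev <- idx
      pending_bond <- ""
    } else {
      # organic-subset atom
      if (two %in% c("Cl", "Br")) {
        el <- two; arom <- FALSE; i <- i + 2L
      } else if (ch %in% c("C", "N", "O", "F", "P", "S", "I")) {
        el <- ch; arom <- FALSE; i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s", "p")) {
        el <- toupper(ch); arom <- TRUE; i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", i,
             " in SMILES: ", smiles)
      }
      idx <- add_atom(el, arom, 0L, NA_integer_)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      prev <- idx
      pending_bond <- ""
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(ring) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(element) == 0L) stop("no atoms in SMILES: ", smiles)

  bad <- setdiff(unique(element), ELEMENTS)
  if (length(bad) > 0L) {
    stop("unsupported element(s) ", paste(bad, collapse = ", "),
         " in SMILES: ", smiles)
  }

  .finalize_mol(element, aromatic, charge, hexp, b_a1, b_a2, b_sym, smiles)
}

# bracket atom body, e.g. "nH", "N+", "O-", "13C", "C@@H", "S+2"
.parse_bracket_atom <- function(body, smiles) {
  rest <- sub("^[0-9]+", "", body)                    # isotope ignored
  m <- regexpr("^([A-Z][a-z]?|[cnops])", rest)
  if (m < 0L) stop("cannot parse bracket atom [", body, "] in: ", smiles)
  sym <- regmatches(rest, m)
  rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
  arom <- sym %in% c("c", "n", "o", "p", "s")
  el <- if (arom) toupper(sym) else sym
  rest <- gsub("@", "", rest)                         # stereo ignored
  h <- 0L
  hm <- regexpr("^H[0-9]*", rest)
  if (hm > 0L) {
    htok <- regmatches(rest, hm)
    h <- if (htok == "H") 1L else as.integer(substr(htok, 2L, nchar(htok)))
    rest <- substr(rest, attr(hm, "match.length") + 1L, nchar(rest))
  }
  chg <- 0L
  if (nchar(rest) > 0L) {
    if (grepl("^\\+[0-9]+$", rest)) chg <- as.integer(substr(rest, 2L, nchar(rest)))
    else if (grepl("^-[0-9]+$", rest)) chg <- -as.integer(substr(rest, 2L, nchar(rest)))
    else if (grepl("^\\++$", rest)) chg <- nchar(rest)
    else if (grepl("^-+$", rest)) chg <- -nchar(rest)
    else stop("cannot parse bracket atom [", body, "] in: ", smiles)
  }
  list(element = el, aromatic = arom, charge = chg, hcount = h)
}

.finalize_mol <- function(element, aromatic, charge, hexp, b_a1, b_a2, b_sym,
                          smiles) {
  n <- length(element)
  nb <- length(b_a1)
  order <- numeric(nb)
  b_arom <- logical(nb)

  # provisional orders; default bonds between two aromatic atoms are resolved
  # after ring perception (aromatic if the bond is in a ring, single otherwise)
  defaultaa <- logical(nb)
  for (k in seq_len(nb)) {
    sym <- b_sym[k]
    if (sym == "=") order[k] <- 2
    else if (sym == "#") order[k] <- 3
    else if (sym == ":") { order[k] <- 1.5; b_arom[k] <- TRUE }
    else if (sym == "-") order[k] <- 1
    else {
      if (aromatic[b_a1[k]] && aromatic[b_a2[k]]) defaultaa[k] <- TRUE
      order[k] <- 1
    }
  }
  ring_bond <- .ring_bonds(n, b_a1, b_a2)
  arom_default <- defaultaa & ring_bond
  order[arom_default] <- 1.5
  b_arom[arom_default] <- TRUE

  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = order, aromatic = b_arom)

  degree <- tabulate(c(b_a1, b_a2), nbins = n)
  bondsum <- numeric(n)
  for (k in seq_len(nb)) {
    bondsum[b_a1[k]] <- bondsum[b_a1[k]] + order[k]
    bondsum[b_a2[k]] <- bondsum[b_a2[k]] + order[k]
  }

  hcount <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(hexp[i])) {
      hcount[i] <- hexp[i]
    } else {
      vals <- .VALENCES[[element[i]]]
      need <- ceiling(bondsum[i] - 1e-9)
      v <- vals[vals >= need]
      hcount[i] <- if (length(v) == 0L) 0L else as.integer(v[1L] - need)
    }
  }

  ring_atom <- logical(n)
  ring_atom[unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))] <- TRUE

  # hybridization by local bond pattern; halogens get "other" (all-zero block)
  hyb <- character(n)
  n_double <- n_triple <- integer(n)
  for (k in seq_len(nb)) {
    if (order[k] == 2) {
      n_double[b_a1[k]] <- n_double[b_a1[k]] + 1L
      n_double[b_a2[k]] <- n_double[b_a2[k]] + 1L
    } else if (order[k] == 3) {
      n_triple[b_a1[k]] <- n_triple[b_a1[k]] + 1L
      n_triple[b_a2[k]] <- n_triple[b_a2[k]] + 1L
    }
  }
  for (i in seq_len(n)) {
    hyb[i] <- if (element[i] %in% c("F", "Cl", "Br", "I")) "other"
    else if (n_triple[i] > 0L || n_double[i] >= 2L) "sp"
    else if (n_double[i] == 1L || aromatic[i]) "sp2"
    else "sp3"
  }

  structure(list(
    n = n, element = element, aromatic = aromatic, charge = charge,
    hcount = hcount, bonds = bonds, degree = degree,
    ring_bond = ring_bond, ring_atom = ring_atom, hybridization = hyb,
    smiles = smiles
  ), class = "sc_mol")
}

# a bond is a ring bond iff it is not a bridge of the bond graph
.ring_bonds <- function(n, a1, a2) {
  nb <- length(a1)
  if (nb == 0L) return(logical(0L))
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[a1[k]]] <- c(adj[[a1[k]]], k)
    adj[[a2[k]]] <- c(adj[[a2[k]]], k)
  }
  is_ring <- logical(nb)
  for (k in seq_len(nb)) {
    # BFS from a1 to a2 avoiding bond k
    src <- a1[k]; dst <- a2[k]
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    found <- FALSE
    while (length(queue) > 0L && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (a1[e] == v) a2[e] else a1[e]
        if (!seen[w]) {
          if (w == dst) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    is_ring[k] <- found
  }
  is_ring
}

#' @export
print.sc_mol <- function(x, ...) {
  cat("<sc_mol> ", x$n, " heavy atoms, ", nrow(x$bonds), " bonds (",
      sum(x$ring_bond), " in rings), formula-ish: ",
      paste0(names(table(x$element)), table(x$element), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a SMILES string
#'
#' @param smiles A SMILES string.
#' @returns Integer heavy-atom (non-hydrogen) count.
#' @export
heavy_atom_count <- function(smiles) {
  parse_smiles(smiles)$n
}

# number of independent rings (cyclomatic number); the molecule graph is
# connected by construction (no '.' support)
.n_rings <- function(mol) {
  nrow(mol$bonds) - mol$n + 1L
}

# adjacency list of heavy-atom indices
.adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# total formal charge
.formal_charge <- function(mol) sum(mol$charge)

# count of aromatic atoms
.n_aromatic_atoms <- function(mol) sum(mol$aromatic)

# number of aromatic rings, approximated as the cyclomatic number of the
# subgraph induced by aromatic bonds (exact for isolated and fused rings)
.n_aromatic_rings <- function(mol) {
  ab <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  if (nrow(ab) == 0L) return(0L)
  atoms <- sort(unique(c(ab$a1, ab$a2)))
  # components of the aromatic subgraph
  idx <- match(seq_len(mol$n), atoms)
  n_a <- length(atoms)
  parent <- seq_len(n_a)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(ab))) {
    ri <- find(idx[ab$a1[k]]); rj <- find(idx[ab$a2[k]])
    if (ri != rj) parent[ri] <- rj
  }
  n_comp <- length(unique(vapply(seq_len(n_a), find, 1L)))
  nrow(ab) - n_a + n_comp
}
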