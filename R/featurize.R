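# Conversion of molecules into heavy-atom graphs with one-hot chemistry
# features and min-max normalized physics features.
#
# Node feature layout (in block order):
#   chem (24) = identity 9 | degree 0-5 (6) | attached H 0-4 (5) |
#               hybridization sp/sp2/sp3 (3) | aromaticity (1)
#   phys (2)  = partial charge | inverse effective Born radius
# Edge feature layout: bond type one-hot (single, double, triple, aromatic)
# when the feature set includes chemistry; normalized inverse bonded distance
# when it includes physics.

BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Featurization configuration
#'
#' @param feature_set `"chem"`, `"phys"`, or `"all"`.
#' @param include_edge_features Emit per-edge feature vectors (the
#'   graph-convolution architecture ignores edges; the message-passing one
#'   requires them).
#' @returns A `feature_config` list with derived `node_dim` and `edge_dim`.
#' @export
feature_config <- function(feature_set = c("chem", "phys", "all"),
                           include_edge_features = TRUE) {
  feature_set <- match.arg(feature_set)
  node_dim <- switch(feature_set, chem = 24L, phys = 2L, all = 26L)
  edge_dim <- if (!include_edge_features) 0L
              else switch(feature_set, chem = 4L, phys = 1L, all = 5L)
  structure(list(feature_set = feature_set,
                 include_edge_features = include_edge_features,
                 node_dim = node_dim, edge_dim = edge_dim),
            class = "feature_config")
}

.one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (!is.na(i)) v[i] <- 1
  v
}

#' Chemistry node feature vector (24 entries)
#'
#' One-hot blocks in fixed order: atom identity over the 9-element
#' vocabulary, heavy-atom degree 0-5, attached hydrogens 0-4, hybridization
#' (sp, sp2, sp3 — all zero for other states, e.g. halogens), and an
#' aromaticity bit.
#'
#' @param element Element symbol.
#' @param degree Heavy-atom degree, 0-5.
#' @param n_h Attached hydrogen count, 0-4.
#' @param hybridization `"sp"`, `"sp2"`, `"sp3"`, or `"other"`.
#' @param aromatic Logical.
#' @returns Numeric vector of length 24.
#' @export
chem_node_vector <- function(element, degree, n_h, hybridization, aromatic) {
  if (!element %in% ELEMENTS) stop("element outside vocabulary: ", element)
  if (degree < 0L || degree > 5L) stop("degree out of range 0-5: ", degree)
  if (n_h < 0L || n_h > 4L) stop("attached-H count out of range 0-4: ", n_h)
  c(.one_hot(element, ELEMENTS),
    .one_hot(degree, 0:5),
    .one_hot(n_h, 0:4),
    .one_hot(hybridization, c("sp", "sp2", "sp3")),
    as.numeric(aromatic))
}

#' Physics node feature vector (2 entries)
#'
#' @param charge Partial charge (e).
#' @param inv_born_radius Inverse effective Born radius (1/Angstrom).
#' @param normalizer A fitted [fit_normalizer()] object with bounds for
#'   `"charge"` and `"inv_born_radius"`.
#' @returns Numeric vector of length 2, both entries in `[0, 1]`.
#' @export
phys_node_vector <- function(charge, inv_born_radius, normalizer) {
  c(normalizer_transform(normalizer, "charge", charge),
    normalizer_transform(normalizer, "inv_born_radius", inv_born_radius))
}

#' Edge feature vector
#'
#' @param bond_type One of `"single"`, `"double"`, `"triple"`, `"aromatic"`
#'   (required when the feature set includes chemistry).
#' @param distance Bonded distance in Angstrom (required when the feature set
#'   includes physics; must be positive).
#' @param config A `feature_config`.
#' @param normalizer Fitted normalizer with an `"inv_distance"` bound (only
#'   needed for physics features).
#' @returns Numeric vector of length `config$edge_dim`.
#' @export
edge_vector <- function(bond_type = NULL, distance = NULL, config,
                        normalizer = NULL) {
  out <- numeric(0L)
  if (config$feature_set %in% c("chem", "all")) {
    if (is.null(bond_type) || !bond_type %in% BOND_TYPES) {
      stop("bond_type must be one of ", paste(BOND_TYPES, collapse = ", "))
    }
    out <- c(out, .one_hot(bond_type, BOND_TYPES))
  }
  if (config$feature_set %in% c("phys", "all")) {
    if (is.null(distance) || distance <= 0) {
      stop("positive bonded distance required for physics edge features")
    }
    out <- c(out, normalizer_transform(normalizer, "inv_distance", 1 / distance))
  }
  out
}

#' Fit a min-max normalizer on training-set feature values
#'
#' Bounds are fitted on the training partition only and reused at inference,
#' where out-of-range values are clamped into `[0, 1]`. A constant feature
#' (max equals min) maps to 0 by convention.
#'
#' @param values Named list of numeric vectors, one per numeric feature
#'   (names used by this package: `"charge"`, `"inv_born_radius"`,
#'   `"inv_distance"`).
#' @returns An `sc_normalizer`: data frame of (feature, min, max).
#' @export
fit_normalizer <- function(values) {
  if (length(values) == 0L) stop("no features to fit")
  rows <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (length(v) == 0L || all(is.na(v))) stop("no values for feature ", nm)
    data.frame(feature = nm, min = min(v, na.rm = TRUE),
               max = max(v, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("sc_normalizer", "data.frame"))
}

#' Apply a fitted min-max transform
#'
#' @param normalizer An `sc_normalizer`.
#' @param feature Feature name.
#' @param x Numeric values.
#' @returns Values mapped into `[0, 1]` (clamped; degenerate bounds give 0).
#' @export
normalizer_transform <- function(normalizer, feature, x) {
  if (is.null(normalizer) || !inherits(normalizer, "sc_normalizer")) {
    stop("a fitted normalizer is required for numeric features")
  }
  row <- which(normalizer$feature == feature)
  if (length(row) != 1L) stop("normalizer has no bounds for '", feature, "'")
  lo <- normalizer$min[row]; hi <- normalizer$max[row]
  if (hi <= lo) return(rep(0, length(x)))
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Build the molecular graph of one record
#'
#' Heavy atoms become nodes (deterministically ordered by the canonical atom
#' ranking), bonds become undirected edges stored once. Implicit hydrogens
#' are folded into the attached-H node feature. Physics features require a
#' per-atom GB feature table (see [gb_atom_features()]) carrying charges,
#' inverse Born radii, and the interatomic distance matrix.
#'
#' @param record One row of an `sc_records` data frame.
#' @param config A `feature_config`.
#' @param normalizer Fitted normalizer (required for physics features).
#' @param gb_features Optional table from [gb_atom_features()] (required for
#'   physics features).
#' @returns An `sc_graph`: `mol_id`, `n`, `node_features` (n x d), `edges`
#'   (m x 2, 1-based, `a1 < a2`), `edge_features` (m x e or NULL), `config`.
#' @export
featurize_molecule <- function(record, config, normalizer = NULL,
                               gb_features = NULL) {
  mol <- parse_smiles(record$smiles)
  needs_phys <- config$feature_set %in% c("phys", "all")
  if (needs_phys && is.null(gb_features)) {
    stop("gb_features required for feature set '", config$feature_set,
         "' (record '", record$id, "')")
  }
  ranks <- canonical_ranks(mol)
  pos <- order(ranks)              # pos[p] = original atom index at node p
  X <- matrix(0, mol$n, config$node_dim)
  for (p in seq_len(mol$n)) {
    i <- pos[p]
    feats <- numeric(0L)
    if (config$feature_set %in% c("chem", "all")) {
      feats <- chem_node_vector(mol$element[i], mol$degree[i],
                                min(mol$hcount[i], 4L), mol$hybridization[i],
                                mol$aromatic[i])
    }
    if (needs_phys) {
      feats <- c(feats, phys_node_vector(gb_features$charge[i],
                                         gb_features$inv_born_radius[i],
                                         normalizer))
    }
    X[p, ] <- feats
  }

  nb <- nrow(mol$bonds)
  inv_pos <- ranks                 # original atom i sits at node ranks[i]
  e1 <- pmin(inv_pos[mol$bonds$a1], inv_pos[mol$bonds$a2])
  e2 <- pmax(inv_pos[mol$bonds$a1], inv_pos[mol$bonds$a2])
  ord <- order(e1, e2)
  edges <- cbind(a1 = e1[ord], a2 = e2[ord])

  E <- NULL
  if (config$edge_dim > 0L) {
    dists <- if (needs_phys) attr(gb_features, "distances") else NULL
    E <- matrix(0, nb, config$edge_dim)
    for (r in seq_len(nb)) {
      k <- ord[r]
      btype <- if (mol$bonds$aromatic[k]) "aromatic"
               else c("single", "double", "triple")[mol$bonds$order[k]]
      dist <- if (needs_phys) dists[mol$bonds$a1[k], mol$bonds$a2[k]] else NULL
      E[r, ] <- edge_vector(btype, dist, config, normalizer)
    }
  }

  structure(list(mol_id = record$id, n = mol$n, node_features = X,
                 edges = edges, edge_features = E, config = config),
            class = "sc_graph")
}

#' @export
print.sc_graph <- function(x, ...) {
  cat("<graph> ", x$mol_id, ": ", x$n, " nodes x ", ncol(x$node_features),
      " features, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Collect raw numeric physics feature values of a record set
#'
#' @param records An `sc_records` data frame.
#' @param gb_tables Named list (id -> [gb_atom_features()] table).
#' @returns Named list of numeric vectors (`charge`, `inv_born_radius`,
#'   `inv_distance`) suitable for [fit_normalizer()].
#' @export
raw_numeric_features <- function(records, gb_tables) {
  charge <- inv_r <- inv_d <- numeric(0L)
  for (id in records$id) {
    tab <- gb_tables[[id]]
    if (is.null(tab)) stop("no GB features for record '", id, "'")
    charge <- c(charge, tab$charge)
    inv_r <- c(inv_r, tab$inv_born_radius)
    d <- attr(tab, "distances")
    mol <- parse_smiles(records$smiles[records$id == id])
    bd <- d[cbind(mol$bonds$a1, mol$bonds$a2)]
    inv_d <- c(inv_d, 1 / bd)
  }
  list(charge = charge, inv_born_radius = inv_r, inv_distance = inv_d)
}

#' Featurize a whole record set
#'
#' Convenience pipeline: computes GB feature tables when the configuration
#' includes physics features (using attached structures where available),
#' fits the normalizer on the designated training ids only, and featurizes
#' every record.
#'
#' @param records An `sc_records` data frame.
#' @param config A `feature_config`.
#' @param train_ids Ids whose values fit the normalizer (default: all).
#' @param params A `gb_parameters` object.
#' @returns A list: `graphs` (named list of `sc_graph`), `normalizer` (or
#'   NULL for chem-only), `gb_tables` (or NULL).
#' @export
featurize_records <- function(records, config, train_ids = records$id,
                              params = gb_parameters()) {
  needs_phys <- config$feature_set %in% c("phys", "all")
  gb_tables <- NULL
  normalizer <- NULL
  if (needs_phys) {
    structures <- attr(records, "structures")
    gb_tables <- lapply(seq_len(nrow(records)), function(i) {
      st <- if (!is.null(structures)) structures[[records$id[i]]] else NULL
      gb_atom_features(records[i, ], params, structure = st)
    })
    names(gb_tables) <- records$id
    train <- records[records$id %in% train_ids, , drop = FALSE]
    normalizer <- fit_normalizer(raw_numeric_features(.as_records(train),
                                                      gb_tables))
  }
  graphs <- lapply(seq_len(nrow(records)), function(i) {
    featurize_molecule(records[i, ], config, normalizer,
                       gb_features = gb_tables[[records$id[i]]])
  })
  names(graphs) <- records$id
  list(graphs = graphs, normalizer = normalizer, gb_tables = gb_tables)
}

# short stable key for a fitted normalizer (bounds rounded into the key)
.normalizer_key <- function(normalizer) {
  if (is.null(normalizer)) return("none")
  paste(normalizer$feature, sprintf("%.10g:%.10g", normalizer$min,
                                    normalizer$max),
        sep = "=", collapse = "|")
}

#' Save / load a featurized-graph cache
#'
#' Single-file archive keyed by (molecule ids, feature set, normalizer
#' bounds), so a cache is only reused for the configuration that built it.
#'
#' @param featurized Output of [featurize_records()].
#' @param file Path of the cache file.
#' @returns `file` invisibly / the featurized list.
#' @export
save_graph_cache <- function(featurized, file) {
  cfg <- featurized$graphs[[1L]]$config
  saveRDS(list(graphs = featurized$graphs, normalizer = featurized$normalizer,
               key = list(ids = names(featurized$graphs),
                          feature_set = cfg$feature_set,
                          edge = cfg$include_edge_features,
                          normalizer = .normalizer_key(featurized$normalizer))),
          file)
  invisible(file)
}

#' @rdname save_graph_cache
#' @param config Expected `feature_config`; mismatched caches are rejected.
#' @export
load_graph_cache <- function(file, config = NULL) {
  obj <- readRDS(file)
  if (!is.null(config) &&
      (obj$key$feature_set != config$feature_set ||
       obj$key$edge != config$include_edge_features)) {
    stop("graph cache was built for feature set '", obj$key$feature_set,
         "', not '", config$feature_set, "'")
  }
  obj
}
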