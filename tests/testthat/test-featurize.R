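# Featurization: vector layouts, normalization, graph construction.

test_that("feature dimensions are a pure function of the configuration", {
  expect_identical(feature_config("chem")$node_dim, 24L)
  expect_identical(feature_config("phys")$node_dim, 2L)
  expect_identical(feature_config("all")$node_dim, 26L)
  expect_identical(feature_config("chem")$edge_dim, 4L)
  expect_identical(feature_config("phys")$edge_dim, 1L)
  expect_identical(feature_config("all")$edge_dim, 5L)
  expect_identical(feature_config("chem", include_edge_features = FALSE)$edge_dim, 0L)
})

test_that("chem_node_vector encodes the one-hot blocks in order", {
  v <- chem_node_vector("C", 2L, 2L, "sp3", FALSE)
  expect_length(v, 24L)
  expect_equal(which(v[1:9] == 1), 1L)            # identity[C]
  expect_equal(which(v[10:15] == 1), 3L)          # degree 2 (0-based block)
  expect_equal(which(v[16:20] == 1), 3L)          # 2 attached H
  expect_equal(which(v[21:23] == 1), 3L)          # sp3
  expect_identical(v[24], 0)                       # not aromatic
  v2 <- chem_node_vector("N", 2L, 0L, "sp2", TRUE)
  expect_identical(v2[24], 1)
  expect_equal(which(v2[1:9] == 1), 2L)
  # categorical blocks each sum to one (hybridization may be all-zero)
  v3 <- chem_node_vector("Cl", 1L, 0L, "other", FALSE)
  expect_identical(sum(v3[21:23]), 0)
  expect_identical(sum(v3[1:9]), 1)
  expect_error(chem_node_vector("Si", 1L, 0L, "sp3", FALSE), "vocabulary")
  expect_error(chem_node_vector("C", 6L, 0L, "sp3", FALSE), "degree")
  expect_error(chem_node_vector("C", 1L, 5L, "sp3", FALSE), "attached-H")
})

test_that("min-max normalizer maps training range to [0,1] and clamps", {
  nm <- fit_normalizer(list(charge = c(1, 3)))
  expect_equal(normalizer_transform(nm, "charge", c(1, 3, 2)), c(0, 1, 0.5))
  expect_equal(normalizer_transform(nm, "charge", 5), 1)   # clamped above
  expect_equal(normalizer_transform(nm, "charge", -2), 0)  # clamped below
  const <- fit_normalizer(list(charge = c(2, 2)))
  expect_equal(normalizer_transform(const, "charge", 2), 0)  # convention
  expect_identical(fit_normalizer(list(charge = c(1, 3))), nm)  # refit stable
  expect_error(fit_normalizer(list()), "no features")
  expect_error(normalizer_transform(nm, "inv_distance", 1), "no bounds")
  expect_error(phys_node_vector(0.1, 0.5, NULL), "normalizer")
})

test_that("edge_vector encodes bond type and normalized inverse distance", {
  chem <- feature_config("chem")
  expect_equal(edge_vector("aromatic", config = chem), c(0, 0, 0, 1))
  expect_equal(edge_vector("triple", config = chem), c(0, 0, 1, 0))
  expect_equal(edge_vector("single", config = chem), c(1, 0, 0, 0))
  allc <- feature_config("all")
  nm <- fit_normalizer(list(inv_distance = c(0.5, 0.8)))
  v <- edge_vector("single", 1.54, allc, nm)
  expect_length(v, 5L)
  # raw inverse distance 1/1.54 = 0.649, then min-max over [0.5, 0.8]
  expect_equal(v[5], (1 / 1.54 - 0.5) / 0.3, tolerance = 1e-9)
  expect_error(edge_vector("single", -1, allc, nm), "positive")
  expect_error(edge_vector("widdershins", config = chem), "bond_type")
})

test_that("featurize_molecule builds the heavy-atom graph", {
  cfg <- feature_config("chem")
  g <- featurize_molecule(make_records("e", "CCO", expt = -5)[1L, ], cfg)
  expect_identical(g$n, 3L)
  expect_identical(nrow(g$edges), 2L)
  expect_identical(dim(g$node_features), c(3L, 24L))
  expect_identical(dim(g$edge_features), c(2L, 4L))
  b <- featurize_molecule(make_records("b", "c1ccccc1", expt = -0.9)[1L, ], cfg)
  expect_identical(b$n, 6L)
  expect_identical(nrow(b$edges), 6L)
  expect_true(all(b$node_features[, 24] == 1))          # aromatic bits
  expect_true(all(b$edge_features[, 4] == 1))           # aromatic bonds
  # physics features demand a GB table
  expect_error(featurize_molecule(make_records("e", "CCO", expt = -5)[1L, ],
                                  feature_config("all")), "gb_features")
})

test_that("featurization is invariant to input atom order (graph isomorphism)", {
  cfg <- feature_config("chem")
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "CN1CCC[C@H]1c1cccnc1", "c1ccoc1")) {
    ref <- featurize_molecule(make_records("x", s, expt = 0)[1L, ], cfg)
    for (seed in 1:3) {
      alt_s <- permute_smiles(s, seed)
      alt <- featurize_molecule(make_records("x", alt_s, expt = 0)[1L, ], cfg)
      # canonical node ordering makes the graphs identical, not just isomorphic
      expect_equal(alt$node_features, ref$node_features)
      expect_equal(alt$edges, ref$edges)
      expect_equal(alt$edge_features[order(alt$edges[, 1], alt$edges[, 2]), ],
                   ref$edge_features[order(ref$edges[, 1], ref$edges[, 2]), ])
    }
  }
})

test_that("full physics featurization keeps numeric features in [0,1]", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_molecules = 8, seed = 12))
  fz <- featurize_records(ds$records, feature_config("all"))
  expect_s3_class(fz$normalizer, "sc_normalizer")
  for (g in fz$graphs) {
    expect_identical(ncol(g$node_features), 26L)
    expect_identical(ncol(g$edge_features), 5L)
    expect_true(all(g$node_features[, 25:26] >= 0 &
                      g$node_features[, 25:26] <= 1))
    expect_true(all(g$edge_features[, 5] >= 0 & g$edge_features[, 5] <= 1))
    # one-hot blocks still sum to one
    expect_true(all(rowSums(g$node_features[, 1:9, drop = FALSE]) == 1))
  }
  # normalizer fitted on a subset treats that subset as the training range
  train <- ds$records$id[1:4]
  fz2 <- featurize_records(ds$records, feature_config("all"),
                           train_ids = train)
  vals <- raw_numeric_features(ds$records[ds$records$id %in% train, ],
                               fz2$gb_tables)
  row <- fz2$normalizer[fz2$normalizer$feature == "charge", ]
  expect_equal(row$min, min(vals$charge))
  expect_equal(row$max, max(vals$charge))
})

test_that("graph caches round-trip and reject mismatched configurations", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_molecules = 5, seed = 14))
  fz <- featurize_records(ds$records, feature_config("chem"))
  f <- withr::local_tempfile(fileext = ".rds")
  save_graph_cache(fz, f)
  back <- load_graph_cache(f, feature_config("chem"))
  expect_identical(names(back$graphs), ds$records$id)
  expect_equal(back$graphs[[1L]]$node_features, fz$graphs[[1L]]$node_features)
  expect_error(load_graph_cache(f, feature_config("all")), "feature set")
})

test_that("conformers are deterministic per id and reproduce bond lengths", {
  mol <- parse_smiles("CCO")
  c1 <- embed_conformer(mol, seed = 42L)
  c2 <- embed_conformer(mol, seed = 42L)
  expect_identical(c1$coords, c2$coords)
  c3 <- embed_conformer(mol, seed = 43L)
  expect_false(identical(c1$coords, c3$coords))
  # bonded heavy-atom distances near their targets
  d <- sqrt(sum((c1$coords[1, ] - c1$coords[2, ])^2))
  expect_lt(abs(d - 1.54), 0.15)
})
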