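# FreeSolv-dialect parsing, filters, physics tables, statistics.

test_that("parse_freesolv reads the dialect and preserves order and fields", {
  rec <- parse_freesolv(text = freesolv_fixture_lines())
  expect_s3_class(rec, "sc_records")
  expect_identical(nrow(rec), 5L)
  expect_identical(rec$id[1L], "fix_0001")
  expect_identical(rec$smiles[2L], "c1ccccc1")
  expect_equal(rec$expt_hfe, c(-5.00, -0.90, 2.00, -7.03, -9.71))
  expect_equal(rec$expt_uncertainty[3L], 0.60)
  expect_equal(rec$calc_hfe[1L], -4.30)
  expect_identical(rec$n_heavy, c(3L, 6L, 1L, 8L, 4L))
})

test_that("comment-only input yields an empty record set", {
  rec <- parse_freesolv(text = c("# only", "# headers"))
  expect_identical(nrow(rec), 0L)
})

test_that("parse errors name the offending line or record", {
  bad <- c("# h", "a; CCO; x; -1; 0.6; -1; 0")
  expect_error(parse_freesolv(text = c(bad, "b; CC; y; zzz; 0.6; -1; 0")),
               "line 3.*non-numeric")
  expect_error(parse_freesolv(text = c("# h", "a; CCO; x; -1; 0.6")),
               "line 2.*7")
  expect_error(parse_freesolv(text = c("a; [Si]C; x; -1; 0.6; -1; 0")),
               "record 'a'")
  expect_error(parse_freesolv(text = c("a; CCO; x; -1; 0.6; -1; 0",
                                       "a; CC; y; -1; 0.6; -1; 0")),
               "duplicate")
})

test_that("parse-serialize-parse is the identity on emitted fields", {
  rec <- parse_freesolv(text = freesolv_fixture_lines())
  rec2 <- parse_freesolv(text = write_freesolv(rec))
  expect_identical(rec2$id, rec$id)
  expect_identical(rec2$smiles, rec$smiles)
  expect_identical(rec2$name, rec$name)
  expect_equal(rec2$expt_hfe, rec$expt_hfe)
  expect_equal(rec2$expt_uncertainty, rec$expt_uncertainty)
  expect_equal(rec2$calc_hfe, rec$calc_hfe)
})

test_that("uncertainty filter applies the two-regime rule with non-strict boundaries", {
  rec <- make_records(
    id = sprintf("m%d", 1:6),
    smiles = rep("CCO", 6L),
    expt = c(-3.2, -10.0, -3.2, -6.0, -6.0, 5.9),
    unc = c(0.7, 0.9, 0.6, 0.60001, 0.61, 0.65)
  )
  rep <- filter_low_uncertainty(rec)
  # m1: |hfe|<6, 0.7>0.6 -> removed; m2: relative 9% <= 10% -> kept
  # m3: boundary 0.6 -> kept; m4: |hfe|>=6, rel 10.00017% > 10% -> removed
  # m5: rel 10.17% -> removed; m6: |hfe|<6 and 0.65>0.6 -> removed
  expect_setequal(rep$removed$id, c("m1", "m4", "m5", "m6"))
  expect_setequal(rep$kept, c("m2", "m3"))
  expect_true(all(rep$removed$reason == "high_uncertainty"))
  # exact 10% relative boundary is kept
  rec10 <- make_records("b1", "CCO", expt = -10, unc = 1.0)
  expect_identical(filter_low_uncertainty(rec10)$kept, "b1")
})

test_that("filters partition the input and are idempotent", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_molecules = 150, seed = 11))
  rec <- ds$records
  rep <- filter_low_uncertainty(rec)
  expect_identical(sort(c(rep$kept, rep$removed$id)), sort(rec$id))
  expect_length(intersect(rep$kept, rep$removed$id), 0L)
  kept <- apply_filters(rec, rep)
  rep2 <- filter_low_uncertainty(kept)
  expect_identical(nrow(rep2$removed), 0L)
  expect_identical(sort(rep2$kept), sort(kept$id))

  srep <- drop_single_heavy_atom(rec)
  expect_identical(sort(c(srep$kept, srep$removed$id)), sort(rec$id))
})

test_that("single-heavy-atom filter removes exactly the one-node molecules", {
  rec <- make_records(c("a", "b", "c", "d"), c("C", "CC", "S", "N"),
                      expt = c(2, 1.8, -0.4, -4.3))
  rep <- drop_single_heavy_atom(rec)
  expect_setequal(rep$removed$id, c("a", "c", "d"))
  expect_identical(rep$kept, "b")
  expect_true(all(rep$removed$reason == "single_heavy_atom"))
})

test_that("attach_physics_predictions annotates matched records only", {
  rec <- make_records(c("m1", "m2"), c("CCO", "CC"), expt = c(-5, 1.8))
  out <- attach_physics_predictions(rec, c(m1 = -4.0), "toy")
  expect_equal(out$phys_toy, c(-4.0, NA))
  out2 <- attach_physics_predictions(rec,
                                     data.frame(id = character(0L),
                                                value = numeric(0L)), "toy")
  expect_true(all(is.na(out2$phys_toy)))
  expect_error(attach_physics_predictions(rec, c(zz = 1), "toy"),
               "not present.*zz")
  expect_error(
    attach_physics_predictions(rec, data.frame(id = c("m1", "m1"),
                                               value = c(1, 2)), "toy"),
    "duplicate")
  expect_equal(unname(physics_predictions(out, "toy")["m1"]), -4.0)
})

test_that("freesolv_statistics computes the dataset descriptors", {
  rec <- parse_freesolv(text = freesolv_fixture_lines())
  st <- freesolv_statistics(rec)
  expect_identical(st$n_records, 5L)
  expect_identical(st$n_removed_single_heavy_atom, 1L)  # methane
  # fix_0004: |HFE| >= 6 and 0.80/7.03 = 11.4% > 10% -> removed;
  # fix_0005: 0.90/9.71 = 9.3% <= 10% -> kept
  expect_identical(st$n_removed_uncertainty, 1L)
  expect_identical(st$n_low_uncertainty_subset, 3L)
  expect_identical(st$n_default_uncertainty, 2L)
  expect_equal(st$mean_hfe, mean(c(-5, -0.9, 2, -7.03, -9.71)))
  expect_equal(st$min_hfe, -9.71)
  expect_identical(st$n_acyclic, 3L)   # CCO, C, CC(=O)N
  expect_identical(st$n_ring, 2L)
  expect_equal(st$rmse_calc_vs_expt,
               sqrt(mean(c(0.7, 0.1, 0.5, 1.03, 0.71)^2)))
})

test_that("structure files attach by id with heavy-atom validation", {
  rec <- make_records("eth", "CCO", expt = -5)
  dir <- withr::local_tempdir()
  sdf <- file.path(dir, "eth.sdf")
  writeLines(c("eth", "  test", "",
               "  3  2  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0",
               "    1.5000    0.0000    0.0000 C   0  0",
               "    2.1000    1.3000    0.0000 O   0  0",
               "  1  2  1  0", "  2  3  1  0", "M  END", "$$$$"), sdf)
  out <- attach_structures(rec, sdf)
  st <- attr(out, "structures")$eth
  expect_identical(nrow(st), 3L)
  expect_identical(st$element, c("C", "C", "O"))
  # wrong stem -> error; wrong atom count -> error
  file.copy(sdf, file.path(dir, "unknown.sdf"))
  expect_error(attach_structures(rec, file.path(dir, "unknown.sdf")),
               "does not match")
  rec2 <- make_records("eth", "CCCO", expt = -5)
  expect_error(attach_structures(rec2, sdf), "heavy atoms")
})

test_that("mol2 structures parse coordinates and charges", {
  dir <- withr::local_tempdir()
  mol2 <- file.path(dir, "wat.mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "wat", " 3 2", "SMALL", "USER_CHARGES",
               "@<TRIPOS>ATOM",
               "  1 O1  0.000  0.000  0.000 O.3  1 WAT -0.8340",
               "  2 H1  0.960  0.000  0.000 H    1 WAT  0.4170",
               "  3 H2 -0.240  0.930  0.000 H    1 WAT  0.4170",
               "@<TRIPOS>BOND", "1 1 2 1", "2 1 3 1"), mol2)
  tab <- solvcorr:::.read_mol2_coords(mol2)
  expect_identical(tab$element, c("O", "H", "H"))
  expect_equal(tab$charge, c(-0.834, 0.417, 0.417))
  expect_equal(tab$x, c(0, 0.96, -0.24))
})
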