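# Shared fixtures, all built in code.

# quick record-set constructor
make_records <- function(id, smiles, expt, unc = 0.6, calc = expt) {
  df <- data.frame(
    id = id, smiles = smiles, name = id,
    expt_hfe = expt, expt_uncertainty = unc,
    calc_hfe = calc, calc_uncertainty = 0,
    n_heavy = vapply(smiles, solvcorr::heavy_atom_count, 1L, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  class(df) <- c("sc_records", "data.frame")
  df
}

# a small FreeSolv-dialect file as text lines
freesolv_fixture_lines <- function() {
  c("# FreeSolv-style fixture",
    "# id; SMILES; name; expt; d_expt; calc; d_calc; refs...",
    "fix_0001; CCO; ethanol; -5.00; 0.60; -4.30; 0.02; ref_a; ref_b",
    "fix_0002; c1ccccc1; benzene; -0.90; 0.20; -0.80; 0.03; ref_a; ref_b",
    "fix_0003; C; methane; 2.00; 0.60; 2.50; 0.01; ref_a; ref_b",
    "fix_0004; Oc1ccc(Cl)cc1; 4-chlorophenol; -7.03; 0.80; -6.00; 0.04; r; r",
    "fix_0005; CC(=O)N; acetamide; -9.71; 0.90; -9.00; 0.05; r; r")
}

# expected values frozen from an independent RDKit oracle (heavy-atom count,
# total hydrogen count, Murcko scaffold membership); the scaffold strings are
# compared within this package's canonical form, the counts are toolkit facts
rdkit_oracle <- list(
  list(smiles = "CCO", n = 3L, h = 6L, acyclic = TRUE),
  list(smiles = "c1ccccc1", n = 6L, h = 6L, acyclic = FALSE),
  list(smiles = "Cc1ccccc1", n = 7L, h = 8L, acyclic = FALSE),
  list(smiles = "O=c1cc[nH]c(=O)[nH]1", n = 8L, h = 4L, acyclic = FALSE),
  list(smiles = "CC(=O)Oc1ccccc1C(=O)O", n = 13L, h = 8L, acyclic = FALSE),
  list(smiles = "c1ccc2ccccc2c1", n = 10L, h = 8L, acyclic = FALSE),
  list(smiles = "c1ccccc1-c1ccccc1", n = 12L, h = 10L, acyclic = FALSE),
  list(smiles = "CN1CCC[C@H]1c1cccnc1", n = 12L, h = 14L, acyclic = FALSE),
  list(smiles = "FC(F)(F)c1ccccc1", n = 10L, h = 5L, acyclic = FALSE),
  list(smiles = "c1ccoc1", n = 5L, h = 4L, acyclic = FALSE),
  list(smiles = "c1cc[nH]c1", n = 5L, h = 5L, acyclic = FALSE),
  list(smiles = "CC(=O)N", n = 4L, h = 5L, acyclic = TRUE),
  list(smiles = "O=P(O)(O)O", n = 5L, h = 3L, acyclic = TRUE),
  list(smiles = "C1CCCCC1", n = 6L, h = 12L, acyclic = FALSE),
  list(smiles = "CC(C)Cc1ccc(cc1)C(C)C(=O)O", n = 15L, h = 18L, acyclic = FALSE)
)

# a deterministic random permutation of a SMILES string's atoms, realized by
# rewriting the SMILES from a different traversal: we shuffle atom order by
# round-tripping through a relabelled molecule
permute_smiles <- function(smiles, seed) {
  mol <- solvcorr::parse_smiles(smiles)
  set.seed(seed)
  perm <- sample.int(mol$n)
  inv <- order(perm)
  b <- mol$bonds
  sym <- ifelse(b$order == 2, "=",
         ifelse(b$order == 3, "#", ifelse(b$aromatic, ":", "-")))
  m2 <- solvcorr:::.finalize_mol(
    mol$element[inv], mol$aromatic[inv], mol$charge[inv],
    ifelse(mol$element[inv] == "N" & mol$aromatic[inv],
           mol$hcount[inv], NA_integer_),
    perm[b$a1], perm[b$a2], sym, NA_character_
  )
  solvcorr::mol_to_smiles(m2)
}

# tiny featurized dataset for network tests
tiny_graph_set <- function(n = 6L, seed = 3L, feature_set = "chem") {
  ds <- solvcorr::generate_synthetic_dataset(
    solvcorr::synthetic_spec(n_molecules = n, seed = seed))
  fz <- solvcorr::featurize_records(ds$records,
                                    solvcorr::feature_config(feature_set))
  list(records = ds$records, graphs = fz$graphs, truth = ds$truth)
}
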