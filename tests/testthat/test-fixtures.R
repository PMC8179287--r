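test_that("molecule generation is deterministic, unique, valid, neutral", {
  m1 <- generate_molecules(40, seed = 3)
  m2 <- generate_molecules(40, seed = 3)
  expect_identical(m1, m2)
  expect_equal(anyDuplicated(m1), 0L)
  expect_false(identical(m1, generate_molecules(40, seed = 4)))
  chem_prefetch(m1)
  for (smi in m1) {
    g <- parse_mapped_smiles(smi)
    expect_equal(g$net_formal_charge, 0L)
    expect_true(all(g$atoms$symbol %in% element_vocab()))
  }
})

test_that("the descriptor oracle is deterministic and exactly conserving", {
  spec <- oracle_spec(seed = 123)
  d1 <- oracle_descriptors("Cc1ccc(O)cc1", spec)
  d2 <- oracle_descriptors("Cc1ccc(O)cc1", spec)
  expect_identical(d1, d2)  # bitwise reproducible

  for (smi in fx_molecules()[1:10]) {
    d <- oracle_descriptors(smi, spec)
    expect_equal(sum(d$atoms$charge), 0, tolerance = 1e-12)
    expect_equal(sum(d$atoms$fukui_elec), 1, tolerance = 1e-12)
    expect_equal(sum(d$atoms$fukui_nuc), 1, tolerance = 1e-12)
    expect_true(all(d$bonds$bond_order > 0))
    expect_true(all(d$bonds$bond_length > 0))
  }
  expect_error(oracle_descriptors("[O-]C(=O)C", spec),
               class = "regiosel_parse_error")
})

test_that("noise-free benzene descriptors are fully symmetric", {
  quiet <- oracle_spec(noise_sigma = c(charge = 0), seed = 1)
  quiet$noise_sigma[] <- 0
  d <- oracle_descriptors("c1ccccc1", quiet)
  expect_equal(d$atoms$charge, rep(0, 6), tolerance = 1e-12)
  expect_equal(d$atoms$fukui_elec, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(d$atoms$fukui_nuc, rep(1 / 6, 6), tolerance = 1e-12)
  expect_all_equal(d$atoms$nmr, tol = 1e-10)
  expect_all_equal(d$bonds$bond_order, tol = 1e-10)
})

test_that("donor substituents direct the mock Fukui index ortho/para", {
  quiet <- oracle_spec(seed = 1)
  quiet$noise_sigma[] <- 0
  d <- oracle_descriptors("Oc1ccccc1", quiet)   # phenol
  g <- parse_mapped_smiles(chem_canonical("Oc1ccccc1"))
  Dm <- regiosel:::graph_distances(g)
  o_idx <- which(g$atoms$symbol == "O")
  ortho <- which(Dm[o_idx, ] == 2)
  meta <- which(Dm[o_idx, ] == 3)
  expect_gt(min(d$atoms$fukui_nuc[ortho]), max(d$atoms$fukui_nuc[meta]))
})

test_that("toy reactions are selective with rule-consistent major labels", {
  recs <- fx_records()
  spec <- toy_reaction_spec()
  for (r in recs) {
    expect_gte(length(r$candidates), 2)
    expect_gte(r$yield_pct, 50)
    sub <- strsplit(r$reactant_smiles, ".", fixed = TRUE)[[1]][1]
    g <- parse_mapped_smiles(chem_canonical(sub))
    sites <- vapply(r$candidates, function(cc) cc$pair[1], integer(1))
    sc <- selectivity_rule(g, sites, spec)
    expect_equal(r$major_index, which.max(sc))
  }
  # determinism
  again <- generate_selective_reactions(5, seed = 5)
  expect_identical(again[[1]], recs[[1]])
})

test_that("label noise lowers the rule-prediction ceiling to about 1 - p", {
  p <- 0.3
  recs <- generate_selective_reactions(
    80, toy_reaction_spec(label_noise = p), seed = 21)
  spec <- toy_reaction_spec()
  hits <- vapply(recs, function(r) {
    sub <- strsplit(r$reactant_smiles, ".", fixed = TRUE)[[1]][1]
    g <- parse_mapped_smiles(chem_canonical(sub))
    sites <- vapply(r$candidates, function(cc) cc$pair[1], integer(1))
    as.integer(r$major_index == which.max(selectivity_rule(g, sites, spec)))
  }, integer(1))
  # binomial fluctuation: 3 sigma on n = 80 at p = 0.3 is ~0.15
  expect_lt(abs(mean(hits) - (1 - p)), 0.16)
})

test_that("fixture bundles are self-consistent and byte-stable per seed", {
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- cmd_make_fixtures(list(out_dir = d1, n_molecules = 15,
                               n_reactions = 6, seed = 9))
  p2 <- cmd_make_fixtures(list(out_dir = d2, n_molecules = 15,
                               n_reactions = 6, seed = 9))
  for (f in c("molecules.smi", "descriptors_atoms.csv",
              "descriptors_bonds.csv", "reactions.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  tab <- load_descriptor_table(file.path(d1, "descriptors_atoms.csv"),
                               file.path(d1, "descriptors_bonds.csv"),
                               provenance = "oracle")
  expect_silent(validate_descriptor_table(tab))
  recs <- load_reaction_records(file.path(d1, "reactions.csv"),
                                require_selective = TRUE)
  expect_length(recs, 6)
  unlink(c(d1, d2), recursive = TRUE)
})
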