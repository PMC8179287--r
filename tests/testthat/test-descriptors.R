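test_that("RBF expansion matches its closed form", {
  spec <- rbf_spec(c(0, 0.5, 1.0), gamma = 4)
  # at a grid center the matching component is exactly 1
  expect_equal(drop(rbf_expand(0.5, spec)), c(exp(-1), 1, exp(-1)))
  for (k in seq_along(spec$centers)) {
    expect_equal(rbf_expand(spec$centers[k], spec)[1, k], 1)
  }
  # mirror symmetry about the central center
  x <- 0.13
  expect_equal(drop(rbf_expand(x, spec)), rev(drop(rbf_expand(1 - x, spec))))
})

test_that("RBF expansion is bounded and peaks at the nearest center", {
  spec <- default_rbf_specs(9)$charge
  xs <- seq(-1.5, 1.5, length.out = 41)
  V <- rbf_expand(xs, spec)
  expect_true(all(V > 0 & V <= 1))
  for (r in seq_along(xs)) {
    expect_equal(which.max(V[r, ]), which.min(abs(xs[r] - spec$centers)))
  }
})

test_that("default RBF grids are balanced across channels and units", {
  specs <- default_rbf_specs(8)
  dims <- vapply(specs, function(s) length(s$centers), integer(1))
  expect_true(all(dims == 8L))
  expect_equal(range(specs$charge$centers), c(-1, 1))
  expect_equal(range(specs$fukui_nuc$centers), c(0, 1))
  # shielding grid lives on the ppm scale, far from the charge grid
  expect_gt(max(specs$nmr$centers), 100)
})

test_that("descriptor tables round-trip through CSV", {
  tab <- oracle_table(c("CCO", "Cc1ccccc1O"))
  ap <- tempfile(fileext = ".csv"); bp <- tempfile(fileext = ".csv")
  save_descriptor_table(tab, ap, bp)
  tab2 <- load_descriptor_table(ap, bp, provenance = "oracle")
  expect_equal(tab2$atoms$charge, tab$atoms$charge, tolerance = 1e-12)
  expect_equal(tab2$bonds$bond_length, tab$bonds$bond_length,
               tolerance = 1e-12)
  # written files use 0-based indices
  raw <- utils::read.csv(ap)
  expect_equal(min(raw$atom_index), 0L)
  unlink(c(ap, bp))
})

test_that("misaligned and malformed tables are rejected", {
  tab <- oracle_table("c1ccccc1")
  bad_atoms <- tab$atoms[1:5, ]  # benzene needs 6 atom rows
  expect_error(
    descriptor_table(bad_atoms, tab$bonds, provenance = "oracle"),
    class = "regiosel_alignment_error")
  expect_error(
    descriptor_table(tab$atoms[, -3], tab$bonds, provenance = "oracle"),
    class = "regiosel_schema_error")
  # conservation violation beyond tolerance
  wrong <- tab$atoms
  wrong$fukui_nuc <- wrong$fukui_nuc + 0.5
  expect_error(descriptor_table(wrong, tab$bonds, provenance = "qm"),
               class = "regiosel_alignment_error")
})

test_that("renormalization restores exact conservation sums", {
  tab <- oracle_table(c("CCO", "c1ccncc1"))
  jit <- tab$atoms
  jit$charge <- jit$charge + 0.003
  jit$fukui_elec <- jit$fukui_elec * 1.004
  perturbed <- descriptor_table(jit, tab$bonds, provenance = "qm",
                                validate = FALSE)
  fixed <- renormalize_table(perturbed)
  for (smi in table_molecules(fixed)) {
    d <- desc_for(fixed, smi)
    expect_equal(sum(d$atoms$charge), 0, tolerance = 1e-12)
    expect_equal(sum(d$atoms$fukui_elec), 1, tolerance = 1e-12)
  }
})

test_that("oracle-generated tables satisfy every invariant", {
  tab <- oracle_table(fx_molecules()[1:20])
  expect_silent(validate_descriptor_table(tab))
  expect_error(desc_for(tab, "c1ccccc1CCCCC"),
               class = "regiosel_missing_descriptor_error")
})
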