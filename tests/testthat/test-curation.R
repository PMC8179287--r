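test_that("templates extracted from a mapped reaction regenerate the product", {
  tpl <- extract_template(fx_toluene_rxn(), radius = 0)
  expect_s3_class(tpl, "reaction_template")
  expect_equal(sort(tpl$pair_tmaps), c(5L, 8L))
  outs <- enumerate_candidates(
    tpl, "[CH3:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1.[Cl:8][Cl:9]")
  expect_equal(length(outs), 3)  # ortho/meta/para, symmetry-deduplicated
  expect_true("Cc1ccc(Cl)cc1" %in%
                vapply(outs, function(o) o$product_smiles, character(1)))

  # identity reaction: no reacting core
  expect_error(extract_template("[CH3:1][OH:2]>>[CH3:1][OH:2]"),
               class = "regiosel_no_change_error")
  # unmapped product atom
  expect_error(extract_template("[CH3:1][OH:2]>>[CH3:1]O"),
               class = "regiosel_unmapped_product_atom_error")
  # larger radius yields a more specific rule
  tpl0 <- extract_template(fx_toluene_rxn(), radius = 0)
  tpl1 <- extract_template(fx_toluene_rxn(), radius = 1)
  expect_false(identical(tpl0$smarts, tpl1$smarts))
  expect_gt(nchar(tpl1$smarts), nchar(tpl0$smarts))
})

test_that("site enumeration collapses symmetry-equivalent positions", {
  tpl <- extract_template(fx_toluene_rxn(), radius = 0)
  benzene <- "[cH:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1.[Cl:7][Cl:8]"
  pyridine <- "[cH:1]1[cH:2][cH:3][n:4][cH:5][cH:6]1.[Cl:7][Cl:8]"
  expect_length(enumerate_candidates(tpl, benzene), 1)
  expect_length(enumerate_candidates(tpl, pyridine), 3)
  expect_error(enumerate_candidates(tpl, "[CH4:1].[Cl:2][Cl:3]"),
               class = "regiosel_no_match_error")
  # invariance to input atom renumbering
  toluene_a <- "[CH3:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1.[Cl:8][Cl:9]"
  toluene_b <- "[Cl:1][Cl:2].[cH:3]1[cH:4][cH:5][cH:6][cH:7][c:8]1[CH3:9]"
  prods <- function(x) sort(vapply(enumerate_candidates(tpl, x),
                                   function(o) o$product_smiles, character(1)))
  expect_equal(prods(toluene_b), prods(toluene_a))
})

test_that("selectivity identification needs >= 2 candidates and a unique match", {
  tpl <- extract_template(fx_toluene_rxn(), radius = 0)
  benz <- enumerate_candidates(tpl, "[cH:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1.[Cl:7][Cl:8]")
  expect_false(identify_selective(benz, "Clc1ccccc1")$selective)

  tol <- enumerate_candidates(
    tpl, "[CH3:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1.[Cl:8][Cl:9]")
  res <- identify_selective(tol, "Cc1ccc(Cl)cc1")
  expect_true(res$selective)
  expect_equal(tol[[res$major_index]]$product_smiles, "Cc1ccc(Cl)cc1")
  expect_error(identify_selective(tol, "Brc1ccccc1"),
               class = "regiosel_no_match_error")
})

test_that("yield filtering keeps the >= threshold records and is idempotent", {
  mk <- function(y) reaction_record("[CH3:1][OH:2]",
                                    list(list(pair = c(1L, 2L),
                                              product_smiles = "CO")),
                                    1L, yield_pct = y, validate = FALSE)
  recs <- lapply(c(45, 50, 80, NA), mk)
  kept <- filter_yield(recs, 50)
  expect_equal(vapply(kept, function(r) r$yield_pct, numeric(1)), c(50, 80))
  expect_equal(filter_yield(kept, 50), kept)
  # threshold 0 keeps everything with a reported yield
  expect_length(filter_yield(recs, 0), 3)
  # all-missing yields drop to nothing
  expect_length(filter_yield(lapply(c(NA, NA), mk), 0), 0)
})

test_that("scaffold split is a disjoint cover with greedy 8/1/1 packing", {
  recs <- fx_records()
  sp <- scaffold_split(recs)
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test),
               length(recs))
  keys <- list(train = unique(scaffold_keys(sp$train)),
               val = unique(scaffold_keys(sp$val)),
               test = unique(scaffold_keys(sp$test)))
  expect_length(intersect(keys$train, keys$val), 0)
  expect_length(intersect(keys$train, keys$test), 0)
  expect_length(intersect(keys$val, keys$test), 0)

  # ten equal-size scaffold groups allocate 8/1/1
  ten <- stats::setNames(rep(5L, 10), paste0("scaf", 1:10))
  asg <- greedy_bin_pack(ten)
  expect_equal(as.integer(table(asg)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  # a dominant group lands in train; shortfall is reported, not an error
  dom <- stats::setNames(c(95L, 3L, 2L), c("big", "s1", "s2"))
  asg2 <- greedy_bin_pack(dom)
  expect_equal(unname(asg2["big"]), "train")
  spd <- scaffold_split(c(rep(recs[1], 19), recs[2]))
  expect_gte(length(spd$train), 19)
  expect_true(is.numeric(spd$achieved))
})

test_that("CV splits have fixed disjoint test folds, stable under downsampling", {
  recs <- fx_records()
  n <- length(recs)
  sp <- cv_splits(recs, folds = 10L, test_size = 4L, seed = 2)
  tests <- lapply(sp, `[[`, "test")
  all_test <- unlist(tests)
  expect_equal(length(all_test), 40L)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in seq_along(sp)) {
    expect_length(sp[[f]]$test, 4L)
    expect_length(intersect(sp[[f]]$train, sp[[f]]$test), 0)
    expect_length(intersect(sp[[f]]$train, sp[[f]]$val), 0)
  }
  sp_small <- cv_splits(recs, folds = 10L, test_size = 4L,
                        train_downsample = 10L, seed = 2)
  for (f in seq_along(sp)) {
    expect_equal(sp_small[[f]]$test, sp[[f]]$test)
    expect_length(sp_small[[f]]$train, 10L)
    expect_true(all(sp_small[[f]]$train %in% sp[[f]]$train))
  }
  expect_error(cv_splits(recs, folds = 10L, test_size = 50L),
               class = "regiosel_insufficient_data_error")
})

test_that("curation mines selective records from a raw reaction CSV", {
  raw <- data.frame(
    reaction_id = 1:3,
    mapped_rxn_smiles = c(
      fx_toluene_rxn(),                          # selective, 95%
      paste0("[cH:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1.[Cl:7][Cl:8]",
             ">>[c:1]1([Cl:7])[cH:2][cH:3][cH:4][cH:5][cH:6]1"),  # benzene: 1 site
      fx_toluene_rxn()                           # selective but low yield
    ),
    yield_pct = c(95, 90, 20)
  )
  path <- tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE)
  recs <- curate_reactions(path, radius = 0)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$yield_pct, 95)
  expect_equal(
    recs[[1]]$candidates[[recs[[1]]$major_index]]$product_smiles,
    "Cc1ccc(Cl)cc1")
  unlink(path)
})
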