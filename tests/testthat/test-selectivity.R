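test_that("softmax scoring follows its closed form", {
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_equal(softmax(0), 1)
  expect_equal(sum(softmax(rnorm(7) * 10)), 1, tolerance = 1e-12)
})

test_that("one WLN round on a 3-atom path matches a hand computation", {
  cfg <- selectivity_config(hidden = 4L, depth = 1L, latent = 3L,
                            rbf_dim = 2L)
  model <- init_selectivity("GNN", cfg, seed = 1)
  model$params <- pin_params(model$params)
  rec <- reaction_record("[CH3:1][CH2:2][OH:3]",
                         list(list(pair = c(1L, 3L), product_smiles = "CCO")),
                         major_index = 1L)
  hL <- wln_encode(rec, model)

  g <- parse_mapped_smiles(rec$reactant_smiles)
  X <- atom_features(g)
  E <- bond_features_discrete(g)
  p <- model$params
  relu0 <- function(v) pmax(v, 0)
  h0 <- lapply(seq_len(3), function(u) relu0(drop(p$Win %*% X[u, ]) + p$bin))
  nb <- list(c(2), c(1, 3), c(2))
  bond_of <- function(u, v) which((g$bonds$i == min(u, v)) &
                                    (g$bonds$j == max(u, v)))
  h1 <- t(vapply(seq_len(3), function(u) {
    agg <- numeric(4)
    for (v in nb[[u]]) {
      agg <- agg + relu0(drop(p$Wn %*% h0[[v]]) +
                           drop(p$We %*% E[bond_of(u, v), ]) + p$bn)
    }
    relu0(drop(p$Ws %*% h0[[u]]) + agg + p$bs)
  }, numeric(4)))
  expect_equal(hL, h1, tolerance = 1e-12)
})

test_that("uniform attention mean-pools the value vectors", {
  cfg <- selectivity_config(hidden = 6L, depth = 1L)
  model <- init_selectivity("GNN", cfg, seed = 2)
  model$params$Wq <- model$params$Wq * 0   # all logits zero
  local <- matrix(rnorm(30), 5, 6)
  ctx <- global_attention(local, model)
  V <- local %*% t(model$params$Wv)
  expect_equal(ctx, matrix(colMeans(V), 5, 6, byrow = TRUE),
               tolerance = 1e-12)
  # one-atom system: context is the value transform of itself
  one <- matrix(rnorm(6), 1, 6)
  expect_equal(global_attention(one, model), one %*% t(model$params$Wv),
               tolerance = 1e-12)
})

test_that("fusion concatenates descriptors in fixed channel order", {
  specs <- default_rbf_specs(4)
  ctx <- matrix(rnorm(12), 2, 6)
  desc <- data.frame(charge = c(0.1, -0.1), fukui_elec = c(0.3, 0.2),
                     fukui_nuc = c(0.4, 0.1), nmr = c(120, 180))
  fused <- fuse_qm(ctx, desc, specs)
  expect_equal(dim(fused), c(2L, 6L + 4L * 4L))
  # equal embeddings, different charges: fused reps differ
  ctx2 <- ctx; ctx2[2, ] <- ctx[1, ]
  f2 <- fuse_qm(ctx2, desc, specs)
  expect_false(isTRUE(all.equal(f2[1, ], f2[2, ])))
  # an atom's fused row ignores the other atoms' descriptors
  desc3 <- desc; desc3$charge[2] <- 0.9
  expect_equal(fuse_qm(ctx, desc3, specs)[1, ], fused[1, ])
  expect_error(fuse_qm(ctx, desc[, -2], specs),
               class = "regiosel_missing_descriptor_error")
})

test_that("pair pooling is a symmetric elementwise sum", {
  fused <- matrix(rnorm(20), 4, 5)
  expect_equal(pool_reacting_pair(fused, c(2, 3)),
               fused[2, ] + fused[3, ])
  expect_equal(pool_reacting_pair(fused, c(3, 2)),
               pool_reacting_pair(fused, c(2, 3)))
  expect_equal(pool_reacting_pair(fused * 0, c(1, 4)), numeric(5))
  expect_error(pool_reacting_pair(fused, c(1, 9)),
               class = "regiosel_unresolved_map_error")
})

test_that("candidate scores are normalized, symmetric, and rotation-covariant", {
  model <- init_selectivity("QM-GNN", seed = 3)
  tab <- fx_table()
  rec <- fx_toluene_record()
  sc <- score_candidates(rec, model, tab)
  expect_equal(sum(sc), 1, tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))

  # single candidate: probability 1
  rec1 <- reaction_record(rec$reactant_smiles, rec$candidates[1], 1L,
                          yield_pct = 80)
  expect_equal(as.numeric(score_candidates(rec1, model, tab)), 1)

  # symmetry-equivalent ortho sites (maps 3 and 7) score identically when
  # the descriptors respect the symmetry (noise-free oracle)
  quiet <- oracle_spec(); quiet$noise_sigma[] <- 0
  tab_sym <- oracle_table(c("Cc1ccccc1", "ClCl"), spec = quiet)
  rec_sym <- reaction_record(
    rec$reactant_smiles,
    list(list(pair = c(3L, 8L), product_smiles = "Cc1ccccc1Cl"),
         list(pair = c(7L, 8L), product_smiles = "Cc1ccccc1Cl")),
    major_index = 1L)
  sc_sym <- score_candidates(rec_sym, model, tab_sym)
  expect_equal(sc_sym[1], sc_sym[2], tolerance = 1e-9)
  l1 <- extract_latent(rec_sym, 1, model, tab_sym)
  l2 <- extract_latent(rec_sym, 2, model, tab_sym)
  expect_equal(l1, l2, tolerance = 1e-9)
  expect_length(l1, model$hyper$latent)

  # rotating the candidate list rotates the scores with it
  rot <- reaction_record(rec$reactant_smiles, rec$candidates[c(2, 3, 1)],
                         major_index = 2L, yield_pct = 80)
  sc_rot <- score_candidates(rot, model, tab)
  expect_equal(as.numeric(sc_rot), as.numeric(sc)[c(2, 3, 1)],
               tolerance = 1e-10)
})

test_that("latent distances are Euclidean and obey the triangle inequality", {
  expect_equal(latent_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(latent_distance(c(0, 0), c(3, 4)), 5)
  expect_error(latent_distance(1:3, 1:4),
               class = "regiosel_length_mismatch_error")
  set.seed(13)
  for (rep in 1:25) {
    a <- rnorm(6); b <- rnorm(6); cc <- rnorm(6)
    expect_lte(latent_distance(a, cc),
               latent_distance(a, b) + latent_distance(b, cc) + 1e-12)
  }
})

test_that("selectivity gradients agree with finite differences (all modes)", {
  tab <- fx_table()
  rec <- fx_records()[[1]]
  for (mode in c("QM-GNN", "GNN", "QM", "FP")) {
    cfg <- selectivity_config(hidden = 5L, depth = 2L, latent = 4L,
                              rbf_dim = 3L, fp_bits = 64L)
    model <- init_selectivity(mode, cfg, seed = 4)
    item <- regiosel:::selectivity_item(rec, model,
                                        if (mode %in% c("QM-GNN", "QM")) tab)
    lg <- regiosel:::sel_loss_grad_item(model, item)
    eps <- 1e-6
    set.seed(7)
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      for (ii in sample(length(p), min(3, length(p)))) {
        mm <- model
        mm$params[[nm]][ii] <- mm$params[[nm]][ii] + eps
        l1 <- regiosel:::sel_loss_grad_item(mm, item)$loss
        mm$params[[nm]][ii] <- mm$params[[nm]][ii] - 2 * eps
        l0 <- regiosel:::sel_loss_grad_item(mm, item)$loss
        fd <- (l1 - l0) / (2 * eps)
        an <- if (is.null(lg$grads[[nm]])) 0 else lg$grads[[nm]][ii]
        expect_lt(abs(fd - an), 1e-4 + 1e-2 * max(abs(fd), abs(an)))
      }
    }
  }
})

test_that("cross-entropy at uniform initialization equals ln k", {
  # zeroed scorer weights give uniform scores over the candidate set
  model <- init_selectivity("QM-GNN", seed = 5)
  model$params$w2 <- model$params$w2 * 0
  model$params$b2 <- 0
  tab <- fx_table()
  for (rec in fx_records()[1:5]) {
    item <- regiosel:::selectivity_item(rec, model, tab)
    lg <- regiosel:::sel_loss_grad_item(model, item)
    expect_equal(lg$loss, log(length(rec$candidates)), tolerance = 1e-10)
  }
})

test_that("strict ablation separation: GNN ignores descriptors, QM ignores the graph", {
  recs <- fx_records()[1:6]
  tab <- fx_table()
  # poison every descriptor value (keep structure so tables still parse)
  poisoned <- tab
  set.seed(31)
  for (ch in c("charge", "fukui_elec", "fukui_nuc", "nmr")) {
    poisoned$atoms[[ch]] <- sample(poisoned$atoms[[ch]])
  }
  poisoned$bonds$bond_order <- poisoned$bonds$bond_order + 0.5
  poisoned$bonds$bond_length <- poisoned$bonds$bond_length + 0.3

  gnn <- init_selectivity("GNN", seed = 6)
  qm <- init_selectivity("QM", seed = 6)
  qmgnn <- init_selectivity("QM-GNN", seed = 6)
  changed_qm <- changed_qmgnn <- FALSE
  for (rec in recs) {
    expect_equal(as.numeric(score_candidates(rec, gnn, poisoned)),
                 as.numeric(score_candidates(rec, gnn, tab)),
                 tolerance = 1e-14)
    changed_qm <- changed_qm ||
      !isTRUE(all.equal(as.numeric(score_candidates(rec, qm, poisoned)),
                        as.numeric(score_candidates(rec, qm, tab))))
    changed_qmgnn <- changed_qmgnn ||
      !isTRUE(all.equal(as.numeric(score_candidates(rec, qmgnn, poisoned)),
                        as.numeric(score_candidates(rec, qmgnn, tab))))
  }
  expect_true(changed_qm)
  expect_true(changed_qmgnn)
})

test_that("training rejects degenerate records and learns on labels", {
  tab <- fx_table()
  recs <- fx_records()
  deg <- reaction_record(recs[[1]]$reactant_smiles,
                         recs[[1]]$candidates[1], 1L, yield_pct = 80)
  expect_error(
    train_selectivity(c(recs[1:4], list(deg)), recs[5:6], "QM-GNN", tab,
                      epochs = 1L),
    class = "regiosel_degenerate_record_error")

  # permuted labels give chance-level held-out accuracy; true labels beat it
  fit <- train_selectivity(recs[1:30], recs[31:34], "QM", tab,
                           epochs = 15L, seed = 8)
  acc_true <- selectivity_accuracy(fit$model, recs[35:40], tab)
  chance <- mean(vapply(recs[35:40],
                        function(r) 1 / length(r$candidates), numeric(1)))
  expect_gt(acc_true, chance)
})

test_that("selectivity checkpoints restore scoring exactly", {
  tab <- fx_table()
  model <- init_selectivity("QM-GNN",
                            selectivity_config(hidden = 8L, latent = 6L),
                            seed = 12)
  dir <- tempfile()
  save_selectivity(model, dir)
  model2 <- load_selectivity(dir)
  rec <- fx_records()[[2]]
  expect_equal(as.numeric(score_candidates(rec, model2, tab)),
               as.numeric(score_candidates(rec, model, tab)),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
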