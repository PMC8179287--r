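test_that("the summation constraint follows its closed form", {
  expect_equal(apply_constraint(c(0.5, -0.3), c(0.5, 0.5), 0), c(0.4, -0.4))
  # zero excess: output equals input for any weights
  q <- c(0.2, -0.5, 0.3)
  expect_equal(apply_constraint(q, c(0.7, 0.2, 0.1), 0), q)
  # single atom: the full correction lands on it
  expect_equal(apply_constraint(0.17, 1, 0), 0)
  # sums are exact for arbitrary inputs
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    q <- rnorm(n); w <- softmax(rnorm(n)); Q <- rnorm(1)
    expect_equal(sum(apply_constraint(q, w, Q)), Q, tolerance = 1e-12)
  }
})

test_that("constraint attention weights are a softmax over atom scores", {
  A <- matrix(rep(1, 6), 2, 3)        # identical hidden states
  expect_equal(constraint_weights(A, c(0.3, -0.2, 0.1)), c(0.5, 0.5))
  expect_equal(constraint_weights(matrix(rnorm(3), 1), rnorm(3)), 1)
  # scores (ln 2, 0) give weights (2/3, 1/3)
  A2 <- rbind(c(log(2), 0), c(0, 0))
  expect_equal(constraint_weights(A2, c(1, 0)), c(2 / 3, 1 / 3))
  # cosine similarity is scale-invariant in the atom hidden state
  A3 <- rbind(c(1, 2), c(2, 4))
  w <- constraint_weights(A3, c(0.5, -1), similarity = "cosine")
  expect_equal(w, c(0.5, 0.5))
})

test_that("one-round encoding of a 3-atom path matches a hand computation", {
  cfg <- dmpnn_config(hidden = 4L, depth = 1L, head_hidden = 3L)
  model <- init_dmpnn(cfg, seed = 1)
  model$params <- pin_params(model$params)
  g <- parse_mapped_smiles("CCO")   # path: C1-C2-O3
  enc <- dmpnn_encode(g, model)

  # independent oracle: direct evaluation of the update equations with
  # plain per-atom loops
  X <- atom_features(g)
  E <- bond_features_discrete(g)
  p <- model$params
  relu0 <- function(v) pmax(v, 0)
  edges <- list(); eb <- integer(0)                    # directed u->v
  for (t in seq_len(nrow(g$bonds))) {
    edges <- c(edges, list(c(g$bonds$i[t], g$bonds$j[t])),
               list(c(g$bonds$j[t], g$bonds$i[t])))
    eb <- c(eb, t, t)
  }
  h0 <- lapply(seq_along(edges), function(k) {
    u <- edges[[k]][1]
    relu0(drop(p$Wi %*% c(X[u, ], E[eb[k], ])) + p$bi)
  })
  a_hand <- t(vapply(1:3, function(u) {
    inc <- Reduce(`+`, c(list(numeric(4)),
                         h0[vapply(edges, function(e) e[2] == u, logical(1))]))
    relu0(drop(p$Wa %*% c(X[u, ], inc)) + p$ba)
  }, numeric(4)))
  expect_equal(enc$atom_hidden, a_hand, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- dmpnn_config(hidden = 5L, depth = 3L, head_hidden = 4L)
  model <- init_dmpnn(cfg, seed = 3)
  tab <- oracle_table(c("Cc1ccncc1O"))
  item <- regiosel:::table_to_items(tab)[[1]]
  lg <- regiosel:::dmpnn_loss_grad_mol(model$params, model$hyper,
                                       model$scalers, item$s, item$targets)
  eps <- 1e-6
  set.seed(9)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (ii in sample(length(p), min(4, length(p)))) {
      pp <- model$params
      pp[[nm]][ii] <- pp[[nm]][ii] + eps
      l1 <- regiosel:::dmpnn_loss_grad_mol(pp, model$hyper, model$scalers,
                                           item$s, item$targets,
                                           want_grad = FALSE)$loss
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps
      l0 <- regiosel:::dmpnn_loss_grad_mol(pp, model$hyper, model$scalers,
                                           item$s, item$targets,
                                           want_grad = FALSE)$loss
      fd <- (l1 - l0) / (2 * eps)
      an <- if (is.null(lg$grads[[nm]])) 0 else lg$grads[[nm]][ii]
      expect_lt(abs(fd - an), 1e-4 + 1e-2 * max(abs(fd), abs(an)))
    }
  }
})

test_that("untrained models already satisfy the conservation sums exactly", {
  model <- init_dmpnn(seed = 99)
  for (smi in c("CCO", "c1ccccc1", "CC(C)Cc1ccc(O)nc1")) {
    p <- predict_descriptors(smi, model)
    expect_equal(sum(p$atoms$charge), 0, tolerance = 1e-12)
    expect_equal(sum(p$atoms$fukui_elec), 1, tolerance = 1e-12)
    expect_equal(sum(p$atoms$fukui_nuc), 1, tolerance = 1e-12)
  }
  # benzene symmetry: every channel constant across the ring
  pb <- predict_descriptors("c1ccccc1", model)
  for (ch in c("charge", "fukui_elec", "fukui_nuc", "nmr")) {
    expect_all_equal(pb$atoms[[ch]], tol = 1e-9)
  }
  expect_all_equal(pb$bonds$bond_order, tol = 1e-9)
})

test_that("atom-order permutation permutes predictions identically", {
  model <- init_dmpnn(seed = 4)
  g1 <- parse_mapped_smiles("OCC")
  g2 <- parse_mapped_smiles("CCO")
  e1 <- dmpnn_encode(g1, model)$atom_hidden[g1$canonical_order, ]
  e2 <- dmpnn_encode(g2, model)$atom_hidden[g2$canonical_order, ]
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("charged molecules are rejected for descriptor prediction", {
  model <- init_dmpnn(seed = 1)
  expect_error(predict_descriptors("[NH4+]", model),
               class = "regiosel_parse_error")
})

test_that("training improves validation loss; zero epochs is the identity", {
  mols <- fx_molecules()
  tr <- oracle_table(mols[1:40]); va <- oracle_table(mols[41:55])
  f0 <- train_multitask(tr, va, dmpnn_config(hidden = 16L, depth = 2L),
                        epochs = 0L, seed = 2)
  init <- init_dmpnn(dmpnn_config(hidden = 16L, depth = 2L), seed = 2)
  expect_equal(f0$model$params, init$params)

  f5 <- train_multitask(tr, va, dmpnn_config(hidden = 16L, depth = 2L),
                        epochs = 5L, seed = 2)
  expect_lt(min(f5$history$val_loss), f5$history$val_loss[1])
  # loss is a mean over molecules: duplicating every one leaves it unchanged
  items <- regiosel:::table_to_items(tr)
  l1 <- regiosel:::dmpnn_batch_loss_grad(f5$model$params, f5$model$hyper,
                                         f5$model$scalers, items,
                                         want_grad = FALSE)$loss
  l2 <- regiosel:::dmpnn_batch_loss_grad(f5$model$params, f5$model$hyper,
                                         f5$model$scalers, c(items, items),
                                         want_grad = FALSE)$loss
  expect_equal(l2, l1, tolerance = 1e-12)
  expect_equal(multitask_loss(f5$model, tr), l1, tolerance = 1e-12)
})

test_that("checkpoints restore models exactly", {
  model <- init_dmpnn(dmpnn_config(hidden = 8L, depth = 2L), seed = 6)
  dir <- tempfile()
  save_dmpnn(model, dir)
  model2 <- load_dmpnn(dir)
  p1 <- predict_descriptors("Cc1ccccc1O", model)
  p2 <- predict_descriptors("Cc1ccccc1O", model2)
  expect_equal(p2$atoms, p1$atoms, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
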