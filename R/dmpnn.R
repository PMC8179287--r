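# Multitask constrained descriptor predictor.
#
# A single directed-message-passing encoder (messages live on directed
# edges, which avoids immediate message echo between bonded atoms) is shared
# by per-descriptor feed-forward readout heads.  The charge and Fukui heads
# carry an attention-based summation constraint: a learnable query vector u
# scores every atom's hidden state, a softmax turns the scores into weights
# w_i, and the excess between the molecular target sum Q and the sum of the
# initial per-atom predictions is spread over the atoms,
#
#     q_i_final = q_i + w_i * (Q - sum_j q_j),
#
# so the constrained channels satisfy their conservation sums exactly, for
# trained and untrained weights alike.  Gradients are hand-derived
# reverse-mode, verified against finite differences in the tests.

CONSTRAINED_CHANNELS <- c("charge", "fukui_elec", "fukui_nuc")

# target sum of a constrained channel: 0 (net formal charge) for charges,
# 1 for either Fukui index
channel_Q <- function(channel, g) {
  if (channel == "charge") as.numeric(g$net_formal_charge) else 1
}

#' Default hyperparameters of the descriptor model
#'
#' @param hidden message/atom hidden width H
#' @param depth number of message-passing rounds T (>= 1)
#' @param head_hidden hidden width of each readout head
#' @param similarity `"dot"` (default) or `"cosine"` similarity between atom
#'   hidden states and the constraint query vector
#' @return named list of hyperparameters
#' @export
dmpnn_config <- function(hidden = 32L, depth = 3L, head_hidden = 32L,
                         similarity = c("dot", "cosine")) {
  stopifnot(depth >= 1, hidden >= 1, head_hidden >= 1)
  list(hidden = as.integer(hidden), depth = as.integer(depth),
       head_hidden = as.integer(head_hidden),
       similarity = match.arg(similarity))
}

#' Initialize an (untrained) multitask descriptor model
#'
#' @param config a [dmpnn_config()]
#' @param seed integer seed for the weight initialization
#' @return a `dmpnn_model` (params, hyper, per-channel target scalers,
#'   manifest)
#' @export
init_dmpnn <- function(config = dmpnn_config(), seed = 1L) {
  H <- config$hidden; Hh <- config$head_hidden
  Fa <- atom_feature_dim(); Fb <- bond_feature_dim()
  params <- with_seed(child_seed(seed, "dmpnn-init"), {
    p <- list(
      Wi = nn_init_mat(H, Fa + Fb), bi = numeric(H),
      Wm = nn_init_mat(H, H),
      Wa = nn_init_mat(H, Fa + H), ba = numeric(H)
    )
    for (ch in ATOM_CHANNELS) {
      p[[paste0("W1_", ch)]] <- nn_init_mat(Hh, H)
      p[[paste0("b1_", ch)]] <- numeric(Hh)
      p[[paste0("w2_", ch)]] <- nn_init_mat(1, Hh)
      p[[paste0("b2_", ch)]] <- numeric(1)
    }
    for (ch in CONSTRAINED_CHANNELS) {
      p[[paste0("u_", ch)]] <- stats::rnorm(H, 0, 1 / sqrt(H))
    }
    for (ch in BOND_CHANNELS) {
      p[[paste0("W1_", ch)]] <- nn_init_mat(Hh, H)
      p[[paste0("b1_", ch)]] <- numeric(Hh)
      p[[paste0("w2_", ch)]] <- nn_init_mat(1, Hh)
      p[[paste0("b2_", ch)]] <- numeric(1)
    }
    p
  })
  scalers <- list()
  for (ch in c(ATOM_CHANNELS, BOND_CHANNELS)) {
    scalers[[ch]] <- c(mu = 0, sd = 1)
  }
  structure(list(
    params = params, hyper = config, scalers = scalers,
    manifest = list(seed = as.integer(seed),
                    element_vocab = element_vocab(),
                    atom_feature_dim = atom_feature_dim(),
                    bond_feature_dim = bond_feature_dim(),
                    trained = FALSE)
  ), class = "dmpnn_model")
}

#' @export
print.dmpnn_model <- function(x, ...) {
  cat("<dmpnn_model> H=", x$hyper$hidden, " T=", x$hyper$depth,
      " (", if (isTRUE(x$manifest$trained)) "trained" else "untrained", ")\n",
      sep = "")
  invisible(x)
}

# --- molecule structure (directed edge lists + features), cached -----------

.struct_cache <- new.env(parent = emptyenv())

mol_struct <- function(smiles_or_graph) {
  if (inherits(smiles_or_graph, "mol_graph")) {
    g <- smiles_or_graph
    key <- g$smiles_input
  } else {
    key <- smiles_or_graph
    g <- NULL
  }
  ck <- paste0("s:", key)
  if (exists(ck, envir = .struct_cache)) return(get(ck, envir = .struct_cache))
  if (is.null(g)) g <- parse_mapped_smiles(key)
  n <- n_atoms(g)
  m <- nrow(g$bonds)
  src <- dst <- rev_idx <- integer(2 * m)
  if (m > 0) {
    for (t in seq_len(m)) {
      src[2 * t - 1] <- g$bonds$i[t]; dst[2 * t - 1] <- g$bonds$j[t]
      src[2 * t] <- g$bonds$j[t]; dst[2 * t] <- g$bonds$i[t]
      rev_idx[2 * t - 1] <- 2 * t; rev_idx[2 * t] <- 2 * t - 1
    }
  }
  E1 <- bond_features_discrete(g)
  E2 <- if (m > 0) E1[rep(seq_len(m), each = 2), , drop = FALSE] else
    matrix(0, 0, bond_feature_dim())
  s <- list(graph = g, n = n, m = m, X = atom_features(g), E2 = E2,
            src = src, dst = dst, rev = rev_idx,
            brep = if (m > 0) seq(1, 2 * m, by = 2) else integer(0))
  assign(ck, s, envir = .struct_cache)
  s
}

# --- forward ----------------------------------------------------------------

dmpnn_forward <- function(params, hyper, s, keep = FALSE) {
  TT <- hyper$depth
  n <- s$n
  ne <- length(s$src)
  H <- hyper$hidden
  if (ne > 0) {
    In0 <- cbind(s$X[s$src, , drop = FALSE], s$E2)
    Z0 <- In0 %*% t(params$Wi)
    Z0 <- sweep(Z0, 2, params$bi, "+")
    H0 <- relu(Z0)
    Hs <- vector("list", TT); Zs <- vector("list", TT); Ms <- vector("list", TT)
    Hs[[1]] <- H0
    if (TT > 1) {
      for (t in 2:TT) {
        IN <- rowsum_into(Hs[[t - 1]], s$dst, n)
        Ms[[t]] <- IN[s$src, , drop = FALSE] - Hs[[t - 1]][s$rev, , drop = FALSE]
        Zs[[t]] <- H0 + Ms[[t]] %*% t(params$Wm)
        Hs[[t]] <- relu(Zs[[t]])
      }
    }
    Hf <- Hs[[TT]]
    INA <- rowsum_into(Hf, s$dst, n)
  } else {
    In0 <- NULL; Z0 <- NULL; H0 <- NULL; Hs <- NULL; Zs <- NULL; Ms <- NULL
    Hf <- matrix(0, 0, H)
    INA <- matrix(0, n, H)
  }
  Ain <- cbind(s$X, INA)
  Apre <- sweep(Ain %*% t(params$Wa), 2, params$ba, "+")
  A <- relu(Apre)
  out <- list(A = A, Apre = Apre, Ain = Ain, Hf = Hf, INA = INA)
  if (keep) out <- c(out, list(In0 = In0, Z0 = Z0, Hs = Hs, Zs = Zs, Ms = Ms))
  out
}

head_forward <- function(params, ch, inp) {
  W1 <- params[[paste0("W1_", ch)]]; b1 <- params[[paste0("b1_", ch)]]
  w2 <- params[[paste0("w2_", ch)]]; b2 <- params[[paste0("b2_", ch)]]
  pre <- sweep(inp %*% t(W1), 2, b1, "+")
  hid <- relu(pre)
  z <- drop(hid %*% t(w2)) + b2
  list(z = z, hid = hid, pre = pre)
}

# backward through a head: dz is dL/dz (vector); returns list(grads additions,
# dinp matrix)
head_backward <- function(params, ch, inp, fw, dz, grads) {
  w2 <- params[[paste0("w2_", ch)]]
  dzm <- matrix(dz, ncol = 1)
  grads <- acc_grad(grads, paste0("w2_", ch), t(dzm) %*% fw$hid)
  grads <- acc_grad(grads, paste0("b2_", ch), sum(dz))
  dhid <- dzm %*% w2
  dpre <- dhid * drelu(fw$pre)
  grads <- acc_grad(grads, paste0("W1_", ch), t(dpre) %*% inp)
  grads <- acc_grad(grads, paste0("b1_", ch), colSums(dpre))
  list(grads = grads, dinp = dpre %*% params[[paste0("W1_", ch)]])
}

#' Encode a molecule with the directed message-passing encoder
#'
#' @param g a `mol_graph` (or SMILES string)
#' @param model a `dmpnn_model`
#' @return list with `atom_hidden` (n x H matrix a_i) and `bond_hidden`
#'   (directed-edge hidden states, 2m x H)
#' @export
dmpnn_encode <- function(g, model) {
  if (is.character(g)) g <- parse_mapped_smiles(g)
  rs_assert(n_atoms(g) >= 1, "empty_dataset", "empty molecule")
  s <- mol_struct(g)
  fw <- dmpnn_forward(model$params, model$hyper, s)
  list(atom_hidden = fw$A, bond_hidden = fw$Hf)
}

#' Attention weights of the summation constraint
#'
#' `w_i = softmax_i(similarity(a_i, u))`; weights are positive and sum to 1.
#' @param a per-atom hidden matrix (n x H)
#' @param u query vector (length H)
#' @param similarity `"dot"` or `"cosine"`
#' @return numeric weight vector of length n
#' @export
constraint_weights <- function(a, u, similarity = "dot") {
  s <- constraint_scores(a, u, similarity)$s
  softmax(s)
}

constraint_scores <- function(a, u, similarity) {
  if (similarity == "dot") {
    list(s = drop(a %*% u))
  } else {
    an <- sqrt(rowSums(a^2)) + 1e-12
    un <- sqrt(sum(u^2)) + 1e-12
    list(s = drop(a %*% u) / (an * un), an = an, un = un)
  }
}

# backward of scores wrt a and u given ds
constraint_scores_backward <- function(a, u, similarity, sc, ds) {
  if (similarity == "dot") {
    list(da = outer(ds, u), du = drop(t(a) %*% ds))
  } else {
    an <- sc$an; un <- sc$un
    s <- sc$s
    da <- outer(ds / (an * un), u) - (ds * s / an^2) * a
    du <- drop(t(a) %*% (ds / (an * un))) - sum(ds * s) * u / un^2
    list(da = da, du = du)
  }
}

#' Apply the attention-based summation constraint
#'
#' `q_final = q + w * (Q - sum(q))`; the output sums to `Q` exactly for any
#' weight vector with `sum(w) = 1`.
#'
#' @param q_init initial per-atom predictions
#' @param w per-atom weights summing to 1
#' @param Q target molecular sum
#' @return corrected per-atom values
#' @export
apply_constraint <- function(q_init, w, Q) {
  stopifnot(length(q_init) == length(w))
  stopifnot(abs(sum(w) - 1) < 1e-8)
  q_init + w * (Q - sum(q_init))
}

# full multitask forward on one molecule struct; returns per-channel vectors
dmpnn_predict_struct <- function(model, s) {
  fw <- dmpnn_forward(model$params, model$hyper, s)
  out <- list()
  for (ch in ATOM_CHANNELS) {
    hf <- head_forward(model$params, ch, fw$A)
    sc <- model$scalers[[ch]]
    val <- hf$z * sc[["sd"]] + sc[["mu"]]
    if (ch %in% CONSTRAINED_CHANNELS) {
      w <- constraint_weights(fw$A, model$params[[paste0("u_", ch)]],
                              model$hyper$similarity)
      val <- apply_constraint(val, w, channel_Q(ch, s$graph))
    }
    out[[ch]] <- val
  }
  for (ch in BOND_CHANNELS) {
    if (s$m > 0) {
      B <- fw$Hf[s$brep, , drop = FALSE] + fw$Hf[s$rev[s$brep], , drop = FALSE]
      hf <- head_forward(model$params, ch, B)
      sc <- model$scalers[[ch]]
      out[[ch]] <- hf$z * sc[["sd"]] + sc[["mu"]]
    } else {
      out[[ch]] <- numeric(0)
    }
  }
  out
}

#' Predict all six QM descriptors for a molecule
#'
#' Runs the multitask model on the canonical heavy-atom graph.  Constrained
#' channels (charge, both Fukui indices) satisfy their molecular sums
#' exactly even for an untrained model.  Charged molecules are rejected:
#' Fukui constraints assume neutral species.
#'
#' @param smiles molecule SMILES
#' @param model a `dmpnn_model`
#' @return a `descriptor_prediction`: list of `atoms` / `bonds` data.frames
#'   in the descriptor-table schema plus `provenance = "ml"`
#' @export
predict_descriptors <- function(smiles, model) {
  can <- chem_canonical(smiles)
  rs_assert(!is.na(can), "parse", paste("cannot parse", smiles))
  g <- parse_mapped_smiles(can)
  rs_assert(g$net_formal_charge == 0L, "parse",
            "descriptor prediction supports neutral molecules only")
  s <- mol_struct(g)
  pred <- dmpnn_predict_struct(model, s)
  structure(list(
    atoms = data.frame(smiles = can, atom_index = seq_len(s$n),
                       charge = pred$charge, fukui_elec = pred$fukui_elec,
                       fukui_nuc = pred$fukui_nuc, nmr = pred$nmr,
                       stringsAsFactors = FALSE),
    bonds = if (s$m > 0) data.frame(
      smiles = can, atom_index_1 = g$bonds$i, atom_index_2 = g$bonds$j,
      bond_order = pred$bond_order, bond_length = pred$bond_length,
      stringsAsFactors = FALSE)
    else data.frame(smiles = character(), atom_index_1 = integer(),
                    atom_index_2 = integer(), bond_order = numeric(),
                    bond_length = numeric(), stringsAsFactors = FALSE),
    provenance = "ml"
  ), class = "descriptor_prediction")
}

#' Predicted descriptor table for many molecules
#' @param smiles character vector
#' @param model a `dmpnn_model`
#' @return a `descriptor_table` with provenance `"ml"`
#' @export
predict_descriptor_table <- function(smiles, model) {
  chem_prefetch(chem_canonical(smiles))
  preds <- lapply(smiles, predict_descriptors, model = model)
  descriptor_table(
    do.call(rbind, lapply(preds, `[[`, "atoms")),
    do.call(rbind, lapply(preds, `[[`, "bonds")),
    provenance = "ml", validate = FALSE
  )
}

# --- loss + gradients -------------------------------------------------------

# targets: list(atoms = data.frame(channels), bonds = data.frame(channels))
dmpnn_loss_grad_mol <- function(params, hyper, scalers, s, targets,
                                want_grad = TRUE) {
  fw <- dmpnn_forward(params, hyper, s, keep = TRUE)
  n <- s$n
  H <- hyper$hidden
  Fa <- atom_feature_dim()
  loss <- 0
  grads <- list()
  dA <- matrix(0, n, H)
  dHf <- if (s$m > 0) matrix(0, 2 * s$m, H) else matrix(0, 0, H)

  for (ch in ATOM_CHANNELS) {
    y <- targets$atoms[[ch]]
    sc <- scalers[[ch]]
    hf <- head_forward(params, ch, fw$A)
    val <- hf$z * sc[["sd"]] + sc[["mu"]]
    constrained <- ch %in% CONSTRAINED_CHANNELS
    if (constrained) {
      u <- params[[paste0("u_", ch)]]
      scs <- constraint_scores(fw$A, u, hyper$similarity)
      w <- softmax(scs$s)
      Q <- channel_Q(ch, s$graph)
      out <- val + w * (Q - sum(val))
    } else {
      out <- val
    }
    r <- (out - y) / sc[["sd"]]
    loss <- loss + mean(r^2)
    if (!want_grad) next
    gout <- 2 * r / (n * sc[["sd"]])
    if (constrained) {
      dval <- gout - sum(gout * w)
      dw <- gout * (Q - sum(val))
      ds <- softmax_backward(w, dw)
      sb <- constraint_scores_backward(fw$A, u, hyper$similarity, scs, ds)
      dA <- dA + sb$da
      grads <- acc_grad(grads, paste0("u_", ch), sb$du)
    } else {
      dval <- gout
    }
    hb <- head_backward(params, ch, fw$A, hf, dval * sc[["sd"]], grads)
    grads <- hb$grads
    dA <- dA + hb$dinp
  }

  if (s$m > 0) {
    B <- fw$Hf[s$brep, , drop = FALSE] + fw$Hf[s$rev[s$brep], , drop = FALSE]
    for (ch in BOND_CHANNELS) {
      y <- targets$bonds[[ch]]
      sc <- scalers[[ch]]
      hf <- head_forward(params, ch, B)
      val <- hf$z * sc[["sd"]] + sc[["mu"]]
      r <- (val - y) / sc[["sd"]]
      loss <- loss + mean(r^2)
      if (!want_grad) next
      gval <- 2 * r / (s$m * sc[["sd"]])
      hb <- head_backward(params, ch, B, hf, gval * sc[["sd"]], grads)
      grads <- hb$grads
      dHf[s$brep, ] <- dHf[s$brep, ] + hb$dinp
      dHf[s$rev[s$brep], ] <- dHf[s$rev[s$brep], ] + hb$dinp
    }
  }
  if (!want_grad) return(list(loss = loss))

  # atom aggregation backward
  dApre <- dA * drelu(fw$Apre)
  grads <- acc_grad(grads, "Wa", t(dApre) %*% fw$Ain)
  grads <- acc_grad(grads, "ba", colSums(dApre))
  if (s$m > 0) {
    dINA <- dApre %*% params$Wa[, (Fa + 1):(Fa + H), drop = FALSE]
    dHf <- dHf + dINA[s$dst, , drop = FALSE]

    # message-passing backward
    TT <- hyper$depth
    dH <- dHf
    dH0 <- matrix(0, 2 * s$m, H)
    if (TT > 1) {
      for (t in TT:2) {
        dZ <- dH * drelu(fw$Zs[[t]])
        grads <- acc_grad(grads, "Wm", t(dZ) %*% fw$Ms[[t]])
        dM <- dZ %*% params$Wm
        dH0 <- dH0 + dZ
        dIN <- rowsum_into(dM, s$src, n)
        dH <- dIN[s$dst, , drop = FALSE] - dM[s$rev, , drop = FALSE]
      }
    }
    dH0 <- dH0 + dH
    dZ0 <- dH0 * drelu(fw$Z0)
    grads <- acc_grad(grads, "Wi", t(dZ0) %*% fw$In0)
    grads <- acc_grad(grads, "bi", colSums(dZ0))
  }
  list(loss = loss, grads = grads)
}

# mean loss over a set of molecules (list of (struct, targets))
dmpnn_batch_loss_grad <- function(params, hyper, scalers, batch,
                                  want_grad = TRUE) {
  total <- 0
  grads <- list()
  for (item in batch) {
    lg <- dmpnn_loss_grad_mol(params, hyper, scalers, item$s, item$targets,
                              want_grad)
    total <- total + lg$loss
    if (want_grad) for (nm in names(lg$grads)) {
      grads <- acc_grad(grads, nm, lg$grads[[nm]])
    }
  }
  if (want_grad) grads <- lapply(grads, function(g) g / length(batch))
  list(loss = total / length(batch), grads = grads)
}

table_to_items <- function(table) {
  chem_prefetch(table_molecules(table))
  lapply(table_molecules(table), function(smi) {
    d <- desc_for(table, smi)
    s <- mol_struct(smi)
    rs_assert(nrow(d$atoms) == s$n, "alignment",
              paste(smi, ": table does not align with molecule"))
    bonds <- d$bonds
    if (s$m > 0) {
      # align bond rows to graph bond order
      key_g <- paste(s$graph$bonds$i, s$graph$bonds$j)
      key_t <- paste(pmin(bonds$atom_index_1, bonds$atom_index_2),
                     pmax(bonds$atom_index_1, bonds$atom_index_2))
      ord <- match(key_g, key_t)
      rs_assert(!anyNA(ord), "alignment",
                paste(smi, ": bond rows do not match bonds"))
      bonds <- bonds[ord, , drop = FALSE]
    }
    list(s = s, targets = list(atoms = d$atoms, bonds = bonds))
  })
}

#' Mean multitask loss of a model on a descriptor table
#'
#' Sum over channels of the mean squared error of the post-constraint
#' outputs, each channel standardized by the model's target scale; mean over
#' molecules.
#' @param model a `dmpnn_model`
#' @param table a `descriptor_table`
#' @return scalar loss
#' @export
multitask_loss <- function(model, table) {
  items <- table_to_items(table)
  dmpnn_batch_loss_grad(model$params, model$hyper, model$scalers, items,
                        want_grad = FALSE)$loss
}

# per-channel MAE and R^2 in physical units
dmpnn_metrics <- function(model, items) {
  res <- list()
  for (ch in c(ATOM_CHANNELS, BOND_CHANNELS)) {
    pred <- c(); obs <- c()
    for (item in items) {
      p <- dmpnn_predict_struct(model, item$s)
      if (ch %in% ATOM_CHANNELS) {
        pred <- c(pred, p[[ch]]); obs <- c(obs, item$targets$atoms[[ch]])
      } else if (item$s$m > 0) {
        pred <- c(pred, p[[ch]]); obs <- c(obs, item$targets$bonds[[ch]])
      }
    }
    ss <- sum((obs - mean(obs))^2)
    res[[ch]] <- data.frame(
      channel = ch, mae = mean(abs(pred - obs)),
      r2 = if (ss > 0) 1 - sum((obs - pred)^2) / ss else NA_real_
    )
  }
  do.call(rbind, res)
}

#' Train the multitask descriptor model
#'
#' Minimizes the standardized multitask loss (constraint applied during
#' training, end to end) with Adam on shuffled minibatches; tracks the
#' validation loss each epoch and returns the best-on-validation model.
#'
#' @param train_table,val_table `descriptor_table`s
#' @param config a [dmpnn_config()]
#' @param epochs training epochs (0 returns the initialization unchanged)
#' @param lr Adam learning rate
#' @param batch_size molecules per minibatch
#' @param seed integer seed (initialization + shuffling)
#' @param verbose print per-epoch losses
#' @return list with `model`, `metrics` (per-channel validation MAE/R^2) and
#'   `history` (data.frame of train/val loss per epoch)
#' @export
train_multitask <- function(train_table, val_table, config = dmpnn_config(),
                            epochs = 30L, lr = 5e-3, batch_size = 16L,
                            seed = 1L, verbose = FALSE) {
  train_items <- table_to_items(train_table)
  rs_assert(length(train_items) > 0, "empty_dataset", "empty training table")
  val_items <- table_to_items(val_table)
  rs_assert(length(val_items) > 0, "empty_dataset", "empty validation table")

  model <- init_dmpnn(config, seed = seed)
  # target scalers from the training set (sd floor avoids degenerate channels)
  for (ch in ATOM_CHANNELS) {
    y <- unlist(lapply(train_items, function(i) i$targets$atoms[[ch]]))
    model$scalers[[ch]] <- c(mu = mean(y), sd = max(stats::sd(y), 1e-4))
  }
  for (ch in BOND_CHANNELS) {
    y <- unlist(lapply(train_items, function(i) i$targets$bonds[[ch]]))
    if (length(y) > 1) {
      model$scalers[[ch]] <- c(mu = mean(y), sd = max(stats::sd(y), 1e-4))
    }
  }

  best <- model
  best_val <- dmpnn_batch_loss_grad(model$params, model$hyper, model$scalers,
                                    val_items, want_grad = FALSE)$loss
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  if (epochs >= 1) {
    st <- adam_init(model$params)
    with_seed(child_seed(seed, "dmpnn-train"), {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(length(train_items))
        ep_loss <- 0; nb <- 0
        for (start in seq(1, length(ord), by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1, length(ord))]
          lg <- dmpnn_batch_loss_grad(model$params, model$hyper,
                                      model$scalers, train_items[idx])
          if (!is.finite(lg$loss)) {
            rs_abort("nonfinite_loss",
                     sprintf("non-finite loss at epoch %d (batch at %d)",
                             ep, start))
          }
          up <- adam_step(model$params, lg$grads, st, lr = lr)
          model$params <- up$params; st <- up$state
          ep_loss <- ep_loss + lg$loss; nb <- nb + 1
        }
        vl <- dmpnn_batch_loss_grad(model$params, model$hyper, model$scalers,
                                    val_items, want_grad = FALSE)$loss
        history <- rbind(history, data.frame(
          epoch = ep, train_loss = ep_loss / nb, val_loss = vl))
        if (vl < best_val) {
          best_val <- vl
          best <- model
        }
        if (verbose) {
          message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                          ep_loss / nb, vl))
        }
      }
    })
  }
  best$manifest$trained <- epochs >= 1
  best$manifest$train_seed <- as.integer(seed)
  list(model = best, metrics = dmpnn_metrics(best, val_items),
       history = history)
}

# --- checkpoint I/O ---------------------------------------------------------

#' Save / load a descriptor-model checkpoint
#'
#' A checkpoint directory holds `manifest.json` (architecture constants,
#' seeds, element vocabulary, scalers) and `weights.json` (all parameter
#' arrays with their dimensions).  Plain text, human-inspectable.
#'
#' @param model a `dmpnn_model`
#' @param dir checkpoint directory
#' @export
save_dmpnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(model$manifest, list(hyper = model$hyper,
                           scalers = lapply(model$scalers, as.list))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  weights <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), values = as.numeric(p))
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_dmpnn
#' @return `load_dmpnn` returns the restored `dmpnn_model`
#' @export
load_dmpnn <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  weights <- jsonlite::read_json(file.path(dir, "weights.json"))
  params <- lapply(weights, function(w) {
    v <- vapply(w$values, as.numeric, numeric(1))
    d <- vapply(w$dim, as.integer, integer(1))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  })
  hyper <- dmpnn_config(hidden = man$hyper$hidden, depth = man$hyper$depth,
                        head_hidden = man$hyper$head_hidden,
                        similarity = man$hyper$similarity)
  scalers <- lapply(man$scalers, function(s) c(mu = s$mu, sd = s$sd))
  manifest <- man[setdiff(names(man), c("hyper", "scalers"))]
  structure(list(params = params, hyper = hyper, scalers = scalers,
                 manifest = manifest), class = "dmpnn_model")
}
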