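# Selectivity models: the QM-fused graph network (QM-GNN), its end-to-end
# variant with on-the-fly predicted descriptors (ml-QM-GNN), and the three
# ablation baselines (graph-only GNN, descriptor-only FFNN "QM", and
# fingerprint FFNN "FP").
#
# Graph modes encode all reactant molecules (substrate and reagent) with a
# Weisfeiler-Lehman encoder (L rounds of neighbour aggregation), update the
# local embeddings through a global attention layer that lets every atom
# attend over all atoms including disconnected molecules, optionally
# concatenate RBF-expanded atomic QM descriptors (fixed channel order:
# charge, fukui_elec, fukui_nuc, nmr), sum-pool the fused representations
# of the two reacting atoms of each candidate outcome, and score each
# candidate with a feed-forward network; a softmax across the candidate set
# yields per-candidate probabilities, so the model ranks the major outcome
# relative to its regio-isomeric alternatives.

SEL_MODES <- c("GNN", "QM-GNN", "ml-QM-GNN", "QM", "FP")

#' Hyperparameters of the selectivity models
#'
#' @param hidden atom embedding width H of the WLN encoder
#' @param depth number of WLN iterations L
#' @param latent width of the penultimate scoring layer (the latent vectors
#'   of [extract_latent()])
#' @param rbf_dim RBF expansion dimension per descriptor channel
#' @param fp_bits,fp_radius Morgan reaction-fingerprint parameters of the FP
#'   baseline
#' @return named list of hyperparameters
#' @export
selectivity_config <- function(hidden = 32L, depth = 2L, latent = 32L,
                               rbf_dim = 8L, fp_bits = 2048L, fp_radius = 2L) {
  stopifnot(depth >= 0, hidden >= 1, latent >= 1, rbf_dim >= 1)
  list(hidden = as.integer(hidden), depth = as.integer(depth),
       latent = as.integer(latent), rbf_dim = as.integer(rbf_dim),
       fp_bits = as.integer(fp_bits), fp_radius = as.integer(fp_radius))
}

sel_input_dim <- function(mode, config) {
  switch(mode,
         "GNN" = config$hidden,
         "QM-GNN" = ,
         "ml-QM-GNN" = config$hidden + 4L * config$rbf_dim,
         "QM" = 4L * config$rbf_dim,
         "FP" = config$fp_bits)
}

#' Initialize an (untrained) selectivity model
#'
#' @param mode one of `"GNN"`, `"QM-GNN"`, `"ml-QM-GNN"`, `"QM"`, `"FP"`
#' @param config a [selectivity_config()]
#' @param seed integer seed
#' @param rbf_specs named [rbf_spec()] list for the QM modes (defaults to
#'   [default_rbf_specs()] at the configured dimension)
#' @return a `selectivity_model`
#' @export
init_selectivity <- function(mode = "QM-GNN", config = selectivity_config(),
                             seed = 1L, rbf_specs = NULL) {
  mode <- match.arg(mode, SEL_MODES)
  if (is.null(rbf_specs)) rbf_specs <- default_rbf_specs(config$rbf_dim)
  H <- config$hidden
  Fa <- atom_feature_dim()
  Fb <- if (mode %in% c("QM-GNN", "ml-QM-GNN")) 2L * config$rbf_dim
  else bond_feature_dim()
  fused <- sel_input_dim(mode, config)
  params <- with_seed(child_seed(seed, "sel-init"), {
    p <- list()
    if (mode %in% c("GNN", "QM-GNN", "ml-QM-GNN")) {
      p$Win <- nn_init_mat(H, Fa); p$bin <- numeric(H)
      p$Ws <- nn_init_mat(H, H); p$bs <- numeric(H)
      p$Wn <- nn_init_mat(H, H); p$We <- nn_init_mat(H, Fb); p$bn <- numeric(H)
      p$Wq <- nn_init_mat(H, H); p$Wk <- nn_init_mat(H, H)
      p$Wv <- nn_init_mat(H, H)
    }
    p$W1 <- nn_init_mat(config$latent, fused); p$b1 <- numeric(config$latent)
    p$w2 <- nn_init_mat(1, config$latent); p$b2 <- numeric(1)
    p
  })
  structure(list(params = params, hyper = config, mode = mode,
                 rbf_specs = rbf_specs,
                 manifest = list(seed = as.integer(seed), mode = mode,
                                 trained = FALSE)),
            class = "selectivity_model")
}

#' @export
print.selectivity_model <- function(x, ...) {
  cat("<selectivity_model> mode=", x$mode, " H=", x$hyper$hidden,
      " L=", x$hyper$depth,
      " (", if (isTRUE(x$manifest$trained)) "trained" else "untrained", ")\n",
      sep = "")
  invisible(x)
}

# --- descriptor sourcing ----------------------------------------------------

# resolve descriptors for one canonical smiles, from a table (QM) or a
# dmpnn model (ml); ml predictions are cached on the model's environment
resolve_descriptors <- function(smiles, source) {
  if (inherits(source, "descriptor_table")) {
    return(desc_for(source, smiles))
  }
  if (inherits(source, "dmpnn_model")) {
    env <- attr(source, "pred_cache")
    if (is.null(env)) env <- .struct_cache  # fallback shared cache
    key <- paste0("ml:", source$manifest$seed, ":",
                  source$manifest$train_seed %||% "", ":", smiles)
    if (!exists(key, envir = env)) {
      p <- predict_descriptors(smiles, source)
      assign(key, list(atoms = p$atoms, bonds = p$bonds), envir = env)
    }
    return(get(key, envir = env))
  }
  rs_abort("missing_descriptor",
           paste0("mode requires descriptors but no table/model supplied (",
                  smiles, ")"))
}

#' Attach a prediction cache to a descriptor model
#'
#' With a cache attached, repeated reactants cost a single descriptor
#' inference each (results are keyed by canonical SMILES).
#' @param model a `dmpnn_model`
#' @return the model with a cache environment attribute
#' @export
with_pred_cache <- function(model) {
  attr(model, "pred_cache") <- new.env(parent = emptyenv())
  model
}

# --- reaction featurization -------------------------------------------------

# combined reactant-set structure; component-to-table alignment via the
# canonical output order of each component
reaction_struct <- function(record) {
  g <- parse_mapped_smiles(record$reactant_smiles)
  comps <- strsplit(record$reactant_smiles, ".", fixed = TRUE)[[1]]
  offsets <- integer(length(comps))
  comp_graphs <- vector("list", length(comps))
  off <- 0L
  for (ci in seq_along(comps)) {
    cg <- parse_mapped_smiles(comps[ci])
    comp_graphs[[ci]] <- cg
    offsets[ci] <- off
    off <- off + n_atoms(cg)
  }
  rs_assert(off == n_atoms(g), "parse", "component atom counts do not add up")
  lut <- map_lookup(g)
  pairs <- lapply(record$candidates, function(cc) {
    idx <- lut[as.character(cc$pair)]
    rs_assert(!anyNA(idx), "unresolved_map",
              paste("candidate map pair", paste(cc$pair, collapse = "-"),
                    "not found in reactant set"))
    as.integer(idx)
  })
  m <- nrow(g$bonds)
  src <- dst <- rev_idx <- integer(2 * m)
  for (t in seq_len(m)) {
    src[2 * t - 1] <- g$bonds$i[t]; dst[2 * t - 1] <- g$bonds$j[t]
    src[2 * t] <- g$bonds$j[t]; dst[2 * t] <- g$bonds$i[t]
    rev_idx[2 * t - 1] <- 2 * t; rev_idx[2 * t] <- 2 * t - 1
  }
  list(graph = g, n = n_atoms(g), m = m, X = atom_features(g),
       src = src, dst = dst, rev = rev_idx,
       comps = comp_graphs, offsets = offsets, pairs = pairs,
       major = record$major_index, record = record)
}

# per-atom QM descriptor matrix (n x 4, channel order charge, fukui_elec,
# fukui_nuc, nmr) and per-bond descriptor matrix (m x 2) for the combined
# graph, aligned through each component's canonical order
reaction_descriptors <- function(rstruct, source) {
  n <- rstruct$n
  atom_d <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, ATOM_CHANNELS))
  bond_key <- paste(rstruct$graph$bonds$i, rstruct$graph$bonds$j)
  bond_d <- matrix(NA_real_, rstruct$m, 2,
                   dimnames = list(NULL, BOND_CHANNELS))
  for (ci in seq_along(rstruct$comps)) {
    cg <- rstruct$comps[[ci]]
    off <- rstruct$offsets[ci]
    d <- resolve_descriptors(cg$smiles_canonical, source)
    rs_assert(nrow(d$atoms) == n_atoms(cg), "missing_descriptor",
              paste0("descriptor rows do not match ", cg$smiles_canonical))
    # storage row k sits at component atom canonical_order[k]
    for (k in seq_len(nrow(d$atoms))) {
      at <- off + cg$canonical_order[d$atoms$atom_index[k]]
      atom_d[at, ] <- c(d$atoms$charge[k], d$atoms$fukui_elec[k],
                        d$atoms$fukui_nuc[k], d$atoms$nmr[k])
    }
    if (n_atoms(cg) > 1) {
      rs_assert(nrow(d$bonds) == nrow(cg$bonds), "missing_descriptor",
                paste0("bond descriptor rows do not match ",
                       cg$smiles_canonical))
    }
    for (k in seq_len(nrow(d$bonds))) {
      a <- off + cg$canonical_order[d$bonds$atom_index_1[k]]
      b <- off + cg$canonical_order[d$bonds$atom_index_2[k]]
      pos <- match(paste(min(a, b), max(a, b)), bond_key)
      rs_assert(!is.na(pos), "missing_descriptor",
                paste0("descriptor bond ", a, "-", b, " not in graph"))
      bond_d[pos, ] <- c(d$bonds$bond_order[k], d$bonds$bond_length[k])
    }
  }
  rs_assert(!anyNA(atom_d), "missing_descriptor",
            "atoms without descriptors in reactant set")
  rs_assert(rstruct$m == 0 || !anyNA(bond_d), "missing_descriptor",
            "bonds without order/length descriptors in reactant set")
  list(atoms = atom_d, bonds = bond_d)
}

# full training/prediction item for one record under one mode
selectivity_item <- function(record, model, descriptors = NULL) {
  mode <- model$mode
  if (mode == "FP") {
    reactants <- chem_canonical(record$reactant_smiles)
    prods <- vapply(record$candidates, function(cc) cc$product_smiles,
                    character(1))
    fps <- chem_reaction_fp(rep(reactants, length(prods)), prods,
                            bits = model$hyper$fp_bits,
                            radius = model$hyper$fp_radius)
    FPm <- matrix(0, length(prods), model$hyper$fp_bits)
    for (k in seq_along(fps)) {
      rs_assert(isTRUE(fps[[k]]$ok), "parse", "fingerprint failure")
      idx <- vapply(fps[[k]]$idx, as.integer, integer(1)) + 1L
      val <- vapply(fps[[k]]$val, as.numeric, numeric(1))
      FPm[k, idx] <- val
    }
    return(list(kind = "FP", FP = FPm, major = record$major_index,
                ncand = length(prods)))
  }
  s <- reaction_struct(record)
  if (mode == "GNN") {
    s$E2 <- if (s$m > 0) {
      E1 <- bond_features_discrete(s$graph)
      E1[rep(seq_len(s$m), each = 2), , drop = FALSE]
    } else matrix(0, 0, bond_feature_dim())
    s$kind <- "graph"
    s$atom_rbf <- NULL
    return(s)
  }
  d <- reaction_descriptors(s, descriptors)
  if (mode == "QM") {
    s$kind <- "QM"
  } else {
    s$kind <- "graph"
    E1 <- cbind(rbf_expand(d$bonds[, "bond_order"], model$rbf_specs$bond_order),
                rbf_expand(d$bonds[, "bond_length"], model$rbf_specs$bond_length))
    s$E2 <- if (s$m > 0) E1[rep(seq_len(s$m), each = 2), , drop = FALSE]
    else matrix(0, 0, 2 * model$hyper$rbf_dim)
  }
  s$atom_rbf <- cbind(
    rbf_expand(d$atoms[, "charge"], model$rbf_specs$charge),
    rbf_expand(d$atoms[, "fukui_elec"], model$rbf_specs$fukui_elec),
    rbf_expand(d$atoms[, "fukui_nuc"], model$rbf_specs$fukui_nuc),
    rbf_expand(d$atoms[, "nmr"], model$rbf_specs$nmr)
  )
  s
}

# --- forward / backward -----------------------------------------------------

sel_encode_forward <- function(params, hyper, item) {
  L <- hyper$depth
  n <- item$n
  Z0 <- sweep(item$X %*% t(params$Win), 2, params$bin, "+")
  h <- relu(Z0)
  hs <- vector("list", L + 1); hs[[1]] <- h
  tpres <- Zs <- vector("list", L + 1)
  if (L > 0 && length(item$src) > 0) {
    for (l in seq_len(L)) {
      tpre <- sweep(hs[[l]][item$src, , drop = FALSE] %*% t(params$Wn) +
                      item$E2 %*% t(params$We), 2, params$bn, "+")
      tk <- relu(tpre)
      Nagg <- rowsum_into(tk, item$dst, n)
      Z <- sweep(hs[[l]] %*% t(params$Ws) + Nagg, 2, params$bs, "+")
      hs[[l + 1]] <- relu(Z)
      tpres[[l]] <- tpre; Zs[[l]] <- Z
    }
  } else if (L > 0) {
    for (l in seq_len(L)) {
      Z <- sweep(hs[[l]] %*% t(params$Ws), 2, params$bs, "+")
      hs[[l + 1]] <- relu(Z)
      Zs[[l]] <- Z
    }
  }
  hL <- hs[[L + 1]]
  # global attention over all atoms (all molecules)
  sq <- sqrt(hyper$hidden)
  Qm <- hL %*% t(params$Wq); Km <- hL %*% t(params$Wk); Vm <- hL %*% t(params$Wv)
  logits <- Qm %*% t(Km) / sq
  P <- softmax_rows(logits)
  C <- P %*% Vm
  E <- hL + C
  list(Z0 = Z0, hs = hs, tpres = tpres, Zs = Zs, hL = hL,
       Qm = Qm, Km = Km, Vm = Vm, P = P, C = C, E = E)
}

sel_encode_backward <- function(params, hyper, item, fw, dE, grads) {
  n <- item$n
  sq <- sqrt(hyper$hidden)
  L <- hyper$depth
  dhL <- dE                      # residual path
  dC <- dE
  dP <- dC %*% t(fw$Vm)
  dVm <- t(fw$P) %*% dC
  dlog <- softmax_rows_backward(fw$P, dP)
  dQm <- dlog %*% fw$Km / sq
  dKm <- t(dlog) %*% fw$Qm / sq
  grads <- acc_grad(grads, "Wq", t(dQm) %*% fw$hL)
  grads <- acc_grad(grads, "Wk", t(dKm) %*% fw$hL)
  grads <- acc_grad(grads, "Wv", t(dVm) %*% fw$hL)
  dhL <- dhL + dQm %*% params$Wq + dKm %*% params$Wk + dVm %*% params$Wv

  dh <- dhL
  if (L > 0) {
    for (l in L:1) {
      dZ <- dh * drelu(fw$Zs[[l]])
      grads <- acc_grad(grads, "Ws", t(dZ) %*% fw$hs[[l]])
      grads <- acc_grad(grads, "bs", colSums(dZ))
      dh <- dZ %*% params$Ws
      if (length(item$src) > 0) {
        dtk <- dZ[item$dst, , drop = FALSE]
        dtp <- dtk * drelu(fw$tpres[[l]])
        grads <- acc_grad(grads, "Wn",
                          t(dtp) %*% fw$hs[[l]][item$src, , drop = FALSE])
        grads <- acc_grad(grads, "We", t(dtp) %*% item$E2)
        grads <- acc_grad(grads, "bn", colSums(dtp))
        dh <- dh + rowsum_into(dtp %*% params$Wn, item$src, n)
      }
    }
  }
  dZ0 <- dh * drelu(fw$Z0)
  grads <- acc_grad(grads, "Win", t(dZ0) %*% item$X)
  grads <- acc_grad(grads, "bin", colSums(dZ0))
  grads
}

# fused per-atom representation matrix for a graph-mode item
sel_fused <- function(item, fw) {
  if (is.null(item$atom_rbf)) fw$E else cbind(fw$E, item$atom_rbf)
}

# candidate input rows (ncand x fused) for any non-FP item
sel_candidate_inputs <- function(item, fw) {
  if (item$kind == "QM") {
    Fm <- item$atom_rbf
  } else {
    Fm <- sel_fused(item, fw)
  }
  t(vapply(item$pairs, function(pr) Fm[pr[1], ] + Fm[pr[2], ],
           numeric(ncol(Fm))))
}

sel_score_forward <- function(params, R) {
  pre <- sweep(R %*% t(params$W1), 2, params$b1, "+")
  hid <- relu(pre)
  sc <- drop(hid %*% t(params$w2)) + params$b2
  list(pre = pre, hid = hid, scores = sc)
}

# forward pass; returns probabilities, latents, and intermediates
sel_forward_item <- function(model, item, keep = FALSE) {
  params <- model$params
  if (item$kind == "FP") {
    hf <- sel_score_forward(params, item$FP)
    p <- softmax(hf$scores)
    return(list(p = p, scores = hf$scores, latent = hf$hid, hf = hf,
                fw = NULL, R = item$FP))
  }
  fw <- if (item$kind == "QM") NULL
  else sel_encode_forward(params, model$hyper, item)
  R <- sel_candidate_inputs(item, fw)
  hf <- sel_score_forward(params, R)
  p <- softmax(hf$scores)
  list(p = p, scores = hf$scores, latent = hf$hid, hf = hf, fw = fw, R = R)
}

# cross-entropy loss + full gradients for one item
sel_loss_grad_item <- function(model, item) {
  out <- sel_forward_item(model, item)
  p <- out$p
  loss <- -log(max(p[item$major], 1e-12))
  dsc <- p
  dsc[item$major] <- dsc[item$major] - 1
  grads <- list()
  dhid <- matrix(dsc, ncol = 1) %*% model$params$w2
  dpre <- dhid * drelu(out$hf$pre)
  grads <- acc_grad(grads, "w2", matrix(dsc, nrow = 1) %*% out$hf$hid)
  grads <- acc_grad(grads, "b2", sum(dsc))
  grads <- acc_grad(grads, "W1", t(dpre) %*% out$R)
  grads <- acc_grad(grads, "b1", colSums(dpre))
  dR <- dpre %*% model$params$W1
  if (item$kind %in% c("FP", "QM")) {
    return(list(loss = loss, grads = grads, p = p))
  }
  H <- model$hyper$hidden
  dF <- matrix(0, item$n, ncol(dR))
  for (k in seq_along(item$pairs)) {
    pr <- item$pairs[[k]]
    dF[pr[1], ] <- dF[pr[1], ] + dR[k, ]
    dF[pr[2], ] <- dF[pr[2], ] + dR[k, ]
  }
  dE <- dF[, seq_len(H), drop = FALSE]
  grads <- sel_encode_backward(model$params, model$hyper, item, out$fw, dE,
                               grads)
  list(loss = loss, grads = grads, p = p)
}

# --- public ops -------------------------------------------------------------

#' WLN local embeddings of a reactant set
#'
#' @param record a `reaction_record` (or mapped SMILES of a reactant set)
#' @param model a graph-mode `selectivity_model`
#' @param descriptors descriptor source for the QM modes (a
#'   `descriptor_table`, or a `dmpnn_model` for `ml-QM-GNN`)
#' @return per-atom local embedding matrix (n x H)
#' @export
wln_encode <- function(record, model, descriptors = NULL) {
  rs_assert(model$mode %in% c("GNN", "QM-GNN", "ml-QM-GNN"), "index",
            "wln_encode applies to graph modes only")
  item <- as_sel_item(record, model, descriptors)
  sel_encode_forward(model$params, model$hyper, item)$hL
}

#' Global attention context over all reactant atoms
#'
#' Each atom attends over every atom of every reactant molecule (scaled
#' dot-product attention); the returned context has the width of the input.
#' With all logits equal (e.g. zero query/key weights) the context is the
#' mean-pooled value vector.
#'
#' @param local per-atom local embedding matrix
#' @param model a graph-mode `selectivity_model`
#' @return per-atom context matrix of the same dimensions
#' @export
global_attention <- function(local, model) {
  p <- model$params
  sq <- sqrt(model$hyper$hidden)
  logits <- (local %*% t(p$Wq)) %*% t(local %*% t(p$Wk)) / sq
  P <- softmax_rows(logits)
  P %*% (local %*% t(p$Wv))
}

#' Fuse a learned atomic embedding with RBF-expanded QM descriptors
#'
#' Concatenation in the fixed channel order charge, fukui_elec, fukui_nuc,
#' nmr; output length is `H + 4 * rbf_dim`.
#'
#' @param context per-atom embedding matrix (n x H)
#' @param atom_desc data.frame or matrix with the four atomic descriptor
#'   columns
#' @param specs named [rbf_spec()] list
#' @return fused per-atom representation matrix
#' @export
fuse_qm <- function(context, atom_desc, specs = default_rbf_specs()) {
  for (ch in ATOM_CHANNELS) {
    rs_assert(ch %in% colnames(atom_desc) || ch %in% names(atom_desc),
              "missing_descriptor", paste("missing descriptor channel:", ch))
  }
  ad <- as.data.frame(atom_desc)
  cbind(context,
        rbf_expand(ad$charge, specs$charge),
        rbf_expand(ad$fukui_elec, specs$fukui_elec),
        rbf_expand(ad$fukui_nuc, specs$fukui_nuc),
        rbf_expand(ad$nmr, specs$nmr))
}

#' Sum-pool the fused representations of a reacting atom pair
#'
#' @param fused per-atom fused representation matrix
#' @param pair length-2 vector of atom indices (rows of `fused`)
#' @return numeric vector (elementwise sum of the two rows)
#' @export
pool_reacting_pair <- function(fused, pair) {
  rs_assert(length(pair) == 2 && all(pair >= 1) && all(pair <= nrow(fused)),
            "unresolved_map", "pair does not resolve to fused rows")
  fused[pair[1], ] + fused[pair[2], ]
}

as_sel_item <- function(record, model, descriptors = NULL) {
  if (inherits(record, "reaction_record")) {
    selectivity_item(record, model, descriptors)
  } else {
    record  # already an item
  }
}

#' Score the candidate outcomes of a reaction
#'
#' Returns the per-candidate softmax probabilities under the model.  Mode
#' `"GNN"` never reads descriptors (the `descriptors` argument is ignored);
#' mode `"QM"` never runs the graph encoder; `"QM-GNN"` requires a
#' `descriptor_table`; `"ml-QM-GNN"` requires a `dmpnn_model` and predicts
#' descriptors on the fly.  Ties in the top-1 candidate break toward the
#' lowest candidate index.
#'
#' @param record a `reaction_record`
#' @param model a `selectivity_model`
#' @param descriptors descriptor source as required by the mode
#' @return a `selectivity_scores` object (numeric probabilities summing
#'   to 1, attribute `top1`)
#' @export
score_candidates <- function(record, model, descriptors = NULL) {
  if (model$mode == "GNN") descriptors <- NULL
  item <- as_sel_item(record, model, descriptors)
  out <- sel_forward_item(model, item)
  structure(out$p, top1 = which.max(out$p), class = "selectivity_scores")
}

#' @export
print.selectivity_scores <- function(x, ...) {
  cat("<selectivity_scores>", paste(sprintf("%.3f", unclass(x)), collapse = " "),
      " top1 =", attr(x, "top1"), "\n")
  invisible(x)
}

#' Latent reaction vector of one candidate
#'
#' The activations of the penultimate scoring layer for the candidate, the
#' continuous representation used for latent-space distance analysis.
#'
#' @param record a `reaction_record`
#' @param candidate_index candidate to extract
#' @param model a `selectivity_model`
#' @param descriptors descriptor source as required by the mode
#' @return numeric vector of length `latent`
#' @export
extract_latent <- function(record, candidate_index, model,
                           descriptors = NULL) {
  if (model$mode == "GNN") descriptors <- NULL
  item <- as_sel_item(record, model, descriptors)
  ncand <- if (item$kind == "FP") item$ncand else length(item$pairs)
  rs_assert(candidate_index >= 1 && candidate_index <= ncand, "index",
            "candidate_index out of range")
  out <- sel_forward_item(model, item)
  out$latent[candidate_index, ]
}

#' Euclidean distance between two latent reaction vectors
#' @param v1,v2 numeric vectors of equal length
#' @return nonnegative scalar, 0 iff the vectors are equal
#' @export
latent_distance <- function(v1, v2) {
  rs_assert(length(v1) == length(v2), "length_mismatch",
            "latent vectors differ in length")
  sqrt(sum((v1 - v2)^2))
}

# --- training ---------------------------------------------------------------

#' RBF grids fitted to the descriptors a record set will actually see
#'
#' Resolves descriptors for every reactant molecule of `records` from the
#' given source (table or descriptor model) and fits the expansion grids to
#' the observed ranges via [rbf_specs_from_table()].
#'
#' @param records list of `reaction_record`
#' @param descriptors a `descriptor_table` or `dmpnn_model`
#' @param dim expansion dimension per channel
#' @return named list of [rbf_spec()]
#' @export
specs_from_source <- function(records, descriptors, dim = 8L) {
  comps <- unique(unlist(lapply(records, function(r) {
    strsplit(r$reactant_smiles, ".", fixed = TRUE)[[1]]
  })))
  cans <- unique(chem_canonical(comps))
  if (inherits(descriptors, "dmpnn_model")) {
    tab <- predict_descriptor_table(cans, descriptors)
  } else {
    rs_assert(inherits(descriptors, "descriptor_table"), "missing_descriptor",
              "no descriptor source to fit RBF grids to")
    per <- lapply(cans, desc_for, table = descriptors)
    tab <- descriptor_table(do.call(rbind, lapply(per, `[[`, "atoms")),
                            do.call(rbind, lapply(per, `[[`, "bonds")),
                            provenance = descriptors$provenance,
                            validate = FALSE)
  }
  rbf_specs_from_table(tab, dim = dim)
}

sel_items <- function(records, model, descriptors) {
  rsmis <- vapply(records, function(r) r$reactant_smiles, character(1))
  comps <- unlist(strsplit(rsmis, ".", fixed = TRUE))
  chem_prefetch(c(rsmis, comps))
  chem_prefetch(chem_canonical(unique(comps)))
  lapply(records, function(r) {
    rs_assert(length(r$candidates) >= 2, "degenerate_record",
              "selective training requires >= 2 candidates per record")
    selectivity_item(r, model, descriptors)
  })
}

sel_top1_accuracy <- function(model, items) {
  hits <- vapply(items, function(it) {
    p <- sel_forward_item(model, it)$p
    as.integer(which.max(p) == it$major)
  }, integer(1))
  mean(hits)
}

#' Train a selectivity model
#'
#' Minimizes the softmax cross-entropy of each record's candidate set
#' against the recorded major outcome with Adam; reports validation top-1
#' accuracy per epoch and returns the best-on-validation model.
#'
#' @param train,val lists of `reaction_record` (every record selective,
#'   i.e. at least two candidates)
#' @param mode model mode, see [score_candidates()]
#' @param descriptors descriptor source as required by the mode
#' @param config a [selectivity_config()]
#' @param epochs,lr,batch_size optimizer settings
#' @param seed integer seed
#' @param rbf_specs optional named [rbf_spec()] list; by default the QM
#'   modes fit their grids to the descriptor ranges observed on the
#'   training and validation reactants ([specs_from_source()])
#' @param verbose print per-epoch progress
#' @return list with `model`, `accuracy` (per-epoch validation top-1 curve)
#'   and `best_accuracy`
#' @export
train_selectivity <- function(train, val, mode = "QM-GNN",
                              descriptors = NULL,
                              config = selectivity_config(),
                              epochs = 30L, lr = 2e-3, batch_size = 8L,
                              seed = 1L, rbf_specs = NULL, verbose = FALSE) {
  rs_assert(length(train) > 0 && length(val) > 0, "empty_dataset",
            "empty training or validation set")
  if (mode == "ml-QM-GNN" && inherits(descriptors, "dmpnn_model") &&
      is.null(attr(descriptors, "pred_cache"))) {
    descriptors <- with_pred_cache(descriptors)
  }
  if (is.null(rbf_specs) && mode %in% c("QM-GNN", "ml-QM-GNN", "QM")) {
    rbf_specs <- specs_from_source(c(train, val), descriptors,
                                   dim = config$rbf_dim)
  }
  model <- init_selectivity(mode, config, seed = seed,
                            rbf_specs = rbf_specs)
  train_items <- sel_items(train, model, descriptors)
  val_items <- sel_items(val, model, descriptors)

  best <- model
  best_acc <- sel_top1_accuracy(model, val_items)
  curve <- data.frame(epoch = 0L, val_top1 = best_acc)
  if (epochs >= 1) {
    st <- adam_init(model$params)
    with_seed(child_seed(seed, "sel-train"), {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(length(train_items))
        for (start in seq(1, length(ord), by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1, length(ord))]
          grads <- list()
          tl <- 0
          for (it in train_items[idx]) {
            lg <- sel_loss_grad_item(model, it)
            tl <- tl + lg$loss
            for (nm in names(lg$grads)) {
              grads <- acc_grad(grads, nm, lg$grads[[nm]])
            }
          }
          if (!is.finite(tl)) {
            rs_abort("nonfinite_loss",
                     sprintf("non-finite loss at epoch %d", ep))
          }
          grads <- lapply(grads, function(g) g / length(idx))
          up <- adam_step(model$params, grads, st, lr = lr)
          model$params <- up$params; st <- up$state
        }
        acc <- sel_top1_accuracy(model, val_items)
        curve <- rbind(curve, data.frame(epoch = ep, val_top1 = acc))
        if (acc >= best_acc) {  # >= prefers later epochs at equal accuracy
          best_acc <- acc
          best <- model
        }
        if (verbose) message(sprintf("epoch %3d  val top-1 %.3f", ep, acc))
      }
    })
  }
  best$manifest$trained <- epochs >= 1
  best$manifest$train_seed <- as.integer(seed)
  list(model = best, accuracy = curve, best_accuracy = best_acc)
}

#' Top-1 accuracy of a selectivity model on a record set
#' @param model a `selectivity_model`
#' @param records list of `reaction_record`
#' @param descriptors descriptor source as required by the mode
#' @return fraction of records whose top-scoring candidate is the major one
#' @export
selectivity_accuracy <- function(model, records, descriptors = NULL) {
  if (model$mode == "GNN") descriptors <- NULL
  items <- sel_items(records, model, descriptors)
  sel_top1_accuracy(model, items)
}

#' Save / load a selectivity-model checkpoint (plain-text JSON)
#' @param model a `selectivity_model`
#' @param dir checkpoint directory
#' @export
save_selectivity <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(model$manifest,
      list(hyper = model$hyper, mode = model$mode,
           rbf_specs = lapply(model$rbf_specs, unclass))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  weights <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), values = as.numeric(p))
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_selectivity
#' @return `load_selectivity` returns the restored model
#' @export
load_selectivity <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  weights <- jsonlite::read_json(file.path(dir, "weights.json"))
  params <- lapply(weights, function(w) {
    v <- vapply(w$values, as.numeric, numeric(1))
    d <- vapply(w$dim, as.integer, integer(1))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  })
  hyper <- do.call(selectivity_config,
                   man$hyper[c("hidden", "depth", "latent", "rbf_dim",
                               "fp_bits", "fp_radius")])
  specs <- lapply(man$rbf_specs, function(s) {
    rbf_spec(vapply(s$centers, as.numeric, numeric(1)), as.numeric(s$gamma))
  })
  manifest <- man[setdiff(names(man), c("hyper", "mode", "rbf_specs"))]
  structure(list(params = params, hyper = hyper, mode = man$mode,
                 rbf_specs = specs, manifest = manifest),
            class = "selectivity_model")
}
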