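# Reaction curation: template extraction and re-application, selectivity
# identification, yield filtering, and dataset splitting (random CV with
# training-set downsampling, and a single scaffold split decided by greedy
# bin-packing), mirroring how selective substitution reactions are mined
# from a raw reaction corpus.

#' Extract a reaction template from an atom-mapped reaction
#'
#' Detects the reacting core (atoms whose mapped bonding environment or
#' hydrogen count changes between reactants and the recorded product),
#' grows it by `radius` bonds, and emits a reaction-SMARTS-style rewrite
#' rule with explicit hydrogen counts.  The self-application invariant is
#' enforced: re-applying the rule to its own reactants must regenerate the
#' recorded product (see [enumerate_candidates()]).
#'
#' @param mapped_rxn_smiles `reactants>reagents>products` SMILES, all
#'   product heavy atoms mapped, single product molecule
#' @param radius bonds beyond the changed atoms to include (default 1)
#' @param check verify the self-application invariant (default TRUE)
#' @return a `reaction_template`: list with `smarts`, `radius`,
#'   `changed_maps`, and `pair_tmaps` (the template map numbers of the new
#'   bond, i.e. the reacting atom pair)
#' @export
extract_template <- function(mapped_rxn_smiles, radius = 1L, check = TRUE) {
  res <- chem_call("extract_template",
                   list(rxns = list(mapped_rxn_smiles),
                        radius = as.integer(radius)))[[1]]
  if (!isTRUE(res$ok)) {
    type <- switch(res$error,
                   NoChangeDetected = "no_change",
                   UnmappedProductAtom = "unmapped_product_atom",
                   "parse")
    rs_abort(type, res$message %||% "template extraction failed")
  }
  pair <- if (length(res$new_bond_maps) >= 1) {
    vapply(res$new_bond_maps[[1]], as.integer, integer(1))
  } else NULL
  tpl <- structure(list(
    smarts = res$smarts, radius = as.integer(radius),
    changed_maps = vapply(res$changed_maps, as.integer, integer(1)),
    pair_tmaps = pair
  ), class = "reaction_template")
  if (check) {
    reactants <- strsplit(mapped_rxn_smiles, ">", fixed = TRUE)[[1]][1]
    recorded <- strsplit(mapped_rxn_smiles, ">", fixed = TRUE)[[1]][3]
    outcomes <- enumerate_candidates(tpl, reactants)
    prods <- vapply(outcomes, function(o) o$product_smiles, character(1))
    rs_assert(chem_canonical(recorded) %in% prods, "no_match",
              "template self-application does not regenerate the product")
  }
  tpl
}

#' @export
print.reaction_template <- function(x, ...) {
  cat("<reaction_template> r=", x$radius, "  ", x$smarts, "\n", sep = "")
  invisible(x)
}

#' Enumerate candidate regio-isomeric outcomes of a template
#'
#' Applies the template at every matching site of the reactant set and
#' deduplicates outcomes by canonical product SMILES, so symmetry-equivalent
#' sites collapse to a single candidate.
#'
#' @param template a `reaction_template` (or a reaction-SMARTS string)
#' @param reactants atom-mapped reactant-set SMILES (`.`-separated)
#' @return list of candidate outcomes: `pair` (reacting atom-map numbers,
#'   where resolvable) and `product_smiles`
#' @export
enumerate_candidates <- function(template, reactants) {
  smarts <- if (inherits(template, "reaction_template")) template$smarts
  else template
  pair_tmaps <- if (inherits(template, "reaction_template")) {
    template$pair_tmaps
  } else NULL
  res <- chem_call("apply_template",
                   list(smarts = smarts, pair_tmaps = pair_tmaps,
                        reactants = list(reactants)))[[1]]
  if (!isTRUE(res$ok)) {
    type <- switch(res$error, NoMatch = "no_match", "parse")
    rs_abort(type, res$message %||% "template application failed")
  }
  lapply(res$outcomes, function(o) {
    pr <- if (!is.null(o$pair)) {
      vapply(o$pair, as.integer, integer(1))
    } else NULL
    list(pair = pr, product_smiles = o$product)
  })
}

#' Identify whether an enumerated reaction is selective
#'
#' A reaction is selective when at least two distinct candidate outcomes
#' exist and the recorded product matches exactly one of them; that
#' candidate becomes the major outcome.
#'
#' @param candidates list of candidate outcomes (see
#'   [enumerate_candidates()])
#' @param recorded_product SMILES of the recorded product
#' @return list with `selective` (logical) and `major_index` (index of the
#'   matching candidate, or NA when not selective)
#' @export
identify_selective <- function(candidates, recorded_product) {
  rec <- chem_canonical(recorded_product)
  prods <- vapply(candidates, function(o) chem_canonical(o$product_smiles),
                  character(1))
  hit <- which(prods == rec)
  rs_assert(length(hit) >= 1, "no_match",
            "recorded product is not among the enumerated candidates")
  list(selective = length(candidates) >= 2 && length(hit) == 1,
       major_index = if (length(hit) == 1) hit else NA_integer_)
}

#' Filter records by reported yield
#'
#' Keeps records with `yield_pct >= threshold_pct`.  Records with a missing
#' yield are dropped: without a yield one cannot be confident the recorded
#' product is the major outcome rather than merely the desired one.
#'
#' @param records list of `reaction_record`
#' @param threshold_pct yield threshold in percent (default 50)
#' @return filtered list
#' @export
filter_yield <- function(records, threshold_pct = 50) {
  stopifnot(threshold_pct >= 0, threshold_pct <= 100)
  keep <- vapply(records, function(r) {
    !is.na(r$yield_pct) && r$yield_pct >= threshold_pct
  }, logical(1))
  records[keep]
}

#' Scaffold key of a record's substrate
#'
#' The generic Murcko framework (ring systems plus linkers, atoms and bonds
#' made generic) of the largest reactant that contains an aromatic ring;
#' the largest reactant overall when none is aromatic.  Records whose
#' reactants are all acyclic get the key `"<acyclic>"`.
#'
#' @param records list of `reaction_record`
#' @return character vector of scaffold keys
#' @export
scaffold_keys <- function(records) {
  all_comps <- lapply(records, function(r) {
    strsplit(r$reactant_smiles, ".", fixed = TRUE)[[1]]
  })
  chem_prefetch(unlist(all_comps))
  picked <- vapply(seq_along(records), function(ri) {
    graphs <- lapply(all_comps[[ri]], parse_mapped_smiles)
    arom <- vapply(graphs, function(g) any(g$atoms$aromatic), logical(1))
    sizes <- vapply(graphs, n_atoms, integer(1))
    pick <- if (any(arom)) which(arom)[which.max(sizes[arom])]
    else which.max(sizes)
    graphs[[pick]]$smiles_canonical
  }, character(1))
  keys <- chem_scaffold_raw(picked)
  ifelse(is.na(keys) | !nzchar(keys), "<acyclic>", keys)
}

#' Single scaffold split by greedy bin-packing
#'
#' Groups records by scaffold key, then assigns scaffold groups
#' largest-first to the partition that is proportionally most underfilled
#' relative to the target ratios, so no scaffold spans two partitions.
#' Ties (equal group size) break by lexicographic scaffold key; ties in
#' underfill break toward train, then validation.
#'
#' @param records list of `reaction_record`
#' @param ratios length-3 numeric vector (train, val, test) summing to 1
#' @return list with `train`, `val`, `test` (record lists), `assignment`
#'   (scaffold key -> partition), and `achieved` ratios (which can deviate
#'   from the target when a few scaffolds dominate; this is reported, not
#'   an error)
#' @export
scaffold_split <- function(records, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  keys <- scaffold_keys(records)
  groups <- split(seq_along(records), keys)
  assignment <- greedy_bin_pack(vapply(groups, length, integer(1)), ratios)
  part <- function(bin) {
    idx <- sort(unlist(groups[names(assignment)[assignment == bin]],
                       use.names = FALSE))
    records[idx]
  }
  fill <- vapply(c(train = "train", val = "val", test = "test"),
                 function(b) sum(lengths(groups[assignment == b])), numeric(1))
  list(train = part("train"), val = part("val"), test = part("test"),
       assignment = assignment,
       achieved = fill / length(records))
}

#' Greedy bin-packing of scaffold groups into train/val/test
#'
#' Groups are taken largest-first (lexicographic key order on ties) and each
#' is assigned to the partition that is proportionally most underfilled
#' relative to the target ratios; proportional-fill ties break toward train,
#' then validation.  Deterministic.
#'
#' @param sizes named integer vector of group sizes (names are the scaffold
#'   keys)
#' @param ratios length-3 target ratios (train, val, test) summing to 1
#' @return named character vector: group name -> partition
#' @export
greedy_bin_pack <- function(sizes, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  ord <- order(-sizes, names(sizes))
  fill <- c(train = 0, val = 0, test = 0)
  target <- ratios * sum(sizes)
  assignment <- stats::setNames(character(length(sizes)), names(sizes))
  for (gi in ord) {
    frac <- fill / pmax(target, 1e-9)
    bin <- names(frac)[which.min(frac)]
    assignment[gi] <- bin
    fill[bin] <- fill[bin] + sizes[gi]
  }
  assignment
}

#' Random cross-validation splits with fixed test size and optional
#' training downsampling
#'
#' Partitions the records into `folds` disjoint test sets of exactly
#' `test_size` records; for each fold the remainder is split into a
#' validation set and a training set, and the training set is optionally
#' downsampled with the fold-specific seed.  Test membership of a fold is
#' identical across downsampling levels by construction.
#'
#' @param records list of `reaction_record`
#' @param folds number of folds (>= 2)
#' @param test_size records per test fold (`folds * test_size <= N`)
#' @param train_downsample optional cap on the training-set size
#' @param val_size validation records per fold (default: same as test_size,
#'   capped by availability)
#' @param seed integer seed
#' @return list of folds; each fold is a list with `train`, `val`, `test`
#'   index vectors into `records`
#' @export
cv_splits <- function(records, folds = 10L, test_size = NULL,
                      train_downsample = NULL, val_size = NULL, seed = 1L) {
  n <- length(records)
  stopifnot(folds >= 2)
  if (is.null(test_size)) test_size <- floor(n / folds)
  rs_assert(folds * test_size <= n, "insufficient_data",
            sprintf("folds * test_size = %d exceeds N = %d",
                    folds * test_size, n))
  perm <- with_seed(child_seed(seed, "cv-perm"), sample.int(n))
  lapply(seq_len(folds), function(f) {
    test <- sort(perm[((f - 1) * test_size + 1):(f * test_size)])
    rest <- setdiff(perm, test)  # keeps permutation order
    vs <- min(val_size %||% test_size, max(length(rest) - 1, 0))
    val <- sort(rest[seq_len(vs)])
    train <- setdiff(rest, val)
    if (!is.null(train_downsample) && train_downsample < length(train)) {
      train <- sort(with_seed(child_seed(seed, paste0("cv-ds-", f)),
                              sample(train, train_downsample)))
    } else {
      train <- sort(train)
    }
    list(train = train, val = val, test = test)
  })
}

#' Curate selective reactions from a raw reaction CSV
#'
#' For each raw record (columns `reaction_id`, `mapped_rxn_smiles`,
#' `yield_pct`): extract a template, enumerate candidates, keep the
#' reaction when it is selective, and apply the yield filter.
#'
#' @param path raw CSV path
#' @param radius template radius
#' @param yield_threshold yield filter threshold in percent
#' @param class_map optional function(template smarts) -> class label
#' @return list of curated `reaction_record`
#' @export
curate_reactions <- function(path, radius = 1L, yield_threshold = 50,
                             class_map = NULL) {
  rs_assert(file.exists(path), "io", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mapped_rxn_smiles", "yield_pct")
  rs_assert(all(need %in% names(df)), "schema",
            paste("raw CSV missing columns:",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  out <- list()
  for (r in seq_len(nrow(df))) {
    rec <- tryCatch({
      rxn <- df$mapped_rxn_smiles[r]
      parts <- strsplit(rxn, ">", fixed = TRUE)[[1]]
      tpl <- extract_template(rxn, radius = radius, check = FALSE)
      cands <- enumerate_candidates(tpl, parts[1])
      sel <- identify_selective(cands, parts[3])
      if (!sel$selective) NULL
      else reaction_record(parts[1], cands, sel$major_index,
                           yield_pct = df$yield_pct[r],
                           reaction_class = if (is.null(class_map)) "unknown"
                           else class_map(tpl$smarts))
    }, regiosel_error = function(e) NULL)
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  filter_yield(out, yield_threshold)
}
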