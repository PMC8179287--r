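# ReactionRecord data model and dataset CSV I/O.
#
# A record holds one atom-mapped reactant set (possibly multi-molecule,
# including the reagent), the enumerated candidate regio-isomeric outcomes
# (reacting atom-map pairs + product SMILES), the index of the recorded
# major outcome, an optional yield, and a reaction class label.

#' Construct a reaction record
#'
#' @param reactant_smiles atom-mapped SMILES of the full reactant set
#'   (`.`-separated molecules; map numbers unique across the set)
#' @param candidates list of candidate outcomes, each a list with `pair`
#'   (length-2 integer vector of reacting atom-map numbers) and
#'   `product_smiles`
#' @param major_index index into `candidates` of the recorded major outcome
#' @param yield_pct optional yield percentage in [0, 100]
#' @param reaction_class categorical class label
#' @param validate resolve map numbers against the parsed reactant set
#' @return a `reaction_record`
#' @export
reaction_record <- function(reactant_smiles, candidates, major_index,
                            yield_pct = NA_real_,
                            reaction_class = "unknown", validate = TRUE) {
  rs_assert(length(candidates) >= 1, "degenerate_record",
            "a record needs at least one candidate outcome")
  rs_assert(major_index >= 1 && major_index <= length(candidates), "index",
            "major_index out of range")
  rec <- structure(list(
    reactant_smiles = reactant_smiles,
    candidates = candidates,
    major_index = as.integer(major_index),
    yield_pct = as.numeric(yield_pct),
    reaction_class = reaction_class
  ), class = "reaction_record")
  if (validate) {
    g <- parse_mapped_smiles(reactant_smiles)
    maps <- g$atoms$map_number
    for (cc in candidates) {
      rs_assert(length(cc$pair) == 2 && all(cc$pair %in% maps),
                "unresolved_map",
                paste("candidate pair", paste(cc$pair, collapse = "-"),
                      "does not resolve to reactant atoms"))
    }
  }
  rec
}

#' @export
print.reaction_record <- function(x, ...) {
  cat("<reaction_record> ", x$reactant_smiles, "\n  ",
      length(x$candidates), " candidates, major = ", x$major_index,
      if (!is.na(x$yield_pct)) paste0(", yield = ", round(x$yield_pct, 1), "%"),
      " [", x$reaction_class, "]\n", sep = "")
  invisible(x)
}

#' Map number -> atom index lookup for a record's reactant set
#' @keywords internal
map_lookup <- function(g) {
  m <- g$atoms$map_number
  idx <- which(!is.na(m))
  stats::setNames(idx, m[idx])
}

#' Write reaction records to the dataset CSV schema
#'
#' Columns: `reaction_id`, `mapped_rxn_smiles` (reactant set only),
#' `candidate_pairs` (semicolon-separated `a-b` map pairs),
#' `candidate_products` (semicolon-separated SMILES), `major_index`
#' (1-based), `yield_pct`, `class`.
#'
#' @param records list of `reaction_record`
#' @param path output CSV path
#' @export
save_reaction_records <- function(records, path) {
  df <- data.frame(
    reaction_id = seq_along(records),
    mapped_rxn_smiles = vapply(records, function(r) r$reactant_smiles, character(1)),
    candidate_pairs = vapply(records, function(r) {
      paste(vapply(r$candidates,
                   function(cc) paste(cc$pair, collapse = "-"), character(1)),
            collapse = ";")
    }, character(1)),
    candidate_products = vapply(records, function(r) {
      paste(vapply(r$candidates, function(cc) cc$product_smiles, character(1)),
            collapse = ";")
    }, character(1)),
    major_index = vapply(records, function(r) r$major_index, integer(1)),
    yield_pct = vapply(records, function(r) r$yield_pct, numeric(1)),
    class = vapply(records, function(r) r$reaction_class, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read reaction records from the dataset CSV schema
#'
#' @param path input CSV path
#' @param require_selective reject single-candidate (degenerate) records
#' @param validate resolve candidate map pairs against the reactant sets
#' @return list of `reaction_record`
#' @export
load_reaction_records <- function(path, require_selective = FALSE,
                                  validate = TRUE) {
  rs_assert(file.exists(path), "io", paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mapped_rxn_smiles", "candidate_pairs", "candidate_products",
            "major_index")
  rs_assert(all(need %in% names(df)), "schema",
            paste("reaction CSV missing columns:",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  lapply(seq_len(nrow(df)), function(r) {
    pairs <- strsplit(df$candidate_pairs[r], ";", fixed = TRUE)[[1]]
    prods <- strsplit(df$candidate_products[r], ";", fixed = TRUE)[[1]]
    rs_assert(length(pairs) == length(prods), "schema",
              paste("row", r, ": pair/product count mismatch"))
    if (require_selective && length(pairs) < 2) {
      rs_abort("degenerate_record",
               paste("row", r, "has a single candidate"))
    }
    cands <- mapply(function(p, s) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      list(pair = ab, product_smiles = s)
    }, pairs, prods, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    reaction_record(
      df$mapped_rxn_smiles[r], cands, df$major_index[r],
      yield_pct = if ("yield_pct" %in% names(df)) df$yield_pct[r] else NA_real_,
      reaction_class = if ("class" %in% names(df)) df$class[r] else "unknown",
      validate = validate
    )
  })
}

#' Write per-candidate selectivity predictions to CSV
#'
#' Columns: `reaction_id`, `candidate_index`, `score`, `top1_index`.
#' @param scores list of numeric probability vectors, one per record
#' @param path output CSV path
#' @export
save_predictions <- function(scores, path) {
  rows <- do.call(rbind, lapply(seq_along(scores), function(r) {
    s <- scores[[r]]
    data.frame(reaction_id = r, candidate_index = seq_along(s),
               score = as.numeric(s), top1_index = which.max(s))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
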