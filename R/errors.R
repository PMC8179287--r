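#' Classed error conditions
#'
#' All errors raised by regiosel carry a condition class of the form
#' `regiosel_<type>_error` (plus `regiosel_error`), so callers can
#' discriminate programmatically with `tryCatch`.  The types in use are:
#' `parse` (invalid SMILES), `mapping` (duplicated atom-map numbers),
#' `schema` (malformed descriptor/reaction CSV), `alignment` (descriptor rows
#' do not match the molecule), `missing_descriptor`, `no_change`
#' (template extraction found no reacting core), `unmapped_product_atom`,
#' `no_match` (template does not apply), `empty_dataset`,
#' `degenerate_record` (single-candidate reaction), `insufficient_data`,
#' `unresolved_map`, `length_mismatch`, `nonfinite_loss`, `index`, and `io`.
#'
#' @param type short error type, e.g. "parse"
#' @param message human-readable message
#' @param data optional list attached to the condition
#' @return never returns; signals a condition
#' @keywords internal
rs_abort <- function(type, message, data = NULL) {
  cond <- structure(
    class = c(paste0("regiosel_", type, "_error"), "regiosel_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

#' @keywords internal
rs_assert <- function(ok, type, message) {
  if (!isTRUE(ok)) rs_abort(type, message)
  invisible(TRUE)
}
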