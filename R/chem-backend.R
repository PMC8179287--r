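# RDKit subprocess backend.  All cheminformatics primitives (SMILES parsing,
# canonicalization, template chemistry, scaffolds, fingerprints) go through a
# single bundled Python helper, batched per call and cached per SMILES so an
# interpreter start-up is paid once per batch, not once per molecule.

.chem_cache <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for cheminformatics
#'
#' The backend requires a Python with RDKit importable.  Resolution order:
#' option `regiosel.python`, environment variable `REGIOSEL_PYTHON`, then
#' `python` on the PATH.
#' @return path to the interpreter
#' @export
backend_python <- function() {
  p <- getOption("regiosel.python",
                 Sys.getenv("REGIOSEL_PYTHON", unset = ""))
  if (!nzchar(p)) p <- Sys.which("python")
  rs_assert(nzchar(p), "io", "no python interpreter found for the RDKit backend")
  p
}

backend_script <- function() {
  s <- system.file("python", "chem_backend.py", package = "regiosel")
  rs_assert(nzchar(s), "io", "chem_backend.py not found in installed package")
  s
}

#' Low-level call into the RDKit backend
#' @param op backend operation name
#' @param payload named list, JSON-serialized as the request body
#' @return parsed JSON response (nested lists)
#' @keywords internal
chem_call <- function(op, payload = list()) {
  req <- c(list(op = op), payload)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  jsonlite::write_json(req, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    backend_python(), shQuote(backend_script()),
    stdin = infile, stdout = outfile, stderr = errfile))
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(errfile, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    rs_abort("io", paste0("chemistry backend failed (op=", op, "): ", msg))
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# Vectorized, cached per-SMILES op. fn(batch) must return a list parallel to batch.
chem_cached <- function(prefix, keys, fn) {
  if (length(keys) == 0) return(list())
  ck <- paste0(prefix, ":", keys)
  missing <- !vapply(ck, exists, logical(1), envir = .chem_cache)
  if (any(missing)) {
    got <- fn(keys[missing])
    mk <- ck[missing]
    for (i in seq_along(mk)) assign(mk[i], got[[i]], envir = .chem_cache)
  }
  lapply(ck, get, envir = .chem_cache)
}

#' Clear the cheminformatics backend cache
#' @export
clear_chem_cache <- function() {
  rm(list = ls(.chem_cache), envir = .chem_cache)
  invisible(NULL)
}

#' Prefetch parses for a batch of SMILES
#'
#' Parsing goes through the Python backend; one call per molecule would pay
#' one interpreter start-up each.  Pipeline entry points call this on the
#' full SMILES vector so subsequent per-molecule lookups hit the cache.
#' @param smiles character vector
#' @return invisibly, the number of newly parsed entries
#' @export
chem_prefetch <- function(smiles) {
  smiles <- unique(smiles[!is.na(smiles)])
  if (length(smiles)) invisible(chem_parse_raw(smiles))
  invisible(length(smiles))
}

chem_parse_raw <- function(smiles) {
  chem_cached("parse", smiles, function(s) {
    chem_call("parse", list(smiles = as.list(s)))
  })
}

#' Canonical SMILES (atom maps stripped)
#' @param smiles character vector
#' @return character vector; NA for unparseable input
#' @export
chem_canonical <- function(smiles) {
  out <- chem_cached("can", smiles, function(s) {
    chem_call("canonical", list(smiles = as.list(s)))
  })
  vapply(out, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Atom-mapped SMILES with map numbers in canonical atom order
#'
#' Canonicalizes the molecule and assigns map numbers `offset + 1 .. offset + n`
#' following the canonical atom order, so map number `offset + k` always refers
#' to storage position `k` of the descriptor tables.
#' @param smiles character vector
#' @param offset integer added to every map number
#' @return character vector of mapped SMILES
#' @export
chem_map_smiles <- function(smiles, offset = 0L) {
  out <- chem_call("map_smiles",
                   list(smiles = as.list(smiles), offset = offset))
  vapply(out, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

chem_scaffold_raw <- function(smiles) {
  out <- chem_cached("scaf", smiles, function(s) {
    chem_call("scaffold", list(smiles = as.list(s)))
  })
  vapply(out, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

chem_reaction_fp <- function(reactants, products, bits = 2048L, radius = 2L) {
  items <- mapply(function(r, p) list(reactants = r, product = p),
                  reactants, products, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  keys <- paste0(reactants, ">>", products, "#", bits, "#", radius)
  chem_cached("rfp", keys, function(k) {
    sel <- match(k, keys)
    chem_call("reaction_fp",
              list(reactions = items[sel], bits = bits, radius = radius))
  })
}
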