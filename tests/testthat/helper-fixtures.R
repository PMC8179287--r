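# Shared fixtures, memoized per test run (the chemistry backend caches
# parses per SMILES, so reuse across test files is nearly free).

fx_env <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (!exists(key, envir = fx_env)) assign(key, force(expr), envir = fx_env)
  get(key, envir = fx_env)
}

# small selective toy-reaction set + matching oracle descriptor table
fx_records <- function() {
  fx_memo("records", generate_selective_reactions(40, seed = 5))
}

fx_substrates <- function() {
  fx_memo("substrates", {
    unique(unlist(lapply(fx_records(), function(r) {
      chem_canonical(strsplit(r$reactant_smiles, ".", fixed = TRUE)[[1]])
    })))
  })
}

fx_table <- function() {
  fx_memo("table", oracle_table(unique(c(fx_substrates(),
                                         "Cc1ccccc1", "ClCl"))))
}

fx_molecules <- function() {
  fx_memo("molecules", generate_molecules(60, seed = 11))
}

# deterministic small "pinned" weights so hand-computed oracles and the
# implementation share exactly the same parameters
pin_array <- function(arr, scale = 0.05, phase = 0) {
  arr[] <- scale * sin(seq_along(arr) + phase)
  arr
}

pin_params <- function(params, scale = 0.05) {
  for (k in seq_along(params)) {
    params[[k]] <- pin_array(params[[k]], scale, phase = k)
  }
  params
}

# mapped toluene + Cl2 with ortho/meta/para chlorination candidates
fx_toluene_record <- function(major = 3L) {
  reaction_record(
    "[CH3:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1.[Cl:8][Cl:9]",
    list(
      list(pair = c(3L, 8L), product_smiles = "Cc1ccccc1Cl"),
      list(pair = c(4L, 8L), product_smiles = "Cc1cccc(Cl)c1"),
      list(pair = c(5L, 8L), product_smiles = "Cc1ccc(Cl)cc1")
    ),
    major_index = major, yield_pct = 80,
    reaction_class = "aromatic_CH_functionalization"
  )
}

# toy mapped chlorination reaction of toluene (para product recorded)
fx_toluene_rxn <- function() {
  paste0("[CH3:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1.[Cl:8][Cl:9]",
         ">>",
         "[CH3:1][c:2]1[cH:3][cH:4][c:5]([Cl:8])[cH:6][cH:7]1")
}

expect_all_equal <- function(x, tol = 1e-10) {
  expect_lt(max(x) - min(x), tol)
}
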