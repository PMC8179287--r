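Package: regiosel
Title: Regioselectivity Prediction with Learned Reaction Representations and
    On-the-Fly Quantum Mechanical Reactivity Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the regioselectivity of substitution
    reactions from atom-mapped reaction SMILES.  Implements a multitask
    directed-message-passing network that predicts six quantum-mechanical
    reactivity descriptors (atomic partial charge, electrophilic and
    nucleophilic condensed Fukui indices, NMR shielding constant, bond order
    and bond length) with an attention-based summation constraint that makes
    predicted charges and Fukui indices satisfy their molecular conservation
    sums exactly, and a Weisfeiler-Lehman selectivity network with global
    attention that fuses the learned reaction representation with
    radial-basis-expanded descriptors to rank candidate regio-isomeric
    products.  Also provides the reaction-curation pipeline (template
    extraction and re-application, selectivity identification, yield
    filtering, random cross-validation and greedy bin-packed scaffold
    splits) and a self-contained synthetic fixture generator (topology-based
    descriptor oracle and toy selective reactions) so every learning
    experiment runs without quantum-chemistry software or proprietary data.
    Cheminformatics primitives are delegated to RDKit through the system
    Python interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: Python (>= 3.8) with rdkit, available as 'python' on the
    PATH (override via option 'regiosel.python').
Config/testthat/edition: 3
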