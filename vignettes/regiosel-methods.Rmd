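---
title: "Models and methods in regiosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in regiosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many substitution reactions can, in principle, occur at several sites of a
substrate: an electrophile attacking toluene may end up ortho, meta, or
para to the methyl group.  regiosel predicts which candidate regio-isomeric
outcome is the major one, given only an atom-mapped reaction SMILES.  The
package couples two networks:

1. a **selectivity network** that scores every enumerated candidate outcome
   of a reaction and normalizes the scores to probabilities with a softmax
   across the candidate set, and
2. a **multitask descriptor network** that predicts, from the 2D molecular
   graph alone, the six quantum-mechanical reactivity descriptors the
   selectivity network can fuse with its learned representation: atomic
   partial charge (e), electrophilic and nucleophilic condensed Fukui
   indices (e), isotropic NMR shielding (ppm), bond order (dimensionless),
   and bond length (Å).

Because descriptor databases from DFT pipelines and mined reaction corpora
are expensive or proprietary, the package also ships a fully synthetic
fixture world (a topology-based descriptor oracle and a toy reaction
generator) in which every learning claim made by the test suite can be
verified against a known ground truth.

## The selectivity network

Reactant molecules — substrate and reagent together — are parsed into one
heavy-atom graph per reaction.  Atoms carry discrete features (one-hot
element over C, O, N, P, S, F, Cl, Br, I, Si, B plus an "other" bucket;
one-hot degree 0–4, valence 0–6, hydrogen count 0–4; an aromaticity flag:
30 slots total; the exact one-hot budgets are implementation constants
documented in `atom_features()`).  Bonds carry either discrete features
(one-hot type + ring flag, the `GNN` baseline) or, in the QM modes, the
radial-basis expansion of bond order and bond length.

A Weisfeiler–Lehman encoder updates atom states for `L` rounds (default
`L = 2`, hidden width `H = 32`):

    h_u^{l+1} = ReLU( W_s h_u^l + Σ_{v∈N(u)} ReLU(W_n h_v^l + W_e e_uv + b_n) + b_s )

A scaled dot-product **global attention** layer then lets every atom attend
over all atoms of all reactant molecules — this is what carries
substrate–reagent and long-range (> L bonds) information — and the local
state plus attention context forms the learned atomic embedding.  In the
QM-fused modes the embedding is concatenated with the RBF expansions of the
four atomic descriptors in the fixed channel order charge, electrophilic
Fukui, nucleophilic Fukui, NMR shielding.  Each descriptor channel uses the
same expansion dimension (default 8), so the concatenated QM block
(4 × 8 = 32) matches the learned embedding width and neither information
source dominates by construction.

For each candidate outcome, the fused representations of the two reacting
atoms (resolved through their atom-map numbers) are sum-pooled, passed
through a feed-forward scorer whose penultimate layer (default width 32) is
the latent reaction vector exposed by `extract_latent()`, and the resulting
scores are softmax-normalized across the record's candidate set.  Training
minimizes the cross-entropy of this softmax against the recorded major
outcome — the model learns to *rank* outcomes relative to their
alternatives, not to score reactions absolutely.  Top-1 ties break toward
the lowest candidate index, deterministically.

Five modes share this module:

* `GNN` — graph only; never reads a descriptor source (enforced, and
  verified by a poisoned-table test);
* `QM-GNN` — descriptors from an external table;
* `ml-QM-GNN` — descriptors predicted on the fly by the multitask network,
  cached per canonical SMILES so repeated reactants cost one inference;
* `QM` — descriptor-only FFNN over the pooled RBF blocks of the two
  reacting atoms; never runs the graph encoder;
* `FP` — a signed Morgan difference reaction fingerprint (2048 bits,
  radius 2) scored by an FFNN.

## The constrained multitask descriptor network

A directed message-passing encoder (messages on directed edges, `T = 3`
rounds, width 32) feeds one readout head per descriptor channel.  Channels
with a physical conservation law are corrected by an attention constraint:
a learnable query vector `u` scores each atom's hidden state `a_i`
(dot-product similarity by default; cosine available by configuration), a
softmax turns the scores into weights `w_i`, and

    q_i_final = q_i + w_i (Q − Σ_j q_j)

spreads the excess between the target molecular sum `Q` and the raw head
outputs over the atoms.  `Q` is the net formal charge for the charge
channel and 1 for either Fukui channel; shielding, bond order and bond
length are unconstrained.  The constraint is linear, differentiable, and
applied during training (end-to-end), so the sums hold to machine precision
for trained and untrained weights alike — the acceptance suite checks this
on 100 random-weight molecules at 1e-6.

Charged species are rejected at prediction time: computing Fukui indices
requires electronic-structure information for ionized states that a model
trained on neutral molecules does not carry.  Hydrogens are folded into a
heavy-atom count feature; all channels are predicted for heavy atoms only.

Training details: per-channel squared losses are standardized by the
training-set target scale so ppm-scale shielding cannot dominate e-scale
charges; bond heads consume the sum of the two directed-edge hidden states
of each bond (a symmetric readout); optimization is Adam (default learning
rate 5e-3, minibatch 16 molecules, 30 epochs) with the best-on-validation
model returned; every stochastic step derives from a single recorded seed.
All gradients are hand-derived reverse-mode and are verified against
central finite differences in the test suite for every parameter tensor of
every mode.

## Synthetic fixtures: what they emulate and what they do not

`generate_molecules()` draws substituted aromatics from a fragment grammar
(benzene, pyridine, pyrimidine, thiophene, naphthalene, quinoline and
biphenyl cores with 1–3 substituents from a fixed donor/acceptor set) plus
short heteroatom chains, deduplicated by canonical SMILES.

`oracle_descriptors()` assigns descriptors by small, interpretable topology
rules: charges follow summed electronegativity differences to neighbours
(re-centred to the exact molecular sum); the mock Fukui indices are
softmax-normalized site activities peaked at bond distances 2 and 4 from
donor substituents (nucleophilic channel) or withdrawing groups
(electrophilic channel), echoing ortho/para direction; shielding, bond
order and bond length are element/bond-type baselines with local
corrections.  Default per-channel noise (charge 0.02 e, Fukui 0.01,
shielding 5 ppm, bond order 0.02, bond length 0.01 Å) is added *before*
the conservation renormalization, so the constrained sums stay exact.  The
charge noise of 0.02 e sets the recovery floor for the parameter-recovery
experiment: a perfect model would reach a held-out MAE of
σ·√(2/π) ≈ 0.016 e, and the acceptance bound is 2σ = 0.04 e.

`generate_selective_reactions()` builds toy electrophilic aromatic
chlorinations (substrate + Cl₂) by applying a C–H substitution template at
every symmetry-distinct aromatic site; the major site is the argmax of
`fukui_nuc(site) − 0.015 · steric(site)` evaluated on noise-free oracle
descriptors, where the steric penalty counts heavy atoms within two bonds
(purely topological, no 3D).  The steric weight of 0.015 makes sterics a
secondary but real effect next to typical Fukui contrasts of 0.05–0.15.
A substrate only yields a record when the preferred site beats the
runner-up by at least `min_margin` (default 0.01, the oracle's Fukui noise
scale): below that margin the argmax label is numerically fragile rather
than a stable function of the descriptors — the toy analogue of an
ambiguous product mixture that yield-based curation would exclude.
An optional label-noise probability flips the major label to a random
*minor* candidate, so the accuracy ceiling of the true rule is exactly
1 − p.  Substrate map numbers follow canonical atom order, making map k the
k-th descriptor-table row.

These fixtures are deliberately *not* chemically realistic: descriptor
magnitudes only loosely resemble DFT values, and the selectivity rule is a
known function of topology.  Passing tests therefore demonstrate that the
architecture can represent and recover descriptor-mediated selectivity and
that every contract (conservation, alignment, determinism) holds — they do
not certify accuracy on real reaction corpora, which require externally
computed descriptor tables and mined, atom-mapped reactions.

## Curation and splitting

Templates are extracted from fully product-mapped reactions by detecting
atoms whose mapped bonding or hydrogen count changes, growing the core by a
configurable bond radius (the radius is exposed because no single value
suits every corpus), and emitting a reaction-SMARTS rule with explicit
hydrogen counts.  The module contract is the self-application invariant:
re-applying a rule to its own reactants must regenerate the recorded
product.  Candidate enumeration deduplicates outcomes by canonical product
SMILES so symmetry-equivalent sites collapse; a reaction is selective when
at least two candidates remain and the recorded product matches exactly
one.  Records below a 50% yield threshold are excluded, and records with
*missing* yields are dropped too — without a yield one cannot be confident
the reported product is the major outcome rather than merely the desired
one.

The scaffold split groups records by the generic Murcko framework (ring
systems plus linkers, atoms and bonds made generic) of the largest
aromatic-ring-containing reactant and assigns scaffold groups largest-first
to the proportionally most-underfilled partition (targets 80:10:10), with
lexicographic tie-breaks recorded in the split manifest.  When one scaffold
dominates, the achieved ratios deviate from the target; this is reported,
never an error.  Random cross-validation uses disjoint fixed-size test
folds with optional training-set downsampling drawn with the fold seed, so
test membership is identical across downsampling levels.

## Numerical choices and limitations

* RBF grids: charge [−1, 1] e, Fukui [0, 1], shielding [0, 400] ppm, bond
  order [0.5, 3.2], bond length [0.9, 2.2] Å, width `γ = 1/Δ²` for grid
  spacing Δ; values outside a grid decay smoothly, they do not error.
* Externally computed tables may violate conservation up to 1e-2 and can be
  renormalized on request; model and oracle tables are validated at 1e-6.
* Degenerate inputs: single-atom molecules are legal everywhere (the
  constraint then forces the whole correction onto one atom);
  single-candidate records are legal for scoring (probability 1) but are
  rejected for training, where ranking needs at least two outcomes.
* Checkpoints are plain JSON (manifest + weight arrays), so restored models
  reproduce scores to double precision.
* The experiment sizes used by the automated checks — 500 training
  molecules for descriptor recovery, 700 toy reactions (560 train) for
  selectivity recovery, 200-record training sets for the small-data
  contrast, 3 seeds for seed-averaged comparisons — are chosen as the
  smallest sets on which the recovered quantities are stable; all are
  regenerated from seeds at run time.
* Known limitations: no stereochemistry, no charged or open-shell species,
  no 3D/conformer information, heavy-atom graphs only, and the fingerprint
  baseline folds hashed Morgan counts, so rare collisions are possible.

## Reproducibility

Every training function takes an integer seed that controls
initialization, shuffling, and downsampling; fixture generation derives
per-molecule noise streams from the seed and the canonical SMILES, so
tables are identical regardless of generation order.  Command-layer runs
write a JSON manifest with the full configuration, package version and
seeds next to their artifacts.
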