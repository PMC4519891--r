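---
title: "Multi-objective lattice folding: model, operators and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective lattice folding: model, operators and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccfold)
```

## The model

`fccfold` predicts coarse-grained protein structure ab initio: the chain is
a Cα-only self-avoiding walk (SAW) on the 3-D face-centered cubic lattice,
whose 12-neighbour geometry is the best discrete approximation of real Cα
backbones. A conformation is equivalently a string of direction labels 1–12
(`fcc_directions()`) or an integer coordinate matrix; `decode_moves()`
converts one into the other and enforces self-avoidance. Multiplying the
lattice coordinates by 3.8/√2 (`scale_coordinates()`) sets the consecutive
Cα–Cα distance to 3.8 Å, the mean spacing in real backbones.

Two kinds of objective are minimized:

* **Contact energies.** `hp_energy()` counts −1 for every
  hydrophobic–hydrophobic lattice contact (squared distance 2, chain
  separation ≥ 2), with the hydrophobic class {C, F, I, L, M, V, W, Y}.
  `cp_energy()` generalizes this to any symmetric 20×20 contact potential;
  no specific published matrix is bundled because these potentials exist in
  several variants — the function accepts whichever table the user trusts,
  validated for symmetry on load.
* **Backbone angle preferences.** At residue *i*, κ is the bend angle of
  the Cα atoms of residues *i*−2, *i*, *i*+2 (0–180°), and α is the signed
  dihedral of residues *i*−1, *i*, *i*+1, *i*+2 (−180°, 180°]. A chain of
  *n* residues defines max(0, *n*−4) pairs (indices 3 … *n*−2, 1-based).
  Each pair is binned into the packaged 13×6 preference matrix
  (`ka_preferences()`), and `ka_energy()` returns minus the summed
  preferences, so that — like the contact terms — lower means better.

Compact globules maximize contacts but realize backbone bends real proteins
never use. The multi-objective modes therefore minimize
(E^HP, K^KA) jointly, and additionally impose a hard feasibility rule
(`check_angle_constraint()`): a conformation containing any (κ, α) pair
that is geometrically degenerate or bins to a zero-preference cell is
discarded outright.

## The discrete angle spaces of the lattice

`enumerate_angle_pairs()` exhaustively generates all self-avoiding 5-point
fragments (first point at the origin, first move fixed — the lattice point
group makes the realized angle set independent of that choice) and computes
(κ, α) at the center residue, excluding colinear degenerate fragments. The
realized κ values span exactly 30° to 150°; straight fragments (κ = 0° or
180°) exist geometrically but are treated as degenerate and infeasible,
which is what makes the 30–150° range exact.

The realized α values form six *magnitude* classes — 0°, 54.7°, 70.5°,
109.5°, 125.3°, 180° — each appearing with both signs because the lattice
point group contains reflections, so every chiral fragment coexists with
its mirror image. `angle_spaces()` therefore reports clusters of |α|. The
preference matrix distinguishes six α columns, labelled 60°, 80°, 180°,
−130°, −110°, −10°; these labels are carried over from the DSSP-space
statistics the matrix was derived from (real proteins, being chiral, favour
one sign per class), and correspond one column per lattice magnitude class.

### Binning conventions

* κ is rounded to the nearest 10° center; values rounding below 30° or
  above 150° are unbinnable, score zero, and violate the constraint.
* α is assigned to the nearest of the six column centers by circular
  distance on the signed value. On-lattice α values fall far from bin
  boundaries, so the assignment is unambiguous; the one consequence worth
  knowing is that the mirror image of a conformation can score differently,
  which mirrors (deliberately) the chirality of the underlying statistics.
* The 30° preference row is all zero, so the sharpest realizable lattice
  bend is always infeasible.
* Degenerate fragments (colinear triples → undefined α; κ at exactly 0° or
  180°) contribute nothing to `ka_energy()` and fail the constraint.

## Search engines

All four engines (`fold()` modes `ga-hp`, `ga-cp`, `nsga`, `nsga2`) share
the reproduction pipeline: binary tournament parent selection; with
probability *P*~c~ a rotation-based crossover; one improving pull move of
local search per offspring (accepted only if it lowers the primary contact
energy, otherwise reverted); K-site mutation with probability *P*~m~; then
elitist survival over the merged parent+offspring pool — by energy in the
single-objective modes, by dominance rank (NSGA) or rank then crowding
distance (NSGA-II) in the multi-objective modes. Defaults follow the study
conditions (`fold_config()`): population = sequence length, generations =
2 × length, *P*~c~ = 0.85, *P*~m~ = 1/length, K = 3.

Design choices that were genuinely open:

* **Crossover.** The operator splits at a random point G, keeps parent 1's
  head, and re-attaches parent 2's tail as a rigid body under each of 17
  lattice rotations about G: 9 square-based (coordinate axes × 90°, 180°,
  270°) and 8 triangle-hexagon-based (the four body-diagonal 3-fold axes ×
  120°, 240° — the unique axis family with 2π/3 symmetry on this lattice).
  Rotating the re-attachment is what lifts the success rate of one-point
  crossover on a rigid chain: most junctions collide, but rarely under all
  17 orientations. All collision-free (and, in the multi-objective modes,
  angle-feasible) offspring enter the pool; survival prunes.
* **Pull move.** The textbook pull move relocates residue *i*+1 to a free
  neighbour of residue *i* and drags the tail along. We restrict candidates
  to free *common* neighbours of *i* and the old *i*+1 whenever a successor
  exists: the shifted tail then re-uses previously occupied sites, so every
  accepted pull is provably a valid SAW without a rejection loop. When no
  candidate passes, the conformation is returned unchanged (liveness).
* **Mutation.** K consecutive move labels are redrawn and the chain
  re-decoded; invalid mutants are redrawn up to a bound, then the parent is
  kept. The small window (K = 3) keeps changes local.
* **Constraint handling.** Multi-objective offspring are checked at the
  source (each operator takes a validity predicate) and infeasible products
  are discarded with bounded retries; parents always remain candidates for
  survival, so the population can never empty. Initial populations come
  from `random_feasible_saw()`, a backtracking generator that enforces the
  angle constraint incrementally while growing the walk; if its budget is
  exhausted the individual is admitted infeasible, flagged, and ranked
  after every feasible front.
* **NSGA.** The original NSGA used fitness sharing with a niche radius; we
  use pure dominance-rank survival with random truncation of the split
  front. This is documented as a deviation — the niche radius adds a
  parameter the rest of the design never needs, and NSGA-II's crowding
  provides the diversity mechanism where it matters.
* **Population size** counts residues, not moves.
* **Tie-breaks.** Survival truncation shuffles before sorting so index ties
  are RNG-driven; all randomness flows from the single `set.seed(seed)` at
  the start of `fold()`, making runs byte-for-byte reproducible.

## Structure comparison

`drmsd()` implements the distance-matrix RMSD: the root mean squared
difference of all C(n, 2) pairwise Cα distances. It needs no superposition
and is invariant under rigid motions *and* reflections. Superposition
(Kabsch) RMSD is intentionally not offered, to avoid mixing two metrics
with the same name. References are compared as raw Cα coordinates; no
lattice fitting of the native is performed.

## What the synthetic data does and does not emulate

Tests and examples run on random 20-letter sequences and random SAWs
(`random_saw()`, a grow-with-restart generator — simple and adequate for
fixtures, though for long chains it mildly over-samples compact walks
relative to the uniform SAW distribution). Synthetic sequences have i.i.d.
residue composition; real proteins have correlated hydrophobicity patterns,
secondary-structure propensities, and native structures to compare against.
Passing tests therefore demonstrate the *mechanics* — legality of every
operator product, exactness of the energies and angles, dominance-correct
survival, reproducibility, and that the multi-objective engine reaches far
better angle-preference energies than the contact-only GA on matched seeds
— not predictive accuracy on real proteins, which requires benchmark
sequences and native Cα coordinates supplied as FASTA/PDB inputs (the
packaged 75-entry identifier list tells you which chains to fetch).

Problem sizes used by the test suite: exhaustive enumeration at fragment
length 5 (1728 walks); operator property tests at chain lengths 6–45 with
hundreds to a thousand repetitions; full engine runs at lengths 10–14 for
unit tests, and ten paired GA-HP / NSGA-II runs at length 20 under the
study conditions (population 20, 40 generations) for the comparative
check. These sizes were chosen to exercise every code path at
minute-scale runtimes on a single core.

## Known limitations

* The contact-potential objective is only as good as the supplied matrix;
  none is bundled.
* The angle preference matrix is packaged data; the pipeline that derived
  it from experimentally solved, low-redundancy structures via DSSP is out
  of scope here and cannot be regenerated from this package.
* Runtime grows steeply with chain length (lattice folding is NP-hard);
  lengths beyond ~90 residues are outside the intended regime.
* dRMSD compares same-length chains only; no sequence-structure alignment
  is attempted.
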