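# fccfold

Ab initio protein structure prediction on the 3-D face-centered cubic (FCC)
lattice, optimized as a **multi-objective** problem: a contact-based free
energy *and* an empirical backbone angle preference term, searched with
NSGA / NSGA-II.

## The problem and the model

Predicting a protein's tertiary structure from sequence alone is
computationally intractable at atomic detail, so lattice models coarse-grain
the chain to its Cα trace. On the FCC lattice — the lattice that best fits
real Cα backbones — every residue occupies an integer point with 12
neighbours at squared distance 2, and a conformation is a self-avoiding walk
(SAW) encoded as a string over the 12 direction labels.

Three fitness functions drive the search (all minimized):

- **E<sup>HP</sup>** — the hydrophobic-polar contact energy: −1 per lattice
  contact (squared distance 2, chain separation ≥ 2) between two hydrophobic
  residues (C, F, I, L, M, V, W, Y);
- **E<sup>CP</sup>** — a general contact-potential energy: each contact
  weighted by a user-supplied symmetric 20×20 statistical potential
  (Berrera- or Miyazawa–Jernigan-style);
- **K<sup>KA</sup>** — the backbone angle preference energy: for every
  residue *i* the virtual bend angle κ (Cα of *i*−2, *i*, *i*+2) and the
  virtual dihedral α (Cα of *i*−1 … *i*+2) are binned into a packaged 13×6
  empirical preference matrix, and K<sup>KA</sup> = −Σ preferences.

Pure contact optimization collapses chains into maximally compact globules
with backbone geometry no real protein has. The multi-objective engines
minimize (E<sup>HP</sup>, K<sup>KA</sup>) jointly under a hard feasibility
rule (the FCC′ constraint): any conformation containing a (κ, α) pair with
zero empirical preference — or degenerate colinear geometry — is discarded.
Search uses rotation-based crossover (one-point crossover with the tail
re-attached under each of 17 lattice rotations: 9 square-based + 8
triangle-hexagon-based), a generalized pull-move local search, K-site
mutation, binary tournaments, and elitist survival by dominance rank (NSGA)
or rank + crowding distance (NSGA-II). Predictions are compared to
references by distance-matrix RMSD over all pairwise Cα distances, with the
lattice step scaled to 3.8 Å.

## Worked example

```r
library(fccfold)
seq <- "CFCPPCFCPPCFCPPCFCPP"          # 20 residues, 8 hydrophobic
run <- fold(seq, mode = "nsga2", seed = 1)

length(run$front)                       # 20 (front members, with duplicates)
unique(run$front_objectives)
#>       energy      ka
#>  [1,]    -20  -27.83
#>  [2,]     -2 -180.42
#>  ...
#> [12,]    -19  -29.47

best <- run$front[[which.min(run$front_objectives[, "energy"])]]
hp_energy(best)                         # -20
ka_energy(best)                         # -27.83
```

The final Pareto front trades contact energy against angle realism: one end
reaches E<sup>HP</sup> = −20 (a compact hydrophobic core, modest angle
score), the other K<sup>KA</sup> = −180.42 (near-ideal backbone angles, few
contacts). Every front member is a valid SAW satisfying the angle
constraint. `write_ca_pdb(best, "best.pdb")` exports the scaled Cα trace;
`drmsd(scale_coordinates(best), ref_coords)` scores it against a reference
in Å.

A command-line front end is included:

```sh
Rscript inst/cli/fccfold.R predict --fasta in.fasta --mode nsga2 --seed 1 --out outdir
Rscript inst/cli/fccfold.R evaluate --model outdir/id.pdb --ref native.pdb
Rscript inst/cli/fccfold.R enumerate-angles
Rscript inst/cli/fccfold.R fixtures --n 20 --count 10 --seed 1
```

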