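# disofold

Order/disorder assignment for protein structure ensembles by free-energy
minimization.

## The problem

Structure prediction pipelines search for the lowest-*energy* conformation,
but the native state of a protein minimizes the *free energy*. The
difference matters most for proteins with intrinsically disordered regions
— flexible terminal tails and internal loops that never adopt a single
conformation. Scored by energy alone, such regions are either packed
artifactually against the folded core (they have nothing to lose by making
spurious contacts) or they drag the ranking of otherwise good models.

`disofold` implements two complementary treatments for users analysing
decoy sets or NMR-style multi-model ensembles:

1. **Free-energy assignment.** Every residue is either fully ordered or
   fully disordered. Ordered residues contribute their pairwise interaction
   energy with all other ordered residues; disordered residues trade that
   energy for configurational entropy. For an assignment with disordered
   terminal runs ("tails") and internal runs ("loops") of length *L*,

   *F* = *E* − Σ<sub>tail residues</sub> *E*<sub>d</sub> −
   Σ<sub>loops</sub> *β*·ln(*L*/*L*<sub>0</sub>)

   with defaults *E*<sub>d</sub> = 2.0, *β* = 1.5, *L*<sub>0</sub> = 0.3
   (temperature absorbed into the parameters). The lowest-*F* assignment is
   found by exhaustive enumeration of the two terminal tails, or by a
   greedy search that flips four consecutive residues at a time for
   internal loops (at least four residues long). Aggregating the optimal
   assignments over an ensemble gives a per-residue disorder-frequency
   profile, scored against reference disorder by the mean per-residue
   probability of the correct state (1.0 = perfect), with the all-ordered
   null model as baseline.

2. **Repulsive-only re-scoring.** When disorder is known in advance (a
   sequence-based predictor, NMR order parameters), the designated residues
   are reduced to minimal-radius glycine-like centers that contribute only
   steric repulsion: they cannot buy energy by intercalating into the core,
   and clash-free conformations of the disordered segments leave the score
   untouched. Models are then compared by core RMSD and core GDT-TS —
   computed over the folded part only.

Interaction energies come from a coarse 12-6 pair potential on per-residue
interaction centers (side-chain centroid, Cα for glycine) with an
attractive/repulsive split; externally computed pair tables can be injected
in its place. A seeded synthetic-decoy generator plants ground-truth tails,
loops, and "collapsed" segments packed against the core, so every claim is
testable without downloads.

## Worked example

```r
library(disofold)

# a 40-residue core with a 10-residue disordered N-tail, 8 decoys
g <- generate_ensemble(synthetic_spec(n_core = 40, n_tail_n = 10,
                                      n_models = 8, seed = 11))
prof <- profile_ensemble(g$ensemble, fe_params(), mode = "terminal")
head(tidy(prof), 12)
#> # A tibble: 12 × 3
#>    residue aa    freq_disordered
#>      <int> <chr>           <dbl>
#>  1       1 G               1
#>  2       2 G               1
#>  3       3 G               1
#>  4       4 G               1
#>  5       5 G               1
#>  6       6 G               1
#>  7       7 G               1
#>  8       8 G               1
#>  9       9 G               1
#> 10      10 G               1
#> 11      11 A               0
#> 12      12 A               0

ref <- reference_from_mask(which(g$ground_truth), n_residues(g$native))
accuracy_score(prof, ref)$score        # 1
null_model_score(ref)$score       # 0.8
glance(prof$assignments[[1]])
#> # A tibble: 1 × 7
#>       E tail_term loop_term     F n_disordered n_tail c_tail
#>   <dbl>     <dbl>     <dbl> <dbl>        <int>  <int>  <int>
#> 1 -132.        20         0 -152.           10     10  0
```

On this fixture the planted tail is flagged in every model (frequency 1)
with no over-call into the core, so the accuracy score of 1.0 beats the
all-ordered null (0.80); on harder seeds the boundary residue is
occasionally mis-called. `autoplot(prof, ref)` draws the
profile against the reference; `autoplot(compensation_curve(...))` shows
how entropy credit and retained energy trade off along a greedy
trajectory.

The command-line entry point wraps the same functions:

```sh
Rscript exec/disofold simulate --seed 11 --n-core 40 --tail-n 10 --out fix
Rscript exec/disofold assign --ensemble fix.pdb --mode terminal --out fix
Rscript exec/disofold score --ensemble fix.pdb --native fix.native.pdb \
    --mask fix.mask --replonly --out fix
```

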