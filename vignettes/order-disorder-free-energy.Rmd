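---
title: "Assigning order and disorder to structure ensembles by free-energy minimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning order and disorder to structure ensembles by free-energy minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disofold)
```

## The model

`disofold` treats each residue of a structure model as either fully
ordered or fully disordered. An ordered residue contributes the sum of its
pairwise interaction energies with all other ordered residues and no
entropy; a disordered residue contributes no interaction energy and earns
an entropy credit whose form depends on topology:

* a **tail** — a maximal disordered run that includes the first or last
  residue — earns $E_d$ *per residue* (a free chain end explores
  conformations independently residue by residue);
* an internal **loop** of length $L$, pinned at both ends by ordered
  flanks, earns $\beta \ln(L / L_0)$ *per loop* (closed-loop entropy grows
  only logarithmically with length).

The free energy of an assignment is then

$$ F \;=\; E \;-\; \sum_{\text{tail residues}} E_d \;-\;
   \sum_{\text{loops}} \beta \ln (L / L_0), $$

and the assignment reported for a model is the one minimizing $F$.
Temperature is not an independent quantity anywhere in the package: it is
absorbed into $E_d$ and $\beta$, which are expressed directly in the
energy units of the interaction matrix.

A residue is therefore called disordered exactly when its entropy credit
outweighs the attractive interactions it must give up — the physically
intuitive criterion for intrinsic disorder in a native state.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `E_d` | 2.0 | energy | per-residue tail credit; larger values peel longer tails |
| `beta` | 1.5 | energy | loop-entropy scale |
| `L0` | 0.3 | residues | loop-entropy reference length; must satisfy $L/L_0 > 1$ |
| `min_loop_len` | 4 | residues | shortest admissible internal disordered run |
| `block` | 4 | residues | flip granularity of the greedy search |
| `max_stretches` | 2 | — | disordered stretches allowed in terminal enumeration (one per terminus) |

The defaults are the fitted operating point of the published
parameterization of this free-energy form; scanning $E_d$ over a grid
(`scan_parameters()`) on planted benchmarks reproduces the qualitative
behavior that under-crediting tails ($E_d = 1.4$) under-calls disorder
while 2.0–2.6 recover planted tails. Note the scaling covariance: scaling
the interaction matrix together with $E_d$ and $\beta$ by a common factor
rescales every $F$ without changing any argmin, so only the *ratio* of
energy scale to entropy credits is meaningful.

### Loop entropy is per loop, tail entropy per residue

The two entropy forms are deliberately different. Tail credit is linear in
length (each released residue adds the same configurational freedom), and
is applied per disordered terminal residue. Loop credit depends only on
the loop's length through $\ln(L/L_0)$ and is applied once per loop:
doubling a loop adds $\beta\ln 2$, not another full credit. A run touching
position 1 or $N$ is always classified as a tail, even when it grew from
an internal flip that later merged with a terminus.

## The two searches

**Terminal enumeration** (`enumerate_terminal()`) considers every pair of
tail lengths $(a, b)$ with $a + b < n$ — the restriction to at most two
disordered stretches, one per terminus, is what makes exhaustive
enumeration affordable. Full disorder is excluded: the model always
retains a folded core, and the energy of an empty ordered set is
degenerate.

**Greedy internal search** (`greedy_internal()`) starts all-ordered and
repeatedly flips the best window of `block` consecutive currently-ordered
residues, at any offset, until no flip lowers $F$. Windows adjacent to an
existing disordered run merge with it, and a merged run touching a
terminus is re-scored as a tail. Three design choices keep the procedure
deterministic and well-defined:

* *best-improvement*, not first-improvement, is committed each round;
* only order→disorder flips are allowed — no backtracking;
* ties are broken toward lower $F$, then fewer disordered residues, then
  the leftmost window.

The same tie cascade, generalized to "lexicographically greatest ordered
vector" (equivalently: the smaller N-terminal tail), governs
`enumerate_terminal()` and the test oracle `exhaustive_search()`, so all
three searches are comparable state by state.

`exhaustive_search()` enumerates every topology-valid assignment (internal
runs at least `min_loop_len`, at least one ordered residue) by composing
runs recursively rather than filtering $2^n$ masks — for $n = 20$ and
`min_loop_len = 4` the valid space has 8,770 assignments, which makes
oracle equivalence testable at realistic sizes. Greedy is an upper bound
on the optimum by construction; it attains it on planted single-loop
instances whose loop length is a multiple of `block`, and the test suite
asserts exactly that (a planted loop of length 5 is recovered only to
block granularity — this is a property of the published search procedure,
not a defect).

## The energy backend

Pairwise energies come from a 12-6 potential
$\varepsilon[(\sigma/r)^{12} - 2(\sigma/r)^6]$ on per-residue interaction
centers (side-chain heavy-atom centroid; C$\alpha$ for glycine), with
$\sigma$ the sum of two per-residue radii (GLY 2.0 Å … TRP 3.4 Å), split
into an attractive channel ($\le 0$) and a repulsive channel ($\ge 0$,
capped at `rep_cap = 10` so the $r \to 0$ singularity cannot destabilize a
search), zero beyond 12 Å and for bonded neighbors $|i-j| \le 1$. The well
depth defaults to $\varepsilon = 3$, chosen once so that a residue in a
compact core (first-shell contacts near $\sigma$, coordination ≈ 4–8)
retains interaction energy comfortably above the tail credit $E_d = 2$,
while a solvent-separated tail residue (contacts ≳ 5.5 Å) stays below it —
the regime in which the fitted entropy parameters are meaningful. With a
unit well depth the coarse potential is too shallow for *any* compact
C$\alpha$-only geometry to hold its core at $E_d = 2$, and the searches
peel entire chains.

The backend is intentionally replaceable: `load_interaction_matrix()`
accepts plain-text pair tables (`i j e_attr e_rep`), so energies from a
full molecular-mechanics scoring function can drive every downstream
operation unchanged. Hydrogen-bond and solvation terms are not modeled
separately; the attractive channel stands for all favorable contributions,
which keeps the masking decomposition below exact.

## Repulsive-only masking

`masked_energy()` scores pairs touching a designated residue set by their
repulsive channel only — including masked–masked pairs, so disordered
segments cannot stabilize each other either. The decomposition identity

> masked energy = full energy − (attractive energy of every pair touching
> the mask)

holds exactly and is property-tested. `masked_energy_reduced()`
additionally moves masked residues to their C$\alpha$ and the smallest
radius in the set before computing their pair terms, mimicking reduction
to a minimal glycine-like sphere. The operational consequence — and the
core of the second approach — is *conformational independence*: for
clash-free conformations of the masked segments the score depends only on
the unmasked coordinates, so a model is no longer rewarded for packing its
disordered tail against the core. One open modeling question is whether
masked residues should still pay intra-residue or backbone-torsion
penalties; this implementation has no such terms, so the answer here is no.

## Reference disorder, scoring, and core metrics

`reference_from_ensemble()` derives reference disorder from an NMR-style
ensemble: models are superposed onto the medoid model (smallest summed
all-C$\alpha$ RMSD to the rest) and each residue's root-mean-square
deviation from its mean position is compared with a 2 Å threshold. The
printed threshold has length units, so the deviation is computed as an RMS
distance in Å. The superposition starts from an all-C$\alpha$ fit and then
iterates a *trimmed* re-fit on the residues currently below threshold.
A single rigid all-C$\alpha$ fit was tried first and rejected: long
re-sampled tails dominate the least-squares frame and rotate rigid cores
apart, flagging interior residues that do not move. The trimmed iteration
is deterministic, converges in a few rounds, and recovers planted
disordered segments to within the ambiguity of their boundary residues.

`accuracy_score()` averages, over residues, the predicted frequency of the
state the reference assigns; `null_model_score()` is the same score for
the all-ordered baseline, i.e. the ordered fraction of the reference. The
two are definitionally linked (the accuracy of a flat-zero profile equals the
null), which the tests assert.

Core RMSD uses a Kabsch superposition (SVD with reflection guard) over
core C$\alpha$s only, cross-checked in the suite against an independent
implementation. Core GDT-TS averages, over cutoffs {1, 2, 4, 8} Å, the
largest core fraction superposable within the cutoff; the maximum is
searched by seeding fits from every contiguous core fragment of lengths
{3, 5, 7} (plus the whole core) and iterating include-refit to
convergence. On small cores an exhaustive fit-on-every-subset oracle
bounds the heuristic from above; they agree exactly on structured
instances (rigid motions, displaced blocks, sub-ångström noise), while on
heavily corrupted instances the heuristic can undershoot the oracle —
inherent to any seeded-extension search of this kind, and documented by a
one-sided bound in the tests.

## The synthetic generator

`generate_ensemble()` plants ground truth the analysis modules are then
asked to recover. The geometry is coarse by design — only contact and
deviation statistics matter to the methods under test:

* **Core**: a compact self-avoiding C$\alpha$ walk, 3.8 Å bonds,
  hard-sphere separation 4.7 Å (just outside the potential's repulsive
  zone for alanine pairs, so compact cores are attractive, not clashing),
  confined to a sphere sized for protein-like density. Chain ends and
  loop anchors are required to land in the outer shell so grown segments
  can escape. Per model the core is jittered by `core_noise` (0.3 Å
  default), re-drawn if any virtual bond leaves (2, 5) Å.
* **Tails**: per-model outward random walks keeping ≥ 5.6 Å from the
  core (relaxed stepwise if the anchor is crowded), far enough that a
  tail residue's residual attraction stays below $E_d$.
* **Loops**: circular arcs bridging the two anchors, bulging away from
  the core centroid with a per-model random tilt about the chord; the arc
  length is set by the loop's residue count so bonds stay in range for
  minor and major arcs alike.
* **Collapse**: in `collapse_fraction` of the models, disordered tails
  instead hug the core at contact distances drawn from 3.6–4.6 Å, with
  the first three contacts forced into the tight 3.55–3.80 Å band. The
  band is chosen from the potential's geometry: most contacts sit in the
  attractive well (full energy rewards the collapse), while the tight
  ones sit inside the repulsive zone that survives masking — so
  repulsive-only re-scoring demotes every collapsed model. This is the
  stress fixture for the second approach; it uses a small `core_noise`
  (0.05 Å) so the per-model core energy spread does not mask the
  segment-conformation signal.

Sequences are assigned poly-alanine (ordered) / poly-glycine (disordered);
the backend keys only on radii, and sequence realism is out of scope.
Generation is a pure function of the mandatory seed (RNG state is isolated
and restored); if a draw exhausts its bounded per-segment retries, the
whole construct is re-drawn deterministically within the same stream, and
a hard generation error is raised only after ten attempts.

What the generator does *not* emulate: secondary structure, side chains,
Ramachandran statistics, realistic decoy energy landscapes, or
experimental noise. Passing tests therefore demonstrate that the searches,
scores and masking behave as specified on ensembles with planted contact
statistics — not that prediction accuracy on real decoy sets matches any
published benchmark, which depends on a full molecular-mechanics energy
and real structures.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in about a minute: oracle equivalence on 200
12-residue and 100 20-residue instances, tail recovery over 20 ensembles
of 8 models (cores of 40, tails 2–20), internal-loop benchmarks over 15
seeds, 100 random rigid transforms for metric sanity. Tolerances: the
breakdown identity and oracle F-comparisons at $10^{-12}$ (pure
arithmetic), clash-free masking invariance at $10^{-9}$ (one cutoff-zero
subtraction), superposition cross-checks at $10^{-6}$ (SVD conditioning),
PDB round-trips at $10^{-3}$ (format precision). Ties in every search are
resolved by the fixed cascade above, so identical inputs give identical
assignments everywhere.

## Known limitations

* The greedy search cannot split or shrink a committed run; planted loops
  whose length is not a multiple of the block are recovered to block
  granularity only.
* Internal-loop profiles are conservative: a loop is flagged only when its
  residual attraction is genuinely weaker than its loop entropy, which on
  dense synthetic cores yields disorder frequencies well below 1 even for
  planted loops.
* The GDT-TS heuristic is a lower bound off the structured regime (see
  above).
* The 12-6 backend is a stand-in with a single attractive channel; all
  statements about real proteins should be made with energies injected
  from a full scoring function.
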