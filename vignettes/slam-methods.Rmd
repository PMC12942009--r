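---
title: "Spatio-linear alignment of binding sites: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-linear alignment of binding sites: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slamr)
```

## The problem

Two proteins with no detectable sequence or fold similarity can still share a
ligand-binding cavity: a local constellation of a few dozen heavy atoms with
compatible chemistry in a compatible spatial arrangement. `slamr` detects such
local 3D similarity between a query cavity (the neighborhood of a bound probe
ligand) and target substructures — other ligand cavities or solvent-exposed
surface patches — and scores whether the probe ligand could dock at the
matched site.

The central trick is to avoid explicit 3D search altogether. Every heavy atom
is made the center of a small neighborhood; the neighborhood is serialized
into a *linear sequence* of its k nearest heavy atoms sorted by increasing
distance from the center. If two neighborhoods from two proteins are
superimposable, their distance-sorted sequences align well position by
position; if not, the alignment degrades into mismatches and gaps. Local 3D
similarity detection thereby reduces to many cheap global sequence
alignments, followed by a geometric consistency step.

## Atom annotation

Each heavy atom carries two kinds of chemistry:

* **A four-bit key** (donor, acceptor, bulkiness, electropositivity).
  Hydrogen-bond donor/acceptor flags come from a bundled per-residue template
  covering backbone and side-chain atoms of the 20 standard residues (plus
  selenomethionine), with an element-based fallback for hetero atoms.
  Bulkiness is conformation-dependent: an atom is bulky when
  \(w_i^3 + \sum_j w_j^3 > 10\,\text{Å}^3\) (strict), summing the cubed van
  der Waals radii of the atom and its van der Waals contact neighbors
  (distance at most the radius sum; the contact tolerance defaults to 0 Å).
  Electropositivity is 1 when the atom *and all* its contact neighbors have
  Pauling electronegativity at most 2.5, so it essentially never fires inside
  ordinary protein matter (carbon is 2.55) and marks phosphorus/metal
  environments. Key similarity is the number of shared positions, 0–4.
  Because bulkiness and electropositivity depend on coordinates, annotations
  must be recomputed whenever coordinates change; `annotate_atoms()` is
  therefore always applied to the current conformation.
* **A reduced residue alphabet.** Residues map to seven groups
  ({A,G,P,S,T}, {C}, {D,E,N,Q}, {F,W,Y}, {H,K,R}, {I,L,M,V}, other). The
  7×7 group weight matrix is obtained by averaging PAM250 entries over all
  residue pairs within each group pair and affinely rescaling to [0, 4] so
  the residue term and the chemistry term have the same range. The neutral
  seventh group (hetero and non-standard atoms) scores the midpoint 2 against
  everything, so cavities containing nucleotide or ligand atoms align without
  special cases. One consequence of the affine rescaling is that only the
  most self-similar group (cysteine, PAM250 diagonal 12) attains the full
  weight 4; an identical alanine pair scores about 2.5. Reduced-alphabet
  choices of this kind are known to matter little, and the mapping and
  matrix are configurable.

The atom-to-atom substitution score is the sum
`group_weight + chem_weight * key_similarity`, bounded by 8 with the default
`chem_weight = 1`.

## The engine

For substructures A and B, the engine (`slam_align()`) proceeds in five
steps.

1. **Neighborhoods** (`build_neighborhoods()`): one per heavy atom; the k
   nearest other heavy atoms sorted by increasing distance. k defaults to 7
   (an eight-atom neighborhood counting the center) and may be raised to 11.
   Distance ties break lexicographically by atom id, making every downstream
   result bit-reproducible.
2. **All-against-all alignment** (`accumulate_pair_evidence()`): every
   A-sequence against every B-sequence with an affine-gap Needleman–Wunsch
   (gap open −4 — the magnitude of the best possible match — and extension
   −1; end gaps are penalized; deterministic traceback). An alignment
   contributes only if its score reaches a *quality gate*: a fraction of the
   smaller sequence's self-alignment score. The gate defaults to 0.85. This
   value was chosen by measuring the two score populations the gate must
   separate on planted-motif fixtures: alignments of truly corresponding
   neighborhood centers score above ~0.78 of self at their 5th percentile,
   while random center pairs stay below ~0.84 at their 95th; 0.85 sits at
   the top of the separation band, so nearly all chance alignments are
   excluded while recurrences of true pairs survive. Each gated alignment
   adds its full score to every matched atom pair (the cumulative-quality
   reading of pair evidence) and the matched-pair set of each gated
   alignment is retained as a *seed* for clustering.
3. **Candidate selection** (`select_candidate_pairs()`): the evidence values
   split into a background of incidental matches and a high tail of
   recurrent pairs. The default policy keeps pairs above mean + 2·SD of the
   evidence distribution; quantile and fixed-value policies are available.
   When no cluster can be formed from this strict cut, the engine relaxes
   the multiplier stepwise (2 → 1 → 0.5) — a deterministic fallback for
   borderline inputs whose outlier tail is thin.
4. **Correlation-constrained clustering** (`cluster_pairs()`): groups of
   matched pairs are merged agglomeratively; the merge chosen at each step
   is the one whose union has the highest Pearson correlation r between the
   within-A and within-B interatomic distance vectors, and merging stops
   when no union exceeds the threshold r ≥ 0.85. Seeds are the per-alignment
   candidate-pair sets, so every union carries enough distances for a
   well-defined correlation. Atom conflicts between groups (one atom claimed
   by two different pairs) are resolved in favor of the higher-evidence
   pair, keeping every group one-to-one. Groups of at least 4 pairs (six
   distance components) are emitted. Singleton seeding is retained as a
   fallback when no alignment seeds are supplied; there, two-pair unions use
   the relative distance agreement `1 − |dA − dB|/max(dA, dB)` in place of
   the undefined correlation.
5. **Score-ascent refinement and Ncorr5.** Each emitted cluster — and, as
   additional starting points, the highest-evidence alignment seed groups —
   is refined by a deterministic hill climb over the full evidence table:
   add a non-conflicting pair; when growth stalls, repair — swap a pair for
   the single member it conflicts with, apply a transposition (a pair
   conflicting two members, together with its complementary pair, replaces
   both, which escapes swapped-assignment optima between chemically
   equivalent atoms), or remove a member. Every accepted move strictly
   increases `Ncorr5 = N·r⁵` under the r ≥ 0.85 constraint, so the climb
   terminates; converged duplicates are collapsed. This step implements
   directly the principle that the reported alignments are
   Ncorr5-maximized: candidate selection alone cannot carry weakly
   evidenced true pairs (edge atoms of a shared region accumulate little
   evidence), but geometry identifies them unambiguously once a core
   exists. Alignments are ranked by Ncorr5, descending.

The fifth power in `Ncorr5` sharpens the separation between consistent
(r → 1) and spurious (r ≈ 0.85–0.95) alignments while keeping the score in
units of matched atoms: r = 0.9 retains 59% of N, r = 0.99 retains 95%.
Because only interatomic distances enter, the whole engine is invariant
under rigid motion of either substructure — and intentionally blind to
uniform scaling, which a correlation cannot see; real protein matter does
not scale, so this costs nothing in practice.

Two behavioral notes. First, N·r⁵ ≤ N with equality only at r = 1, so an
alignment of a jittered 25-atom motif tops out slightly *below* 25 even at
perfect recovery — significance thresholds (below) should be read with this
bound in mind. Second, the refinement step will happily assemble the best
geometrically consistent matching between two unrelated substructures;
on random 80-atom fixtures this background reaches Ncorr5 ≈ 15–17, well
below the significance threshold, but it is the reason the threshold exists
at all.

## Significance thresholds and calibration

Screen scores are maxima over many alignments, so their background follows
the Gumbel law `F(x) = exp(−exp(−(x−μ)/β))`. `fit_gumbel()` uses moment
estimates (β̂ = s·√6/π, μ̂ = x̄ − γβ̂) with an optional MLE refinement.
`double_log_curve()` plots `log(−log F̂)` against the score: a Gumbel
background is a straight line of slope −1/β, and an excess of true
high-scoring matches bends the upper tail upward.

`significance_threshold()` automates the visual knee reading: the line is
fitted on the lower 90% of scores; scanning beyond that regime, the first
run of 5 consecutive points whose positive residual exceeds 3× the larger of
the fit residual SD and the binomial sampling noise of the empirical CDF
(`2/√(n·(1−F̂))`) marks the knee. On pure Gumbel samples the detector
returns nothing. The packaged mixture generator
(`simulate_score_mixture()`) encodes the calibration scenario: a
Gumbel(10, 2) background of 10⁵ scores plus a planted block of uniform
scores in [30, 40]. The default signal size of 40 follows from the survival
crossing: the departure becomes visible where the signal fraction overtakes
the background survival function, `exp(−(x−μ)/β) ≈ n_signal/n`, which for
these defaults happens near score 26 — between the conventional
significance (25) and stringent (30) cutoffs. The fixed policies return 25
(significant), 30 (stringent comparisons) and 35 (surface screens).

## Reference inputs: cavities and surface patches

`extract_ligand_cavity()` builds the query/target unit from a complex: every
whole residue with at least one heavy atom within 7 Å of any ligand heavy
atom, the ligand itself excluded; cavities under 40 heavy atoms are
discarded as too small to align reliably. `compute_sasa()` implements
Shrake–Rupley areas with a 1.4 Å water probe and a deterministic
golden-spiral sampling of 960 points per atom sphere (two-sphere test
systems agree with the closed-form overlap areas to well under 1%); areas
are computed per isolated protein chain, with ligands and waters excluded
from the occlusion environment by default since the reference databases are
built per chain. Atoms with strictly more than 2 Å² exposed area are
surface-exposed, and `extract_surface_patch()` applies the same 7 Å
whole-residue shell around each such atom. `build_patch_database()`
persists one patch per surface atom (an optional residue-set deduplication
collapses near-identical neighbors) with a TSV manifest; annotated
structures can be written with the per-atom areas as a pseudo-chain 'X' in
the B-factor column, keeping the files valid PDB.

## Pose transfer and the FE-score

A 3D alignment fixes a correspondence between query cavity atoms and target
atoms; `kabsch_superpose()` (closed-form SVD solution, reflections
excluded) turns it into the rigid transform that carries the probe ligand
into the target frame (`transfer_ligand()`). The transferred pose is then
locally optimized against the rigid receptor. With `engine = "vina"` an
external AutoDock Vina executable is run in local-only mode on
package-written PDBQT inputs and its affinity is reported. The default
`engine = "stub"` is a built-in rigid-body local search under a soft steric
energy (quadratic clash repulsion inside 0.75× the radius sum, a smooth
contact reward near it): it preserves the pipeline's shape — clash-free
poses in a pocket score negative, clashed poses are pushed out — but its
energies are not physical binding free energies and must not be interpreted
as such.

Docking quality is summarized by `FE-score = FE/(Shift + 0.1)`, where FE is
the optimized energy (kcal/mol) and Shift the displacement between
transferred and optimized pose. Shift defaults to heavy-atom RMSD (a
centroid-distance alternative is available; RMSD also sees rotations of
elongated ligands). A large shift means the alignment-based placement was
poor and correctly drives the score toward zero. Scores strictly below −1.5
classify a docking as a true positive, and `evaluate_screen()` aggregates a
screen into hit/TP counts, a ROC curve over the alignment-score ranking and
a trapezoid AUC.

## The synthetic generators, and what passing tests mean

All tests run on synthetic structures built in code:

* `make_random_structure()`: a persistent self-avoiding random walk of
  alpha-carbons (3.8 Å steps) carrying full heavy-atom residue templates,
  about 8 heavy atoms per residue, all atoms ≥ 1.2 Å apart. Side-chain
  geometry is an idealized compact spiral — the engine consumes only
  distances and chemistry, so torsional realism buys nothing.
* `plant_shared_motif()`: copies a spatially contiguous piece of one
  structure into another under a random rigid transform with per-coordinate
  Gaussian jitter, preserving chemistry and returning the exact atom
  pairing. This is the ground-truth oracle for recovery experiments; the
  companion `shuffle_chemistry()` produces decoys with identical geometry
  and permuted chemistry.
* `make_toy_complex()`: a hetero ligand with a constructed pocket — chosen
  residue counts inside the 7 Å shell, a distant ring guaranteed outside —
  so extraction filters can be checked against brute force.

These fixtures emulate the *logical* structure of real data (local
correspondence embedded in unrelated context, chemistry-coupled geometry,
bounded noise) but not its statistics: real cavities have backbone-ordered
residues, realistic packing densities, richer chemistry ratios and
correlated noise. Passing the planted-motif suite therefore demonstrates
that the engine recovers embedded correspondences under coordinate noise at
the stated sizes, not that screening sensitivity on crystallographic
databases matches any published figure; full-scale screens additionally
require the external reference databases and a physical docking engine.

Problem sizes in the shipped tests were chosen to exercise every code path
at comfortable desk scale: hosts of 10 residues (~80 heavy atoms), motifs
of 20–30 atoms, jitter up to σ = 0.3 Å per coordinate across 20 seeds,
score-calibration samples of 10⁵, and toy screens of one query against
three targets.

## Numerical choices and degenerate inputs

* Ties (equal distances, equal scores, equal correlations) always break
  lexicographically by atom id or row order; repeated runs are identical.
* A Pearson correlation needs ≥ 3 pairs and non-degenerate distance
  vectors; fewer pairs or equilateral geometry signal `NA` with a warning,
  and clusters are only emitted at ≥ 4 pairs.
* The Kabsch solution refuses collinear point sets (the rotation about the
  common axis is unobservable).
* Gap penalties, the gate, the candidate policy, k, r_min, all radii and
  thresholds live in one validated configuration object (`slam_config()`),
  serialize to YAML, and are embedded verbatim in every results file.
* Structure reading keeps the first model of multi-model files and the
  highest-occupancy alternate location (ties toward 'A'); unknown elements
  are an error, never a silently defaulted radius.

## Known limitations

* The engine is sequence-order-agnostic and rigid: conformational change
  between query and target beyond the jitter scale defeats the distance
  correlation by design.
* The stub docking energy is a plumbing device, not an energy model;
  FE-score thresholds carry physical meaning only with a real docking
  engine behind them.
* Evidence accumulation assumes enough chemical diversity for the gate to
  separate true from chance alignments; on deliberately uniform atom sets
  (all carbons in one residue type) the evidence table degenerates and no
  alignment is reported.
* Hill-climb refinement finds a local Ncorr5 maximum; it provably recovers
  planted motifs at the tested noise levels but carries no global
  optimality guarantee.
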