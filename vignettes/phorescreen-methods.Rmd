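---
title: "Methods: pharmacophore screening, enrichment statistics and MM-PBSA bookkeeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore screening, enrichment statistics and MM-PBSA bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Ligand-based virtual screening against a target such as squalene synthase
(SQS) proceeds in stages: a pharmacophore hypothesis is learned from known
actives, validated on a labeled test set, used to screen a compound library,
and the hits are refined by docking-score thresholds and protein–ligand
interaction analysis; top candidates are finally examined with MM-PBSA
binding-energy bookkeeping and reverse target profiling. `phorescreen`
implements every computational stage of that protocol as composable,
tibble-in/tibble-out functions, with a synthetic benchmark generator that
plants a known signal so each stage can be tested against ground truth.

The commercial components of the usual workflow (pharmacophore engines such
as HipHop, docking engines such as CDOCKER/LibDock, MD engines) are *not*
reimplemented: the package consumes their tabular outputs, or synthetic
stand-ins, through documented text formats.

## Pharmacophore model and mapping

A model is a named set of typed feature spheres — hydrogen-bond acceptor
(`A`), donor (`D`), hydrophobe (`H`), aromatic ring (`R`) — each with a 3D
center, tolerance radius $t_i$ and weight $w_i$, plus excluded-volume (Ev)
spheres no ligand heavy atom may enter. Feature perception on ligands uses a
small curated rule set (`feature_rules()`, versioned so analyses can pin
it): A/D at heteroatom positions, H at centroids of non-aromatic carbon
clusters of three or more atoms, R at aromatic-ring centroids.

`map_ligand()` searches over conformers and all kind-compatible injective
assignments of model features to ligand feature points (omitting at most
`allow_omit` features), superposes the matched points by the least-squares
rigid (Kabsch) fit, and accepts a placement when every displacement $d_i$
is within its tolerance and no heavy atom falls inside an Ev sphere. The
overlay score is the fitvalue

$$\mathrm{fit} = \sum_i w_i \, \max\!\left(0,\; 1 - (d_i / t_i)^2\right),$$

which equals $\sum_i w_i$ exactly at zero displacement and decreases
monotonically in each $d_i$. The commercial FitValue formula is unpublished,
so this quadratic falloff is the package's own definition; published
absolute fitvalues (e.g. a reported 0.66 for a docked pose) are therefore
not reproduction targets. The search is exhaustive — feature counts in this
setting are small (3–5 model features, a handful of ligand points) — and the
tests check it against an independent enumeration built on Horn's
quaternion superposition. Ties break deterministically: higher fitvalue,
then fewer omitted features, then lower conformer index, then
lexicographically earliest assignment. With fewer than three matched points
the rigid fit is underdetermined; the fit routine still returns a valid
minimizer and the convention is documented rather than forbidden.
Ring-normal orientation of `R` features is not constrained.

## Common-feature hypothesis generation

`generate_common_feature_models()` is a deliberately simple qualitative
(common-feature) generator in the HipHop family: a reference compound is
taken from the highly active training members (`principal = 2`), every 3–5
point subset of its features becomes a candidate, and a candidate survives
only if every `principal = 2`, `max_omit = 0` compound maps it with nothing
omitted. Compounds with `principal = 0` (`max_omit = 2`) impose no
constraint — all their features may be ignored — but add their fitvalue when
they happen to map. Up to `max_ev` excluded volumes (default 5) are placed
at consensus voids: points on a shell around the model that stay at least
one clearance radius away from every mapped training conformer's heavy
atoms, chosen greedily for spatial spread from a seeded candidate set.
Models are ranked by `rank_score`, the sum of training fitvalues; the
published rank formula is likewise unpublished, so only orderings, never
absolute rank values, are meaningful here.

## Validation indices

For a labeled test set of $D$ compounds with $A$ actives, a hit list of
size $H_t$ containing $H_a$ actives:

$$\mathrm{HRA} = 100 \cdot \frac{H_a}{A}, \qquad
\mathrm{IEI} = \frac{H_a / H_t}{A / D}, \qquad
\mathrm{CAI} = \frac{\mathrm{HRA}}{100} \cdot \mathrm{IEI}.$$

HRA is the recall of actives (percent); IEI the enrichment of actives among
hits over the base rate (a uniformly random hit set has expected IEI 1, a
property the tests verify by Monte Carlo); CAI their product with HRA as a
fraction, so CAI ≤ IEI always. Indices are stored at full precision and
rounded only for presentation; published tables of this kind mix rounding
and truncation, so comparisons are made at ±0.01. When $H_t = 0$, IEI and
CAI are reported as undefined (`NA` with a flag), not as a crash.
`select_best()` picks, among hypotheses meeting the conventional
HRA ≥ 80% / IEI ≥ 2 / CAI ≥ 2 thresholds, the one with the highest rank
score, falling back to highest CAI with a warning when none qualifies.

## Fingerprint similarity

2D similarity uses hashed path-based OpenBabel FP2 fingerprints (1024 bits;
the scheme is configurable) and the Tanimoto coefficient
$|a \wedge b| / |a \vee b|$. Two empty fingerprints are defined to have
similarity 0, with a warning. `similarity_report()` bins coefficients into
left-open/right-closed intervals $(l, u]$ (the first bin also includes its
lower edge), so bins partition the library and counts conserve; a published
table whose printed bin labels overlap is normalized this way. Percentages
are true percentages of the library size.

## The consensus cascade

`run_cascade()` applies, in order: Lipinski's rule of five (MW ≤ 500 Da,
logP ≤ 5, donors ≤ 5, acceptors ≤ 10; strict zero-violation default with a
configurable allowance, properties always recomputed from structure via
OpenBabel descriptors), the pharmacophore screen, a docking-score threshold,
and a key-residue interaction filter. The docking threshold keeps records
scoring at least a fraction (default 0.8) of the reference ligand's scores
on *both* score columns — the protocol reports two scores per ligand and
selects high scorers on both; an either-column mode is available. Scores
are treated as higher-is-better, matching tools that report positive
docking scores (note the sign convention differs from raw CDOCKER
energies). `interaction_frequency()` counts compounds per residue (not raw
interaction events), the quantity plotted in key-residue column diagrams;
`key_residue_overlap()` intersects a record's residues with a reference key
set (for SQS: PHE54, VAL179, LEU183, LEU211, PRO292). Survivor sets are
nested by construction and the final ranking is by overlap count, then
docking score, then fitvalue, with deterministic ties.

## MM-PBSA bookkeeping

Per snapshot, the binding energy is
$E_{vdW} + E_{ele} + G_{polar} + G_{nonpolar}$ (kJ/mol), with
$G_{nonpolar} = \gamma \cdot \mathrm{SASA} + \beta$ available as a helper.
The entropy term $-T\Delta S$ is zero by default, matching common g_mmpbsa
practice; a config hook accepts an external estimate. The single-trajectory
approximation (complex frames only) is the default; `binding_energy()`
implements the three-species form when complex, protein and ligand frame
sets are all supplied. Summaries report component-wise mean ± sample
standard deviation, and the total mean equals the sum of component means by
construction. Whether published "±" values are SD or SEM is typically
unstated, so comparisons beyond means are shape-only. Per-residue
decompositions are aggregated the same way and are *not* asserted to
telescope to the total — decomposition schemes need not.

## Trajectory summaries

RMSD superposes each snapshot onto a reference by the same Kabsch routine
used in mapping and reports the root-mean-square deviation; RMSF superposes
onto the first frame, measures each atom's fluctuation about its mean
position, and averages (root-mean-square) within residues. Both accept
`fit = FALSE`: without superposition, a single atom displaced by $d$ among
$N$ gives exactly $d/\sqrt{N}$ and a rigidly moved frame gives its raw
offset. The fitted value is never larger, and the optimal fit strictly
improves on any net displacement (at $N = 100$, $d = 1$ Å: 0.0995 Å vs
0.1 Å), which is why the closed-form checks in the tests pin the unfitted
convention and bound the fitted one.

## Synthetic benchmark: what it does and does not emulate

`make_library()` plants a four-point A/H/H/R arrangement (pairwise
distances 3–5 Å, embedded from the distance matrix by classical MDS, with
an error on non-embeddable inputs) into `n_actives` molecules — jittered
by `jitter_sd` (default 0.3 Å), randomly rotated and translated, padded
with random extra feature points — while decoys get the same kind multiset
at uniform random positions. The default composition, 154 actives and 462
decoys, mirrors a typical hypothesis-validation test set. Molecules are
geometry-only feature clouds with a minimal carbon scaffold; full chemistry
(a SMILES pool with deliberate rule-of-five violators) is generated
separately by `make_chem_library()` for the stages that need it. Docking
tables plant an additive active-score shift over a base level set at 70% of
the reference scores, and key-residue interactions with higher probability
for actives; energy frames are independent Gaussians per component.

Passing tests on this benchmark demonstrate signal recovery, calibration
and the contracts of every stage; they do not demonstrate performance on
real chemotypes, real docking physics, conformational ensembles of real
inhibitors, or database-scale chemical diversity — no claim is made that
the generator emulates a real compound database's chemical space.

All generators are pure functions of their specification and seed
(Mersenne-Twister via `set.seed()`); manifests record labels, planted
coordinates and the seed, sufficient to recompute all ground truth.

## Numerical and design choices

* **Feature tolerance 1.6 Å, Ev radius 1.2 Å, unit weights** — defaults in
  the range pharmacophore tools commonly use; the source protocol does not
  state its radii, so these are configuration, not literature values.
* **Conformer generation** — commercial "BEST" conformer search is
  proprietary, and the obvious substitute (OpenBabel's 3D generator) is not
  deterministic run-to-run, which breaks the reproducibility contract.
  The package instead enumerates torsions about rotatable acyclic single
  bonds in 120° steps from the input geometry (or a spanning-tree
  internal-coordinate embedding when none is given), scores a soft
  steric-clash strain, prunes to a 20 kcal/mol window above the minimum and
  caps the ensemble at 255 — the conventional flexible-search settings.
  When the torsion grid exceeds the cap, a seeded subsample (always
  containing the base geometry) is evaluated. Ring conformers are not
  enumerated (rings are treated as rigid), and the strain function is a
  clash penalty, not a force field; supply explicit 3D coordinates for
  conformationally subtle ring systems.
* **Kabsch fit** — SVD-based with a determinant correction so reflections
  are never returned.
* **Lipinski H-bond acceptors** — the classic N+O count (OpenBabel `HBA1`);
  the logP estimator (Wildman–Crippen atom contributions) is recorded in
  the output metadata.
* **Problem sizes in the test-suite** — mapping-oracle agreement on a
  5-molecule micro-benchmark; cascade nesting over 100 random
  configurations; planted-signal enrichment on the full 154/462 benchmark;
  Gaussian-recovery and calibration checks at 10,000 draws. These sizes
  were chosen to make the statistical assertions sharp (3-standard-error
  bounds, binomial p < 0.01) while keeping the default suite around a
  minute.

## Known limitations

* Perception rules are curated and minimal: no tautomer/protonation
  enumeration, no SMARTS engine, no charged-feature kinds.
* The common-feature generator explores subsets of a single reference
  compound's features; arrangements present in all actives but absent from
  the reference conformer are missed.
* Docking and MD are consumed, never computed; re-dock RMSD validation of
  a docking engine is out of scope.
* Absolute values that depend on proprietary scoring functions
  (fitvalues, rank scores, fingerprint schemes behind published similarity
  tables) are non-reproducible by construction and are treated as
  narrative, not targets.
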