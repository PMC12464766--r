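---
title: "Quadrant-aligned modeling of asymmetric dihydroxylation selectivity: methods and design"
author: "ADquadrant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant-aligned modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the
design decisions taken where the design was genuinely open.

## The problem

The Sharpless asymmetric dihydroxylation (SAD) adds two hydroxyl groups
across one face of an alkene, with the face chosen by the chiral ligand of
AD-mix α or β. The classical quadrant mnemonic rationalizes the outcome by
drawing the alkene in a 2×2 frame: the bulky substituent sits bottom-left
(Q1), and α-type ligands deliver the oxygens to the bottom face, β-type to
the top. The mnemonic predicts *which* enantiomer forms but not *how
selective* the reaction is. This package operationalizes the mnemonic as an
alignment algorithm, attaches physically interpretable descriptors to the
aligned quadrants, and regresses the *magnitude* of enantioselectivity —
expressed as the activation free-energy difference ΔΔG‡ — per substitution
class.

## Structures, conformers and charges

Molecules are parsed, canonicalized and embedded in 3-D by RDKit through a
batched helper process. SMILES inputs are rebuilt from their canonical
form, so atom order — and therefore every downstream descriptor — is
independent of how the input was written. Embedding uses ETKDG with an
explicit random seed followed by an MMFF cleanup, which makes coordinates
bit-reproducible; this determinism is a design requirement, not a
convenience, because alignment audits and feature matrices must be exactly
reproducible from a seed.

Conformer ensembles are produced by torsion driving: every rotatable
single bond receives a perturbed dihedral drawn from the staggered wells,
clashing candidates (non-bonded contact below 0.55 × the sum of vdW radii)
are rejected, and survivors are pruned at 0.5 Å heavy-atom RMSD after
optimal superposition. The default target is 25 conformers with uniform
weights; molecules without rotatable bonds replicate their base conformer
so the ensemble size is always as requested. The conformer count and the
uniform weighting are free choices (an energy-weighted ensemble can be
substituted by setting the weights); descriptor trends are stable from a
handful of conformers onward, and the package's own studies use 2–3
conformers per molecule as a desk-scale setting.

Partial charges default to Gasteiger's partial equalization of orbital
electronegativity: fast, connectivity-only, and exactly symmetric for
symmetry-equivalent atoms. The charge registry also exposes OpenBabel's
EEM/MMFF94/QEq/EQeq models and accepts user backends, so a semiempirical
or DFT-level charge model can be plugged in without touching descriptor
code — that is the intended upgrade path toward quantum-chemical fidelity,
which this package deliberately does not implement itself.

## Alignment: the Q1 priority cascade

The target alkene is the unique nonaromatic, noncumulated C=C bond
(ambiguity requires an explicit selector; a stereogenic alkene without
declared geometry is an error, except in rings where geometry is implied).
Its four positional substituents are extracted as breadth-first fragments
with deterministic, canonical-rank tie-breaking.

Four candidate frames can place a position into Q1 while preserving the
alkene geometry: two in-plane rotations (which keep the molecular faces)
and two out-of-plane flips (which mirror them, recorded as `faceFlip`).
The cascade filters candidates in priority order:

1. Q1 holds the largest-volume substituent,
2. the smallest-volume substituent lands cis to Q1 (in Q2),
3. Q1 holds the largest ESP₉₉,
4. the largest ESP₉₉ lands trans to Q1 (in Q3),
5. the Q1 attachment atom has the largest polarizability,
6. the largest-polarizability attachment atom lands trans.

The volume criterion is configurable: the full substituent volume
("Max Volume") or the 3-BFS-truncated volume, which deliberately blurs
volume differences so that electronic rules lower in the cascade decide
more often. Tie tolerances are needed because descriptors are continuous:
volumes tie below 2 % relative difference, ESP values below 0.5 kcal/mol,
polarizabilities on equal element. These tolerances are package choices —
the cascade's priority order implies ties must be passable but no
published tolerance exists. If all six rules leave several frames
(perfectly symmetric alkenes such as stilbene), the frame is picked by
lexicographic fragment-signature order and flagged `tie_broken`; the
surviving frames of a symmetric alkene yield equivalent feature vectors up
to the small geometric asymmetry of the embedded conformer.

Classes follow the hydrogen pattern of the aligned unit: Mono, Gem, Cis,
Trans, TriQ2/TriQ3/TriQ4 (suffix = quadrant of the lone hydrogen), Tetra.
Ethylene itself is featurizable but labeled `Unsub`, outside the eight
substituted classes.

## The 57-feature space

Per quadrant (concatenated counterclockwise Q1→Q2→Q3→Q4, 7 features
each): Sterimol L, B1, B5 of the fragment truncated to its first three
heavy atoms (plus their hydrogens), measured along the alkene-carbon →
attachment-atom axis from the alkene carbon and conformer-averaged; the
full and 3-BFS van der Waals volumes; and ESP_MIN / ESP₉₉ (nearest-rank
99th percentile) of the point-charge electrostatic potential on the
fragment's surface (vdW radii × 1.2, ≈2 points/Å², points inside any
atom's scaled sphere removed, Coulomb constant 332.06 kcal·Å/(mol·e²)).
Hydrogen positions run through the same code on their one-atom fragment,
so every vector is dense. Volumes integrate on a 0.2 Å grid averaged over
four interleaved sublattice offsets; the offset average cancels lattice
alignment bias and keeps even single-atom spheres accurate to a few
tenths of a percent (verified against analytic spheres and Monte-Carlo
sampling).

Per alkene: radial distribution functions around each alkene carbon,
RDF(c, k) = Σ_conf w Σ_a p_a exp(−B (d(c,a) − r_k)²) over all other atoms,
with spheres r_k = k Å (k = 1…7), smoothing B = 20 Å⁻², and p_a the
element's static dipole polarizability — a conformer-dependent measure of
dispersion and steric occupancy around the reacting bond. The sphere
spacing, count and smoothing are fixed package constants chosen so
adjacent spheres overlap modestly at molecular distances.

The 15-feature electronic block is a Hückel-level surrogate for
natural-bond-orbital analysis: a topological π Hamiltonian over the
conjugated system containing the alkene (standard heteroatom h/k
parameters; α = −6.3 eV, β = −3.2 eV) supplies π/π* energies and
occupancies (projections of the local C1–C2 π bond orbital onto the
filled spectrum) and HOMO/LUMO; the dipole magnitude comes from the
partial charges; "natural-type" charges on C1, C2 and the four quadrant
attachment atoms, plus their sum, come from the charge model. These are
surrogate-level trends — they order conjugation and substituent effects
(an acrylonitrile-type acceptor lowers the LUMO; the gap is exactly
LUMO − HOMO) — not quantum-chemical observables. A registry-level swap to
a semiempirical backend would upgrade them without changing the feature
schema.

## Diol mapping and CIP-independent face assignment

A reactant maps onto a putative product by element-colored graph
isomorphism of its heavy-atom skeleton with the C=C saturated and one
oxygen grafted on each alkene carbon (LAD matching with element domains;
the matched oxygens must be hydroxyls). Failures — wrong atom count,
skeleton mismatch — are data with reasons, not errors, mirroring the
partial coverage inherent to substructure matching over diverse
literature structures.

The face of addition is read from tetrahedral parity: at each mapped
carbinol carbon, the sign of the determinant of (O, other alkene carbon,
bottom-quadrant substituent) vectors decides whether the oxygen added
from the aligned frame's top or bottom. Parity is conformation-independent
— it survives relaxation of the product geometry — and involves no CIP
priorities, so exotic substituents cannot flip the label through priority
reordering. Carbons whose two quadrant substituents are structurally
identical carry no stereo information and are skipped; if the two carbons
disagree the product shows an anti-addition pattern and is rejected; if
different symmetry-equivalent mappings yield both labels the product is
face-degenerate (e.g. meso diols of symmetric cis-alkenes) and flagged.
A chiral product whose input declared no stereochemistry is refused
(detected by comparing the canonical form of the embedded geometry with
its mirror image).

The generative counterpart builds syn-addition diols explicitly in 3-D:
both oxygens placed 1.43 Å along the aligned frame normal on the chosen
face, with the former sp2 carbons pyramidalized 0.40 Å toward the
oxygens. The pyramidalization matters: with the three remaining
substituents left coplanar, stereo perception keys off a near-zero chiral
volume and can flip for crowded quaternary carbinols. Mnemonic accuracy —
the fraction of records where α gave bottom-face and β top-face addition
— is then exactly 1 on sets built to follow the mnemonic, which is the
package's internal validity check for the whole alignment/mapping chain.

## Selectivity scale and modeling protocol

Enantiomeric excess converts to ΔΔG‡ = RT ln((1+ee)/(1−ee)) with
R = 1.987204×10⁻³ kcal/(mol·K) at a fixed 273.15 K — the dominant
literature condition — with ee ≥ 99.9 % capped before conversion to avoid
the logarithmic divergence. Reactions run with both AD-mixes are averaged
to a single positive magnitude, focusing models on *how selective* rather
than *which enantiomer*.

Feature preprocessing standardizes each column on the training partition
and drops the later member of any pair with |Pearson r| > 0.95 (the
threshold is a package choice for "highly correlated"); zero-variance
columns are dropped with a log entry. The stored transform record
re-applies the exact same centering, scaling and column selection to new
data. Splits are stratified per class (models are per-class), with
round(0.8·n) training members and at least one test member, under a
recorded seed.

The estimator registry wraps established learners — xgboost gradient
boosting, random forest, kernlab Gaussian process, e1071 SVR, glmnet
ridge/lasso — behind a uniform fit/predict/sample/bounds interface.
Partial-least-squares and k-neighbors regression are not registered
because no suitable implementation is available in the package's
dependency set; the registry accepts user-registered kinds. Defaults per
class: gradient boosting everywhere except Trans (random forest) and
Tetra (Gaussian process). Hyperparameter search runs 50 randomized draws
from the documented spaces and then 25 Bayesian (expected-improvement
under a Gaussian-process surrogate) refinements, each scored by 5-fold
cross-validated MAE with seeded fold assignment; the full trace lands in
the bundle manifest. Metrics: MAE; R² (coefficient of determination); r²
(squared Pearson correlation — identical predictions shifted by a
constant keep r² = 1 but lower R²); and Q²F3 = 1 − (PRESS/n_EXT)/(TSS/n_TR),
whose training-set-based denominator makes it robust to the size and
spread of small external sets. q² from 5-fold or leave-one-out
out-of-fold predictions diagnoses stability.

SHAP attributions are exact TreeSHAP for gradient-boosting bundles and a
constrained kernel estimator otherwise: sampled feature coalitions,
interventional expectations over a background sample, and a weighted
least-squares solve with the efficiency constraint eliminated
analytically — so local accuracy (base + Σ contributions = prediction)
holds exactly by construction in both paths, and attribution units are
kcal/mol of predicted ΔΔG‡.

## The synthetic generator and what passing tests mean

The generator grafts fragments from an eight-member vocabulary (H,
methyl, ethyl, trifluoromethyl, methoxymethyl, isopropyl, tert-butyl,
phenyl — spanning the volume and ESP ranges so cascade rules 1–4 are all
exercised) onto the four positions to realize each requested class,
emitting directional SMILES only for stereogenic alkenes. Placement of
the strictly largest fragment pins the hydrogen quadrant of the
trisubstituted classes. Every generated structure is featurized and must
classify to its intended class — a contract enforced at generation.

Synthetic targets follow y = baseline + Σ w_f·z_f + ε with standardized
features z_f, Gaussian ε, and clipping at zero. The baseline default of
1.5 kcal/mol keeps targets on the positive ΔΔG‡ scale typical of the
reaction (the trans-class literature median is ≈1.99 kcal/mol); without
it, clipping would censor half the distribution.

The package's recovery benchmark generates 300 tetrasubstituted alkenes
(the combinatorially richest class, so structures are distinct), injects
w = (0.8, 0.5, 0.4) on Q1 Max Volume, Q2 ESP₉₉ and C1 RDF 3 — one
steric, one electrostatic, one dispersion feature — at σ = 0.15 kcal/mol,
and demands test MAE ≤ 0.25 kcal/mol with the three injected features in
the top-4 mean-|SHAP| ranks. A gradient-boosting model is used for this
study (the workhorse architecture; exact TreeSHAP keeps 240 attributions
cheap). Passing shows the pipeline is information-preserving and the
attribution faithful under a known ground truth. It does *not* show that
real SAD selectivity is predictable at that error: real data carry
DFT-level electronic structure, publication-bias skew, heteroatom
chemistry outside the vocabulary, and experimental noise that the
generator does not emulate. Reproducing the literature-scale models
requires the curated reaction database and quantum-chemical descriptors,
both outside this package's scope.

## Numerical choices and degenerate inputs

* Volume grid 0.2 Å, four-offset averaged; vdW radii from the Bondi
  compilation (H = 1.10 Å); polarizabilities from the CRC atomic table.
* ESP percentile by nearest rank; fully buried fragment surfaces return
  zeros rather than NA.
* BFS fragment order breaks ties by canonical atom rank, making fragment
  signatures and the cascade tie-break reproducible.
* Conformer RMSD pruning uses Kabsch superposition on heavy atoms.
* Rigid molecules replicate their base conformer to the requested
  ensemble size instead of returning a singleton.
* The Q²F3 denominator guards against constant training targets (an
  undefined-metric error rather than Inf).
* All stochastic stages — embedding, torsion driving, set generation,
  noise, splits, folds, search, coalition sampling — consume explicit
  seeds; RNG state is saved and restored around every seeded block.

## Known limitations

Electronic descriptors are Hückel-level surrogates, not NBO observables;
ESP statistics derive from empirical point charges, not quantum ESP
grids. Aromatic and cumulated C=C bonds are never treated as the target
alkene, and tautomers/protomers are not enumerated. Mapping covers clean
dihydroxylation products (reactant skeleton + two hydroxyls); rearranged
or derivatized products are reported as unmapped. Symmetric-alkene
feature vectors depend mildly on the embedded conformer's asymmetry.
Diastereoselectivity of chiral substrates is out of scope — the modeling
scale is the magnitude of enantioselectivity of achiral alkenes.
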