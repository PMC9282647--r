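---
title: "Structure-based hERG liability classification: models and methods"
author: "hergsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based hERG liability classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergsift)
```

## The problem

Drug-induced blockade of the hERG potassium channel (Kv11.1) prolongs the
cardiac QT interval and can trigger fatal arrhythmia, which makes hERG the
primary antitarget screened during early drug discovery. Most in-silico
hERG filters are ligand-based (QSAR, pharmacophores) and inherit the
restricted applicability domain of their training chemotypes. A
structure-based alternative starts from molecular docking into the channel's
central cavity: every candidate compound receives a docking score (DS) and a
docked pose, and a classifier built on those outputs can in principle be
applied to any chemotype that docks.

`hergsift` implements the post-docking half of that workflow. It never runs
a docking engine; it consumes poses and scores (GLIDE-style kcal/mol,
lower-is-better, or GOLD-style fitness, higher-is-better — the orientation
is always explicit configuration, never inferred) and produces:

1. a curated, thresholded binder/nonbinder dataset from ChEMBL-style
   bioactivity tables;
2. per-residue protein–ligand interaction fingerprints (IFs) from docked
   poses;
3. an L1-regularised linear SVM on the docking score alone ("DS model") or
   fused with the fingerprint bits ("DS/IF model");
4. an external-validation protocol with balanced resampling, metric
   distributions and Kolmogorov–Smirnov (KS) model comparison;
5. a practically usable DS decision threshold, and a KS-occurrence ranking
   of the binding-site interactions associated with high binding affinity.

## Data curation and labelling

Bioactivity tables are filtered in a fixed order, with an audit count after
each step: IC50-only annotations; human target organism; direct-binding
("B") assays; no data-validity warnings; parsable structures; molecular
weight within [200, 600] Da; structural duplicates collapsed. The duplicate
key is the canonical SMILES of the desalted parent (largest fragment); among
duplicates the record with the lowest IC50 is kept, which is the
conservative choice for a toxicity endpoint. IC50 values arrive in nM
(ChEMBL `standard_value` convention, a units column overrides) and are
converted to µM internally. The ChEMBL sentinel "not a number" is recognised
case-insensitively in the activity value field.

Labels use two thresholds: binders have IC50 ≤ 1 µM; nonbinders have
IC50 above an *inactivity threshold* chosen from 1–80 µM (80 µM default),
plus the sentinel records; compounds strictly between the bounds are
excluded. Raising the inactivity threshold can only shrink the nonbinder
set, a monotonicity property the tests check.

Internal diversity is the mean pairwise Tanimoto distance over hashed
circular fingerprints. No installed R package provides Morgan/ECFP-style
fingerprints, so the package computes its own atom-environment fingerprint
on the molecular graph parsed by ChemmineR/OpenBabel: the initial atom
invariant is (element, heavy degree, total hydrogen count, with implicit
hydrogens estimated from default valence minus the bond-order sum), refined
for two rounds over bonded neighbours, and all identifiers from radius 0–2
are folded into 2048 bits with a mixed polynomial string hash. The pairwise
loop is exact (bit-matrix cross products), not sampled. Representative
compounds are chosen by k-means (k = 5) on the binary fingerprint vectors,
taking the lowest-IC50 member of each cluster — the protocol used to pick
ligands for induced-fit docking.

## Binding site and interaction fingerprints

The common binding site is every residue with a heavy atom within 9 Å of
any heavy atom of the reference pose (conventionally the best-scoring
docked molecule). hERG is a homotetramer, so residue keys are
monomer-collapsed: the four chain copies of residue 656 are one key
`656_PHE`.

Each site residue contributes a nine-bit string, in fixed order: any
contact, backbone contact, side-chain contact, polar-residue contact,
hydrophobic-residue contact, H-bond with a binding-site acceptor, H-bond
with a binding-site donor, aromatic-residue contact, charged-residue
contact. A bit is 1 when the interaction occurs in *at least one monomer*
(elementwise OR over chains). Every specific bit implies the contact bit.

The nine interaction categories come with SIFt-convention geometry, since
the category definitions alone do not fix thresholds:

* contact: any heavy-atom pair ≤ 4.5 Å;
* H-bond: donor–acceptor heavy-atom distance ≤ 3.5 Å, with a D–H⋯A angle
  ≥ 120° applied only when explicit hydrogens are present (all geometric
  rules work heavy-atom-only, matching how docked poses are usually
  delivered);
* class bits: contact with a residue in the corresponding class set —
  hydrophobic {ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO, TYR}, aromatic
  {PHE, TYR, TRP, HIS}, polar {SER, THR, ASN, GLN, CYS, TYR, HIS}, charged
  {ASP, GLU, LYS, ARG, HIS}; overlaps are intentional.

Protein H-bond atoms are typed by a per-residue table (backbone N donates,
backbone O/OXT accept; side-chain atoms per residue). Ligand N/O atoms are
donors when they carry a hydrogen or a formal positive charge and acceptors
unless positively charged; when a pose has no hydrogen information, N/O
atoms are treated as both, a deliberately permissive fallback. All cutoffs
and class sets are configuration (`geometry_rules()`) and are recorded in
the JSON manifest written next to every fingerprint table. Because the
original fingerprints were produced by a proprietary tool whose thresholds
are undisclosed, numerical identity with them is not claimed anywhere; the
engine is instead validated bit-for-bit against an independent brute-force
all-pairs oracle on randomized synthetic complexes, plus rigid-motion
invariance, cutoff monotonicity and the OR-merge identity.

## The classifier

Features combine one continuous predictor with binary ones: the docking
score is standardized, $DS_{st} = (DS - \mu)/\sigma$, with $\mu, \sigma$
estimated from the *training* scores only and applied unchanged to external
compounds (the leakage-free reading of "observed DSs"); fingerprint bits are
recoded −1/+1 for absence/presence. Binders are encoded +1.

The model is a linear SVM with an L1 penalty,

$$\min_{w, b}\; \frac{1}{n}\sum_i \ell\big(y_i (w^\top x_i + b)\big) + \lambda \lVert w \rVert_1,$$

with $\ell$ the hinge loss smoothed by a small Huber zone (half-width
δ = 0.1) so the objective has a Lipschitz gradient. Optimisation is FISTA
proximal gradient with soft-thresholding — the same proximal family as the
SpaRSA solver used for the original models — with warm starts along a
descending λ path, convergence tolerance 1e-6 on the objective and at most
10⁴ iterations; the step size comes from a power-iteration estimate of the
spectral norm. Soft-thresholding produces exact zeros, so the selected
interactions are read directly off the nonzero weights.

λ is searched over 20 log-spaced values in (10⁻³, 1). Selection uses
held-out classification error on stratified 20% tuning splits of the
training partition, averaged over 5 random splits, and takes the sparsest λ
within one standard error of the minimum (the `lambda.1se` convention).
Two design points deserve a note, because a simpler scheme was tried first
and proved wrong in a measurable way: a *single* 20% split of ~100-compound
training sets selects λ with high variance, and plain minimum-error
selection over-selects, occasionally keeping a quarter of deliberately
uninformative noise bits. Averaged splits plus the one-SE rule zero all
planted noise bits across seeds while leaving the planted signal and the
DS/IF accuracy gain intact. Ties go to the larger λ, and if the full-data
refit at the boundary λ degenerates to an all-zero model although the
tuning error showed signal, the next tying λ is used.

Prediction is $\mathrm{sign}(w^\top x + b)$; a margin of exactly zero is
called nonbinder. The tie case matters only for degenerate (all-zero)
models, where it pins balanced-set accuracy at exactly 0.5 instead of
leaving it to floating-point noise; the convention is fixed and documented
rather than left implementation-defined.

## Evaluation protocol

Each of 100 repeats draws an external set of 50 binders + 50 nonbinders
without replacement, balances the remaining compounds by undersampling the
majority class, fits the standardizer and classifier on that balanced
training set, and evaluates on the external compounds: ACC, SE, SP, NPV
(undefined denominators yield NA, not an abort), AUC in the Mann–Whitney
form (ties counted half), and — for DS-only models — the DS decision
threshold, found by scanning the observed DS range at step 0.01 and
reporting the midpoint of the two grid points straddling the label flip
(within half a step of the analytic crossing $\mu - b\sigma/w$). Thresholds
are computed per repeat and reported as mean ± sd, matching how the
published threshold tables carry standard-deviation columns. Per-repeat RNG
streams derive from (seed, repeat index), so runs are reproducible and
adding an extra computed quantity does not perturb the resampling.

Models are compared by two-sample KS tests on their per-repeat metric
samples (statistic $\sup_t |\hat F_1(t) - \hat F_2(t)|$; exact p-values for
min(n) ≤ 25 via the conditional distribution, asymptotic otherwise; no
multiple-testing correction, matching how the original comparisons are
reported).

## Residue importance

For every fingerprint column, the IC50 distributions of interacting
(bit = 1) versus non-interacting (bit = 0) compounds are compared by a KS
test on a random subsample (default fraction 0.8 — the original subsample
size is unstated, so the fraction is configuration and logged), repeated
100 times; the importance of an interaction is the number of trials with
p < 0.05, reported as `557_aromatic[100]`-style labels sorted by
occurrence. The direction call (lower vs higher IC50 for interacting
compounds) compares median log-IC50 on the full data; the KS test itself is
invariant to the log transform. Only lower-IC50-associated interactions are
written to the readable table, mirroring the published convention; the CSV
keeps everything. Rows are canonicalised by compound id before sampling, so
the result does not depend on the caller's row order.

A calibration note: under the null, the fraction of significant
(bit, trial) pairs should be ≈ α. Occurrence counts of a single bit are
strongly correlated across trials when subsamples overlap by 80%, so the
package's calibration test uses many independent bits and few trials per
bit (500 × 20, subsample fraction 0.5), where pair dependence is weak
enough for a tight band around 0.05. This is a property of the test design,
chosen for statistical validity, not of the importance procedure itself.

## Synthetic study conditions

`synthetic_spec()` fixes the reference conditions used by the tests and the
acceptance script:

* 300 binders + 300 nonbinders (large enough for the 50+50 protocol with
  comfortable training remainders, small enough to run on one CPU in
  minutes);
* docking scores Gaussian with means −8 (binders) and −6 (nonbinders),
  common σ = 1 — a two-σ separation on a GLIDE-like kcal/mol scale, giving
  a closed-form ideal AUC of Φ(√2) ≈ 0.9214 against which the DS-only
  pipeline is checked (±0.03);
* a three-residue site (27 fingerprint columns) with three planted bits
  enriched in binders (557_aromatic 0.75/0.25, 557_hydrophobic 0.70/0.30,
  656_contact 0.70/0.30) and all other columns Bernoulli(0.3) in both
  classes;
* IC50 log-normal with median 10 µM and geometric SD 10, clipped to
  1 nM–1 mM, multiplied by `ic50_effect` (default 0.1) once per planted bit
  present.

`make_toy_complex()` builds C*n*-symmetric toy receptors: poly-alanine-style
backbones with one representative side-chain atom per residue (enough to
exercise all nine detectors), chains rotated about a central axis, and
ligand atoms placed at exact requested distances from named receptor atoms
along the inward direction — so the construction itself is the oracle for
geometric tests.

What the generator deliberately does *not* emulate: real pose geometry,
docking-score scales of any particular engine, correlation between docking
score and IC50, fingerprint bit correlations within a residue, or assay
noise structure. Passing the synthetic recovery tests therefore shows the
machinery is correct and calibrated, not that any particular accuracy will
be reached on real docking output.

## Numerical choices and degenerate inputs

* Constant training scores make the standardizer ill-defined and are an
  error, as is single-class training input.
* Metric denominators of zero yield NA metrics; runs continue.
* A DS scan without a label flip returns NA with a warning.
* Alternate PDB locations keep the highest-occupancy copy; non-standard
  residues and waters are excluded from receptors.
* SDF pose records without a score tag are skipped and counted, mirroring
  the exclusion of undocked molecules from the published dataset.
* Importance trials in which a bit has only one value in the subsample are
  skipped for that bit and counted in the `skipped` attribute; fully
  constant columns report zero occurrences and no direction.
* All randomness flows from explicit seeds through `derive_seed()` streams.

## Problem sizes

The test suite and the acceptance script run the full protocol (100
repeats, 50+50 external) on the 600-compound reference conditions, the
fingerprint oracle on 100+ randomized complexes, 1000 AUC enumeration
cases, exhaustive KS permutation enumerations up to n+m = 8, and a 10⁴-pair
KS null calibration — sizes chosen so a complete run finishes in a few
minutes on a single CPU while keeping every statistical band meaningful.

## Known limitations

* The package consumes docking output; nothing here validates the docking
  itself, and the published headline performances (AUC ≈ 0.86 on ChEMBL-
  scale data) require commercial engines and specific receptor
  conformations, so they are out of reach of the bundled synthetic checks.
* Fingerprint geometry is SIFt-convention but not numerically identical to
  the proprietary implementation that produced the original tables.
* No π-stacking plane-angle detector and no salt-bridge-specific detector
  beyond the charged-contact bit — the nine-bit scheme does not include
  them.
* The circular fingerprint is a faithful atom-environment/ECFP-style
  construction but its bit positions are not RDKit- or Canvas-compatible;
  only set-based similarities are meaningful.
* MOL2 poses and bond-order perception beyond the SDF content are not
  supported.
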