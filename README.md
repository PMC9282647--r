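# hergsift

Structure-based classification of hERG channel binders from docking output.

Blockade of the hERG potassium channel (Kv11.1) is the leading cause of
drug-induced QT prolongation and torsades de pointes, which makes hERG the
standard antitarget of early drug discovery. `hergsift` implements the
post-docking workflow for building and validating structure-based
hERG-liability classifiers: it consumes docking scores and docked poses
(it never runs a docking engine) and provides

* **Curation** of ChEMBL-style bioactivity tables into binder/nonbinder
  datasets: IC50-only, human, binding-assay, validity-clean records with
  molecular weight in [200, 600] Da, desalted-parent duplicate collapse, an
  audit count per filter, internal-diversity computation and k-means
  representative selection.
* **Interaction fingerprints**: a 9 Å binding site around the best-scoring
  pose, and per residue a nine-bit string (contact, backbone, side chain,
  polar, hydrophobic, H-bond acceptor of the site, H-bond donor of the
  site, aromatic, charged), OR-merged across the four channel monomers.
* **The classifier** — the package's central model: an L1-regularised
  (LASSO) linear SVM,

  $$\min_{w,b}\ \tfrac1n\textstyle\sum_i \ell\!\big(y_i(w^\top x_i+b)\big) + \lambda\lVert w\rVert_1,$$

  with hinge loss on features combining the standardized docking score
  $DS_{st}=(DS-\mu)/\sigma$ with fingerprint bits coded −1/+1 ("DS-only"
  vs "DS/IF" models). `lasso_svm()` returns a classed S3 object with
  `print`, `summary`, `coef`, `predict` and `plot` methods; sparsity is
  exact (soft-thresholding), so the retained interactions are directly
  interpretable.
* **Validation**: 100-repeat balanced resampling with 50+50 external
  compounds per repeat; ACC/SE/SP/NPV/AUC distributions reported as
  mean ± sd; Kolmogorov–Smirnov comparison of models; docking-score
  decision thresholds from a 0.01-step scan.
* **Residue importance**: KS tests of IC50 distributions for interacting
  vs non-interacting compounds over 100 random subsamples, reported as
  `557_aromatic[100]`-style occurrence tables.
* **Synthetic data**: toy tetrameric receptors with exact ligand-placement
  geometry and score/fingerprint/IC50 datasets with planted structure, so
  the entire pipeline runs and is tested without downloads or commercial
  software.

## Worked example

```r
library(hergsift)

# reference synthetic conditions: DS ~ N(-8, 1) for binders vs N(-6, 1) for
# nonbinders (a two-sigma separation), 27 fingerprint bits of which three
# are enriched in binders, log-normal IC50 with planted effects
d <- make_dataset(synthetic_spec(seed = 42))

proto <- resampling_protocol(n_repeats = 20, external_n_per_class = 50, seed = 42)
dist_ds   <- resample_evaluate(d$ds, d$labels, protocol = proto)
dist_dsif <- resample_evaluate(d$ds, d$labels, d$if_table, protocol = proto)
print(dist_ds)
#> DS model, 20 resampling repeats (mean ± sd):
#>   ACC        0.83 ± 0.04
#>   SE         0.82 ± 0.06
#>   SP         0.84 ± 0.05
#>   NPV        0.83 ± 0.05
#>   AUC        0.92 ± 0.02
#>   threshold  -7.05 ± 0.08
print(dist_dsif)
#> DS/IF model, 20 resampling repeats (mean ± sd):
#>   ACC        0.89 ± 0.02
#>   SE         0.88 ± 0.05
#>   SP         0.89 ± 0.04
#>   NPV        0.88 ± 0.04
#>   AUC        0.96 ± 0.02
compare_models(dist_ds, dist_dsif, "ACC")
#> [1] 0.000153
```

Reading the numbers: the DS-only model's mean AUC (0.92) sits at the
closed-form ideal for a two-sigma score separation, Φ(√2) ≈ 0.9214; its
decision threshold (−7.05 kcal/mol) recovers the midpoint of the two score
populations; and fusing the interaction fingerprints lifts accuracy from
0.83 to 0.89, a difference the KS test calls highly significant — the
qualitative DS/IF > DS result the workflow is designed to expose.

```r
imp <- residue_importance(d$if_table, d$ic50_uM, n_trials = 100, seed = 42)
print(imp, top = 5)
#> Residue-interaction importance (100 KS trials, alpha = 0.05):
#>   557_aromatic[100]
#>   557_hydrophobic[100]
#>   656_contact[100]
#>   557_polar[35]
#>   656_aromatic[18]
```

The three planted interactions are flagged in all 100 trials; everything
else trails far behind (occurrence counts of unplanted bits are noisy
because overlapping subsamples correlate the trials — see the methods
vignette).

A thin command-line wrapper over the same functions ships at
`system.file("cli", "hergsift.R", package = "hergsift")` with subcommands
`simulate`, `curate`, `label`, `diversity`, `representatives`, `site`,
`fingerprint`, `train`, `evaluate`, `threshold` and `residue-analysis`;
every run writes a JSON manifest (config, seeds, input hashes) beside its
outputs.

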