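# aromaQSPR

Quantitative structure–property relationship (QSPR) modeling of odor
thresholds, built for the workflow used to model the aroma components of
wine: a compound's odor threshold (OT, the lowest concentration a trained
panel reliably smells) is modeled as log10(OT in nmol) from numeric
molecular descriptors. The package is aimed at cheminformaticians and
flavor/fragrance researchers who need the *whole* modeling chain —
curation, descriptor filtering, rational dataset division, two-stage
variable selection, PLS regression, a full validation battery,
applicability-domain diagnostics, and wine-level "composite" predictions —
as tested, scriptable R functions rather than a chain of GUI tools.

## The modeling chain

1. **Curation** (`merge_sources`): per-source thresholds are compared on the
   log10 scale; concordant sources (spread ≤ δ, default 1 log-unit) are
   averaged, discordant compounds removed, every decision logged.
2. **Descriptor pre-filtering** (`prefilter`): drop columns with missing
   values, SD < 10⁻⁴, and the later member of every pair with |r| ≥ 0.95.
3. **Rational division** (`kmedoid`, `assign_test`): PAM k-medoid clustering
   (BUILD + SWAP, deterministic) on autoscaled descriptors, then ~25% of
   each cluster — every 4th compound in the distance-from-medoid ranking —
   held out as the test set.
4. **GFA variable selection** (`evolve`): a genetic algorithm over regression
   equations whose terms are either raw descriptors or truncated spline
   basis functions ⟨a − x⟩ = max(0, a − x), scored by Friedman's lack of fit

       LOF = LSE / (1 − (c + d·p)/M)²,

   with c basis terms, p fitted parameters (knots included), M training
   samples and smoothness d (default 1.00; mutation probability 0.5,
   5000 iterations by default, initial equation length 4). The union of
   descriptors in the top 5 equations forms the reduced pool.
5. **Best-subset MLR** (`enumerate_best_subsets`): every size-6 subset of the
   reduced pool (C(32,6) = 906,192 fits run in seconds through a compiled
   kernel) is fitted by OLS and ranked by trimmed-MAE class
   (good/moderate/bad) on a validation set; the union of the top 5 models is
   the final pool.
6. **PLS** (`fit_nipals`, `select_lv`): single-response NIPALS with the
   latent-variable count chosen by honest leave-one-out cross-validation
   (per-fold re-autoscaling), plus `vip` scores.
7. **Validation** (`validation_report`): R², Ra², s, F, Q²(LOO), rm²/Δrm²
   (scaled), R²pred, Q²F2, Lin's CCC, Golbraikh–Tropsha checklist, MAE-based
   criteria — with the standard acceptance thresholds (0.5; CCC 0.750;
   Δrm² ≤ 0.2) and `y_randomization` (R²int < 0.4, Q²int < 0.05).
8. **Applicability domain** (`dmodx`, `hotelling_t2`): DModX with an F-based
   99% critical limit, Hotelling T² ellipse at 95%.
9. **Composite wines** (`composite_descriptors`, `predict_composite`): a
   wine's composite log(OT) is the fitted model applied to the
   (weighted-)mean model-descriptor vector of its aroma components.

`run_pipeline()` chains all stages; `make_study()` generates synthetic
studies with the same statistical structure (correlated descriptor blocks,
pathological columns, planted linear + spline signal) so everything is
testable without proprietary descriptor software.

## Worked example

```r
library(aromaQSPR)

study <- make_study(synthetic_spec(seed = 1))   # 85 compounds + 4 discordant
wines <- make_wines(names(study$y), seed = child_seed(1, "wines"))
cfg <- pipeline_config(
  compounds = study$compounds, descriptors = study$X, wines = wines,
  gfa = gfa_config(population_size = 100, iterations = 500),
  n_perm = 100, seed = 1)
pl <- run_pipeline(cfg)
print(pl)
#> QSPR pipeline: 85 compounds (66 train / 19 test), 100 -> 94 -> 10 descriptors
#> final model: 5 LV | R2 0.903 | Q2 0.853 | R2pred 0.878 | CCC 0.936
#> composite log(OT):
#> wine1 wine3 wine4 wine2
#> 2.347 2.635 2.661 3.156
print(pl$report)
#> R2 0.903 | Ra2 0.885 | s 1.354 | Q2(LOO) 0.853 | rm2(LOO) 0.771 | drm2(LOO) 0.125
#> R2pred 0.878 | Q2F2 0.877 | CCC 0.936 | rm2(test) 0.828 | drm2(test) 0.015
#> MAE class: training good, test good | GT: Passed | overall: all thresholds met
print(pl$randomization)
#> Y-randomization (100 permutations): R2int = 0.108, Q2int = -0.294 -> PASS (R2int < 0.4, Q2int < 0.05)
```

Reading the output: the four discordant literature records were removed at
curation (89 → 85); pre-filtering kept 94 of 100 descriptor columns; the
rational split held out 19 compounds; GFA + best-subset reduced the pool to
10 final columns (two of them spline terms); the 5-latent-variable PLS model
fits the training set with R² 0.903, cross-validates at Q² 0.853, predicts
the held-out set at R²pred 0.878 / CCC 0.936 (all above the acceptance
thresholds), survives response permutation, and ranks the four synthetic
wines by composite log(OT) — lowest first, i.e. the wine whose components
are, on average, the most potent odorants.

Real data enter the same way: a compound CSV (`id,name,smiles,source,ot_nmol`
long format, or pre-curated `id,name,smiles,log_ot`), a descriptor CSV
(first column `id`, any numeric descriptor set), and optionally a wine
composition CSV (`wine_id,component_id[,weight]`). A thin CLI wrapper lives
at `inst/scripts/qspr-pipeline.R`.

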