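# beaknest

Do birds with different beaks build with different materials? `beaknest` is an
R package for linking species-level beak morphology and ecology to
nest-material use across large avian comparative datasets, with explicit
quantification of the two biases that inflate naive results: phylogenetic
signal and class-frequency imbalance. It is aimed at comparative biologists
working with trait databases (beak measurements, body mass, hand-wing index,
diet and habitat factors), literature-derived nest-material descriptions, and
posterior samples of phylogenies.

## What it does

1. **Material coding** (`code_materials`, `resolve_primary`): free-text
   material descriptors are coded into seven categories — binder, fibre,
   grass, leaf, mineral, silk, twig — through an editable exact-match lexicon.
   Each species gets a used-material set, a *primary* material (the category a
   source flags as most used; else the only category; else the first listed;
   `mixed` when sources disagree), and a *specialist* flag (exactly one
   category used).

2. **Random-forest models** (`fit_forest`, `run_binary_models`,
   `run_primary_model`, `run_specialist_model`): bootstrap-aggregated
   classification trees (5000 trees at study scale) predicting material use
   from 12 morpho-ecological variables. All accuracies are out-of-bag (OOB):
   each species is predicted by majority vote of the trees whose bootstrap
   excluded it, so no separate test split is needed. Per-predictor *marginal*
   (full-model accuracy minus accuracy without it) and *independent* (accuracy
   with only it) contributions come from `contribution_analysis`.

3. **Bias controls** (`phylo_null`, `downsample_null`):
   * the *phylogenetic-simulation null* refits every continuous predictor
     under Brownian motion (rate σ², ML-estimated by GLS) and every
     categorical predictor under an equal-rates Mk model on each topology of a
     tree sample, simulates replacement predictors, and re-runs the forest
     against the observed labels — accuracy retained under this null is
     attributable to shared evolutionary history, not ecology;
   * the *downsampling null* repeatedly balances all classes to the smallest
     class size and refits — accuracy lost under this null was majority-class
     guessing.

4. **Confirmatory phylogenetic GLMs** (`beak_pca`, `phylo_logistic`,
   `select_model`): PCA collapses the correlated beak + body-size variables
   (PC1 ≈ size, PC2 ≈ width/depth-to-length shape); binary material use is
   then regressed on standardized predictors with phylogenetically correlated
   residuals, correlation `exp(-α d)` in patristic distance `d` (OU-type
   attraction α; estimating-equation fit). Candidate models are ranked by AIC
   with ΔAIC > 2 treated as a meaningful difference.

5. **Synthetic data** (`synth_config`, `generate_dataset`): Yule trees,
   predictors with tunable phylogenetic signal, and multinomial-logit material
   labels with separately tunable ecological and latent phylogenetic drivers,
   so every stage of the pipeline is testable without external databases.

`run_pipeline` ties the stages together and writes a result bundle (coded
profiles, confusion matrices and heat maps, a five-column per-material summary
table, null distributions, contribution and GLM tables, and a reproducibility
manifest).

## Worked example

```r
library(beaknest)

cfg <- synth_config(n_species = 200, n_trees = 5, seed = 42)
ds  <- generate_dataset(cfg)
table(ds$profiles$primary)
#>  binder   fibre   grass    leaf mineral    silk    twig
#>      34      56      34      18       6      14      38

rfc <- rf_config(n_trees = 100, seed = 7)
run_primary_model(ds$profiles, ds$predictors, rfc)
#> Classifier report (out-of-bag)
#>   overall accuracy: 37.5% (n = 200)
#>   per-class accuracy (%):
#>  binder   fibre   grass    leaf mineral    silk    twig
#>    44.1    71.4     8.8    27.8     0.0     0.0    31.6

labels <- setNames(factor(ds$profiles$primary), ds$profiles$species_id)
phylo_null(labels, ds$predictors, ds$trees, rfc, n_topologies = 3, seed = 7)
#> phylogenetic null: median accuracy 42.0% (IQR 41.5-42.5, 3 replicates)

downsample_null(labels, ds$predictors, rfc, n_reps = 5, seed = 7)
#> downsampled null: median accuracy 21.4% (IQR 21.4-26.2, 5 replicates)
```

Reading: the forest predicts primary material in 37.5% of species — far above
the balanced-chance 1/7 ≈ 14% but close to the phylogenetic null (42.0%), so
on these synthetic defaults (moderate trait signal plus a latent phylogenetic
label component) shared history alone can carry the prediction; balancing the
seven classes drops accuracy to 21.4%, exposing how much of the raw number was
frequency bias. Rare classes (mineral, silk) are never predicted correctly —
the failure mode the downsampling column is designed to reveal.

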