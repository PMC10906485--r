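# birdacuity

Phylogenetically controlled comparative analysis of visual acuity in
birds: how acuity (in cycles per degree, cpd) scales with eye size and
body mass, and how it varies with habitat complexity, light level, diet,
prey mobility and foraging mode — with every analysis run under a
phylogenetic covariance so that related species are not treated as
independent observations.

The package is aimed at researchers in visual and sensory ecology who
have (or simulate) a species trait table and a dated phylogeny, and want
the complete analysis chain in one tested place.

## What it implements

* **PGLS** under the Brownian-motion covariance
  `C[i, j] = shared root-to-tip branch length`, fit by
  `beta = (X' C^-1 X)^-1 X' C^-1 y` through a Cholesky whitening, with
  ML log-likelihoods, AIC (`k = p + 1`), a C-weighted `R^2`, and Cook's
  distances computed on the whitened model (`fit_gls`,
  `cooks_distance_gls`, `exclude_outliers`).
* **Pagel's lambda**: ML estimation of the phylogenetic-signal parameter
  scaling the off-diagonals of `C`, with a likelihood-ratio test against
  `lambda = 0` (`pagels_lambda`, `lambda_transform`).
* **The residual cascade**: *relative eye size* = PGLS residuals of log
  eye size on log body mass; *residual acuity* = PGLS residuals of log
  acuity on relative eye size (`residual_cascade`).
* **All-subsets AIC model selection** over eye size + ecological
  predictors (factors enter as whole blocks), with
  `delta_i = AIC_i - min AIC`, relative likelihoods
  `l_i = exp(-delta_i / 2)` and Akaike weights `w_i = l_i / sum(l_j)`,
  plus a 0.7-threshold collinearity screen (`all_subsets`,
  `fit_subsets`, `rank_models`, `collinearity_screen`).
* **Phylogenetic ANOVA** with a Brownian simulation null (group labels
  fixed, trait resimulated on the tree), Holm–Bonferroni-corrected post
  hoc contrasts and GLS estimated marginal means (`phyl_anova`,
  `posthoc_pairwise`, `holm_adjust`, `marginal_means`).
* **Ecological classifiers**: the strict-70% habitat rule, keyword-table
  light levels with a nocturnal override, the 50% dominant-diet rule,
  prey mobility, far/near foraging modes, acuity unit conversion to cpd
  and per-species record selection (`classify_*`, `to_cpd`,
  `select_record`).
* **A synthetic-data generator** (Yule tree, Brownian log body mass,
  allometric log eye size with slope 0.23, log acuity with slope 0.81,
  clade-clustered ecological categories) whose ground truth drives the
  parameter-recovery tests (`simulate_yule_tree`, `simulate_bm`,
  `simulate_dataset`).
* **An end-to-end pipeline** (`run_pipeline`, `write_report`) and a thin
  CLI (`inst/scripts/acuity_pipeline.R` with `run`, `simulate`,
  `classify`, `anova` subcommands).

## Worked example

Simulate a 94-species dataset with the generator's default structure and
run the full pipeline:

```r
library(birdacuity)

sim <- simulate_dataset(synthetic_params(n_tips = 94, seed = 1))
cfg <- pipeline_config(tree = sim$tree, traits = sim$data,
                       n_sims = 1000, seed = 2)
report <- run_pipeline(cfg)
report
#> Phylogenetic acuity analysis report
#>   species: 89 analyzed (94 in, 0 missing data, 5 outliers excluded)
#>   Pagel's lambda(acuity) = 1.000 (LRT P = 1.8e-24)
#>   acuity ~ eye size: slope = 0.745 +/- 0.111, R2 = 0.34
#>   best model: diet_class + light_class + log_eye_size (weight 0.21)
```

The acuity–eye size PGLS after outlier exclusion:

```r
report$fit_acuity_eye_final
#> Generalized least squares fit (n = 89, df = 87)
#>              Estimate Std.Error      t      p
#> (Intercept)    0.8925    0.3364 2.6535 0.0095
#> log_eye_size   0.7454    0.1111 6.7095 0.0000
#> sigma2 = 0.05752  logLik = 22.637  AIC = -39.27  R2 = 0.341
```

Reading this: the dataset was generated with an acuity–eye size slope of
0.81, and the fitted slope 0.75 ± 0.11 recovers it within one standard
error; lambda is estimated at 1 because the generator's residual noise is
fully Brownian; five species were flagged by the 4/n Cook's-distance rule
and excluded before the refit. One of the fifteen phylogenetic ANOVAs
(foraging mode × log acuity):

```r
report$anova$foraging_mode$log_acuity
#> Phylogenetic ANOVA: F(1, 87) = 2.759
#>   P (classical)     = 0.1003
#>   P (phylogenetic)  = 0.4126   [1000 Brownian simulations, seed 15]
#> Pairwise contrasts (simulation-null p, Holm-adjusted):
#>                  t  p_raw p_holm
#> far vs near -1.661 0.4126 0.4126
```

The classical p-value ignores the tree; the phylogenetic p-value is the
tail frequency of the simulated Brownian null and is the one to report.
Here the generator assigned no foraging-mode effect, and the test
correctly finds none. `write_report(report, "results")` writes the model
tables, contrast table, species table, pruned tree, JSON report and log.

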