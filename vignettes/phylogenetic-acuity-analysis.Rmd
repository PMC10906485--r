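---
title: "Phylogenetically controlled analysis of avian visual acuity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically controlled analysis of avian visual acuity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(birdacuity)
```

## The scientific problem

Visual acuity — the ability to resolve static spatial detail, measured in
cycles per degree (cpd) — varies by two orders of magnitude across birds.
Optics predicts that acuity scales with eye size (longer focal lengths give
finer angular sampling), and visual ecology predicts that species that must
resolve objects from far away (open-habitat species scanning for predators,
raptors and scavengers localizing food at distance) should invest in higher
acuity than species foraging at close range in cluttered, dim habitats.

Comparative tests of these predictions cannot treat species as independent
data points: closely related species resemble each other because they share
evolutionary history. Every analysis in this package therefore runs under a
phylogenetic covariance model, and the package bundles the full chain of
methods needed for such a study: tree handling, PGLS, phylogenetic signal,
model selection, phylogenetic ANOVA, deterministic ecological classifiers,
a synthetic-data generator, and an end-to-end pipeline.

## The statistical model

### Brownian covariance and Pagel's lambda

Under Brownian trait evolution on a rooted tree with branch lengths, the
expected covariance of two tips is proportional to the branch length shared
by their root-to-tip paths. `phylo_vcv()` builds this matrix $C$:
$C_{ij}$ = depth of the most recent common ancestor of tips $i$ and $j$,
$C_{ii}$ = depth of tip $i$. Non-ultrametric trees and polytomies are
handled naturally; ultrametricity is never assumed or checked, because the
supermatrix trees used in comparative work are not guaranteed ultrametric
and the Brownian covariance is well defined regardless.

When a subtree is extracted with `prune_tree()`, the stem between the
original root and the most recent common ancestor of the kept tips is
retained (as `root.edge`) and added to all entries of the covariance, so
that `phylo_vcv(prune_tree(t, S))` equals the corresponding submatrix of
`phylo_vcv(t)` exactly.

Pagel's $\lambda$ scales the off-diagonal entries of $C$:
$C(\lambda) = \lambda C + (1 - \lambda)\,\mathrm{diag}(C)$, interpolating
between star-like independence ($\lambda = 0$) and full Brownian covariance
($\lambda = 1$). `pagels_lambda()` maximizes the intercept-only Gaussian
likelihood over $\lambda \in [0, 1]$ (bounded scalar optimization,
tolerance $10^{-8}$, endpoints checked explicitly) and tests
$H_0{:}\ \lambda = 0$ by a likelihood ratio test.

### PGLS

`fit_gls()` estimates $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 C)$ by generalized least squares,

$$\hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y,$$

computed through the Cholesky factor of $C$ (whitening), with an
eigenvalue-clipping fallback (floor $10^{-10}$) for covariances made
near-singular by zero-length terminal branches. Conventions, chosen once
and used everywhere:

* **Likelihood scale.** All log-likelihoods are maximized (ML, not REML)
  likelihoods, because $\hat\lambda$ and model AICs are compared across
  different fixed-effects structures, and $-2\ln L$ is only comparable
  across models on the ML scale.
* **Reported $\sigma^2$** is the unbiased estimate
  $\mathrm{RSS}_C/(n-p)$; the likelihood itself profiles
  $\sigma^2_{ML} = \mathrm{RSS}_C/n$.
* **AIC** counts $k = p + 1$ parameters (regression coefficients plus
  $\sigma^2$); when $\lambda$ is estimated it adds one more. This
  convention is stated explicitly so that AIC values are reproducible.
* **$R^2$** is the GLS generalization $1 - \mathrm{RSS}_C/\mathrm{TSS}_C$,
  where both quadratic forms are $C$-weighted and the total sum of squares
  comes from the intercept-only GLS fit under the same $C$. It is reported
  only for models containing an intercept.
* **Degrees of freedom** for t-tests are $n - p$; the fit object also
  carries `n_obs`, so either convention can be reconstructed from the
  serialized report.
* **Factors** use treatment (reference-level) coding with the first level
  alphabetically as reference, for determinism.

### Influence diagnostics

Cook's distances are computed on the whitened model: premultiply $X$ and
$y$ by the inverse Cholesky factor of $C$, then apply the textbook OLS
formula. With $C = I$ this is exactly the classical Cook's distance.
`exclude_outliers()` implements two rules: `"4/n"` (exclude $D_i > 4/n$,
the default) and `"topk:K"` (exclude the $K$ most influential species,
which reproduces a fixed-size exclusion set). Exclusion is single-pass:
fit once, exclude, refit once.

A limitation worth knowing: under strong phylogenetic correlation, a
gross error in one tip's trait value spreads into the whitened residuals
of its close relatives, so the 4/n rule may flag a contaminated species
*together with* its sisters, or — for tips on long terminal branches —
absorb the shock into the tip's large conditional variance. Influence
isolation is exact only in the uncorrelated limit, and that is the regime
in which the test suite certifies the rule (a single injected 10-SD
outlier is the unique exclusion in 100/100 replicates under an identity
covariance). On real phylogenetic data the exclusion list should be
reviewed, not consumed blindly — which mirrors how comparative studies in
practice name their excluded species.

### The residual cascade

Two derived quantities isolate different layers of visual investment:

1. **Relative eye size** — residuals of the PGLS regression of log eye
   axial length on log body mass. Positive values mean larger eyes than
   the allometric expectation for that body mass.
2. **Residual acuity** — residuals of the PGLS regression of log acuity
   on relative eye size: acuity beyond what eye investment predicts.

The direction of stage 1 (eye size on body mass, not the reverse) follows
from the interpretation of the residuals as "larger eyes than expected for
their body mass". With zero residual noise the stage-1 residuals are all
zero and stage 2 is rank-deficient; this degenerate case raises an error
rather than returning an arbitrary answer.

### Model selection

`all_subsets()` enumerates all $2^m$ predictor subsets (including the
intercept-only model) in a deterministic order; categorical predictors
enter as whole treatment-coded blocks — a subset either contains the whole
factor or none of it, matching how ecological classifications are treated
as single predictors. For eye size plus five ecological variables this is
a 64-model space, and 32 models when eye size is forced absent.
`rank_models()` computes $\Delta_i = \mathrm{AIC}_i - \min \mathrm{AIC}$,
relative likelihoods $l_i = e^{-\Delta_i/2}$ and Akaike weights
$w_i = l_i / \sum_j l_j$. AIC (not AICc) is the default.

`collinearity_screen()` scores predictor pairs before model building:
Pearson $r$ for numeric pairs, Cramér's V for categorical pairs and the
correlation ratio $\eta$ for mixed pairs, flagging scores strictly above
0.7. The mixed-type measures are a package choice (no single standard
exists); the measure used for each pair is recorded in the output so the
screen is reproducible.

### Phylogenetic ANOVA

`phyl_anova()` computes the ordinary one-way $F$ statistic on the raw
data, then builds its null distribution by simulating Brownian motion on
the phylogeny — rate set to the ML Brownian rate of the observed trait —
with the observed group labels held fixed, recomputing $F$ for each of
`n_sims` simulated traits (the simulation construction of Garland and
colleagues, as popularized by `phytools::phylANOVA`). The phylogenetic
p-value is the +1-corrected tail frequency
$(1 + \#\{F_{sim} \ge F_{obs}\})/(1 + n_{sims})$, which is never exactly
zero. Post hoc pairwise $t$ statistics (pooled within-group variance) are
referred to the same simulation null and Holm-adjusted over the
$L(L-1)/2$ comparisons; classical F- and t-distribution p-values are
reported alongside. A seed is mandatory and results are reproducible
bit-for-bit given `(seed, n_sims)`.

`marginal_means()` estimates per-level means as coefficients of a
cell-means GLS fit under $C$; on a clustered tree these shrink toward
clade root states, so the arithmetic means are reported next to them —
the package emits both rather than deciding which one a reader wants.

### Ecological classifiers

Five deterministic classifiers turn raw trait fields into analysis
categories; all are pure functions and fail loudly on unknown tokens:

* **Habitat complexity** (`classify_habitat`): foraging-stratum
  percentages are summed into spatially complex (understory + mid-high),
  open (aerial + open water) and horizon-dominated (ground + water
  surface + canopy) classes; the class whose sum *strictly* exceeds 70%
  wins (at most one can, when the strata total $\le$ 100), otherwise the
  species is a habitat generalist. Exactly 70 is a generalist, following
  the wording "greater than 70%".
* **Light level** (`classify_light`): nocturnality overrides everything
  (low light); otherwise habitat keywords are matched against fixed
  low/medium/high tables and the majority class over matched keywords
  wins, ties resolving to medium. Unmatched, non-nocturnal species raise
  an error rather than defaulting, because light assignment is otherwise
  a manual judgement.
* **Dominant diet** (`classify_diet`): the three-way aggregation (plants;
  invertebrates; vertebrates including scavenged prey) with a $\ge 50\%$
  dominance rule; no category at 50%, or a 50/50 tie, is an omnivore.
  The mapping from the ten raw diet-score categories ships as an editable
  list (`elton_diet_map`).
* **Prey mobility** (`classify_prey_mobility`): live vertebrates and
  invertebrates count as mobile; plant matter and scavenged prey as
  immobile; an exact tie is flagged for a manual call.
* **Foraging mode** (`classify_foraging`): the species' primary (first
  listed) maneuver decides: aerial chase, pursuit diving, scavenging and
  sallying are distance ("far") maneuvers; gleaning, pecking, dabbling,
  kicking/scratching and probing are close-up ("near") ones. Taking the
  first-listed maneuver as primary is an explicit, overridable package
  decision — the ordering of the input list is the user's statement of
  primacy.

`to_cpd()` converts acuity units: one grating cycle spans two minimum
angles of resolution, so cpd $= 30/\mathrm{MAR(arcmin)}$
$= 0.5/\mathrm{MAR(deg)}$, and cycles per radian convert by $\pi/180$.
`select_record()` resolves multiple records per species: anatomical
(RGC-density) estimates are preferred over behavioral ones, then the most
recent source year, then the highest reported acuity.

## The synthetic-data generator

`simulate_dataset()` generates data with exactly the structure the
analysis assumes, so that parameter recovery is a meaningful test:

* a pure-birth (Yule) tree, grown forward from two lineages with
  exponential waiting times and extended by a final waiting time after the
  $n$-th tip appears, so the expected depth is
  $\sum_{k=2}^{n} 1/(k\,b)$ for birth rate $b$ — the closed form the test
  suite checks against;
* log body mass evolving by Brownian motion
  (`sigma2_mass = 0.6`, root `log(300)` g — giving the roughly 1.5
  natural-log-unit spread of body masses seen across a diverse bird
  sample);
* log eye size $= 1.2 + 0.23 \cdot$ log mass $+$ Brownian noise
  (rate 0.02), the allometric slope matching the scale of published
  eye–mass allometries;
* log acuity $= 0.85 + 0.81 \cdot$ log eye $+$ category effects $+$
  Brownian noise (rate 0.05), centering acuity near 15 cpd for a
  10-mm eye and leaving roughly half the variance unexplained, the
  regime reported for real acuity data;
* five clade-clustered categorical variables mirroring the analysis
  categories, produced by thresholding an auxiliary Brownian trait at its
  level quantiles — this creates the phylogenetically non-random category
  membership that motivates phylogenetic ANOVA in the first place — with
  configurable additive effects on log acuity (all zero by default);
* one shared RNG stream per dataset: a single seed reproduces the tree,
  the traits and the labels byte-for-byte.

Default `n_tips` is 94, the scale of the motivating study; the
recovery simulations in the tests use 200 tips, where the estimator
variance is small enough for tight tolerance bands.

What the generator does *not* emulate, and what passing tests therefore do
not show: measurement error in acuity (literature values mix behavioral
and anatomical assays with different biases), missing data patterns,
model misspecification (real residuals need not be Brownian), and
non-ultrametric study trees (the generator's trees are ultrametric by
construction, though all analysis code accepts non-ultrametric input).

## Numerical and calibration notes

* **Cholesky with clipping.** All covariance solves go through `chol()`;
  on failure the matrix is eigendecomposed and eigenvalues floored at
  $10^{-10}$. This handles zero-length terminal branches gracefully while
  still erroring on genuinely singular cases.
* **Boundary LRT for $\lambda$.** The default p-value uses the plain
  $\chi^2_1$ upper tail, which is conservative at the $\lambda = 0$
  boundary; the 50:50 point-mass/$\chi^2_1$ mixture is available via
  `mixture = TRUE`. The test suite measures the realized size of both: at
  200 tips even the mixture test is conservative (the ML estimate sits
  exactly at the $\lambda = 0$ boundary far more than half the time), a
  finite-sample property this implementation shares, statistic-for-
  statistic, with the reference implementation in `phytools`. Interpret a
  significant $\lambda$ LRT with confidence; interpret a non-significant
  one as weaker evidence than its nominal level suggests.
* **Monte Carlo sizes.** The calibration tests use 100–500 replicates per
  condition and 500 Brownian simulations per ANOVA — sizes chosen so that
  Monte Carlo standard errors are comfortably inside the tolerance bands
  being asserted (for a rate near 0.05, 500 replicates give a standard
  error just under 0.01).
* **Determinism.** Every stochastic operation takes a seed; the pipeline
  derives per-analysis seeds from the single configured seed, so a full
  report is reproducible from its configuration alone (the report records
  a configuration hash and the package version).

## The pipeline

`run_pipeline()` executes the full analysis in a fixed order: record
selection and unit conversion; ecological classification; dropping species
without eye size or body mass; pruning the tree to the analyzed species;
log transforms (natural log by default, configurable and recorded);
Pagel's $\lambda$ on acuity; the acuity–eye size PGLS with Cook's distance
exclusion and refit; the collinearity screen; 64- and 32-model AIC tables;
the residual cascade; and phylogenetic ANOVAs with post hoc contrasts and
marginal means for every ecological variable crossed with acuity, relative
eye size and residual acuity. Species are conserved exactly across stages
(input = analyzed + missing-data drops + outlier exclusions), and
`write_report()` serializes the result as JSON, tidy CSVs, Newick and a
log. A thin command-line wrapper (`inst/scripts/acuity_pipeline.R`) exposes
`run`, `simulate`, `classify` and `anova` subcommands.

```{r, eval = FALSE}
sim <- simulate_dataset(synthetic_params(n_tips = 94, seed = 1))
cfg <- pipeline_config(tree = sim$tree, traits = sim$data,
                       n_sims = 1000, seed = 2)
report <- run_pipeline(cfg)
report
write_report(report, "results")
```

## Known limitations

* Only Brownian (and $\lambda$-scaled Brownian) correlation structures;
  no Ornstein–Uhlenbeck models, mixed models or measurement-error models.
* The $\lambda$ LRT is conservative in finite samples (above).
* Cook's-distance exclusions on strongly correlated data can implicate
  relatives of a contaminated tip (above).
* The ecological classifiers implement fixed keyword tables and rules;
  species outside those vocabularies fail loudly by design and need a
  manual assignment upstream.
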