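# carafa

Three-layer analysis of ground-beetle (Carabidae) responses to forest
management: assemblage composition, body-trait models, and developmental
instability measured by fluctuating asymmetry (FA).

Forest interventions (clearings, the ecotones they create, and closed
control stands) reshape beetle communities — but presence/absence alone
says little about how stressful the new habitat is for the individuals in
it. carafa links three complementary signals, for ecologists and
entomologists working with pitfall/emergence trap data and repeated
bilateral measurements:

1. **Assemblage layer.** Partial canonical correspondence analysis of the
   sample × species matrix on environmental constraints, with month and
   air temperature partialled out. Significance uses a restricted
   Monte-Carlo permutation test — independent random **cyclic shifts**
   within each site's monthly series, preserving temporal
   autocorrelation — and forward selection with Benjamini–Hochberg
   adjustment. Identity traits are summarised as community-weighted means
   (CWM) and Rao's quadratic entropy `Q = Σᵢⱼ dᵢⱼ pᵢ pⱼ`, passively
   projected into the ordination.
2. **Trait layer.** Replicate-based measurement-error (ME) screening
   (sides × individuals ANOVA), then head width modelled on wing-morph
   score (1 = apterous, 2 = brachypterous, 3 = macropterous), treatment
   and body size with `lme4` mixed models and a Bayesian Gaussian
   regression (JAGS) with R-hat and PSIS-LOO diagnostics.
3. **FA layer.** The directional-asymmetry corrected index

       sᵢ = (Rᵢ − Lᵢ) / (0.5 (Lᵢ + Rᵢ)),   FAᵢ = sᵢ − Σ s / N,

   computed per species × trait cohort, guarded by a gating procedure
   that discards traits dominated by measurement error, antisymmetry
   (platykurtic s), directional asymmetry (mean s ≠ 0), and annotates
   size-dependent asymmetry with a body-size covariate. Gated FA is
   modelled against treatment (Tukey LS-means), wing × sex × treatment
   stages (with Levene variance checks), validated across traits by
   Kendall's W, and related to environmental factors by a Bayesian model
   whose effects are read from 95% credible intervals.

A synthetic generator with separable asymmetry components
(`R − L = δ + FA + A`, measurement noise per replicate, optional size
dependence) emulates the study design — 3 treatments × paired transects ×
6 monthly periods, ~26 species — and gives every stage a
parameter-recovery and calibration test.

## Worked example

```r
library(carafa)

run <- run_pipeline(run_config(seed = 7, n_perm = 999))
run$results$assemblage$forward_selection
```

```
            variable explained_pct pseudo_F     p  p_adj selected entry_order
1              herbs         64.62    51.15 0.001 0.0025     TRUE           1
2             litter          6.79     6.42 0.001 0.0025     TRUE           2
3 treatment_clearing          2.07     2.02 1.000 1.0000    FALSE           3
4  treatment_ecotone          0.50     0.49 1.000 1.0000    FALSE           4
5  treatment_control          0.00     0.00 1.000 1.0000    FALSE           5
```

Herb cover drives the simulated composition (it is the generator's
gradient), litter adds a conditional share, and the treatment dummies add
nothing once the gradients are in — the adjusted permutation p-values
say so directly. The FA gating table for the same run:

```r
table(run$results$fa$gating$verdict)
#> antisymmetry      true_FA
#>            1           15
```

fifteen species × trait cohorts pass the gate; one clean cohort is
excluded as platykurtic — at α = 0.05 occasional false exclusions are
expected and preferable to contaminated FA inference. The environmental
Bayesian model on the first gated cohort (effects per SD of each
predictor, response |FA|):

```r
run$results$fa$env_bglm$posterior
#>         term    mean      sd       l95    u95 p_positive rhat n_eff significant
#>  (Intercept) 0.01170 0.18800 -0.361000 0.3780      0.761 1.04 10700           0
#>        herbs 0.00495 0.00293 -0.000733 0.0108      0.954 1.00  8000           0
#>       litter 0.00543 0.00295 -0.000453 0.0113      0.966 1.00  7740           0
#> max R-hat 1.040 (converged); elpd_loo 252.4 (SE 7.7); 93.1% Pareto k <= 0.7
```

No environmental effect is injected in this simulation and none is
declared: both 95% credible intervals cover zero (`significant = 0`).
Layer 1's selected variables (herbs, litter) were handed to layer 3
automatically.

See `vignettes/three-layer-pipeline.Rmd` for the models, the gating
procedure, the generator's parameter card and the package's numerical
choices. A thin shell front-end is installed at
`inst/scripts/carafa-cli.R`
(`simulate | assemblage | traits | fa | run-all | validate`).

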