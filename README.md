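# gutmix

Reverse-oriented weighted quantile sum (WQS) analysis of prenatal lead
exposure and the childhood gut microbiome.

`gutmix` is for environmental-epidemiology and microbiome analysts who
want to relate an early-life exposure to a metagenomic taxa profile
measured later, treating the microbiome as a *mixture*. The package
implements the full analysis pipeline as tested, reusable functions: a
synthetic cohort generator with known ground truth, preprocessing
(relative abundance, two-batch prevalence filtering, decile scoring
with zeros pinned at 0, seeded chained-equation imputation), Shannon /
Bray–Curtis diversity testing (Kruskal–Wallis, adjusted regression,
PERMANOVA with Freedman–Lane residual permutation), the WQS model with
random subsets and repeated holdouts, taxa-wide association with an
eigenvalue-based effective number of tests, and pathway-overlap
summaries for the important taxa.

## The model

Taxa relative abundances are decile-scored within taxon (zeros stay
0). For simplex weights $w$ the mixture index is
$\mathrm{WQS}_i = \sum_j w_j q_{ij}$, and the model — in *reverse*
orientation, an association convention — is

$$\log_2(\mathrm{Pb}_i) = \beta_0 + \beta_1\,\mathrm{WQS}_i + z_i^\top\gamma + \varepsilon_i,$$

with $\beta_1$ sign-constrained during training and $z$ the adjustment
set (child sex, maternal SES, maternal age, maternal BMI, child age,
sequencing batch). Weights are estimated by bootstrap over random
taxon subsets on a training split; $\beta_1$ is re-estimated
unconstrained on the validation split; the distribution of validation
estimates over repeated holdouts gives the point estimate (mean), 95%
interval (2.5–97.5 percentiles), and the fraction of estimates below
zero. Taxa whose weight exceeds the chance threshold $1/c$ in ≥80% of
holdouts are flagged important.

## Worked example

```r
library(gutmix)

cfg <- simulation_config(seed = 7)      # n = 123, 40 taxa, 5 true taxa
sim <- simulate_cohort(cfg)
imp <- impute_covariates(sim$cohort, seed = 3)
Z   <- covariate_design(imp$cohort)
Q   <- decile_score(prevalence_filter(sim$profile, 0.05)$profile)

s <- run_wqs_rsrh(Q, log2(imp$cohort$pb_2t_ugL), Z,
                  wqs_config(n_holdouts = 50, n_bootstrap = 20, seed = 11))
s
#> WQS_RSRH (negative direction): beta = -0.585, 95% HI [-0.905, -0.216]
#> 100% of 50 holdout estimates below zero
#> importance threshold 1/40 = 0.025; 5 taxa important
sort(s$important_taxa)
#> [1] "taxon_01" "taxon_02" "taxon_03" "taxon_04" "taxon_05"
```

The mixture effect is recovered with the right sign (truth: −0.5), the
holdout interval excludes zero, and exactly the five planted taxa —
and none of the 35 noise taxa — clear the importance rule.

The full workflow lives in `analysis/01_simulate.R` …
`analysis/06_pathways.R`: each numbered script is a thin driver over
the package functions that narrates what it finds and writes its
tables under `results/`. A representative run prints, for instance:

```
2T: negative model selected (mean AIC 93.2 vs 117.7); beta = -0.69 [-0.96, -0.36]; 100% of holdouts < 0
  5 taxa above the importance threshold in >=80% of holdouts; 5/5 planted taxa recovered
effective number of tests: 38.0 (of 40 taxa)
pathway overlap: 4 only 2T | 16 common | 4 only 3T
```

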