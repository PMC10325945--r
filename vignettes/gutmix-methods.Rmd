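---
title: "Methods: reverse weighted quantile sum analysis of prenatal lead and the childhood gut microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse WQS analysis of prenatal lead and the gut microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Prenatal metal exposure may leave a lasting imprint on the gut
microbiome of the child. The analysis this package implements relates
maternal blood lead (Pb, µg/L) measured in the second and third
trimesters of pregnancy to shotgun-metagenomic stool profiles collected
from the same children years later. Because the microbiome is measured
after the exposure but modelled as a *mixture* of many correlated,
zero-inflated, compositional taxa, the central statistical tool is a
weighted quantile sum (WQS) regression run in *reverse* orientation:
the taxa mixture forms the index and the exposure is the regression
outcome. This is an association convention, not a causal model — the
index coefficient measures how strongly a weighted combination of taxa
tracks the exposure, and the weights say which taxa carry that
association.

## The model

Each retained taxon is decile-scored within taxon: zero relative
abundance is pinned at score 0, and the non-zero values are
rank-partitioned into ten groups scored 1–10. For weights $w$ on the
simplex ($w_j \ge 0$, $\sum_j w_j = 1$) the mixture index of sample $i$
is $\mathrm{WQS}_i = \sum_j w_j q_{ij}$, and the fitted model is

$$\log_2(\mathrm{Pb}_i) = \beta_0 + \beta_1 \mathrm{WQS}_i + z_i^\top\gamma + \varepsilon_i,$$

with $\beta_1$ sign-constrained (negative or positive, fitted
separately) during weight estimation and $z$ the fixed adjustment set:
child sex, maternal SES (two indicator contrasts, "lower" reference),
maternal age, maternal BMI, child age, and sequencing batch.

Estimation combines two resampling layers:

* **random subsets + bootstrap** (training): each of $B$ bootstrap
  resamples of the training rows fits the constrained model on a
  uniformly random taxon subset of size $\lceil\sqrt{c}\rceil$ for a
  $c$-taxon mixture; weight vectors from converged fits are averaged
  and renormalised. Subsetting keeps the per-fit dimension low when
  taxa are many and correlated.
* **repeated holdouts** (inference): each of $H$ holdouts randomly
  splits the cohort 60/40 ($\lceil 0.6n\rceil$ training subjects, the
  rest validation; 74/49 at the cohort size of 123), estimates weights
  on the training half, then re-estimates $\beta_1$ by *unconstrained*
  least squares on the validation half with the index held fixed. The
  distribution of the $H$ validation estimates is the inferential
  object: its mean is the point estimate, its 2.5–97.5 percentile range
  the 95% interval, and the fraction of estimates below zero a
  direction diagnostic. Re-imposing the sign constraint at validation
  would make that fraction degenerate, so it is deliberately not
  imposed.

A taxon is *important* when its (bootstrap-averaged) weight exceeds the
chance level $1/c$ in at least 80% of the holdouts. The negative- and
positive-direction models are fitted on paired holdout splits and the
final direction chosen by smaller mean validation AIC (ties: BIC, then
log-likelihood; an exact tie returns the negative model flagged
inconclusive).

### Numerical implementation of the constrained fit

The weights are reparameterised by softmax and $(\beta_0, \beta_1,
\gamma)$ profiled out by least squares with $\beta_1$ clipped to the
feasible sign, leaving a smooth objective over $\mathbb{R}^k$ searched
by multi-start BFGS with an analytic gradient (5 starts: uniform
weights plus four random simplex draws; relative tolerance $10^{-8}$,
at most 500 iterations per start). Two guards matter in practice. A
weak ridge on the softmax parameters ($10^{-6}$ of the centred outcome
sum of squares per dimension) removes the softmax shift
non-identifiability and, more importantly, keeps line searches off the
saturated plateaus where a weight reaches exactly 0/1 and the data
gradient vanishes. Second, a solution that still lands deep in
saturation is restarted from a rescaled parameter vector, which
recovers near-boundary optima (e.g. a true $w_1 = 0.94$) that a single
descent can overshoot. Against a dense grid-search oracle on two-taxon
problems the fitted weight agrees to well under the 0.01 grid step.

## Preprocessing decisions

* **Two-batch detection filter.** "Present in at least 5% in both
  batches" is implemented as *prevalence* — non-zero in ≥5% of samples
  within each sequencing batch separately — because 5%/25% are standard
  prevalence cut-offs and a 5% *mean-abundance* rule would retain
  almost nothing in a real gut profile. The mean-abundance reading is
  available behind `metric = "mean_abundance"`. Retained columns are
  not renormalised: the sub-composition keeps each taxon's original
  contribution so results are comparable across cut-offs (5% primary,
  25% sensitivity).
* **Decile scoring pools both batches**; batch enters every model as a
  covariate instead. A per-batch option exists but is off by default.
  Ties share their average rank's group; a taxon with fewer than ten
  distinct non-zero values is still scored, with unequal groups.
* **Exposure transform**: log base 2, after which quartile assignment
  for descriptives cuts at the empirical 25/50/75 percentiles with
  ties going to the lower quartile.
* **Imputation**: covariate missingness (maternal BMI and SES, under
  5%) is completed by seeded chained equations — predictive mean
  matching (5 donors) for continuous columns, a draw from multinomial
  logistic class probabilities for categorical ones, five cycles — and
  a *single* completed dataset is carried forward. Multiple-imputation
  pooling is not used: every downstream model reports one estimate,
  and a fixed seed keeps the whole pipeline reproducible. Observed
  cells are never altered, and PMM guarantees imputed values lie in
  the observed range.

## Diversity analysis

Shannon entropy (natural log) is computed per sample after
renormalising the row, so it is invariant to rescaling; Bray–Curtis
dissimilarity $d(x,y)=\sum|x_i-y_i|/\sum(x_i+y_i)$ is computed on the
*unfiltered* relative abundances by default — the detection filter is a
mixture-analysis device, while diversity conventionally uses the full
profile (a flag allows the filtered table). Alpha diversity is tested
both unadjusted (Kruskal–Wallis across exposure quartiles — the
grouping is an assumption, the source analysis does not state one) and
adjusted (OLS on log2 Pb plus covariates). Beta diversity is tested by
PERMANOVA on the Gower-centred inner-product matrix with sequential
(Type-I) sums of squares, covariates entered first and the exposure
last, so the exposure $R^2$ is covariate-adjusted. The permutation
test is Freedman–Lane: residuals of the Gower matrix under the
covariates-only model are permuted, which preserves exchangeability
under nuisance covariates (permuting raw rows does not). With no
covariates this reduces exactly to the classical raw-permutation test,
and the implementation matches an exhaustive 720-permutation
enumeration at $n = 6$ and vegan's `adonis2` on the observed statistic.

## Taxa-wide association and multiplicity

Each taxon's decile score is regressed on log2 Pb plus the covariates
(Gaussian linear model; decile outcome chosen for robustness to
compositional skew, raw relative abundance available behind a flag).
Raw p-values are reported volcano-style, and the Bonferroni level is
softened to $\alpha / m_\mathrm{eff}$ with the Li–Ji effective number
of tests
$m_\mathrm{eff} = \sum_i [\,\mathbb{1}(|\lambda_i|\ge 1) + (|\lambda_i| - \lfloor|\lambda_i|\rfloor)\,]$
over eigenvalues $\lambda$ of the taxa correlation matrix (computed on
the decile-scored analysis matrix; the simpler eigenvalue-variance
form is available as `method = "nyholt"`). Independent columns give
$m_\mathrm{eff} = M$; a perfectly correlated pair collapses to one
test. On the default 40-taxon synthetic panel $m_\mathrm{eff}$ lands
near 37 — the reciprocal of the 0.027 importance threshold a
37-component index yields.

## Pathway overlap

Pathways of the important taxa are extracted from a stratified
pathway-abundance table, ranked by *occurrence frequency* (the number
of important-taxon strata carrying the pathway; summed abundance only
breaks ties, with lexicographic id as the final key, making top-20
lists deterministic), and the two trimesters' lists partitioned into
unique/common/unique sets. Frequency rather than abundance is the
primary key because the scientific question is how widely a function is
shared across the flagged taxa; an abundance ranking is available.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the statistical structure the analysis
assumes, with known ground truth: 123 subjects in sequencing batches
of 50 and 73; 40 species-level taxa drawn zero-inflated
Dirichlet-multinomial (structural absences mask concentration
parameters *before* the Dirichlet draw, so compositions stay valid by
construction; batch 2 concentrations are multiplicatively shifted to
create a mild batch effect); covariates in plausible cohort ranges
with MCAR missingness on maternal BMI and SES only; and exposures
generated from the *same decile index the mixture stage fits* — five
important taxa at weight 0.2, mixture effect −0.5 per index unit on
log2 Pb, residual SD 0.25, trimesters correlated at 0.7 on the log2
scale, intercept calibrated so median Pb sits near the cohort's
33.6/34.9 µg/L trimester means. Sequencing depth is fixed at 10^5
reads per sample; the default concentration profile decays
geometrically and sums to 10, giving the strong overdispersion and
rank-skew typical of stool metagenomes. Using decile scores as the
generative covariate makes parameter recovery well-posed — the
estimand the WQS stage targets is exactly the generated one.

What it does *not* emulate: real taxonomic correlation structure
beyond compositional closure, depth variation across samples, strain
mixtures, batch effects on detection efficiency, informative
missingness, or mechanistic pathway abundances (the pathway table used
with synthetic cohorts is itself synthetic and only exercises the
bookkeeping). Passing recovery tests therefore demonstrates that the
estimator recovers the model it assumes at the study's size and noise
level, not that the model is correct for any particular real cohort.
The distributional defaults are stated assumptions, not values
inferred from data.

## Validation scales and behaviour

The test suite exercises the stack at the cohort's size with reduced
resampling (50 holdouts × 20 bootstraps; the full analysis
specification is 200 × 100): across 20 replicate signal cohorts
essentially all holdout estimates fall below zero and the five planted
taxa clear the importance rule on seed-averaged importance fractions
while virtually no noise taxa do; across 20 replicate null cohorts the
95% percentile interval covers zero in at least 90%. At this reduced
resampling a single replicate's per-holdout weight average is still
noisy — in a few cohort draws one true taxon's importance fraction
lands just under 0.8 because its realized decile column happens to be
only weakly correlated with the exposure (a compositional sampling
effect) — which is why recovery is judged on fractions averaged across
replicates. PERMANOVA calibration uses 200 null datasets at
$n = 40$ with 499 permutations; the full pipeline runs at 10,000
permutations.

## Known limitations

* The reverse orientation estimates association, not effect; weights
  are not variable-importance measures in any causal sense.
* The subset size $\lceil\sqrt{c}\rceil$, unweighted bootstrap weight
  averaging, and percentile-interval construction are declared choices
  where the repeated-holdout WQS literature leaves them open; a
  signal-weighted averaging option exists behind a flag.
* Holdout splits are unstratified; with markedly unbalanced batches a
  stratified option would be a natural extension.
* The chained-equation imputation returns one completed dataset;
  between-imputation variance is not propagated. At under-5%
  missingness on two columns this is negligible next to the holdout
  resampling variance.
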