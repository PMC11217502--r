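---
title: "Models and methods behind metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

Breeding programmes evaluate a panel of genotypes across several seasons in
replicated trials and must pick entries that are both *good* (high trait
mean) and *dependable* (small genotype-by-season interaction). The motivating
application is fresh seed dormancy in Spanish-type groundnut — freshly
harvested seeds that refuse to germinate for 2–3 weeks resist pre-harvest
sprouting — screened alongside economic traits (pod yield per plant, hundred
pod weight, hundred kernel weight, shelling percentage). `metstab` implements
the full selection toolchain for such data: pooled ANOVA, AMMI, stability and
superiority indices, BLUP-based prediction, and a dormancy screening layer.

## The AMMI model

For a balanced trial with $G$ genotypes, $E$ environments (seasons) and $R$
replicate blocks nested in environments,

$$y_{ijr} = \mu + g_i + e_j + \sum_{k} \sqrt{\lambda_k}\,
\alpha_{ik}\gamma_{jk} + \eta_{ij} + \varepsilon_{ijr},$$

with additive genotype and environment main effects, a low-rank
multiplicative interaction (the singular value decomposition of the
double-centered cell-means matrix), and residual error. `pooled_anova()`
computes the additive decomposition (sources ENV, REP(ENV), GEN, ENV:GEN,
Residuals; ENV is tested against REP(ENV), everything else against the
pooled residual). `ammi_decompose()` double-centers the $G \times E$ cell
means, takes the SVD, and reports eigenvalues $\lambda_k$ (cell-mean scale;
the interaction SS on the replicate scale is $R\sum_k\lambda_k$), orthonormal
genotype/environment scores, and each axis's share
$\theta_k = 100\,\lambda_k/\sum\lambda_k$ of the interaction SS.

Numerical conventions:

* **Sign**: the SVD is sign-ambiguous per axis; each axis is flipped so that
  its largest-magnitude environment loading is positive. Results are then
  reproducible across linear-algebra backends.
* **Axis significance**: the default per-axis test is an F ratio on Gollob
  degrees of freedom $G + E - 1 - 2k$ against the pooled residual mean
  square. This is the conventional choice and what starred PC rows in
  published AMMI tables correspond to, but it is *liberal*: under a
  pure-noise interaction the leading eigenvalue concentrates sum of squares,
  and the acceptance suite measures its empirical size near 0.10–0.12 at
  $\alpha = 0.05$ (a behaviour documented since Cornelius 1993). The
  sequential $F_R$ test (`test = "fr"`), which tests the interaction
  remaining after the first $k-1$ axes, holds close to nominal size and is
  provided as the alternative for users who need calibrated axis selection.
* **Counted significant axes**: at most 2 by default (`max_significant`),
  at least 1 — stability indices conventionally use the first two axes,
  and published tables print exactly PC1 and PC2.

Trait values can be log-transformed for normalisation before any analysis
(`log_transform()`, natural log with a configurable offset defaulting to 1
because 0% dormancy values occur). The transform is applied at the record
level and recorded in the table's provenance: transforming and then
averaging replicates is *not* the same as averaging and then transforming,
so the transform is optional and off by default — all published-table
arithmetic reproduces on the untransformed scale.

## Signal and noise in the interaction

The interaction SS mixes repeatable structure with sampling noise. The noise
share is estimated as $\mathrm{df}_{\mathrm{GSI}} \times
\mathrm{MS}_{\mathrm{Residuals}}$ (the expected contribution of replicate
error to the interaction SS) and the signal is the remainder, clamped at
zero with a warning if the estimate is negative. `partition_signal_noise()`
reproduces published signal/noise tables exactly from the printed degrees of
freedom and mean squares.

## Levene homogeneity across seasons

Pooling seasons assumes homogeneous error variance. The test operates on the
within-environment RCBD residuals
$y - \bar y_{g\cdot} - \bar y_{\cdot r} + \bar y$, not raw values, because
the hypothesis concerns *error* mean squares. Classic Levene machinery (a
one-way ANOVA on absolute deviations) assumes independent observations;
applied verbatim to residuals it is anti-conservative, because each
environment's $GR$ residuals span only $(G-1)(R-1)$ free dimensions. The
default therefore weights each environment by that effective residual df in
the between-group sum of squares and refers $W$ to
$F(E-1,\, E(G-1)(R-1) - E)$; simulation in the acceptance suite confirms the
size is close to nominal. `weights = "count"` restores the textbook
statistic, and `center = "median"` gives the Brown–Forsythe variant.

## Stability and superiority indices

* **ASI** (`asi()`): $\sqrt{\sum_k \alpha_{ik}^2 \theta_k^2}$ over the
  significant axes, $\theta_k$ as fractions. The closed form is not printed
  in the source literature (it is attributed to Jambhulkar et al. 2014);
  this definition — squared scores weighted by squared interaction shares —
  is stated as the package's own contract, with `n_pcs` exposed because
  whether a published analysis used exactly 2 or all significant axes is
  generally not recoverable from printed ranks. Fraction (0–1) weights
  rather than percents keep ASI scale-free; either convention gives the
  same ranks.
* **SSI** (`ssi()`): the rank sum $r_{\mathrm{ASI}} + r_Y$. Ranks use the
  average-rank tie rule, so fractional ranks (6.5) occur and every rank
  column sums to $G(G+1)/2$. The mean-performance ranking direction is
  descending for every trait here — including dormancy intensity, where
  *more* dormancy is better — and configurable per trait.
* **YREM** (`yrem()`): $Y_{ij} = X_{ij}/\max_i X_{ij}$ per environment;
  the across-season average is 1.0 exactly when a genotype suffers no
  crossover interaction, and $1 - \mathrm{avg}$ is the fraction of
  attainable performance lost. A zero cell mean is legitimate (fully
  non-dormant lines score 0% dormancy); only a non-positive environment
  maximum is an error.

## BLUP, heritability and WAASB

Variance components come from the expected-mean-squares identities of the
balanced design ($\hat\sigma^2_e = \mathrm{MS}_R$;
$\hat\sigma^2_{ge} = (\mathrm{MS}_{GE} - \hat\sigma^2_e)/R$;
$\hat\sigma^2_g = (\mathrm{MS}_G - \mathrm{MS}_{GE})/(RE)$), which coincide
with REML there; negative estimates are clamped to zero and flagged. On the
entry-mean basis the reliability
$H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/E + \sigma^2_e/(ER))$ is both
the broad-sense heritability and the BLUP shrinkage factor, so predicted
means are $\mu + H^2(\bar y_i - \mu)$: between the grand mean and the
observed mean, and in the same order as the observed means. Selection
accuracy is $A_s = \sqrt{H^2}$ (the model correlation between predicted and
true genotypic values — the published range 0.98–1.00 admits other
estimators, so this definition is stated explicitly), and
$CV = 100\,\hat\sigma_e/\mu$.

WAASB scores each genotype by the weighted average of its absolute axis
scores from the SVD of the *BLUP-scale* interaction — the double-centered
cell means shrunk by $\sigma^2_{ge}/(\sigma^2_{ge} + \sigma^2_e/R)$ — with
weights equal to each axis's share of interaction variance, summed over all
axes. The $Y \times$ WAASB plane is cut at the trait grand mean and the mean
WAASB into four quadrants (IV = above-mean trait, below-mean WAASB:
productive and broadly adapted). Boundary ties resolve toward the favorable
side, so a genotype exactly on both thresholds lands in quadrant IV.

## Dormancy screening

Intensity of dormancy is the percentage of seeds not germinated by day $d$:
counts are pooled over replicates (robust to unequal seed totals — the
pooled value is the count-weighted average of per-replicate percentages) at
the latest recorded day at or before $d$. Classification uses IOD at 21 days
after sowing: dormant above 80 (the level at which the allele-specific
marker co-segregates with phenotype), non-dormant below 20. The source
literature uses both 10 and 20 as the non-dormant cut-off in different
places; 20 is the repeated operational threshold and is the default, with
both ends configurable. The per-genotype class is taken from the mean of the
field and laboratory 21-day assays. Marker–phenotype concordance is tabulated
in both discordance directions, with intermediates untestable — dormant
genotypes with negative marker calls are reported as discordant without
interpreting whether they are recombinants or assay failures. Donor
selection (`select_donors()`) applies the active criteria jointly (dormant
with mean IOD21 at least 90; per-trait average YREM thresholds; SSI rank at
most $k$ for at least one economic trait) and attaches the per-criterion
evidence; its output can only shrink as any threshold tightens.

## The synthetic trial generator

`synth_config()`/`generate_trial()` produce trials with known ground truth.
Defaults emulate the groundnut dormancy regime: $32 \times 3 \times 3$,
grand mean 70, $\sigma_g = 25$ (the genotype factor dominates the printed
ANOVA tables at 88–94% of SS, which this reproduces), $\sigma_e = 5$,
unstructured interaction noise $\sigma_\eta = 1$, and a rank-1 structured
interaction scaled so its expected share of the interaction SS is 90% — the
"signal" a stability analysis should recover. Five planted donor genotypes
receive a fixed additive effect of $2.5\sigma_g$ and exactly zero structured
interaction (their score rows are zeroed before the interaction basis is
orthonormalised), emulating the sharply separated, stable dormant checks of
a real panel; the planted entry-mean heritability at these defaults is about
0.96, matching the high-heritability regime reported for dormancy traits.
Germination counts are cumulative binomial draws from per-class dormancy
probability schedules (dormant 0.95 at day 21, hence expected IOD21 = 95;
non-dormant 0.05), forced monotone by construction; the marker panel flips
the true allele with probability 0.1 to emulate discordance.

The default trait is generated on an unbounded scale. Percentage clipping to
$[0, 100]$ is available (`percent = TRUE`, with a reported clipping rate)
but off by default: clipping saturates the dormant tail exactly as real IOD
data saturate at 100%, which is realistic but biases variance-component
recovery, so recovery checks use the latent scale. What passing tests on
synthetic data do *not* show: robustness to unbalanced or incomplete
designs (rejected by contract), non-Gaussian error, spatial field trends,
or correlated germination assays — none of which the generator emulates.

## Problem sizes used by the validation suite

Published-arithmetic checks run on the bundled printed tables (32 genotypes,
3 seasons). Oracle-equivalence checks use random matrices up to $10 \times 5$
against an independent eigendecomposition and Henderson mixed-model-equation
solutions. Recovery runs 200 generator seeds at the default
$32 \times 3 \times 3$ design; calibration runs 1000 null datasets at
$10 \times 3 \times 3$ for the Levene and per-axis F tests. These sizes give
Monte-Carlo standard errors well inside the asserted bands while keeping the
default suite fast.

## Known limitations

* Balanced, complete designs only; no EM imputation of missing cells and no
  REML for unbalanced data.
* One environment axis (seasons); no multi-location factorial structure.
* The Gollob axis test is reported for convention but is liberal (see
  above); use `test = "fr"` where calibrated axis selection matters.
* No GGE biplots, AMMI2 ellipses, or alternative stability statistics
  (Eberhart–Russell, Shukla, Wricke).
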