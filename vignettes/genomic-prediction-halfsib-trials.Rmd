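---
title: "Two-stage genomic prediction for half-sib forage trials: models and design choices"
author: "forageGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic prediction for half-sib forage trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageGS)
```

## The problem

Nutritive quality traits in outcrossing forages such as perennial ryegrass
are expensive to phenotype: plot harvests, freeze-drying, NIRS and wet
chemistry per sample. Breeding programs therefore evaluate *half-sib
families* — seed harvested from each maternal parent after open intermating
(a polycross) — in replicated multi-location trials, and increasingly ask
whether genome-wide markers on the maternal parents can predict family
performance, so that selection candidates need only be genotyped.

forageGS implements the complete statistical workflow for that question,
exercisable end-to-end on synthetic data:

1. **Stage one** — plot-level mixed models estimate variance components,
   heritability and per-family adjusted means (BLUPs).
2. **Stage two** — the adjusted means are regressed on genome-wide markers
   (GBLUP on a relationship matrix, or BayesC$\pi$ on marker dosages) and
   predictive ability is estimated by cross-validation.

## Stage one: the trial mixed models

A plot value for family $i$ in row $j$, column $k$ of replicate $l$ at
location $m$ within population $n$ is modelled as

$$y_{ijklmn} = \mu + g_i + s_m + (gs)_{im} + p_n + b_{nml} + r_{nmlj} +
c_{nmlk} + \varepsilon_{ijklmn}$$

with location $s_m$ and population $p_n$ fixed; family
$g_i \sim N(0, \sigma^2_g)$ (or $N(0, G\sigma^2_g)$ for a supplied genomic
relationship matrix $G$), family-by-location
$(gs)_{im} \sim N(0, \sigma^2_{gs})$, and replicate / row / column effects
nested within their blocks, all independent. Single-location and
single-population reductions drop the terms that collapse (a population
factor with one observed level is removed rather than left to make the
fixed design singular).

`reml_fit()` maximizes the restricted likelihood with average-information
(AI) updates: the AI matrix
$\mathrm{AI}_{k\ell} = \tfrac12 y'PV_kPV_\ell Py$ preconditions a Newton-type
step on the variance components, with step-halving whenever a proposal
would decrease the restricted likelihood, and an EM update as fallback when
no AI proposal is acceptable. Components proposing negative values truncate
to the boundary $10^{-10}\,\mathrm{var}(y)$; a component parked at the
boundary with an outward-pointing gradient is pinned there for the next
step (an active-set treatment — without it, EM crawls toward a vanishing
component at a linear rate and exhausts the iteration cap). Convergence is
declared when the largest relative component change drops below $10^{-8}$,
within 200 iterations; non-convergence is an error carrying the iteration
trace. Standard errors come from the inverse AI matrix at convergence,
BLUPs and fixed effects from the mixed-model equations at the converged
components.

Significance of a variance component uses the likelihood-ratio test
against the model without that term. Because the null value sits on the
boundary of the parameter space the reference distribution is the equal
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, i.e.
$p = \tfrac12 P(\chi^2_1 > \mathrm{LR})$ ($p = 0.5$ when $\mathrm{LR}=0$).
A Wald $z$ from the AI standard error is reported alongside for comparison
with the conventional estimate ± SE presentation.

### Heritability on a family-mean basis

With $s$ locations and $b$ replicates,

$$R \;\text{or}\; h^2 = \frac{\sigma^2_g}
{\sigma^2_g + \sigma^2_{gs}/s + \sigma^2_\varepsilon/(sb)}.$$

The same closed form serves three estimands, distinguished by where
$\sigma^2_g$ comes from: *repeatability* (across-population family
variance), *narrow-sense family-mean heritability* (within-population
variance), and *genomic heritability* $h^2_g$ (family variance under a
marker-based $G$ covariance). `nutritive_trait_components()` ships a
reference table of across-location components for 18 nutritive traits of a
517-family, two-location ryegrass trial series; evaluating the formula on
its sodium row gives $R = 0.75$, on its NDF row $R = 0.62$. Some rows
cannot reproduce their tabulated repeatability from the rounded components
— the tetany-ratio row evaluates to $0.52$ against a tabulated $0.61$
because its components are printed to one significant digit — which is a
rounding artefact of the table, not a property of the formula.

### Genotypic and phenotypic correlation

The genotypic correlation between traits $x$ and $y$ is
$r_g = \mathrm{Cov}_g(x,y)/\sqrt{\sigma^2_g(x)\,\sigma^2_g(y)}$. The
covariance is estimated by the *sum-trait identity*: fit the across-location
model to $x$, $y$ and $x+y$ and take
$\mathrm{Cov}_g = [\sigma^2_g(x{+}y) - \sigma^2_g(x) - \sigma^2_g(y)]/2$.
On balanced data this is algebraically identical to the MANOVA
cross-products estimator (mean squares are linear in the data quadratics,
and the polarization identity converts sums to cross-products); it remains
well defined under mild imbalance, where a literal sums-of-cross-products
implementation would need ad hoc balancing. The equivalence is asserted in
the test suite, not assumed. Estimated $|r_g|$ can exceed 1 because the
components are estimated; such values are clamped with a warning.
Phenotypic correlations are plain Pearson correlations of the family BLUPs.

## Genotypes: from reads to relationships

### Why reads, not genotypes

Low-coverage genotyping-by-sequencing (GBS) yields a handful of reads per
site. At depth $d$, a true heterozygote shows only one allele with
probability $2^{1-d}$ — at the panel's mean depth of ~3, a quarter of
heterozygous genotypes are miscalled homozygous. The package therefore
treats the data as allele read counts, and every statistic states how it
deals with undercalling:

* **Naive calls** (het iff both alleles seen) feed the per-SNP statistics.
  They are unbiased in expectation ($E[X\mid g]=g$) but variance-inflated.
* **Hardy-Weinberg disequilibrium** is measured as
  $\hat D = \hat f_{\text{hom-ref}} - \hat p_{\text{ref}}^2$. Undercalling
  pushes $\hat D$ *positive* at honest sites (apparent heterozygote
  deficit), so the filter `hw_diseq > -0.05` removes only sites with
  apparent heterozygote *excess* — the signature of collapsed paralogs.
* The **filter chain** defaults to call rate $\ge 50\%$, MAF $> 0.05$,
  mean site depth $> 1$ and $\hat D > -0.05$. "Depth > 1" is read as a
  per-site mean (strictly greater), recorded in the filter report so the
  per-genotype alternative stays auditable.
* **Mean imputation** replaces missing dosages by the per-SNP observed
  mean, leaving column means untouched.

### Two relationship matrices

`vanraden_grm()` is the standard
$G = (X-2p)(X-2p)'/(2\sum_s p_sq_s)$ on imputed dosages, with $p$
estimated as half the observed column means (a supplied $p$ is accepted
for closed-form checks and marker-subset work).

`kgd_grm()` estimates relatedness from the raw reads with *no imputation*.
Off-diagonals use only the SNPs covered in both individuals; because read
errors are independent between individuals and naive calls are unbiased in
mean, these entries are unbiased at any depth. The diagonal is the
exception: the naive self cross-product of a heterozygote read at depth
$d$ is inflated by exactly $2^{1-d}$ in expectation,

$$E[(X-2p)^2 \mid g] = (g-2p)^2 + \mathbf{1}\{g=1\}\,2^{1-d},$$

(the derivation is three lines: the miscall moves $(1-2p)^2$ to $4p^2$ or
$4q^2$ with probability $2^{-d}$ each, and
$4p^2+4q^2-2(1-2p)^2 = 2$). Under Hardy-Weinberg proportions the expected
inflation per covered SNP is $2p_sq_s\,2^{1-d}$, which is subtracted
cell-wise so the expected diagonal equals $1+F$ under the binomial
read-sampling model. The correction is validated against a simulation
oracle (true genotypes at depth 2, where the naive diagonal is inflated by
roughly 0.6 while the corrected one is unbiased to within Monte-Carlo
error); it is exact in expectation under Hardy-Weinberg founders and
approximate for strongly inbred individuals, whose heterozygote frequency
departs from $2pq$. Pairs sharing no covered SNP are flagged `NA`;
`complete_grm()` replaces such flags by the unrelated expectation 0 with a
warning when a complete matrix is required for model fitting.

## Stage two: prediction models

Both predictors consume family adjusted means (stage-one BLUPs). No
de-regression is applied: with families balanced across replicates within
each environment, shrinkage is uniform and leaves cross-validation
correlations unchanged up to scale.

**GBLUP** fits $y = \mu + g + e$, $g \sim N(0, \sigma^2_g G)$, by exact
REML: the variance ratio is profiled on the spectral decomposition of the
training block of $G$ (one eigendecomposition, then each likelihood
evaluation is $O(n)$), and GEBVs propagate to unphenotyped individuals
through their $G$ rows. The variance ratio is re-estimated inside every
training fold. GBLUP on a VanRaden $G$ is algebraically identical to ridge
regression on centred marker dosages with penalty
$2\sum p_sq_s \cdot \sigma^2_e/\sigma^2_g$; the test suite asserts that
equivalence to $10^{-8}$ against a normal-equations oracle. KGD-GBLUP is
the same model with the depth-adjusted matrix.

**BayesC$\pi$** places a point-mass mixture on marker effects: each effect
is zero with probability $\pi$, otherwise Gaussian with a shared variance.
The Gibbs sampler (written in C++ for speed, drawing from R's RNG so runs
are reproducible under `set.seed()`) updates the grand mean, each marker's
inclusion indicator and effect jointly, the shared effect variance and the
residual variance (both with scaled-inverse-$\chi^2$ priors,
$\nu = 4$), and $\pi$ from its Beta full conditional under a uniform
prior. Prior scales are set from `r2`, the variance share expected under
the markers (default 0.5). Defaults run 10,000 iterations with 2,000
burn-in; the package's own demonstrations use shorter chains, and a
chain-length stability test verifies that doubling iterations leaves GEBVs
essentially unchanged. Setting `fix_pi = 0` forces all markers into the
model, the ridge limit — the posterior-mean GEBVs then agree closely with
GBLUP, which is both a correctness check and the mechanism behind the
empirical finding that the two methods tie on polygenic traits.

**Prediction bias.** Two regression conventions exist and they are not
interchangeable: `lm(gebv ~ observed)` measures dispersion of the
predictions (doubled GEBVs give slope 2), while the calibration check of
genomic evaluation, `lm(observed ~ gebv)`, has expectation 1 for a
correctly shrunken BLUP-type predictor. `prediction_bias()` exposes both;
the calibration direction is the one with a parameter-free expected value,
and the acceptance suite verifies its mean slope is within 0.1 of 1 over
100 well-specified replicates.

## Cross-validation schemes

* `kfold_cv()` — disjoint $k$-part partitions (default $k=10$), model
  trained on $k-1$ parts; held-out predictions are pooled per
  randomization, giving one Pearson correlation per randomization (default
  5), whose mean is the reported predictive ability.
* `monte_carlo_cv()` — independent 80/20 splits (default 500 iterations),
  one correlation per split.
* `within_population_cv()` — $\lfloor n_p/2 \rfloor$ families drawn from
  every population train a single model per iteration; the held-out half
  of each focal population is scored separately. Per-population training
  counts are configuration because deposited per-population sizes are not
  part of the packaged inputs.
* `marker_density_ladder()` — markers subsampled uniformly per fraction
  (default ten steps from 100% down to 0.1%, including 5%, 1% and 0.5%),
  a VanRaden matrix rebuilt per subset from the unfiltered panel, and
  Monte-Carlo CV run per rung.

All schemes log their partitions, are bit-reproducible under a seed, and
store per-iteration vectors so the summary statistics can be recomputed.

## The synthetic panel: what it emulates, and what it does not

`sim_config()` defaults describe the study conditions the package targets:
five breeding populations whose maternal-parent counts
(102/104/117/110/84) total 517 half-sib families; two locations × three
replicates in a row-column layout with populations blocked; GBS reads with
23% missing genotypes and a zero-truncated-Poisson nonzero depth averaging
2.98 (a plain Poisson cannot produce both numbers at once, which is why
missingness and depth are separate knobs); and per-trait variance
components defaulting to the sodium row of the reference table. Population
allele frequencies drift from shared ancestral frequencies by a
Balding-Nichols model ($F_{ST} = 0.05$ by default — modest differentiation
among advanced breeding populations of one species).

The family effect is split as $0.5\,\mathrm{BV}_{\text{mother}} + d_i$
with $d_i \sim N(0, \sigma^2_g/2)$: the maternal parent contributes half
the family variance through markers, the pollen pool and Mendelian
sampling the other half. Marker-based prediction of family means is
thereby informative but capped near $r = \sqrt{0.5}$ of the family-mean
accuracy, as in a real polycross. Breeding values are centred within
population, matching what stage-one population fixed effects do to the
adjusted means. One seed drives separate streams for founders, reads and
trial, so enlarging the SNP panel leaves the trial's noise draws untouched.

Deliberate omissions, and their consequences:

* **No linkage or LD decay.** Every simulated marker is an independent
  locus, so the "effective number of segments" equals the marker count and
  marker subsampling loses tagging information faster than in a real
  genome. The marker-density plateau is therefore demonstrated on panels
  where relationship capture dominates (see below).
* **No relatedness among parents within a population** (no
  multi-generation breeding history). Combined with population-centred
  breeding values this means the default panel offers *no*
  relatedness signal for prediction, and cross-validated predictive
  ability on it is bounded by the marker-capture term
  $\sqrt{nh^2/(nh^2+m)}$ — low for $m \gg n$. Real multi-population
  training sets owe most of their predictive ability to within-population
  relatedness. Worse than merely low: in cross-validation the hold-out
  GEBVs on such a panel are dominated by a leave-one-out reflection
  (within a population block of $G$, family BLUPs sum to roughly zero, so
  removing family $i$ leaves a training sum of about $-\mathrm{BLUP}_i$),
  and predictive ability comes out systematically *negative* — the
  analysis scripts show this and it is worth knowing about for any panel
  with block structure but no within-block relatedness. Property tests
  and the acceptance suite therefore build
  sib-group panels (explicit pedigree simulation in test code) when the
  relatedness-driven regime is the object under study; passing those tests
  says the machinery behaves correctly in that regime, not that any
  particular field panel will reach a particular accuracy.
* **No repeated checks** are simulated; the fixed-effect machinery
  accepts them in real data as extra fixed terms.
* **No spatial correlation** (AR1 rows/columns) — row and column effects
  are i.i.d., as in the fitted models.

## Numerical choices, degenerate inputs, sizes

* Constant responses return a boundary fit (all components 0) rather than
  an error; all-missing SNPs are rejected by imputation with an index;
  monomorphic panels are rejected by the VanRaden denominator check;
  fractions yielding zero markers are errors.
* Variance boundaries at $10^{-10}\mathrm{var}(y)$; AI step-halving up to
  $2^{-4}$; relative tolerance $10^{-8}$; 200-iteration cap.
* The spectral GBLUP profiles $\log\lambda$ over $[-25, 25]$, covering
  variance ratios from $10^{-11}$ to $10^{11}$.
* Eigenvalues of estimated $G$ are floored at 0 before use.
* Demonstration sizes: the packaged analysis scripts run a 154-family,
  4,000-SNP panel (the 517-family proportions scaled down) and the test
  suite uses panels of 40–300 families and up to 10,000 markers, with CV
  iteration counts of 15–50 against defaults of 500. These are the
  package's own choices of demonstration scale; all statistical claims are
  size-calibrated (coverage, type-I error, equivalences) rather than tied
  to a particular panel size.

## Known limitations

* The KGD diagonal correction assumes Hardy-Weinberg heterozygote
  frequencies; strongly inbred panels would need the observed-het form of
  the correction (the derivation above supports it for depths $\ge 2$).
* The family-by-location interaction keeps an identity covariance even
  when the family term is marker-based; no marker-by-environment structure
  is fitted.
* REML is dense ($O(n^3)$ per iteration): comfortable to a few thousand
  plots, not designed for tens of thousands.
* Genotypic correlations carry no standard errors.
* The two-stage procedure double-shrinks; with balanced designs this
  rescales rather than reorders predictions, and no de-regression is
  offered.
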