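---
title: "Species diversity and genetic structure in tree communities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species diversity and genetic structure in tree communities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`commdiv` analyses the relationship between plot-level tree species
diversity and the genetic structure of dominant binary (AFLP-type) markers
in a multi-plot forest community.  This vignette is the package's own
account of the statistical machinery: the measures, the models, their
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.  It states no empirical result that the test suite and
the acceptance script do not themselves compute.

## Data model

Two raw inputs drive everything:

* a **binary marker matrix** per genotyped species: one row per individual
  with a species label and a plot label, one 0/1 column per dominant locus.
  A band (call 1) is the dominant variant '1'; absence of a band (call 0)
  means only recessive variants are present (variant '2').  Failed calls
  are `NA` and simply reduce the per-locus sample size; no imputation is
  performed.
* a **plot-by-species abundance table** of tree counts, plus an optional
  census table `N` counting, per plot, the individuals of a species that
  meet a size criterion (DBH &ge; 7 cm).

Because a dominant marker collapses heterozygotes and dominant homozygotes,
all default frequency computations operate on the two band *phenotypes*.
An optional Hardy-Weinberg square-root transform to allele frequencies
(`locus_frequencies(..., scale = "allele")`) exists but is off by default:
it adds a random-mating assumption the phenotype scale does not need.

Loci whose pooled variant frequency is below 0.05 or above 0.95 are
excluded before any analysis (`filter_loci()`).  The bounds are inclusive:
a locus at exactly 0.05 or 0.95 is retained, because the exclusion rule is
a strict inequality.  Filtering uses each species' pooled individuals, not
per-plot frequencies, so the retained locus set is one per species.

## Diversity profiles (Hill numbers)

All diversities are effective numbers of variants,

$$\nu_a = \Big(\sum_i p_i^a\Big)^{1/(1-a)},$$

with $\nu_0$ the richness, $\nu_2$ the Simpson effective number and
$\nu_\infty = 1/\max_i p_i$ the number of prevalent variants.  Plot-level
species profiles report $(\nu_{sp,0}, \nu_{sp,2}, \nu_{sp,\infty})$.
Numerical choices: the order $a = 1$ is evaluated as the Shannon limit
$\exp(-\sum p_i \log p_i)$ whenever $|a-1| < 10^{-9}$, since the general
formula is unstable there; zero-frequency variants are dropped before
evaluating $\sum p_i^a$ (the $0^a = 0$ convention) and never count toward
richness; frequency vectors must sum to 1 within $10^{-6}$.

At a dominant locus the genetic diversity is the effective number of the
two phenotype variants, $\nu_{g,2} = 1/(f_1^2 + f_2^2) \in [1, 2]$, and
$\nu_{mean,2}$ is its unweighted arithmetic mean over retained loci.  Two
small-sample corrections are available:

* `literal_factor` (default): multiply by $n/(n-1)$ — the stated correction
  factor of the source framework, applied literally;
* `unbiased_simpson`: $1 / [(n\sum \hat p_i^2 - 1)/(n-1)]$, the classical
  unbiased concentration estimator.

Both are exposed because the literal factor slightly overshoots (it can
exceed 2 at small $n$) while the unbiased form is the textbook estimator;
reports record which mode produced them.  $\nu_{mean,2}$ is computed per
plot from plot-level locus frequencies (the unit of the covariation
analysis is the plot); a pooled mode is available through the frequency
subset arguments.

## Covariation statistic C

Monotone, not necessarily linear, co-movement of two plot-level variables
is measured by

$$C = \frac{\sum_{i<j} (x_i - x_j)(y_i - y_j)}
           {\sum_{i<j} |x_i - x_j|\,|y_i - y_j|} \in [-1, 1].$$

$C = 1$ iff every non-tied pair moves in the same direction ("entirely
positive covariation"), $C = -1$ iff strictly opposite; ties contribute
zero to both sums, and when the denominator vanishes (a constant variable)
$C$ is *undefined* and returned as `NA`, never as a number.  This rendering
satisfies every property the framework states — bounds, invariance under
increasing affine transforms of either variable, antisymmetry under order
reversal — and is isolated in one function (`covariation()`) so the formula
is swappable.

The one-sided permutation test (`covariation_test()`, default 5,000
permutations) permutes $y$ across plots.  Conventions, fixed a priori:

* when $n! \le$ `n_perm` all orderings are enumerated and the exact plain
  p-value $\#\{C_\pi \ge C_{obs}\}/n!$ is reported (the identity ordering
  guarantees $p > 0$);
* otherwise sampled permutations use the add-one estimate
  $(1 + b)/(1 + B)$, which cannot produce $p = 0$;
* permuted data sets with undefined $C$ cannot be ranked and are excluded
  from numerator and denominator; their count is reported;
* the sampled mode requires a seeded RNG; pipelines record the seed in the
  run manifest.

## Differentiation $\delta$

For each plot $j$, $D_j$ is the $d_0$ (half-$L_1$) distance between the
plot's variant frequency distribution and the pooled distribution of all
remaining plots (its complement), and

$$\delta = \sum_j c_j D_j, \qquad c_j = n_j / \sum_k n_k.$$

$\delta = 0$ iff all plots share one distribution; $\delta = 1$ iff every
plot's variants are absent from its complement.  For species data the
"variant" is the species identity of each tree — one categorical trait;
this species-composition mode is the default interpretation of the
community-level $\delta$, which the discussion of diversifying forces on
*species* diversity supports.  For genetic data $\delta$ is the unweighted
mean of per-locus values over retained loci; both modes are exposed.

The permutation test reassigns individuals to plots uniformly at random
while preserving the observed plot sizes exactly, and reports the
upper-tail add-one p-value.  Significance is declared against the
two-sided Bonferroni criterion $\alpha/(2m)$; with $\alpha = 0.05$ and
$m = 6$ hypotheses this is $0.05/12 \approx 0.004$ — the observed $\delta$
must exceed 99.6% of reassignment values.  The default 5,000 permutations
resolve that criterion; a warning is issued when `n_perm` cannot.

One property worth noting: merging two plots with *identical* frequency
distributions can increase $\delta$ (each half-plot's complement was
diluted by the other half), so $\delta$ is not monotone under plot
aggregation in the direction one might first guess.  The test suite pins
the true direction down by fuzzing.

## Outlier scan for dominant loci

The scan reimplements the multinomial-Dirichlet outlier model for dominant
data.  At locus $i$ in plot $j$ the latent recessive-allele frequency
$q_{ij}$ follows a beta distribution around the ancestral frequency
$\bar q_i$ with concentration $\theta_{ij} = (1 - F_{ST,ij})/F_{ST,ij}$,
and the differentiation decomposes on the logit scale,

$$\mathrm{logit}(F_{ST,ij}) = \alpha_i + \beta_j,$$

into a locus-specific component $\alpha_i$ (positive: more differentiated
than the genome-wide expectation — diversifying selection; negative:
balancing/purifying) and a population component $\beta_j$.  The observed
band-absence count is binomial with
$P(\text{absence}) = q^2 + F_{IS}\, q(1-q)$, one inbreeding coefficient
per population with a uniform prior on $[0, 1]$ (an unusually wide prior,
retained as stated by the source protocol).  Priors: $\alpha_i \sim N(0,1)$,
$\beta_j \sim N(-2, 1.8)$, $\bar q_i \sim U(0,1)$.

A reversible-jump MCMC toggles each $\alpha_i$ between 0 and free with
prior odds 10 for the neutral model; the jump proposes $\alpha$ from its
prior, so the acceptance ratio is the likelihood ratio times the inclusion
odds.  All other parameters move by random-walk Metropolis; 20 pilot runs
adapt the five proposal scales toward 25-45% acceptance and the scales are
fixed thereafter.  Default chain settings are the published protocol's
(5,000 retained samples, thinning 10, pilot length 5,000, burn-in 50,000);
`scan_config(fast = TRUE)` shortens every component tenfold and is the
profile the test suite uses.  This is a reimplementation of the *model*,
not of any particular executable; agreement is assessed by truth recovery
on synthetic data, not bit-level output comparison.

Per locus the scan reports the model-averaged posterior mean of $\alpha$,
the posterior inclusion probability, and a q-value: loci are ranked by
posterior probability and the q-value is the running mean of
$(1 - \text{posterior probability})$ — the expected false-positive
proportion among the loci declared outliers down to that rank.  Posterior
probabilities of exactly 1 are capped at $1 - 1/\text{samples}$ first, so
sampling error never hides behind a q-value of exactly 0.

A calibration fact, obtained by integrating the ideal-data inclusion Bayes
factor (plot frequencies observed exactly, $\beta$ known): a locus whose
per-plot frequencies span a range of 0.6 yields a posterior probability
near 0.90 under prior odds 10 — *below* the 0.95 calling threshold even
with perfect information.  Decisive detection needs ranges around 0.8-0.9.
This is a property of the model's priors, not of the sampler, and it sets
what synthetic experiments can reasonably demand.

## Staged candidate selection

The staged procedure ties the scan to the covariation tests:

1. keep loci with q-value < 0.05, posterior probability > 0.95 and
   $\alpha > 0$;
2. of these, keep loci with at least one covariation test (three diversity
   orders × two genetic variables) significant at the uncorrected 0.05
   level;
3. rank survivors by posterior probability, keep the top $k = 5$; ties at
   rank $k$ are all kept and the family size $m$ grows accordingly (the
   conservative resolution; with fewer than $k$ survivors, $m$ shrinks to
   the survivor count);
4. the selected loci's covariation p-values face the corrected one-sided
   level $\alpha/m$ (0.05/5 = 0.01); a locus is flagged when any of its
   tests passes.

The procedure is deterministic, and the corrected level is Bonferroni
arithmetic throughout — the vocabulary of the staged design mixes FDR and
family-wise notions, but the arithmetic implemented is the division shown
above, plus the scan's own q-value threshold in stage 1.

## Synthetic data generator

`sim_design()` / `gen_community()` / `gen_markers()` emulate the study
design so every stage is testable without field data: 14 plots of 0.25 ha;
4-9 tree species per plot from a pool of 12 with Dirichlet-multinomial
abundances (60-200 stems per plot — gallery-forest magnitudes); one focal
genotyped species with 17-53 individuals per plot (the main species'
sampling range; the associates' 3-17 ranges are reachable through
`sample_size_range`); 240 polymorphic dominant loci; island-model neutral
differentiation with $q_{ij} \sim \mathrm{Beta}(\theta \bar q_i,
\theta(1-\bar q_i))$, $\theta = (1-F_{ST})/F_{ST}$, $F_{ST} = 0.05$ and
ancestral frequencies uniform on (0.1, 0.9); dominant masking with
$F_{IS} = 0.1$ (mostly outcrossing trees); census counts by binomial
thinning (fraction 0.4) of the focal abundance.

Planted structure, recorded in a `truth` attribute on both the allele and
the phenotype scale:

* **outlier loci**: per-plot allele-frequency gradients spanning
  0.05-0.95 — differentiation strength at which the model is decisively
  sensitive (see the calibration fact above);
* **coupled loci**: the plot-diversity ranks ($\nu_{sp,2}$) spaced equally
  over the same range and blended with a neutral draw,
  $q_j = c \cdot \text{rankmap}(\nu_{sp,2,j}) + (1-c) \cdot q_j^{neutral}$,
  so coupling $c = 0$ is exactly neutral and $c = 1$ a deterministic
  monotone function of plot diversity.

What the generator does *not* emulate: spatial autocorrelation between
plots, linkage between loci, mutation, multi-species genotype matrices in
one run, scoring error, and non-equilibrium demography.  Passing
truth-recovery tests therefore demonstrates correctness of the statistical
machinery under the island-model assumptions, not robustness of the field
study's conclusions to violations of them.

## Problem sizes used by the automated experiments

The test suite fixes these sizes as the package's own choices: scan truth
recovery uses 20 seeds of the 14-plot, 100-neutral + 3-gradient-locus
fixture at the tenfold-shortened chain profile; the end-to-end coupling
experiment uses 50 seeds per arm (coupling 0.9 vs 0) of a 100-neutral +
5-coupled-locus design with a further-shortened chain (200 samples,
thinning 5, 5 pilot runs of 150, burn-in 1,000) and 999 permutations per
test; permutation-level control uses 1,000 null data sets of 14 plots at
499 permutations; oracle equivalence checks use 1,000 random series for
$C$ and a few thousand enumerated tiny tables for $\delta$.

## Known limitations

* The scan's likelihood is for dominant biallelic data only; codominant
  markers are out of scope.
* Convergence diagnostics are acceptance-rate bands and split-half
  agreement of inclusion probabilities; no multi-chain statistic is
  computed.
* $\nu_{g,2}$'s literal $n/(n-1)$ correction can exceed the two-variant
  maximum of 2 at very small $n$; the unbiased mode does not.
* Exhaustive permutation enumeration is limited to 9 plots; beyond that
  the sampled mode with the add-one convention applies.
* The species-abundance input counts all stems, while the census variable
  $N$ applies the DBH &ge; 7 cm criterion; when only censused trees should
  drive the species profiles, pass a censused abundance table explicitly.
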