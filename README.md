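# commdiv

Joint analysis of **plot-level tree species diversity** and the **genetic
structure of dominant binary (AFLP-type) markers** in forest tree
communities — for community geneticists and forest ecologists who want to
ask whether the species diversity of a stand co-varies with the adaptive
genetic structure of its component species.

## What it computes

* **Hill-number diversity profiles.** For any frequency distribution,
  ν<sub>a</sub> = (Σ p<sub>i</sub><sup>a</sup>)<sup>1/(1−a)</sup>: species
  richness ν<sub>sp,0</sub>, Simpson effective number ν<sub>sp,2</sub> and
  prevalent-species number ν<sub>sp,∞</sub> per plot; per-locus genetic
  diversity ν<sub>g,2</sub> = 1/(f₁² + f₂²) with an n/(n−1) small-sample
  correction (or the classical unbiased Simpson estimator), and its
  multilocus mean ν<sub>mean,2</sub>.
* **A Bayesian F<sub>ST</sub> outlier scan for dominant loci.** A
  multinomial-Dirichlet model with
  logit(F<sub>ST,ij</sub>) = α<sub>i</sub> + β<sub>j</sub>, dominant-data
  likelihood P(no band) = q² + F<sub>IS</sub>·q(1−q), and reversible-jump
  MCMC (prior odds 10 for neutrality) toggling each locus effect
  α<sub>i</sub>.  Reports posterior mean α, posterior inclusion
  probability, q-values and a diversifying/balancing/neutral verdict.
  Implemented in C++ for speed.
* **The covariation statistic C** between plot-level variables,
  C = Σ<sub>i&lt;j</sub>(x<sub>i</sub>−x<sub>j</sub>)(y<sub>i</sub>−y<sub>j</sub>) /
  Σ<sub>i&lt;j</sub>|x<sub>i</sub>−x<sub>j</sub>||y<sub>i</sub>−y<sub>j</sub>| ∈ [−1, 1],
  sensitive to monotone (not necessarily linear) co-movement, with
  one-sided permutation tests (exhaustive when feasible, add-one sampled
  otherwise).
* **The differentiation parameter δ** = Σ<sub>j</sub> c<sub>j</sub>D<sub>j</sub>,
  each D<sub>j</sub> the half-L1 distance between plot j's variant
  distribution and its pooled complement, with a size-preserving
  reassignment permutation test against the two-sided Bonferroni criterion
  α/(2m).
* **The staged candidate selection** (scan thresholds → uncorrected C
  significance → top-5 posterior probabilities → Bonferroni-corrected C),
  and a **seeded synthetic-data generator** emulating a 14-plot
  tree-community study with planted outlier loci and an optional monotone
  diversity–frequency coupling.

See `vignette("community-diversity-genetics")` for the full methods
account.

## Worked example

Simulate a 14-plot community whose focal species carries 100 neutral loci
and 5 loci coupled to plot diversity, then run every stage:

```r
library(commdiv)
des <- sim_design(n_plots = 14, n_loci = 105, n_coupled_loci = 5,
                  coupling = 0.9, sample_size_range = c(17, 53), seed = 20001)
res <- run_pipeline(design = des, n_perm = 999,
                    scan_cfg = scan_config(out_iterations = 200, thinning = 5,
                                           pilot_runs = 5, pilot_length = 150,
                                           burn_in = 1000))
print(res)
```

```
Community diversity / genetic-structure pipeline
  loci retained: 97 of 105
  outlier scan: 5 diversifying, 0 balancing of 97 loci
  covariation tests: 30 at candidate loci
  selected top-5: 5; significant after Bonferroni: 5
  delta = 0.557, P(Z>=delta) = 0.001 (significant)
```

Reading the output: the locus filter kept 97 of 105 loci inside the
[0.05, 0.95] frequency window; the scan flagged exactly the 5 planted
coupled loci as diversifying (`res$truth$coupled_loci` confirms); all 5
passed the uncorrected covariation stage, survived the top-5 posterior
ranking and stayed significant at the Bonferroni-corrected level 0.01; and
the community's species composition is strongly differentiated among plots
(δ = 0.557, upper-tail reassignment p = 1/1000).  `res$diversity` holds the
per-plot ν<sub>sp,a</sub>/ν<sub>mean,2</sub> table with its
across-populations mean row, `res$scan$results` the per-locus α, posterior
probabilities and q-values, and `write_reports(res, "out/")` emits the
report bundle (TSV tables, delta/truth/manifest JSON).

The bundled `study_diversity_table()` carries the published 14-plot
diversity summary of the Chihuahua-spruce community study this package's
design emulates; its column means reproduce that study's
across-populations row (6.21 / 3.33 / 2.28).

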