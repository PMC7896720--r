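# radqc

Bioinformatic artifacts in RADseq genotype panels — individuals with heavy
missing data, loci 100% missing in single populations, merged (undersplit)
and split (oversplit) assembly loci — can manufacture population structure
that looks like biology. `radqc` is an R package for fisheries and
population geneticists who need to diagnose and strip those artifacts
before inferring structure, and to test for region-specific changes in
fish growth with a hierarchical Bayesian length-at-age model. Its design
follows a re-analysis of temporally replicated walleye (*Sander vitreus*)
RADseq and length-at-age samples from a large boreal lake, where both the
reported genetic differentiation and the reported region-specific growth
decline dissolved under proper filtering and modelling.

The package has two arms plus a generator that makes every claim testable:

* **Genotype QC and structure.** Genepop I/O; missingness profiles;
  per-locus Weir–Cockerham (1984) variance components, pairwise multilocus
  θ = Σa / Σ(a+b+c), and a pooled-pair F<sub>IS</sub> = 1 − c/(b+c)
  computed on the two samples pooled; Fisher exact tests of genic
  differentiation combined across loci; HDplot paralog diagnostics
  (heterozygosity H, allele read ratio, deviation
  D = (ΣA − N/2)/√(N/4)); an ordered, audited filter cascade including
  the flawed *k*-of-*n* genotyping-rate rule; mean-imputed individual PCA
  with silhouette-based separation scores; and per-locus F<sub>ST</sub>
  distribution summaries with subsample normalization.
* **Growth.** A hierarchical Bayesian length-at-age model,

  Length ~ N(μ, σ),
  μ = β₀ + u₀ⱼ + β₂ⱼ·sex + (β₁ + u₁ⱼ)·age + β₃·south + β₄·contemp + β₅·south×contemp,

  with correlated river-level intercept/slope deviations, river-level sex
  effects, vague normal priors on means, half-Cauchy priors on scales and
  a uniform correlation prior, fit by MCMC (JAGS). Derived posteriors:
  predicted age-11 length per region × period, the per-region decline
  between periods, and the south-minus-north difference-in-differences.
* **Synthetic data.** `simulate_genotypes()` draws Balding–Nichols panels
  with configurable divergence F, injects population-specific whole-locus
  dropout, collapsed-duplicate (undersplit) loci with ~0.75 heterozygote
  read ratios, and oversplit loci, and emits read depths plus full ground
  truth; `simulate_growth()` draws length-at-age records from the model
  above with known parameters.

## Worked example

```r
library(radqc)

# a panmictic four-population panel in which one population suffers
# whole-locus dropout at over half its loci
sim <- simulate_genotypes(geno_sim_config(
  n_pops = 4, n_per_pop = 60, n_loci = 3000, target_fst = 0,
  pop_dropout = list(pop = "P3", frac_loci = 0.55, rate_range = c(0.9, 1)),
  seed = 42))

silhouette_score(pca_genotypes(sim$genotypes), "P3")
#> [1] 0.6508  — strong apparent "structure" in a panmictic panel

filt <- apply_filters(sim$genotypes,
                      filter_spec(filter_locus_missing_in_pop("P3", 0.5)))
silhouette_score(pca_genotypes(filt$genotypes), "P3")
#> [1] -0.0578  — the structure was the missing data

# growth arm: fit the length-at-age model to simulated study conditions
gs <- simulate_growth(growth_sim_config(seed = 1))   # true declines 24/40 mm
fit <- fit_growth(gs$data, mcmc_config(seed = 1))
tidy(period_decline(fit, "north"))$estimate   #> 23.2  (mm, age-11 decline)
tidy(period_decline(fit, "south"))$estimate   #> 40.4
tidy(contrast_south_minus_north(fit))[, c("estimate", "conf.low", "conf.high")]
#>   estimate conf.low conf.high
#> 1     17.2     13.0      21.3
```

The first two numbers say: mean-imputed PCA separates the dropout-ridden
population with silhouette 0.65 although every population was drawn from
one gene pool, and removing loci missing in >50% of that population's
individuals collapses the separation to ~0. The growth numbers recover the
generator's 24 mm northern and 40 mm southern age-11 declines and their
16 mm difference-in-differences with a credible interval excluding zero at
this simulated sample size (500 fish per river).

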