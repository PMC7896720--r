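---
title: "Methods: artifact-aware RADseq QC and hierarchical length-at-age modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: artifact-aware RADseq QC and hierarchical length-at-age modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radqc` packages, as reusable and tested tools, the two analyses that expose
how easily RADseq population-genetic inference and small-sample growth
analysis go wrong: an artifact-aware genotype QC pipeline, and a hierarchical
Bayesian length-at-age model with a region-by-period contrast. This vignette
is the package's own account of the statistical machinery: the models and
their assumptions, the parameters that matter, the numerical choices, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## The genotype data model

Genotypes live in a `genotype_matrix`: individuals by biallelic loci, calls
coded as unphased allele-B dosages 0/1/2 with `NA` for missing. Genepop is
the interchange format; an all-zero token is a missing call, and any call
containing a single zero allele code is treated as missing too. Loci with
more than two observed alleles are rejected at parse time: every statistic
downstream assumes biallelic SNPs.

Two deliberate I/O conventions: population labels are not part of the
genepop format, so they are derived from sample names by a configurable
rule (prefix before the last underscore by default) or supplied explicitly
— the labelling convention of any particular deposit is a configuration
fact, not something to hard-code. And allele A at a locus is the
numerically smallest observed code. An earlier draft used "first code
encountered in file order", but that rule flips dosage polarity whenever a
locus's first non-missing genotype is the B-homozygote, which breaks the
read–write–read identity the I/O layer guarantees; the smallest-code rule
is deterministic and every downstream statistic is polarity-symmetric, so
nothing else changes. For a locus where only one allele code is observed,
code 1 is taken as allele A and any larger code as allele B, so monomorphic
loci also round-trip.

## F-statistics

Per-locus estimates for a pair of samples use the Weir & Cockerham (1984)
two-allele variance components `a` (among populations), `b` (among
individuals within populations) and `c` (within individuals), with
per-locus F~ST~ = a/(a+b+c) and multilocus θ the ratio of sums
Σa/Σ(a+b+c) — the ratio-of-averages convention of the original estimator,
not a mean of per-locus ratios. Per-locus values remain available for
distribution summaries. Negative estimates are reported as computed and
never truncated: near-zero true differentiation makes them routine, and
truncation would bias every multilocus summary upward.

The pair-level F~IS~ deliberately pools the two samples into one and
applies the single-sample estimator 1 − c/(b+c) to the pool. Pooling is
what gives the statistic its diagnostic power for merged loci: a locus
near-fixed heterozygous in one sample and near-invariant in the other has
a pooled observed heterozygosity far above the pooled Hardy–Weinberg
expectation, so the pair's F~IS~ goes strongly negative even though each
sample alone might look less extreme.

A locus is estimable for a pair only when at least two individuals are
genotyped in each sample and the pooled pair is polymorphic; inestimable
loci are flagged and excluded from ratios rather than silently zeroed.

Exact tests of genic differentiation are two-sided Fisher probability
tests on the 2×2 allele-count table per locus — by complete enumeration of
the hypergeometric support (always feasible for a 2×2; a Monte-Carlo path
with a seed exists for completeness) — combined across polymorphic loci by
Fisher's method. This is a deliberate variant of the Markov-chain exact
test some genepop tools run, whose chain parameters are rarely reported;
enumeration is exact, reproducible, and agrees with the chain test in the
limit. Monomorphic loci take p = 1 by convention and are excluded from the
combination. Significance in the pairwise table is flagged at α = 0.01.

## The filter cascade

`apply_filters()` runs an ordered list of steps, each recomputing its
statistic on the current matrix — order matters and is honored, because
the nested dataset definitions the pipeline reproduces apply individual
filtering before F~IS~ filtering. Every step logs before/after counts and
every removal carries the triggering value; counts telescope exactly.

* Individual missingness: remove individuals with missing fraction
  strictly above the threshold (default 0.5).
* Per-population genotyping rate, the *k*-of-*n* rule: retain loci meeting
  rate `r` (default 0.8) in at least `k` of `n` populations. With `k = n`
  this is the conventional filter; with `k < n` it reproduces — on
  purpose, for demonstration — the flawed relaxation that lets a locus be
  100% missing in up to `n − k` populations and thereby builds
  population-specific missingness into the retained panel.
* Per-population locus missingness: remove loci missing in more than a
  threshold fraction of one named population's individuals.
* F~IS~ threshold: remove loci whose pooled-pair F~IS~ is strictly below
  the threshold (−0.2 or 0 in the shipped presets); strict inequality
  matches the convention "remove F~IS~ < t". Loci with undefined F~IS~
  are retained and reported.
* HDplot band: remove loci whose read-ratio deviation D falls outside
  [−5, 5] (or heterozygosity above an optional ceiling). D is pinned here
  as the binomial z-score of pooled heterozygote reads around 0.5,
  D = (ΣA − N/2)/√(N/4): the method's variance convention varies across
  descriptions, so the formula is fixed and documented. Loci without
  usable heterozygotes are never removed by this step, and heterozygotes
  with zero total depth are excluded from the sums and logged.

`four_datasets()` packages the nested presets: unfiltered; individuals
≤50% missing; plus pooled-pair F~IS~ > −0.2; plus F~IS~ > 0.

## PCA and separation scores

Individual PCA imputes missing dosages with the locus mean over genotyped
individuals, centers columns (no variance scaling by default; a switch
exists) and decomposes by SVD. Mean imputation mirrors the default of the
standard genotype-PCA workflows — and is exactly the mechanism by which
population-specific missingness fabricates structure, since heavily
imputed individuals are pulled toward the global centroid and away from
their true neighbours. Loci with zero genotyped individuals are dropped
and reported.

Separation is quantified (tests need a number where a reader judges a
plot) as the mean silhouette width of one population against everything
else over the retained component scores, with 0.25 fixed as the
"separates" bar. Two retained components is the default, matching the
two-dimensional figures such analyses report. A practical measurement
note: the silhouette of a true-null split on two noise PCs wobbles by
about ±0.05 between panels from eigenvector chance alignment, so the
package's own demonstrations evaluate silhouettes as ten-panel sweep
means rather than single-panel values.

Per-locus F~ST~ distributions for a pair are summarized as counts in the
bins [0, 0.05), [0.05, 0.1), [0.1, 0.15), [0.15, 0.2), ≥0.2, plus mean and
maximum over estimable loci, optionally after randomly subsampling both
populations to a common size (the normalization used when comparing pairs
of unequal depth). Negative estimates are counted in the first bin so the
bins partition the estimable loci; the source tables this layout mirrors
start their bins at zero yet count all loci, and this is the one reading
that keeps the accounting consistent — it is logged as a decision and the
per-locus values are returned so any other convention can be recomputed.

## The synthetic-data generator

The generator exists so every stage can be verified against ground truth;
its defaults are the study conditions the package's own checks run under.

Clean loci: ancestral frequency p ~ U(0.1, 0.9); population frequencies
Balding–Nichols, Beta(p(1−F)/F, (1−p)(1−F)/F), so the divergence
parameter F is the target F~ST~; Hardy–Weinberg genotypes within
populations. Balding–Nichols was chosen because it gives a single
interpretable divergence knob that the Weir–Cockerham estimator should
recover — which is exactly what the calibration check asserts (the sweep
mean of θ̂ within 3 Monte-Carlo standard errors of F at F = 0, 0.02,
0.05).

Undersplit (merged-paralog) loci are a collapsed duplicate: a second gene
copy, fixed for allele A everywhere except in the affected populations,
where it segregates at q ~ U(0.3, 0.7). An individual's call at such a
locus comes from the collapsed pile of four gene copies: heterozygous
whenever both alleles are present in the pile, so a merged locus can never
yield a B-homozygote call unless all four copies carry B. This one
mechanism produces, simultaneously, the near-fixed heterozygosity in the
affected sample, the strongly negative pooled-pair F~IS~, the inflated
pairwise F~ST~, and heterozygote allele read ratios near 0.75 (three of
four copies carry A) that the QC arm is designed to catch. Read depths are
negative-binomial (mean 40, dispersion 5) with the heterozygote allele
split binomial at 0.5 for clean loci and at the paralog ratio 0.75 at
collapsed loci in affected populations.

Oversplit loci render true heterozygotes homozygous (a random allele
retained) with probability 0.7 and add 0.2 extra missingness — values
chosen once as a plausibly severe allele-dropout artifact; only the
direction of their effects (heterozygote deficit, extra missingness) is
load-bearing in tests.

Missingness: a base per-call rate (default 0.02, typical of a
well-sequenced RAD panel) plus an optional population dropout block — a
fraction of loci that go missing at a per-locus rate drawn from a
configurable range in one population. The shipped demonstration uses 55%
of loci at rates 0.9–1.0, reproducing the observed real-data pathology of
a population with over half its loci essentially absent and every
individual above 50% missing data.

What the generator does **not** emulate: linkage between loci, selection
or drift across sampling periods, library/batch effects on depth,
genotype-calling error conditional on depth, and read-level sequence
artifacts. Passing tests therefore demonstrate that the statistics and
filters behave correctly under the stated generative mechanisms — not
that real panels contain no other failure modes.

The growth generator draws from exactly the fitted model (below) with
defaults pinned to the conditions the package's checks target: four rivers
(one northern, three southern), 125 fish per river × period × sex cell
(500 per river), ages uniform on 2–19 years (a long-lived,
late-maturing age structure), β₀ = 280 mm, β₁ = 20 mm/yr, β₃ = 10 mm,
β₄ = −24 mm, β₅ = −16 mm (so age-11 length declines 24 mm in the north
and 40 mm in the south, a 16 mm difference-in-differences), mean sex
(male) effect 40 mm with river scale 10 mm, river scales τ₀ = 20 mm,
τ₁ = 3 mm/yr, ρ = 0, and σ = 20 mm. Size and growth values are realistic
for a slow-growing northern walleye population; the effect structure is
the scenario of a region-specific decline whose detectability the
recovery study measures.

## The length-at-age model

For fish i in river j,

Length_i ~ N(μ_i, σ),
μ_i = β₀ + u₀ⱼ + β₂ⱼ·sex_i + (β₁ + u₁ⱼ)·age_i + β₃·south_i + β₄·contemp_i + β₅·south_i·contemp_i,

with (u₀ⱼ, u₁ⱼ) bivariate normal (scales τ₀, τ₁, correlation ρ),
β₂ⱼ ~ N(μ_β₂, σ_β₂), sex coded 0 = female (reference), 1 = male, age in
years untransformed. Location (south vs north reference) indexes regions,
history (contemporary vs historical reference) indexes periods; the i/k
index conventions are fixed this way throughout. Priors: vague normals
N(0, (10·SD(length))²) on mean parameters; half-Cauchy(0, 5·SD(length)) on
all scales — a standard weakly-informative reading of a "vague" scale
prior, composed with a uniform prior on ρ (the concentration-1 prior for a
2×2 correlation matrix) via the scale-times-correlation decomposition.
Hyperparameters are data-scaled and pinned in `mcmc_config()`.

The sampler is JAGS (the model is linear-Gaussian throughout, so blocked
conjugate Gibbs is efficient and exact); the model, priors and run
configuration — not the sampler — are the scientific contract. Four exact
reparameterizations are applied purely for mixing, none changing the
posterior of any reported quantity: age is centered (coefficients mapped
back); river intercept/slope pairs are hierarchically centered around
(β₀ + β₃·south_j, β₁); the bivariate river effect is factored into scalar
conditionals so the glm module can block-update every location parameter
jointly; and the period effect is parameterized per location
(d_north, d_south) with β₄ = d_north and β₅ = d_south − d_north derived.
Half-Cauchy priors enter as `dscaled.gamma(A, 1)`, the half-t with one
degree of freedom. Chains start from data-plausible scale values rather
than prior draws, so little warmup is spent escaping the Cauchy tail.

Run configuration defaults to 10,000 steps per chain with 5,000 warmup and
thinning to every 10th draw, across four chains (the chain count is this
package's choice; split-chain diagnostics need several). Convergence is
summarized per reported quantity by rank-normalized split R-hat and bulk
effective sample size (Vehtari et al. 2021). The rank-normalized forms are
used advisedly: with only four rivers the half-Cauchy scale posteriors are
extremely heavy-tailed, and the classic Gelman–Rubin statistic then
signals spurious non-convergence from unequal tail excursions even when
chains agree everywhere that matters. Falling short of the reporting bar
(R-hat < 1.01, ESS > 1,000) warns but does not error.

Derived quantities are deterministic functions of the saved draws, so
recomputing them reproduces summaries bit for bit. The predicted length at
age a (default 11) for a location × period averages the location's river
intercept/slope deviations — a prediction for the sampled rivers, not a
new-river marginal, which is the pinned default since the regional
prediction is about those rivers — and adds the mean sex effect weighted
by a sex mix of 0.5 (configurable; an even mix is the neutral default when
the sex composition of the target population is unknown). The
difference-in-differences contrast (south decline minus north decline)
cancels all river terms and equals −β₅ draw for draw; it is still computed
through the prediction path so the code has one definition of a
prediction.

With one northern river, β₃ (and with it β₀) is weakly identified — its
posterior is wide because region and river are confounded at J = 4. That
is a property of the design, not the sampler; the history effects, the
age-11 predictions and the contrast are unaffected (the wide pieces cancel
or are well-informed by within-river contrasts).

## Problem sizes and what the checks show

The package's acceptance properties run at these sizes, chosen to match
the study design they emulate: calibration panels of 2 × 50 individuals
and 5,000 loci over 20 seeds per divergence level; oracle agreement on 100
random small tables to 10⁻¹⁰; the missingness demonstration on panmictic
4 × 60 panels with 3,000 loci over 10 seeds; the undersplit demonstration
on 4 × 50 panels with 5,000 loci (2% injected) over 20 seeds; and the
growth recovery and null studies each over 20 replicates of 500 fish per
river. The growth replicate fits use flatter, longer chains
(4 × 14,000, warmup 2,000, thin 2) than the default configuration so that
every monitored quantity clears ESS > 1,000 within each replicate.

## Known limitations

* Strictly biallelic, two-sample statistics; no multi-allelic estimators,
  no r > 2 F~ST~, no LD- or HWE-battery filtering beyond the steps above.
* Real-data HDplot reproduction requires per-genotype allele depths,
  which public genotype-table deposits typically lack; the HDplot step is
  therefore validated on synthetic depths.
* The headline numbers of the motivating re-analysis (locus counts through
  the cascade, the temporal-pair θ sequence, the bin tables, the 24/40/16
  mm growth story) are reproducible with this package only when the
  original public deposit is available locally; the pipeline ships the
  four-dataset presets and table layouts to do so, and its shipped checks
  validate every stage against synthetic ground truth instead.
* Locus-bootstrap confidence intervals for θ are exposed nowhere; the
  package reports point estimates and exact-test significance only.
* The growth model inherits the design's limits: no gear or ageing-error
  terms, no age × sex interaction, and a region effect identified from
  very few rivers.
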