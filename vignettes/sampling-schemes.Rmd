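---
title: "Evaluating sampling schemes for landscape genetics with ibrsamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sampling schemes for landscape genetics with ibrsamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrsamp)
```

## The problem

Landscape genetic studies ask which landscape features impede gene flow. The
analyst fits pairwise genetic distances between sampling locations against
pairwise *effective resistances* computed from candidate resistance surfaces,
and ranks the candidate surfaces by information criteria. A design question
sits upstream of every such study: should the sampling unit be the
*population* (many individuals per site, sites below a minimum sample size
dropped — PSS), the *individual* (one or a few individuals per site, all
sites kept — ISS), or everything that was actually collected, however uneven
(PASS)? `ibrsamp` implements the full analysis chain for all three schemes,
plus a bootstrap experiment that resamples 1–11 individuals per site to
locate the sample size at which ISS inference converges on the full-data
result, and a forward genetic simulator so the whole pipeline can be
validated against a known truth.

## Genetic distances

The response variable is the allele-sharing distance between diploid
multilocus genotypes: for individuals with per-allele counts
$c_{1a}, c_{2a} \in \{0, 1, 2\}$ at locus $l$,

$$D_{ps} = 1 - \frac{\sum_l \sum_a \min(c_{1a}, c_{2a})}{2 L_{obs}},$$

with $L_{obs}$ the number of loci called in both individuals (pairwise
deletion). Site-level matrices average $D_{ps}$ over all cross-site
individual pairs. Larger values mean more dissimilar, so positive resistance
coefficients are read as impeding gene flow; distance orientation only flips
the sign of fixed effects, never the information-criterion ranking.
Bray–Curtis dissimilarity on the concatenated allele-count vectors equals
$D_{ps}$ *exactly* on complete diploid data (both denominators are $2L$);
the package exposes both and the test suite asserts the identity to
$10^{-12}$. Population-level alternatives — Nei's $D_a$ and the
Weir–Cockerham $\theta$ estimate of $F_{ST}$ (slightly negative estimates
retained, not truncated) — are provided for index-correlation checks.

## Effective resistance

A resistance raster becomes an electrical network: cells are nodes, rook
(and optionally diagonal) neighbours are joined by a resistor using the
average-resistance rule $g_{ab} = 2/(r_a + r_b)$, with diagonal conductance
divided by $\sqrt2$ for the longer hop. The pairwise effective resistance
between site nodes is

$$R_{\mathrm{eff}}(s,t) = (e_s - e_t)^\top L^+ (e_s - e_t),$$

computed by grounding one node of the connected component and solving the
reduced sparse symmetric system with a Cholesky factorization (one
factorization per surface, one solve per site). Tests check hand-solved
series and triangle circuits exactly and agree with a dense Moore–Penrose
pseudoinverse oracle to $10^{-8}$ on random rasters, and verify Rayleigh
monotonicity (raising any cell's resistance never lowers any pairwise
resistance). Candidate surfaces follow the usual single-variable
parameterization: binary land-cover layers (2 in the focal class, 1
elsewhere), continuous surfaces at raw values (shifted to be strictly
positive when needed), and an all-ones layer whose effective resistance is
the isolation-by-distance predictor. Resistance values are deliberately not
optimized. A variance-inflation-factor screen on the lower-triangle
predictor vectors (`VIF = 1/(1 - R^2)`, iterative removal above 4) is
computed and logged as advisory output; it does not silently prune the
candidate model list, since screening interacts with a priori hypothesis
sets in ways the analyst should adjudicate.

## The MLPE model

Pairwise distance rows are not independent: two pairs sharing a site are
correlated. The maximum-likelihood-population-effects (MLPE) model handles
this with a random effect for each endpoint site:

$$y = X\beta + Zu + e, \qquad u \sim N(0, \sigma_u^2 I_P), \qquad
e \sim N(0, \sigma_e^2 I_n),$$

where $Z$ is the $n \times P$ pair-site incidence matrix with two unit
entries per row, so $V = \sigma_e^2 I + \sigma_u^2 ZZ^\top$. The likelihood
is profiled over $\phi = \sigma_u^2/\sigma_e^2$: given $\phi$, $\beta$ is
generalized least squares and $\sigma_e^2$ is closed-form. Because the
eigenvectors of $ZZ^\top$ do not depend on $\phi$, one symmetric
eigendecomposition per site set turns every likelihood evaluation into a
diagonal weighting — the bootstrap experiment reuses a single
decomposition across all replicates, sample sizes, and candidate models.
The scalar search runs over $\log(\phi + 10^{-10})$ from three starting
brackets with tolerance $10^{-9}$, and the $\phi = 0$ boundary is checked
explicitly; a constant response (zero residual variance) is caught and
returned at the boundary rather than propagating `log(0)`. Both ML and REML
are available everywhere. Ranking models with different fixed effects is
only strictly valid under ML; REML results are reported alongside because
both conventions circulate in the applied literature, and the contrast
between them is itself informative.

Model selection uses
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ and $BIC = -2\ell + k\ln n$ with $n$
the number of pairwise rows — a debatable but conventional choice of
effective sample size, configurable by passing a different `n`. The
parameter count convention is intercept + slopes + two variance components,
so a single-predictor model has $k = 4$ and a four-predictor model $k = 7$.
Predictors are z-standardized before fitting for numerical stability; this
cannot change the ranking. Ties in the criterion difference (within
$10^{-9}$) break toward smaller $k$, then model name.

## Sampling schemes and the bootstrap experiment

`make_scheme_dataset()` realizes the three schemes. PSS and PASS are
deterministic; ISS draws `n_per_site` individuals per site uniformly
without replacement, and a site holding fewer simply contributes everyone
(mirroring PASS logic — relevant at 40-site density where some sites hold a
single individual). `run_replicates()` repeats the draw `R` times per
sample size (replicate $r$ seeded `base_seed + r`, so the same seed policy
replays exactly), refits every candidate model under each estimation
method, and records how often each model is competitive
($\Delta IC < 2$) plus the mean and standard error of its evidence weight.
A model is "supported" at a sample size if its mean weight strictly exceeds
0.1 or it was competitive in at least 30 of 100 replicates — both
thresholds configurable. `convergence_analysis()` then reports, per sample
size, the fraction of replicates whose competitive set agrees with a
reference set from the deterministic full-data analysis, and the smallest
sample size at which that fraction exceeds 90%. "Agreement" defaults to a
nonempty intersection with the reference top-model set; an exact-containment
mode is exposed because the looser and stricter readings can disagree, and
reporting both is cheap.

## The synthetic generator

The generator exists so that every stage has a testable ground truth. Its
defaults emulate a pond-breeding amphibian microsatellite survey: a
100×100-cell classed landscape, 40 sites with at least 8 cells separation,
uneven per-site sample sizes of 1–25 individuals (334 total, 18 sites at
the population-level threshold of 11), and 8 loci with 12 founding alleles
each. Land-cover classes are quantile slices of a smoothed Gaussian random
field, so realized area fractions match their targets up to cell
granularity; slope-like and solar-like surfaces are independent smoothed
fields mapped to strictly positive ranges. A founder allele-frequency
profile from a field-observed eight-locus *Rana luteiventris* microsatellite
panel ships with the package (`microsat_panel_freqs()`) for users who want
realistic ragged allele spectra instead of the equifrequent default.

Genetic truth is generated forward in time at the allele-frequency level:
one causal cover class is given resistance 50 (1 elsewhere), its pairwise
effective resistances $R_{ij}$ are converted to migration
$m_{ij} = m_0 \exp(-(R_{ij} - \min R)/\rho)$ — scaled, if necessary, so
every deme retains at least half of itself — and each generation applies
deterministic migration mixing followed by multinomial drift of $2N_e$ gene
copies per deme (a stepping-stone approximation; individual-based
coalescent detail is not needed to induce the $F_{ST}$/$D_{ps}$ structure
the analysis consumes). Individuals are finally drawn as independent gene
copies from the deme frequencies. Defaults $N_e = 50$, $m_0 = 0.3$,
$\rho = (\mathrm{median} - \min)/2$ of the true resistances, and 80
generations were chosen once, by inspection of pilot runs, to produce a
strong isolation-by-resistance signal (allele-sharing distance correlating
around 0.5 with true resistance; the causal surface top-ranked on the
full-data analysis in the large majority of seeds). Two modelling choices
deserve emphasis:

* Migration must *not* be row-normalized to a fixed immigration total:
  doing so hands every deme the same gene-flow budget regardless of its
  isolation and erases the resistance signal almost completely. The decay
  form above keeps isolated demes isolated.
* Mean allele-sharing distance is **not** monotone in divergence time in
  general: under strong coupling, demes jointly lose rare alleles and mean
  $D_{ps}$ can fall as frequencies concentrate. What grows reliably with
  divergence time is population *structure* — the between-site minus
  within-site distance contrast, and pairwise $\theta$ — and that is what
  the property tests assert, in the weak-migration regime where drift
  dominates.

What the generator does not emulate: genotyping error and allelic dropout,
null alleles, sibship structure within ponds, microsatellite mutation
(optional stepwise mutation is omitted at these short time scales), and
landscape change over time. Passing tests therefore demonstrate that the
pipeline recovers a known signal of this idealized form, not that any
particular field system will behave as cleanly.

## Numerical and design notes

* Circuit solves use one grounded node per connected component; site nodes
  spanning components are an error, not an `Inf`.
* Effective resistances are computed once on all sites; scheme-level
  analyses take submatrices rather than re-solving circuits per replicate.
* The Monte Carlo Hardy–Weinberg test shuffles gene copies and compares the
  conditional probability of the genotype array given allele counts; the
  linkage test permutes one locus's genotypes with a G statistic on the
  two-locus table (a deliberate simplification of EM-based likelihood
  tests). Both use the add-one estimator $p = (1 + \#extreme)/(B + 1)$, are
  conservative in the presence of ties, and count only testable
  (polymorphic) combinations in the Bonferroni denominator.
* Rarefied allelic richness defaults to $g = 22$ gene copies, twice the
  population-level threshold of 11 — the largest subsample every
  population-level site can support.
* Problem sizes in the shipped tests and acceptance script are desk scale:
  oracle comparisons on rasters up to 20×20 and 4–18-site model toys, 200
  replicates for parameter recovery, 20 seeds for end-to-end recovery, and
  bootstrap curves at 30–100 replicates. All are stated choices of the
  package, balancing statistical resolution against a single-CPU run of a
  few minutes.

## Known limitations

The Weir–Cockerham estimator is the only $F_{ST}$ flavour offered. The
pipeline treats the full-data analysis as the reference truth when judging
ISS convergence, which inherits the usual caveat that the most-informed
dataset is not guaranteed to identify the true driver — on synthetic data
the ground-truth file makes this distinction checkable. REML information
criteria are reported with the caveat above rather than suppressed. The
GenePop reader supports the common single-line-per-individual dialect with
2- or 3-digit codes; exotic variants should be converted to the CSV dialect.
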