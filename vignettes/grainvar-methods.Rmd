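---
title: "Methods: dissecting within-plot grain-size variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting within-plot grain-size variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainvar)
```

## The scientific problem

Wheat yield is classically decomposed into spikes per m2 (SPM2), grains
per spike (GPS), grains per m2 (GPM2 = SPM2 x GPS) and the thousand-kernel
weight (TKW).  TKW is a bulk mean: it hides the large within-plot variance
of individual grain size.  `grainvar` treats that variance -- GSV, the
sample variance of individual grain projected areas (mm2, a proxy for
single-grain mass) within one micro-plot bulk -- as a quantitative trait
of its own, and asks two questions:

1. How much of the genetic variation in GSV is *driven* by canopy
   structure, i.e. mediated by the yield components established before
   flowering?
2. Is there a *specific* genetic determinism of GSV, loci that change the
   dispersion of grain size without moving the mean yield components?

The package implements the whole analysis chain -- distribution
descriptors, spatial adjustment under augmented designs, broad-sense
heritability, a kinship-corrected genome scan, LD-based QTL intervals,
driven/specific classification and variance partitioning -- together with
a seeded synthetic-data generator, so every stage is testable without
access to field or array data.

## Grain-distribution descriptors

Each plot's grain sample (300-500 areas) is summarised by the mean (GSM),
the sample variance (GSV, n-1 denominator), and the 5th/95th percentiles
(linear-interpolation convention, `stats::quantile` type 7).  Neither the
variance denominator nor the percentile convention is forced by the
underlying science; both are fixed and documented here so GSV values are
reproducible.  Because a variance scales as the square of its trait,
across-genotype comparisons of variability also report the CV of the
grain-size standard deviation (sqrt(GSV)) next to the CV of GSV itself.

Yield components are derived from the three measured quantities:
GPM2 = 100 GY / (TKW/1000) (GY in t/ha, so 100 GY is g/m2) and
GPS = GPM2 / SPM2, with both masses on a notional 15% moisture basis
(`to_15pc_humidity()` rescales a dry mass by 1/0.85).

## Spatial adjustment and heritability

Augmented designs replicate only a handful of check genotypes; spatial
trends must be removed before genotype values are comparable.  Adjusted
means come from the mixed model

Y_ijkl = mu + SB_j + B_k + G_i + e_ijkl

with the sub-block effect SB_j random and block and genotype fixed.  The
single variance ratio is estimated by REML, profiled over
gamma = sigma2_SB/sigma2_e after one eigen-decomposition of the sub-block
structure (each objective evaluation is then O(n); the optimiser works on
log gamma over [1e-10, 1e10], tolerance 1e-8).  Fixed effects use
sum-to-zero constraints, and the adjusted mean of genotype i is
mu_hat + G_hat_i.  Negative variance estimates are truncated at zero and
flagged.  The fit is verified in the tests against a dense-algebra GLS
oracle (1e-8) and against `lme4` (1e-3).

Broad-sense heritability uses the checks to carry the spatial
information: a checks-only fit of the same spatial model yields sub-block
BLUPs and block estimates, these are subtracted from every plot, and a
random-genotype REML fit of the corrected values gives
H2 = sigma2_G / (sigma2_G + sigma2_e) on a per-plot basis (no replication
divisor, since most genotypes are unreplicated).  The two entry points
(`heritability_panel2016()`, `heritability_panel2017()`) differ only in
validation strictness: the second demands checks in every sub-block, as a
two-step design requires.

Two properties of this procedure are worth knowing and are measured in the
test suite rather than assumed.  First, the sampling spread of H2 under
the null (sigma2_G = 0) depends strongly on how much replication the
design carries: at a ~25%-replicated augmented layout roughly 80% of null
estimates fall below 0.1, and only a fully replicated layout reaches the
~95% one would naively expect.  Second, subtracting *estimated* spatial
effects injects estimation noise with SD of order 1/sqrt(#check plots per
block), which gives the two-step H2 a small positive offset (~0.03 at four
3x-replicated checks) relative to a one-step fit; the tests assert
mean-level agreement, not replicate-level equality.

## The genome scan

Markers are QC-filtered (missingness > 10%, MAF < 5%, monomorphic -- the
MAF rule is applied as remove-below-5%), mean-imputed, and LD-pruned
(greedy ascending-bp scan, drop when r2 > 0.9 with a retained marker).
The scan model per marker is

Y = mu + X beta + G + E,  G ~ N(0, sigma2_g K_chr),  E ~ N(0, sigma2_e I)

where Y are adjusted means of one trait in one environment and K_chr is
the VanRaden relationship matrix computed from all markers *except* the
tested marker's chromosome (leave-one-chromosome-out), so the tested
signal is not absorbed by the polygenic term.  No population-structure
covariates are added.  The variance ratio is estimated once per
chromosome under the no-marker null (the P3D/EMMAX approximation;
per-marker REML is available behind `per_marker_reml = TRUE`), and each
marker is tested by generalised least squares with a 1-df Wald statistic
referenced to t(n-2).  The t reference (rather than chi-square) is a
deliberate choice: it makes the scan collapse *exactly* to ordinary least
squares when K is proportional to the identity, which is the calibration
contract the tests enforce; at panel sizes the two references differ in
the third decimal of p.  Effects are reported for the minor allele;
significance is LOD = -log10(p) strictly above 3 (configurable).

## QTL intervals

Significant GSV SNPs are turned into intervals in three steps.

1. *Critical LD.* Random inter-chromosomal marker pairs estimate the
   background LD between unlinked loci; the default statistic is the
   empirical 95th percentile of their r2 (a parametric variant
   square-root-transforms, takes the normal 95th percentile and squares
   back).  Which variant the original field protocol used is not
   recoverable; the empirical percentile is the default and the choice is
   configuration, not science.
2. *LD blocks.* Within each chromosome, significant SNPs are clustered by
   average-linkage hierarchical clustering on d = 1 - r2, cutting the tree
   at 1 - critical LD.  Every significant SNP seeds the clustering -- the
   manual Manhattan-plot pre-screen of interactive workflows is replaced
   by this deterministic rule.  Clusters never span chromosomes.
3. *Decay extension.* The Hill-Weir expectation of r2 at recombination
   C = rho d is fitted to sampled intra-chromosomal pairs by
   least squares profiled over the single parameter rho (log-scale golden
   search, always convergent); block boundaries are extended by the
   distance d* where the fitted curve crosses the critical LD (bisection
   to 1e-6; infinite when never crossed, flagged and treated as zero).
   Overlapping extended intervals merge into one locus; the peak SNP is
   the member with the highest LOD.

## Classification and variance partitioning

A GSV QTL is *driven* when at least one SNP significantly associated with
a yield component in the same environment colocalises with it, *specific*
otherwise.  Within an environment the default rule tests component SNP
positions against the extended interval; cross-environment commonality is
stricter, requiring a shared significant member SNP -- the two rules
mirror two genuinely different operations (position overlap vs identity),
and both are exposed (`rule = "interval"` / `"members"`).

For variance partitioning each QTL contributes its member SNP with the
largest absolute minor-allele effect (ties: higher LOD, then lower bp);
adjusted GSV is regressed on all peaks, specific-only peaks and
driven-only peaks, reporting each r2.  Forward stepwise selection from the
intercept-only model, adding whichever candidate lowers AIC most and
stopping at the first non-improvement, yields the optimal QTL subset and
its r2.  Forward-only (not bidirectional) keeps the procedure
deterministic.  Two calibration facts from the tests: forward AIC lands
within 2 AIC of the exhaustive best subset in >= 90% of draws with 8
candidates, and because AIC admits a null predictor with probability
~0.157, a null screen of 8 candidates selects <= 2 variables about 89% of
the time -- "empty or one" is *not* the right null expectation and the
tests encode the correctly calibrated bound.

## The synthetic world

`sim_config()` fixes a stated world, not a tuning surface; its defaults
are chosen once to match the field situation the methods target and the
tests run against them unchanged.

* *Panel and design.* 300 genotypes (4 checks), two environments, an
  augmented layout of 4 blocks x 2 sub-blocks per environment with checks
  replicated three times per block and ~25% of entries carrying one
  replicate -- the structure of a mostly-unreplicated elite panel.
* *Genotypes.* Three chromosomes of 600 Mb x 1000 SNPs.  Each individual's
  two haplotypes are mosaics of 16 founder haplotypes with per-bp
  recombination 5e-9.  Founder haplotypes themselves are locally similar
  (a latent AR(1) process with 30 Mb correlation length thresholded at
  each marker's frequency): with independent founder alleles a mosaic
  alone caps population r2 near 1/(n_founders - 1), far below the
  chromosome-scale LD of real wheat panels, so the founder process is the
  second LD channel.  One percent of calls are masked missing to exercise
  QC and imputation.
* *Traits.* SPM2 ~ 500 +/- environment shift (+100 well-watered, -100
  water-deficit) with 8 additive QTL (effect scale 25 spikes/m2); GPS
  ~ 36 with compensation -2.5 grains per 70-spike increase; mean grain
  area ~ 16.9 mm2 minus a source-limitation slope of 2.5 mm2 per 7000
  extra grains/m2 (the GPM2-TKW trade-off) plus 8 grain-size-potential
  QTL; 6 dispersion QTL multiply the within-plot SD (base 2.4 mm) by
  exp(effect), effect scale 0.10.  Spatial (sub-block) and plot noise are
  0.3 and 0.5 of each trait's internal scale.
* *Grains.* Each plot draws 300-500 areas from a two-level mixture: spike
  class (secondary-tiller proportion ~0.30, rising with spike density on
  the logit scale; secondary grains 10% smaller) then grain position (35%
  distal, 8% smaller).  An upper-tail cap at mu + (2.3 - 0.8 z) sigma,
  with z the plot's standardised spike density, is applied by resampling
  above the cap (soft truncation keeps the density proper).  The cap is
  the canopy mechanism: denser canopies lose their largest grains, which
  *lowers* GSV and P95 as SPM2 rises even though the secondary-tiller
  channel alone would raise it.  The within-spike shrink factors have no
  quantitative field reference; they are free parameters fixed at
  plausible values and documented here.
* *Masses.* Individual grain mass follows the linear area link
  mass(mg) = 3.0 area - 12 + N(0, 4.2) -- calibrated to give an
  area-mass R2 of ~0.8 -- TKW is the per-plot mean mass re-expressed at
  15% humidity, and GY = GPM2 x TKW / 1e5 exactly, so the component
  derivation inverts the generator to machine precision.

With these defaults the generator reproduces, as *emergent* facts, the
correlation structure the method chain is designed to dissect: GSV
negatively correlated with SPM2 (and GPM2), positively with TKW, and
essentially uncorrelated with GPS.  The acceptance tests verify the
SPM2-GSV sign in 18 of 20 independent worlds and verify that dispersion
loci move GSV without moving SPM2 or GPS beyond Monte-Carlo error.  One
caveat is intrinsic to the mechanism: because the cap truncates in SD
units, a larger within-plot SD also shifts the mean slightly, so strong
dispersion loci carry a faint TKW signature.  That is a feature of tail
truncation, not a bug, but it means TKW colocalisation cannot separate
truth classes in recovery experiments -- the planted-truth scenario
therefore scores classification against the canopy components
(SPM2/GPS/GPM2) with the shared-member-SNP rule, and switches the
secondary-tiller slope off so the cap is the only canopy-to-GSV route.

What a green test on this world does *not* establish: robustness to real
genotyping artefacts (the missing mechanism is uniform), to population
structure (founders are exchangeable, so there is none -- consistent with
panels optimised to be unstructured), to G x E beyond additive
environment shifts, or to phenotyping error structures other than
Gaussian noise.

## Numerical choices and degenerate inputs

* REML: profiled 1-D objective, eigen-decomposition reused across
  evaluations; ratio bounds 1e-10..1e10 double as the negative-variance
  truncation (a boundary solution is flagged).  A saturated fixed part
  (n = p) leaves the ratio unidentified; the GLS solution is still exact
  and is returned with a floor residual variance.
* Kinship matrices get 1e-8 added to the diagonal before decomposition.
* Monomorphic markers inside the scan return NA rather than failing the
  whole chromosome.
* The LD-decay crossing distance is Inf when the curve never reaches the
  critical LD; interval extension then falls back to 0 with a warning.
* Rounding for report-style percentage tables is half-up at one or two
  decimals (`round_half_up()`), avoiding platform-dependent half-even
  behaviour.
* All randomness flows from one integer seed; stage sub-streams are
  derived by fixed small offsets, and identical configurations produce
  byte-identical reports.

## Known limitations

* The Fisher r-to-z comparison of correlations between environments
  assumes independent samples, although both environments share
  genotypes; p-values for that comparison are anticonservative to an
  unknown degree.
* Mean-dosage imputation ignores haplotype information; it is adequate
  below the 10% missingness cap but is not a substitute for model-based
  imputation.
* The two-step heritability carries the small positive offset discussed
  above, and plot-basis H2 is not comparable to entry-mean H2 from
  replicated trials.
* QTL intervals inherit the critical-LD threshold's sampling noise; with
  few unlinked pairs the 95th percentile is itself variable, which
  propagates to d* and to interval sizes.
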