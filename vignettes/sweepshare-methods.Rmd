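---
title: "sweepshare: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweepshare: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices, and numerical
decisions behind the package, in the spirit of a methods supplement. It
states no empirical result that the test suite or the acceptance script do
not themselves compute.

## The scientific question

In a species with strong population structure, adaptive fixations can be
locally restricted (each population sweeps its own alleles) or shared
(one beneficial allele spreads across populations by migration, standing
variation, or repeated mutation). Two complementary measurements address
this: (i) per-population genome scans for completed sweeps, compared
across populations after explicit accounting for the scan's own error
rate; and (ii) the asymptotic McDonald–Kreitman estimate of the proportion
of adaptive fixations, compared between per-population and rangewide
samples. The package implements both measurement chains plus the
synthetic-data generation needed to validate them.

## The composite scan statistic

Completed hard sweeps leave three co-located signatures: a diversity
trough, an excess of extreme-frequency derived variants, and elevated
linkage on each flank of the fixed site with reduced linkage across it.
The scan multiplies one self-normalized factor per signature over sliding
windows of `W` consecutive SNPs (step one SNP; window coordinates are the
bp of its first and last SNP):

- `mu_var = span * q_w * S / (L * W)`. Under neutrality the expected span
  of `W` SNPs is about `(W-1)/S * L`, so the factor centres just below 1;
  SNP thinning inside a sweep stretches the span. `q_w` is the proportion
  of callable bases in the window span taken from a BED mask (absent mask:
  `q_w = 1`); multiplying by `q_w` shrinks the statistic in badly callable
  windows where the wide span reflects missing data, not missing
  diversity. Windows with `q_w = 0` are unusable and dropped (counted).
- `mu_sfs = (window fraction of extreme SNPs) / (chromosome-wide
  fraction)`, where extreme means derived count 1 or `n-1`. Pooling both
  extremes makes the factor invariant to ancestral/derived mislabeling. A
  chromosome with no extreme SNPs at all carries no SFS signal; the factor
  is then defined as 1 everywhere and a message is emitted.
- `mu_ld = (mean r^2 left half + mean r^2 right half) /
  (2 * mean r^2 between halves + 1e-6)`, split at the middle SNP, capped
  at 100. The epsilon prevents division blow-ups when the between-half
  linkage is numerically zero; the cap bounds the influence of such
  windows on the spline. Both constants are structural regularizers, not
  tuning knobs: results at the calling stage are driven by the
  simulation-calibrated threshold, which sees the same capped statistic.

The product is reported per window together with the three factors. MAF
filtering (default 0.05, sites at the boundary kept — the `>=` convention)
precedes windowing, and the chromosome-wide quantities (`S`, extreme
fraction) are computed after filtering, so the normalization matches what
the windows see.

## Region calling and thresholds

Window statistics are spatially autocorrelated, so the track is smoothed
with a cubic smoothing spline (`stats::smooth.spline`, penalty by
generalized cross-validation) and regions are defined on the fitted
values. The null distribution comes from simulating neutral chromosomes
matched in sample size and length under the population's demography,
running the identical filter–scan–spline pipeline, pooling all fitted
values across replicates, and taking a quantile (default 99.9%). Pooling
across replicates (rather than per-replicate thresholds) uses all
simulated windows symmetrically and makes the threshold a single
reproducible number per population. The replicate count is a free
parameter: the default is 100, and the test suite uses the documented
minimum of 20 because the pooled quantile is stable in the number of
replicates (tens of thousands of fitted values already enter the pool
from 20 ten-megabase chromosomes).

Runs of consecutive outlier windows become intervals
`[first center, last center + 1)` (0-based half-open, BED-compatible);
intervals with gaps of at most the merge distance (default 50 kb) are
merged; each region carries the argmax of the fitted value as its peak.
Two caveats discovered while property-testing: the number of called
regions is monotone non-increasing in the merge distance always, but
monotone in the threshold only in the outlier regime (quantiles >= 0.95) —
at lax thresholds a lower threshold merges many outliers into fewer giant
regions. Hyperparameters are selected by grid search (defaults: `W` in
{10, 24, 50, 100, 200, 500}, quantile in {0.8, 0.9, 0.95, 0.99, 0.999},
merge distance in {50, 100, 200, 500} kb) maximizing mean replicate
concordance; ties break toward smaller `W`, larger quantile, smaller merge
distance (parsimony).

## Accuracy and the sharing test

Two non-overlapping samples of one population should call the same sweeps;
the extent to which they do not estimates the irreproducible fraction:
`P = 1 - (nS/nP1 + nS/nP2)/2`. The package treats `P` as a scale factor on
the counts entering the hypergeometric sharing test: `N, n1, n2, x` are
multiplied by `P`, rounded half away from zero (so small but real sharing
is not silently erased — base R's round-half-to-even would turn an
adjusted `x` of 0.5 into 0), and clamped to `x' <= n2' <= n1' <= N'`. The
p-value is the exact tail `Pr(X >= x')` computed by log-choose summation.

The total number of testable loci `N` is not observable directly; the
package defines it as the number of non-overlapping slots a called region
could occupy, `floor(genome length / (mean region length + merge
distance))`, with an override argument for users who prefer a fixed `N`.
This makes `N` explicit, reproducible, and conservative (larger assumed
`N` would shrink p-values). Shared counts `x` are computed at the cluster
level: overlapping regions across the pair are single-linkage clustered
and a cluster containing both populations counts once, so one wide region
hitting two small ones is one shared signal, not two. Multiple testing
across pairs uses Benjamini–Yekutieli (valid under the arbitrary positive
dependence created by shared genomic structure).

## Asymptotic McDonald–Kreitman

Sites are classified by codon degeneracy from FASTA + GFF3 (phase-aware,
strand-aware; codons with ambiguous bases or internal stops are skipped
and counted; positions claimed by transcripts with conflicting classes
resolve to the most constrained class, 0-fold winning, or can be dropped).
Polarization against two outgroups follows fixed rules: an outgroup with
minor allele frequency above 0.001 at a site is treated as missing there;
agreement between homozygous outgroups defines the ancestral state; a
state present only in the better-covered outgroup is accepted; sites
missing in the better-covered outgroup, or with two disagreeing homozygous
outgroups, are excluded and counted.

With the unfolded SFS split into selected (0-fold) and neutral (4-fold)
classes, each frequency bin gives
`alpha_i = 1 - (d0/d) * (p_i/p0_i)` — subscript 0 is the neutral class
throughout, the convention under which this is the standard estimator
(prose descriptions in the field occasionally swap the class labels; the
formula is what is implemented). Bins with `p0_i = 0` are undefined and
excluded. The
asymptotic curve `alpha(x) = a + b exp(-c x)` is fitted by bounded
L-BFGS-B least squares with multi-start over `c` in {0.5, 2, 8} plus a
linearized (a, b | c) initializer; bounds are `a <= 1` (alpha is a
proportion-like quantity and its asymptote cannot exceed 1 — this bound
also prevents the runaway `a -> 2, c -> 0` ridge on noisy data), `|b| <=
10`, `c` in [1e-3, 100]. Constant input (`b = 0`) is reported with
`alpha_inf = a`, `c = NA`, and a degeneracy flag rather than a spurious
`c`. Intervals are percentile bootstraps over bins (default 200
replicates); bins are unweighted by default, matching a fit on the
per-bin alpha values themselves.

The partial-pooling mode is an empirical-Bayes penalized fit: each group
is fitted independently, Gauss–Newton sampling variances of `(a, b, log
c)` are extracted from the SSE Hessian, a DerSimonian–Laird estimate gives
the between-group variance and precision-weighted centre per parameter,
and every group is then refitted with the quadratic MAP penalty
`sigma_j^2 * sum((theta - centre)^2 / tau^2)` added to its SSE. Refitting
jointly (rather than shrinking each coordinate of the estimates) respects
the strong sampling correlations among `(a, b, c)`; shrinking coordinates
independently was tried first and increased the error of the asymptote.
`c` is penalized on the log scale because it is positive and
right-skewed. The test suite verifies the motivating property: across
eight simulated populations sharing hyperparameters, partial pooling
reduces the mean squared error of the per-group asymptote relative to
independent fits (about threefold at the simulated noise level).

## The synthetic-data generator

Neutral haplotypes come from the sequentially Markov coalescent (SMC): an
exact piecewise-constant-Ne coalescent tree at the left end of the
chromosome evolves along the sequence by prune–regraft moves at
recombination breakpoints, and mutations fall as a Poisson process on the
marginal tree of each non-recombining segment. The marginal genealogy at
every position is a standard coalescent, so `E[pi] = 4 Ne mu`, the
`1/i` neutral SFS, and Tajima's D centred at 0 hold exactly and are
verified by Monte-Carlo tests. Defaults state a maize-like world:
`Ne = 1e4`, `mu = 3e-8`, `r = 1.6e-8` per bp per generation, haploid
sample size 20 (ten diploids). An earlier independent-blocks design (one
tree per fixed-length block) was discarded: block-independent genealogies
let adjacent windows sit on unrelated trees, which a real ancestral
recombination graph forbids, and that artifact inflated the tail of the
flank-LD factor. What the SMC still does not emulate: gene flow and
admixture, sequencing error and missing genotypes, unphased data, variable
mutation/recombination maps, and the slight underestimation of long-range
LD inherent to SMC relative to the full coalescent with recombination.
A green pipeline test therefore establishes correctness of the machinery
on idealized phased data with known polarity, not robustness to real-data
artifacts (the quality-mask path is exercised with synthetic masks).

Sweeps are injected by a parametric transform rather than forward
simulation, so truth is exact: within a triangular footprint of halfwidth
`L_s` around the center, each SNP is dropped with probability
`q0 (1 - d/L_s)` and, if retained, pushed to derived count 1 or `n-1`
(uniformly chosen carriers) with probability `h0 (1 - d/L_s)`. This
reproduces the diversity deficit and SFS distortion; it deliberately does
*not* create the flanking-LD signature (uniform carrier resampling
destroys local LD), so recovery tests measure detection driven by
`mu_var * mu_sfs` with `mu_ld` roughly neutral inside footprints —
a conservative regime for the composite statistic. Replicate samples are
made by simulating one population at twice the sample size and splitting
it into disjoint halves, so both halves carry the population's sweeps by
construction.

Synthetic uSFS tables invert the per-bin estimator: neutral counts
`p0_i ~ Poisson(theta0/i)`, selected counts
`p_i ~ Poisson((d/d0)(1 - alpha(x_i)) theta0/i)`, with the generating
curve and true asymptote recorded in metadata. Plugging expected counts
back into the estimator returns the curve identically; the tests verify
the stochastic version (bin means over many seeds within 0.01 at
`theta0 = 1e4`).

## Numerical and convention decisions

- Coordinates: VCF/GFF3 1-based inclusive; BED and all internal region
  outputs 0-based half-open; the conversion lives in one I/O layer.
  Overlap means >= 1 shared bp everywhere; book-ended intervals do not
  overlap.
- All generators and commands are pure functions of (inputs, seed); output
  tables carry a provenance header (package version, seed, config hash).
- Config files are YAML; field access uses exact `[[` indexing after a
  partial-matching bug (`$r` resolving to `replicate`) produced a
  pathological recombination rate during development.
- The worked default chromosome for module-level examples is 1 Mb with
  `n = 20`; region-level validation runs on 10-Mb chromosomes with five
  injected sweeps (one per 2 Mb).
- `smooth.spline` occasionally warns about GCV on tied abscissae; windows
  with identical centers are legitimate (identical SNP pairs), and the
  spline handles them by weighting.

## Known limitations

- The scan is tuned for completed hard sweeps; incomplete and soft sweeps
  weaken all three factors and are out of scope.
- The SMC's marginal trees are exact but its joint LD is an approximation;
  thresholds calibrated on it apply to data generated by it, and real-data
  thresholds should come from simulations under the analyst's own
  demography and simulator of record.
- `N` in the sharing test is a modelling choice; conclusions should be
  checked for robustness across the provided override.
- The asymptotic-MK fit assumes no segregating advantageous polymorphisms;
  estimates are conservative in their presence.
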