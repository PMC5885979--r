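---
title: "Normalizing zero-inflated count tables with pairwise ratios"
author: "gmprnorm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing zero-inflated count tables with pairwise ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmprnorm)
```

## The problem

Microbiome sequencing produces a feature-by-sample table of counts
`c_ki` (feature `k = 1..q`, sample `i = 1..n`) whose column totals — the
library sizes — vary for purely technical reasons, often by orders of
magnitude. Before any comparison across samples, each sample needs a
*size factor* `s_i` estimating its relative depth; counts are divided by
it, or its log enters a count regression as an offset.

Total-sum scaling (TSS, `s_i = sum_k c_ki`) is the obvious estimate but
has two failure modes: a handful of outlier counts (e.g. preferential
PCR amplification) inflates it, and truly differential taxa drag every
other taxon's relative abundance in the opposite direction (the
compositional effect). The RNA-seq answers — relative log expression
(RLE, median ratio to a per-feature geometric-mean reference) and the
trimmed mean of M-values (TMM, trimmed weighted mean log-ratio to a
reference sample) — assume a large set of features observed in *every*
sample. OTU tables break that assumption: typically 60–90% of cells are
zero, few or no features are shared by all samples, and the geometric
mean reference is undefined wherever a zero appears. RLE then either
fails outright or rests on a handful of features; adding a pseudo-count
rescues the arithmetic but distorts exactly the abundant-zero features
it is meant to fix.

## Geometric mean of pairwise ratios

The estimator implemented here reverses the order of RLE's two steps.
Although few features are present in *all* samples, any *pair* of
samples usually shares many. So:

1. For every ordered pair `(i, j)`, compute the median count ratio over
   the features nonzero in both samples:
   `r_ij = median { c_ki / c_kj : c_ki * c_kj != 0 }`.
2. Combine each sample's ratios by a geometric mean:
   `s_i = (prod_j r_ij)^(1/n)`.

The median in step 1 makes each pairwise comparison robust to a
minority of differential or outlier features; the geometric mean in
step 2 pools `n` such comparisons, so the estimate uses far more of the
table than a single common-feature set. The product runs over
`j = 1..n` including the self-ratio `r_ii = 1`, matching the definition
literally. Computation is in log space (no overflow at large `n`), and
complexity is `O(n^2 q)` — seconds for `n` in the hundreds; scaling
beyond tens of thousands of samples is out of scope here.

Two details the definition leaves open are resolved as follows and
exposed as parameters:

* **Sparse pairs.** Two samples may share fewer features than a median
  can sensibly summarize. `min_shared` (default 2) declares `r_ij`
  undefined below that count; the geometric mean then runs over the
  *defined* ratios only (the exponent is `1/|defined|`). A sample with
  no defined partner at all is an error naming the sample, not a `NaN`.
* **Median convention.** Even-sized shared sets use the midpoint of the
  two central order statistics. A consequence accepted rather than
  patched: `r_ij = 1/r_ji` holds exactly only for odd shared-set sizes.

Size factors from all methods can be divided by their median
(`rescale_by_median()`) so that different methods are on one scale.

## The comparator methods

The package re-implements the six standard comparators on the same
contract, so benchmarks hold everything but the size factor fixed:

* **TSS** — column totals.
* **RLE / RLE+** — per-feature geometric means over the features with
  no zeros (after adding a pseudo-count of 1 for RLE+), then the
  per-sample median ratio to that reference. With no zero-free feature
  RLE raises its defined "RLE fails" error.
* **TMM / TMM+** — reference sample by the 75th-percentile rule; M and
  A values over features nonzero in both sample and reference; 30%
  two-sided trim on M, 5% on A; precision-weighted mean of the
  surviving M; the library-size-relative factor is multiplied by the
  sample's total count so it is comparable to the others. The trims and
  weights are the canonical published defaults, exposed in
  `tmm_config()`.
* **CSS** — a data-driven percentile chosen from the stability of the
  nonzero-count quantiles across samples (relative-increment threshold
  0.1, floored at the median), then the sum of each sample's counts up
  to its own percentile. This is a CSS-compatible reimplementation of
  the published selection procedure — documented steps, reproducible,
  but not guaranteed bit-identical to the original implementation.

RLE as implemented here is the median-of-ratios size factor, which is
already on the library-size scale; the TMM factor is depth-relative and
therefore is the one multiplied by the total count.

## What the simulators emulate

Benchmark inputs are fully synthetic, which keeps every experiment
reproducible from a seed but means parameters are presets rather than
fits to a particular cohort.

**Dirichlet-multinomial tables** (`default_dm_params()`,
`simulate_dm_counts()`) emulate a filtered stool OTU table: `q = 625`
features whose mean proportions decay as a rank power law (exponent 1),
library sizes from a log-normal (log-mean `log(10^4)`, log-sd 0.7,
truncated to [1000, 100000] reads), and a single overdispersion `theta`
controlling between-sample compositional variability. Column sums equal
the drawn library sizes *exactly*, so the drawn sizes are the ground
truth that size-factor estimates are later scored against.
`calibrate_dispersion()` tunes `theta` by monotone bisection (under a
fixed internal seed, averaging a few tables per evaluation) until the
realized fraction of zero cells hits a target; the three sparsity
presets used throughout are ~60%, 70% and 80% zeros. At the 70% preset
with `n = 98` the tables share on the order of 85 nonzero features per
sample pair — the regime the pairwise estimator is designed for. The
power-law exponent was fixed once at 1.0 because it reproduces both the
calibrated sparsity range and that order of pairwise sharing; it is a
preset, not a fit.

**Perturbations** (`perturb_counts()`) corrupt a simulated table after
the fact, breaking the equality between column sums and true library
sizes — that corruption is the point of the benchmark. `fixed` mode
perturbs one global feature subset with one direction per feature
shared by all samples (differential abundance); `random` mode redraws
the subset and directions per sample (sample-specific outliers).
Strong perturbation maps counts to `sqrt(c)` or `c^2`, moderate to
`0.25c` or `4c`. Perturbed values are rounded half-up (so `sqrt(2)`
becomes 1, `sqrt(3)` becomes 2) and zeros stay zeros; directions are
one Bernoulli(1/2) draw per perturbed feature. The rounding rule and
the direction balance are package choices, documented rather than
inherited.

**ZINB two-group tables** (`default_zinb_params()`,
`simulate_zinb_counts()`) follow a zero-inflated negative binomial:
with probability `p_k` a structural zero, otherwise NB with mean
`mu_k * t_i * fold^(k differential in g)` and variance
`mu + phi_k mu^2`. The preset fixes the two dominant features at
relative abundances 0.168 and 0.083, decays the rest as a power law,
and lets structural-zero probability (0.05 to 0.75) and dispersion
(0.5 to 2) grow with rarity rank. The per-sample multiplier `t_i`
(log-normal, log-sd 0.7) gives size factors something identifiable to
recover; that heterogeneity model is a benchmark convention of this
package. `make_daa_design()` marks 5% of features (rounded half-up;
31 of 625, 15 of 300) differential at fold 4 in a uniformly chosen
group ("balanced"), and the unbalanced scene additionally forces the
two dominant features differential in one fixed group.

What passing these benchmarks does *not* show: real tables have
phylogenetically correlated features, batch structure, and taxon-
specific amplification biases none of which the generators model.
The synthetic results demonstrate robustness properties of the
estimators, not end-to-end performance on any particular cohort.

## The differential-abundance test

`fit_nb_wald()` is deliberately plain: per feature, an NB regression of
counts on group with `log(s_i)` as offset, dispersion by per-feature
profile maximum likelihood (method-of-moments start, floored at 1e-8),
group means by Fisher scoring, and a two-sided Wald test, with
Benjamini–Hochberg correction across features. No empirical-Bayes
dispersion shrinkage, independent filtering, or outlier handling is
applied: the benchmark's contrast of interest is between
*normalizations* with the test held fixed, and a fully specified test
makes that contrast reproducible. Degenerate features are flagged, not
fatal: a feature observed in fewer than two samples reports `p = 1`;
a group with all zeros gets a continuity-corrected mean (0.5
pseudo-reads spread over its size factors) and an honestly large
standard error.

Under a pure NB null the test holds its nominal 5% level; under a
zero-inflated null the excess zeros inflate the dispersion estimate and
the test errs on the conservative side. At the benchmark's sample size
(49 per group) the observed FDR with well-behaved size factors stays
within about twice the nominal 0.05. Under the unbalanced scene,
total-sum scaling loses FDR control while pairwise-ratio factors keep
it near nominal — the compositional effect made visible.

## Evaluation statistics

* `sizefactor_correlation()` — Spearman (default) or Pearson
  correlation between estimated factors and true library sizes. Both
  are exposed because rank and linear agreement answer slightly
  different questions; the rank version is the default as the more
  robust summary.
* `run_perturbation_benchmark()` — the full grid (sparsity preset x
  mode x strength x fraction x method), mean correlation with a
  normal-approximation 95% CI (`mean ± 1.96 SE`) across replicates.
  RLE failures become `NA` cells, never crashes. The whole report is a
  pure function of the master seed.
* `variance_rank_analysis()` — for real-data-style comparisons without
  ground truth: median across features of the across-sample variance of
  normalized abundances, per dataset and method (including a RAW
  no-normalization column), ranked with average ranks on ties.
* `paired_signed_rank()` — two-sided Wilcoxon signed-rank p for paired
  method ranks; exact (a dynamic program over doubled ranks, correct
  under ties) up to 25 informative pairs, normal approximation with tie
  and continuity correction beyond.
* `prevalence_stratify()` — top/middle/bottom prevalence terciles,
  near-equal sizes, ties resolved by feature order; all-equal
  prevalences degenerate to a single top stratum.
* `icc()` — intraclass correlation
  `rho = sigma_b^2 / (sigma_b^2 + sigma_e^2)` by the one-way ANOVA
  estimator: `sigma_e^2 = MSW`,
  `sigma_b^2 = max(0, (MSB - MSW)/k0)` with `k0` the unbalanced-design
  average group size. The ANOVA method was chosen over an iterative
  mixed-model fit because it is deterministic, closed-form, and
  unbiased in expectation for exactly the one-way model the definition
  describes; negative variance estimates are clamped to zero. The
  replicate-reproducibility workflow (size factors estimated on the
  fine-grained table, applied to aggregated counts with the same
  samples) is supported by `normalize_counts()` accepting factors
  computed on a different table with identical sample ids.

## Numerical and design choices

* Geometric means in log space throughout; no `prod()` of hundreds of
  ratios.
* `min_shared = 2` by default: a single shared feature makes the
  "median" a single noisy ratio. Raising it trades coverage for
  stability.
* Rounding of perturbed and simulated real-valued quantities is
  half-up everywhere (`floor(x + 0.5)`), chosen once for
  reproducibility across platforms.
* Dispersion bisection brackets `theta` in `[1e-6, 0.999]` on a log
  scale; an unattainable sparsity target reports the attainable range
  instead of silently returning a boundary value.
* Benchmark problem sizes: the shipped tests reproduce the robustness
  ordering with 10 replicates at `q = 625, n = 98` and the
  differential-abundance contrast with 20 replicates at `q = 300`,
  sizes at which every headline ordering is stable under reseeding
  while the whole suite stays quick to run.
* Rare-feature filtering is *not* applied inside any normalizer; each
  is a pure function of its input table, and filtering policy belongs
  to the caller.

## Known limitations

* The comparator implementations follow their published definitions
  plus the documented choices above; they are faithful in behavior but
  not bit-identical to the original packages' internals (notably CSS's
  percentile search).
* The plain NB Wald test is conservative under strong zero inflation;
  it is a benchmark instrument, not a recommendation over purpose-built
  differential-abundance machinery.
* Synthetic presets stand in for parameters estimated from real
  cohorts; absolute performance numbers depend on them, though the
  method *orderings* reported by the benchmarks are stable across the
  preset ranges we tested.
* GMPR assumes a large invariant part of the count distribution, like
  all size-factor methods here; if most features truly change, no
  median-based estimate recovers depth.

## A minimal session

```{r example}
tab <- read_count_table(system.file("extdata", "example_counts.tsv",
                                    package = "gmprnorm"))
gmpr_size_factors(tab)
normalize_counts(tab, gmpr_size_factors(tab))
```

A command-line wrapper over these functions ships at
`system.file("cli", "gmprnorm.R", package = "gmprnorm")` with
subcommands `normalize`, `simulate-dm`, `simulate-zinb`, `daa`,
`benchmark-perturb` and `evaluate-icc`.
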