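---
title: "Pinpointing rare causal variants: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pinpointing rare causal variants: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarepinpoint)
```

## The problem

Gene-based rare-variant tests aggregate many rare variants in a region into
one association statistic, because individually each variant is too rare to
test. Once a region is implicated, the harder question follows: *which* of
its dozens of rare variants are plausibly causal? This package implements
three selection strategies for binary (case-control) traits and the
machinery to benchmark them against each other:

* **ADA** — the adaptive combination of P-values. Its region statistic is
  built directly from per-site P-values, so the threshold that optimises the
  region statistic doubles as a variant-selection rule.
* **BE-SKAT / BE-BURDEN** — backward elimination wrapped around the SKAT or
  burden score test: variants whose removal makes the region P-value smaller
  are discarded; survival frequencies over random variant subsamples
  ("return counts") are partitioned into interesting vs not.

## Per-site evidence: the Fisher mid-P value

For a variant with `m` minor alleles among `n` alleles total, `n1` of which
belong to the enriched group, the one-sided mid-P value is

    p = P(X > x_obs) + 0.5 * P(X = x_obs),    X ~ Hypergeometric(n, n1, m).

Counting only half the observed table's probability removes most of the
conservativeness of the exact test for the extremely discrete tables rare
variants produce; under permutation the mean mid-P is close to 0.5 where the
exact P is biased upwards. The 2x2 table is allele-based (minor-allele
counts against `2 x` group sizes). A variant more frequent in cases is
*deleterious-inclined*, more frequent in controls *protective-inclined*,
exactly equal frequencies are *balanced* and contribute to neither
directional score.

Two conventions here were genuinely open and are fixed as follows:

* **ADA consumes two-sided mid-P values** (twice the smaller one-sided
  value, capped at 1). With one-sided values the ADA permutation P-value of
  the ANGPTL4 worked example lands near 0.07, irreconcilable with the
  reference value (~0.047) reported for these carrier counts; the two-sided
  convention reproduces it within Monte-Carlo error. `per_site_scan()`
  reports both columns (`p_mid`, `p_two`), and `ada_test(p_type =)` exposes
  the choice.
* **Selection is direction-restricted.** The minimising score cell fixes
  both the optimal threshold and a direction; the selected set is the
  variants *of that direction* below the threshold — the variants that
  actually drive the winning score. The direction-blind alternative selects
  roughly twice as many variants on null regions.

## The ADA test

At truncation threshold `tau` and direction `d`, the significance score is

    S_d(tau) = sum_{i: dir_i = d, p_i <= tau} w_i * (-ln p_i),

with Beta(1, 25)-density weights `w_i = dbeta(MAF_i; 1, 25)` evaluated at
the pooled (cases + controls) MAF — the same weights used by SKAT and
burden, so the three methods are compared on one footing. The threshold grid
defaults to `0.10, 0.11, ..., 0.20`; widening it buys little at typical
sequencing sample sizes because per-site P-values of interesting variants
rarely sit above 0.2. Scores over the `J x 2` grid are converted to
permutation P-values with `B` label permutations (default 1000); the
smallest cell P-value is the test statistic, and its null distribution is
read from the same permutations (each permuted sample's minimum cell
P-value is obtained by ranking its scores inside the pooled permutation
scores — the standard min-P double use, no nested permutation loop). The
final P-value uses the add-one estimator `(1 + k)/(B + 1)`, which cannot
return zero; the plain `k/B` estimator is reported alongside. Any strictly
decreasing evidence transform in place of `-ln` leaves the permutation test
valid; the transform is a pluggable argument.

Ties among cells attaining the minimum are broken towards the smallest
threshold (the most conservative selection). On real data the selection is
gated: if the final P-value exceeds the significance level (default 0.05)
the selected set is empty, since pinpointing inside an unassociated region
is not meaningful. Benchmarking simulations disable the gate so selection
behaviour is measured on every replicate.

## SKAT and burden score tests

Both tests build on the weighted single-variant scores
`U_j = w_j * sum_i G_ij (y_i - ybar)` and their null covariance
`V = ybar(1 - ybar) * (w w') ∘ (Gc' Gc)` under the no-covariate binomial
null. SKAT's statistic is `sum_j U_j^2`, distributed as a mixture of
chi-square(1) variables weighted by the eigenvalues of `V`; the burden
statistic is `(sum_j U_j)^2` against a single chi-square. Burden is
powerful when effects are unidirectional and dilutes itself when risk and
protective variants coexist; SKAT squares first and is immune to the
cancellation.

The mixture tail is computed by adaptive quadrature of Imhof's integral
representation (absolute tolerance `1e-9`), after dropping eigenvalues
below `1e-10` of the largest (which changes the tail by far less than the
tolerance); if the quadrature fails the Liu-Tang-Zhang moment-matched
chi-square is used and the route is recorded. Inside the backward
elimination loop only the moment approximation is used: the loop compares
P-values of closely related subsets thousands of times, and the smooth
approximation preserves the orderings at a fraction of the cost.

**Small-sample adjustment.** For binary traits at a few hundred samples the
asymptotic mixture is anti-conservative. With `small_sample = TRUE` (the
default below 2000 samples) the tail is recomputed from the *exact*
variance of the statistic under independent centred-Bernoulli residuals
together with a kurtosis estimated from phenotype resamples (default
10,000, seedable), via a moment-matched chi-square with `df = 12/kurtosis`.
On the ANGPTL4 example this moves the SKAT P-value from 0.023 (asymptotic)
to about 0.012, in line with the value a parametric bootstrap of the null
gives. The adjustment is intentionally *not* applied inside backward
elimination, whose inner test stays asymptotic.

## Backward elimination

One elimination pass computes the inner test on the current set, then the
P-value after removing each variant in turn; the best strict improvement is
made permanent until no removal helps. Ties are broken towards the smallest
variant index; a set of one variant terminates; a degenerate subset (zero
score variance) counts as P = 1 and can never be preferred. The final
P-value is never worse than the starting one. `be_run()` repeats this on
`B` random subsamples of `r` variants (default `r = 20`, capped at the
region's variant count — note that once `r` reaches the variant count every
subsample is the full region and the procedure is deterministic), counts
survivals, and partitions the return counts with a two-component
binomial-mixture EM: median-split initialisation, at most 200 iterations,
log-likelihood tolerance `1e-8`, higher-mean component labelled
interesting, posterior > 0.5 assignment. All-equal counts carry no
separation signal and yield an empty selection. A minimum-improvement
epsilon (default 0) is exposed for experimentation with stricter
elimination.

## The simulator

`generate_pool()` produces a pool of 10,000 haplotypes by tiling the region
with independently coalescing blocks (default 1250 bp): linkage is complete
within a block and absent between blocks — a deliberately coarse stand-in
for recombination. Each block runs a Kingman coalescent under a
piecewise-constant size history with infinite-sites mutations. The default
history is **stylised, not a demographic estimate**: explosive recent
growth (400x for the most recent epoch), a severe founding bottleneck, a
long intermediate epoch and a compact ancestral population, with
`theta_per_kb = 0.60`. These values were calibrated once, jointly, to two
regime anchors for a 5 kb region and a 500 + 500 sample: about 45 variants
in the analysis marker set, and a realized causal percentage near 8% when
25% of rare pool variants (population MAF < 1%) are designated causal. The
second anchor is the stringent one: it requires most rare causal sites to
remain unobserved in a 2000-chromosome sample, which forces a
singleton-heavy rare tail alongside a substantial 1-5% MAF class. A
consequence worth knowing: the calibrated spectrum carries more
intermediate-frequency (near-continuous P-value) variants than a
growth-only human spectrum would, which raises the absolute false-positive
counts of threshold-based selection under the null somewhat; comparisons
*between* methods are unaffected because all three see the same regions.

Causal variants are drawn uniformly from rare pool sites; `ceiling()`
rounds both the causal count and the risk count (`r_isk` of causal, the
rest protective). Effect sizes come from the population-attributable-risk
relation `GRR = 1 + PAF/(MAF(1 - PAF))` (deleterious; protective variants
get the reciprocal, hence smaller-magnitude effects at equal MAF — e.g.
PAF 0.3% at MAF 1% gives GRR 1.30, PAF 0.5% gives 1.50). Disease status is
Bernoulli with penetrance `f0 * prod_j GRR_j^(carried causal alleles)`,
capped at 1, baseline `f0 = 0.01`. Case-control sampling is rejection
sampling of haplotype pairs drawn with replacement, capped at `max_draws`
(2e6) with a diagnostic error; a scenario with no effective causal variant
is sampled by the exact shortcut of drawing the required number of subjects
directly, since phenotype and genotype are then independent. The analysis
marker set is the sites with population MAF strictly below 5% that are
polymorphic in the sample; monomorphic columns carry no information and
every downstream test would ignore them.

What the simulator does *not* emulate: realistic linkage disequilibrium
within blocks, non-uniform recombination and gene conversion, sequencing
error and missingness, population stratification. Passing benchmarks here
therefore says the methods behave as designed under idealised sampling, not
that their error rates transfer to any particular real study.

## Evaluation

`score_selection()` counts true and false positives against the simulation
truth; PPV is `TP/(TP+FP)` and *undefined* (not zero) for empty selections.
Summaries report both conventions — the headline PPV mean excludes empty
selections, `ppv_mean_zero` counts them as zero — together with standard
deviations, coefficients of variation and significance-stratified rows
(`gene_test_p <= cutoff`). `rank_methods()` orders methods by mean PPV;
because `a/(a+b) > c/(c+d)` iff `a/b > c/d` for positive counts, the PPV
ranking always coincides with the TP/FP signal-to-noise ranking.

## Worked example

The shipped ANGPTL4 carrier table (17 rare and low-frequency variants among
198 high-triglyceride cases and 202 low-triglyceride controls, Dallas Heart
Study European Americans) reconstructs a surrogate genotype matrix with
disjoint heterozygous carriers — the published marginal counts cannot
recover which samples co-carried two variants, and for variants this rare
distinct carriers are the overwhelmingly likely configuration. On this
reconstruction (`angptl4_example()`), with `B = 1000` permutations: ADA
gives a final P-value near 0.045 and pinpoints exactly one variant, E40K —
the only variant of the seventeen with prior literature support for a
triglyceride association; SKAT gives P ≈ 0.012 (small-sample adjusted;
0.023 asymptotic) and BE-SKAT selects three variants including E40K; the
burden test is insensitive here (P ≈ 0.66 on this reconstruction — risk-
and protective-inclined variants dilute each other) and BE-BURDEN selects
eight variants. The burden-side quantities are the ones most sensitive to
the unrecoverable carrier-overlap configuration: plausible overlap among
control carriers raises the burden P-value by several hundredths and can
shift the BE-BURDEN selection by one variant.

## Problem sizes used by the reproduction script

`scripts/acceptance.R` regenerates every headline number with, per run:
300 null-region replicates for the ADA false-positive mean, 100 for each
backward-elimination variant (B = 1000 permutations or subsamples
throughout), and 500 replicates for the realized causal percentage. These
sizes give Monte-Carlo standard errors comfortably inside the
between-method differences being demonstrated.

## Known limitations

* No covariate adjustment anywhere: per-site tests are exact 2x2 tests and
  the score tests use the intercept-only binomial null.
* Quantitative traits, family data, X-linked dosage rules, imputation and
  multiallelic decomposition are out of scope.
* The coalescent stand-in is calibrated to a frequency-regime, not to
  sequence-level realism (see above).
* Backward elimination inherits the greedy path's instability: on data
  where the burden score sum is nearly balanced, the first elimination step
  decides whether the risk- or the protective-side variants survive.
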