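---
title: "LD-based effective size estimation with bias corrections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based effective size estimation with bias corrections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldne)
```

## The estimation problem

Genetic drift leaves a signature in the association between alleles at
different loci: in a closed population of effective size $N_e$, unlinked loci
carry an equilibrium squared gametic correlation of roughly $1/(3N_e)$. The
LD method reads that signature from a single sample of diploid genotypes.
Because a sample of $S$ individuals also generates association by chance, the
observable quantity is

$$E[\hat r^2] \approx E[\hat r^2 \mid S] + \frac{1}{3N_e},$$

and the estimator subtracts the sampling expectation before inverting. For
species that reproduce over many years, *what* the resulting number means
depends on who was sampled: a single newborn cohort reflects the effective
number of breeders $N_b$ of the parental pool of that one reproductive
cycle, while a mixed-age sample reflects a generational $N_e$, biased
downward because the sample mixes cohorts whose parents overlap.

## The composite r² and its calibration

With unphased genotypes the gametic correlation is not directly observable.
The package uses Burrows' composite disequilibrium: writing genotypes as
alternate-allele counts $x, y \in \{0,1,2\}$ over the $n$ individuals
non-missing at both loci,

$$\hat\Delta = \frac{n}{n-1}\left(\frac{\overline{xy}}{2} - 2\hat p_A \hat p_B\right),
\qquad
\hat r^2 = \frac{\hat\Delta^2}{\hat\tau_A \hat\tau_B},
\qquad
\hat\tau = \hat p(1-\hat p) + (\hat P_{hom} - \hat p^2),$$

where $\hat P_{hom}$ is the observed frequency of alternate-allele
homozygotes, so $\hat\tau$ absorbs within-locus departures from
Hardy–Weinberg proportions. Two details matter:

* **The $n/(n-1)$ factor is load-bearing.** The sampling expectations used
  downstream ($1/n + 3.19/n^2$ for $n \ge 30$; $0.0018 + 0.907/n +
  4.44/n^2$ below) are empirical calibrations for the small-sample-corrected
  form of $\hat\Delta$. We verified this by simulation during development:
  with the corrected form, discrete Wright–Fisher truth $N_e = 100$ is
  median-recovered within a few percent at the 50-individual, 300-locus
  design, while the plain moment estimator is ~45% upwardly biased at the
  same design. `pair_r2(correct = FALSE)` exposes the plain form, for which
  the self-correlation of a locus is exactly 1.
* **Pairs are weighted by their own $n$.** Missing data make the
  pairwise-complete sample size unequal across pairs; both the mean
  $\hat r^2$ and the mean sampling expectation are weighted by the pairwise
  $n$, and the point estimate is inverted at the harmonic mean pairwise
  sample size. Pairs that become monomorphic inside their pairwise-complete
  subset are undefined and are skipped but counted
  (`glance()$n_pairs_skipped`).

The inversion uses the closed form
$\hat N = (1/3 + \sqrt{1/9 - 2.76\,\hat r^2_{drift}})/(2\hat r^2_{drift})$
for $S \ge 30$ (coefficients 0.308/2.08 below 30). A negative square-root
argument is clamped to zero; non-positive drift yields an **indeterminate**
estimate, represented as `Inf` internally and `"inf"` in every serialised
output — the standard convention for "the data cannot distinguish this
population from an infinite one".

## Jackknife confidence intervals

With thousands of loci the $O(L^2)$ locus pairs are massively
pseudoreplicated; a CI built from the pair count alone would be absurdly
narrow. The package jackknifes **individuals** (delete-one): the jackknife
variance $V$ of the drift statistic is converted to an effective chi-square
degrees of freedom $n' = 2\overline{\hat r^2}{}^2 / V$, a CI for the mean
$\hat r^2$ is taken from the scaled chi-square,
$[\,n'\overline{\hat r^2}/\chi^2_{1-\alpha/2,n'},\;
n'\overline{\hat r^2}/\chi^2_{\alpha/2,n'}\,]$, the sampling expectation is
subtracted from each bound, and both are mapped through the (monotone
decreasing) inversion. The upper Ne bound is therefore `Inf` exactly when
the lower drift bound is non-positive. The exact chi-square mapping has
implementation freedom in the published description; our arbiter is the
coverage property test (CIs cover a true $N_e = 200$ in well over 80% of
replicates at the 100 × 500 design). When every leave-one-out value
coincides (to numerical noise, relative 1e-12), the CI is collapsed to the
point and flagged `ci_degenerate`.

## Rare-allele screening

Rare alleles inflate $\hat r^2$ disproportionately. The default screen is
**no-singletons** — loci whose minor allele occurs as exactly one copy are
dropped — matching standard practice for large SNP panels; a `pcrit`
minor-allele-frequency threshold and `none` are also available
(`estimator_config()`).

## The bias-correction calculus

Three multiplicative corrections, chained without intermediate rounding;
CI bounds are pushed through exactly the same factors, and infinite bounds
stay infinite (`adjust_cohort_estimate()`, `adjust_mixed_estimate()`).

| step | divisor | applies to |
|---|---|---|
| physical linkage | $0.098 + 0.219\ln(\mathrm{chr})$ | all raw estimates |
| age structure (Nb) | $1.103 - 0.245\log_{10}(\mathrm{ratio})$ | single-cohort path |
| Nb → Ne | $0.485 + 0.758\log_{10}(\mathrm{ratio})$ | single-cohort path |
| mixed-age Ne | $0.8$ (see below) | mixed-age path |

Logarithm bases differ by design: the linkage regression uses the natural
log, the age-structure regressions base 10 — we verified that only this
combination reproduces the published worked tables this package ships as
test oracles.

Two genuinely open conventions had to be decided, and both are exposed as
arguments rather than silently fixed:

* **Life-history ratio** (`ratio_convention`). The age-structure regressions
  are stated in terms of AL/α (adult lifespan over age at maturity), but the
  published worked tables we reproduce are only recovered with
  longevity/α (40/α for both stocks), not with the stated AL/α values
  (34.3/5.7 and 35.1/4.9, which land ~2% lower). The default is
  `longevity_over_alpha`, matching the tables; `AL_over_alpha` implements
  the prose.
* **Mixed-age mode** (`mode`). The prose correction for mixed-age samples is
  a plain division by 0.8 (undoing the expected ~20% downward bias). The
  printed mixed-age tables, however, are reproduced — all four rows, and the
  associated "+74%" total adjustment — only by $(x/0.8)\times 1.103$, i.e.
  with the age-structure regression's intercept applied at ratio 1. The
  default `as_tables` reproduces the tables; `as_text` implements the prose.
  One printed upper bound (the largest mixed-age CI limit) is not exactly
  reproducible under either computation (off by ~0.04%); we treat it as a
  typesetting-level inconsistency and do not calibrate to it.

Because the printed tables round every stage to integers while the chain
must not, reproduction tests carry a ±1 tolerance; the package itself only
rounds for display (`format_adjusted()`, the TSV report), never internally.

The linkage divisor crosses 1 near 61 chromosomes: for ≥ ~61 chromosomes
the correction is a slight *decrease* and a message notes that the residual
linkage bias is minimal.

## The simulators and what "truth" means

`simulate_discrete_wf()` is the clean oracle: $N$ monoecious adults,
multinomial parent draws, haplotype transmission with free recombination by
default; burn-in defaults to $N$ generations (unlinked-locus LD equilibrates
much faster; allele-frequency spectra take longer, and the default covers
both at the desk scales used here). True $N_e$ is the census $N$; the
pedigree of the final cycle also yields a demographic
$N_b = (\bar k N_p - 2)/(\bar k - 1 + V_k/\bar k)$ from realised
offspring-gamete counts ($N_p$ actual parents, $\bar k$, $V_k$ their mean
and variance) — stated explicitly because no single "true Nb" definition is
universal.

`simulate_age_structured()` adds overlapping generations: fixed annual
recruitment, breeding restricted to ages ≥ α, annual survival $s$ to a
maximum age, and optional overdispersion of reproductive success
(per-adult, per-year gamma fecundity weights with variance `dispersion - 1`;
the default 1 gives equal expected contributions, appropriate for a
broadcast spawner null — the real variance in reproductive success of such
species is unknown and is deliberately a free knob, not a calibrated one).
The snapper-like preset (`snapper_sim_config()`) uses α = 5, longevity 40,
survival 0.85, 24 chromosomes, 1000 loci. For the equal-contribution case
the census count of mature adults approximates the generational effective
size (a standard life-table calculation puts the two within ~15% for this
life history), and that is the demographic reference the coverage property
test uses, with a deliberately loose ≥ 70% bound — the age-structure
regressions are themselves approximations.

Loci are carried as haplotypes, so physical linkage is real when asked for:
adjacent loci on a chromosome recombine at `recomb_fraction` (0.5 = free).
This is used only for the directional test that excluding same-chromosome
pairs raises the estimate; the estimator's default keeps all pairs and
leaves linkage to the chromosome-number correction, consistent with how the
worked tables were produced.

What the generator does **not** emulate: RAD-style ascertainment bias,
genotyping error, informative missingness (missing calls are uniform at
random, at the ~0.2–0.6% scale of real reduced-representation data),
selection, migration, or sex structure. Passing tests therefore validate
the estimator's statistical machinery under its own model assumptions, not
robustness to those real-data pathologies.

## Validation designs and numerical choices

The test suite runs entirely at desk scale, chosen so the full suite
completes in minutes while keeping each check statistically meaningful:
oracle equivalence of the composite r² against an exhaustive 3×3
genotype-count computation (1000 random instances, 1e-12); Wright–Fisher
recovery of $N_e = 100$ (50 replicates, 50 × 300 design, median within
25%); jackknife coverage of $N_e = 200$ (100 replicates, 100 × 500 design,
≥ 80% at nominal 95%); and the snapper-like directional properties (30
replicates each): mixed-age estimates fall below cohort-derived Ne, and
pooling diverged populations depresses the estimate via mixture LD.

Other numerical conventions: modal-genotype imputation for PCA breaks ties
toward the smaller genotype (deterministic); permutation p-values use the
add-one rule $(1 + \#\{perm \ge obs\})/(1 + B)$, which is valid (never
anti-conservative) at any $B$; Weir–Cockerham FST is the multi-locus
ratio-of-sums estimator, so loci never enter as pre-averaged ratios; the
unbiased expected heterozygosity uses the $2n/(2n-1)$ gene-copy correction.

## Known limitations

* Parity with existing LD-method software is numerical-contract-level (the
  published formulas), not bit-level; implementation differences in their
  CI internals are expected.
* The random-mating (monoecious, selfing-allowed) model is the only mating
  system; no monogamy variant, no temporal or sibship estimators.
* Estimation at the full 200 × 6818 scale of a real SNP panel is supported
  but memory-hungry (the pair statistics are dense L × L cross-products);
  the validation suite runs at hundreds of loci, which is where the
  estimator's statistical behaviour is established.
* FIS is the population-inbreeding reading $1 - H_O/H_E$ averaged over
  variant loci; the variance-components FIS is out of scope, and diversity
  means are over within-sample variant loci only.
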