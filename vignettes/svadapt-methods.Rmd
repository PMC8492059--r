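---
title: "Models and methods behind svadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svadapt)
```

svadapt analyzes structural-variant (SV) genotypes in multi-population
cohorts: it filters genotypes, measures linkage disequilibrium (LD), scans
for component-specific allele-frequency differentiation under an admixture
model, tags candidate archaic-introgressed variants, and fits selection
parameters to observed allele-frequency profiles by forward simulation and
approximate Bayesian computation (ABC). This vignette explains each model,
its assumptions, the defaults, and the numerical choices; it is the
package's design record, not a results report.

## Genotype quality control

SV genotyping from short reads leaves two characteristic artifacts. Poorly
accessible loci simply fail: we drop variants genotyped in under 50% of
samples (`min_call_rate`). Collapsed paralogous repeats masquerade as
variants at which nearly every individual is heterozygous: we test each
variant in each population with a one-sided exact Hardy–Weinberg test
against heterozygote *excess* and drop variants violating it (p < 1e-4) in
at least half of the populations (13 of the canonical 26; in general
`ceiling(P/2)`). The test conditions on the minor-allele count and uses the
Levene–Haldane distribution of the heterozygote count; the one-sided upper
tail is the p-value. Only excess is penalized — heterozygote *deficits* are
expected under population structure (Wahlund effect) and are not an
artifact signature. Missing genotypes are excluded from both the test
counts and allele frequencies, never imputed.

Allele frequencies are unfolded (always the alternative allele) per
population, with a pooled row, matching the `sum_AC` / `sum_NCHROBS` / `AF`
table layout. SV callset matching uses a 500 bp start-distance and a 10%
length tolerance, with the longer of the two lengths as the denominator and
no type or strand requirement.

## Linkage disequilibrium

Pairwise r² between unphased dosage vectors is computed from
maximum-likelihood haplotype frequencies under random mating, resolving the
phase of double heterozygotes by EM (the estimator behind standard
genotype-analysis tools). Pairs are complete-case; monomorphic partners
return r² = 0 with a flag rather than an error, because a windowed max-LD
scan must tolerate them. The windowed scan takes, for each focal SV and
population, the `n_nearest = 100` panel variants by distance within ±1 Mb
(ties broken by position), excludes the focal variant by id, and reports
the maximum r² with its partner. A 1 Mb default window is used; both the
window and the variant count are configurable.

The closed-form ceiling on r² for minor-allele frequencies
$p_a \le p_b$ is
$$r^2_{max} = \frac{p_a(1-p_b)}{(1-p_a)\,p_b},$$
which explains the discrete peaks (1, 0.497, 0.330, ...) in empirical
max-LD distributions for rare variants. Inputs are folded to minor
frequencies and sorted internally; the formula exceeds 1 otherwise.

## Admixture-aware differentiation scan

The scan models individual $i$'s genotype at variant $j$ as
$g_{ij} \sim \mathrm{Binom}(2, \sum_k q_{ik} f_{kj})$ with admixture
proportions $Q$ and component frequencies $F$. `fit_admixture()` maximizes
this likelihood by the classical alternating EM updates; the log-likelihood
is non-decreasing by construction. $Q$ starts uniform — which keeps
identical samples identical at every iterate — and $F$ starts random, which
breaks the component-label symmetry; labels are therefore arbitrary up to
permutation. EM sharpness grows with the variant panel: at a few hundred
variants maximum-likelihood ancestry of a pure individual plateaus around
0.85–0.95 rather than 1.0, a finite-panel property of the likelihood and
not a defect; genome-scale panels sharpen it. Variants not in the admixture
panel (e.g. SVs) are scored afterwards by `component_freqs()`, which
re-estimates $F$ columns with $Q$ held fixed.

Deviations of non-reference component frequencies from the reference
component, $d_j = (f_{kj} - f_{rj})_{k\ne r}$, are modeled as
$d_j \sim \mathcal{N}(0, c_j C)$ with $c_j = f_{rj}(1-f_{rj})$ and $C$ the
genome-wide $(K-1)\times(K-1)$ covariance estimated as
$\hat C = M^{-1}\sum_j d_j d_j^\top / c_j$ (boundary variants dropped, PSD
projection if needed). The selection hypothesis for component $m$ inflates
that component's variance: a scalar of 10 — representing the furthest a
selected variant could drift — is added to the focal diagonal entry of $C$,
or to every entry when $m$ is the reference component (shifting the root is
equivalent to inflating all entries jointly; the choice of which entries
receive the scalar for the reference component was genuinely open and this
root-shift convention is ours). The likelihood ratio statistic is
$LRS = 2(\ell_{sel} - \ell_{neut})$ with $\ell_{sel}$ maximized over an
interpolation weight $\alpha \in [0,1]$ between $C$ and the inflated
matrix; including $\alpha = 0$ makes the LRS non-negative. The maximization
is a staged grid search (step 0.01, zoomed twice to 1e-6), vectorized over
variants; it matches a dense-grid search to ~1e-9. P-values compare the LRS
to $\chi^2_1$; the statistic is treated as $2\Delta\log L$ precisely so
this comparison is meaningful. Variants with neutral log-likelihood below
−1000 are flagged as null-model failures and excluded from outlier
calling.

Because the χ² reference is approximate for frequency data, outliers are
additionally called empirically: a focal variant is an outlier when its LRS
exceeds the 99.9th percentile of background (SNP/indel) LRS within the same
1% global minor-allele-frequency bin. The percentile is the inverse
empirical CDF (quantile type 1) and the comparison is strict, so a focal
value tied with the background maximum of a small bin is not an outlier;
bins with fewer than $1/(1-0.999)$ background variants are widened
symmetrically with a warning.

## Synthetic cohorts

The generator draws ancestral frequencies $a_j \sim U(0.05, 0.95)$,
component frequencies from the Balding–Nichols model
$f_{kj} \sim \mathrm{Beta}(a_j(1-F_k)/F_k,\,(1-a_j)(1-F_k)/F_k)$, ancestry
proportions from population-specific Dirichlets, and genotypes binomially —
exactly the structure the scan assumes. Defaults: drift $F_k = 0.05$
(continental-scale components), Dirichlet anchor 10 vs 0.3 (sharp but
non-degenerate admixture), missingness 0 unless configured (injected
uniformly at random; real missingness is platform-driven but no model for
it is available). Injections are haplotype-level — two haplotypes per
individual — so that a linked partner variant has a well-defined target r²;
the partner allele is drawn conditionally with
$P(b{=}1\mid a{=}1) = p + r(1-p)$, $P(b{=}1\mid a{=}0) = p(1-r)$ at equal
frequencies, which realizes haplotype correlation $r = \sqrt{r^2}$ exactly.
Breakpoint reads are sampled uniformly from the carrier
(flank–insertion–flank) or non-carrier (flank–flank) haplotype with dummy
qualities; no sequencing error, mapping error, or recombination is
emulated. Tests passing on these cohorts therefore validate the estimators
under their assumed model, not robustness to platform noise.

The scan's power/calibration checks use two deliberate study conditions.
Calibration draws deviations directly from the fitted neutral model
($d_j \sim \mathcal{N}(0, c_j\hat C)$), where the χ²-based false-positive
rate must be conservative. Power uses components at drift 0.01 — the
within-continental scale at which closely related populations differ, which
is where the motivating selection signals live — with the true ancestry
matrix supplied to the scorer; at that drift an allele-frequency shift of
0.4 at common frequencies is a many-sigma outlier and the matched-threshold
rule recovers it reliably. At continental drift (0.05–0.1) the same shift
is within genome-wide noise and no method should flag it.

## Introgression tagging and the diagnostic k-mer

A differentiated SV is a candidate for archaic introgression when (i) its
r² with any putative introgressed marker within ±100 kb exceeds 0.5,
computed in the single population matched to the SV's ancestry component,
and (ii) its pooled allele frequency in the non-admixed outgroup
populations is below 0.01. The outgroup pool excludes recently admixed
cohorts (ASW and ACB by default) and is pooled rather than per-population
(a per-population max-AF mode exists). Archaic allele matching calls the
alternative allele at a site when ≥2 reads support it and reports the count
and fraction of sites agreeing with the modern haplotype; only SNP-like
sites are scored, since no matching criterion for indel/SV sites in
degraded ancient DNA is defensible. The diagnostic-sequence assay
concatenates an upstream flank, the insertion, and a downstream flank (the
canonical case is 11 + 33 + 4 = 48 bp) and counts unique reads containing
it as an exact substring — forward strand only by default, mirroring
stranded read extraction, with a both-strands mode for unstranded
libraries; uniqueness is exact sequence deduplication.

## Demographic simulation

The single-locus Wright–Fisher simulator covers five populations: CEU
splits from the East Asian ancestor at the start of the simulation; the
CHB/JPT and KHV/CDX ancestors split at 9.8 kya; CHB–JPT at 9.0 kya;
KHV–CDX at 1.7 kya (29 years per generation, rounded to 338, 310, 59
generations). All populations grow exponentially from N = 2831 at
1.25e-3 per generation, capped at 17,883 — the printed growth rate and
span do not compose exactly to the printed final size, so the cap enforces
it. The total span defaults to 1686 generations, honoring the prior's
upper bound even though 46 kya at 29 yr/gen is ≈1586; both are
configurable. Each generation applies the deterministic selection update
with fitnesses (1+s, 1+hs, 1), h = 0.5 by default (genic selection, the
convention of standard forward simulators), then binomial drift at the
current size; daughters inherit the parent's frequency and size at splits.
There is no migration, mutation, or recombination — omitting migration
makes selection estimates conservative, since migration would homogenize
frequencies.

Selection acts on the KHV/CDX-ancestral branch and its descendants by
default. When the onset predates that branch's origin, selection is
applied to the branch's ancestors (the East Asian ancestor, and so on) —
without this "lineage tracing" every onset older than the branch is
likelihood-equivalent to onset at the branch's birth, and the onset-time
posterior has an unidentifiable upper tail; with it, early onsets raise
CHB/JPT too and are properly penalized by the data. A
`trace_ancestry = FALSE` switch restores the strict reading.

Summary statistics are Hudson's FST estimator and the population branch
statistic $PBS = (T_{AB} + T_{AC} - T_{BC})/2$, $T = -\log(1-F_{ST})$,
with negative FST truncated at zero and census chromosome counts (2N) as
the default sample sizes in simulation contexts.

## Sequential ABC

Inference of (s, T_adaptive, p0) uses an adaptive population Monte Carlo
scheme: initialize `n_particles` from the uniform priors (s in
[−0.01, 0.2], onset in [1, 1686] generations sampled continuously and
rounded at simulation time, p0 in [0, 1]); each iteration keeps the best
`alpha_keep = 0.5` fraction by Euclidean distance between simulated and
observed five-population end frequencies, resamples and perturbs them with
a component-wise Gaussian kernel of twice the weighted empirical variance
(reflected at the prior bounds, preserving support), and recomputes
importance weights as uniform-prior over kernel-mixture density. It stops
when the fraction of new proposals improving on the previous tolerance
drops below `p_accmin = 0.05`. The distance is unweighted Euclidean by
default (the summary statistic is fixed; the metric was an open choice; a
variance-normalized option exists). One simulation per particle per
iteration; point estimates are weighted medians with equal-tailed weighted
quantile intervals (the inverse cumulative-weight CDF). The default of
2000 particles is a desk-scale choice, not a published value.

The reference observed frequencies (`ighg4_observed_af()`) are
CEU = 0.03, CHB = 0.05, JPT = 0.04, KHV = 0.65, CDX = 0.88: the KHV and
CDX values are published point values; the other three are only displayed
graphically as "much lower" and are fixed here once at small values with
CHB marginally above CEU, as rendered. They are inputs, not tuned
quantities.

## Numerical choices and degenerate inputs

* Frequencies in likelihoods are clamped to [1e-9, 1−1e-9]; variants whose
  reference-component frequency sits within 1e-6 of 0/1 are excluded from
  covariance estimation and scanning (the $c_j = 0$ degeneracy).
* A PSD-but-singular covariance gets a 1e-10 ridge before Cholesky.
* The EM for haplotype frequencies starts at linkage equilibrium and stops
  at a 1e-10 frequency change; ties in the windowed LD scan break by
  ascending position.
* Weighted quantiles use the inverse step CDF (no interpolation), so they
  equal an order-statistics oracle exactly.
* All generators accept a seed and save/restore the global RNG state, so
  library calls never perturb a caller's random stream; the pipeline
  derives per-stage seeds deterministically from one global seed.

## Problem sizes used in the checks

The test suite runs cohorts of 80–300 samples with 100–5000 variants,
10⁴ neutral simulations for the drift and envelope checks, and one
2000-particle ABC run (~30k simulations); these sizes were chosen so each
estimator's sampling error is well below the tested tolerances while the
whole suite stays desk-scale.

## Known limitations

* Single-locus simulation only: no linked-selection, haplotype or
  recombination effects; ABC summaries are end frequencies only.
* The admixture EM is unaccelerated and can need ~10³ iterations near
  boundary optima; panels of ≥500 variants are recommended for stable
  covariance estimates.
* Only one ancestry component is tested at a time; joint multi-component
  selection hypotheses are out of scope.
* Outgroup rarity and LD tagging inherit the biases of the supplied marker
  set; the package does not detect introgression ab initio.
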