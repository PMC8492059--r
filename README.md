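# svadapt

Population-genetic analysis of structural variants (SVs) in multi-population
human cohorts: quality control of graph-genotyped SVs, linkage
disequilibrium (LD) with the closed-form r² ceiling for rare variants, an
admixture-aware likelihood-ratio scan for local adaptation, tagging of
candidate archaic-introgressed SVs with a breakpoint-spanning diagnostic
k-mer assay, and inference of selection parameters (selection coefficient,
onset time, starting frequency) by Wright–Fisher forward simulation and
sequential approximate Bayesian computation (ABC).

The package is aimed at population geneticists who have multi-sample SV and
SNP genotypes (VCF) with a sample→population map and want to go from raw
genotypes to candidate adaptive and introgressed loci, and from observed
allele-frequency profiles to selection-parameter posteriors. A synthetic
cohort generator (Dirichlet admixture over Balding–Nichols component
frequencies) makes the whole pipeline testable without any external data.

## The models in brief

* **QC** — call-rate filter (≥50% genotyped) plus a one-sided exact
  Hardy–Weinberg test against heterozygote *excess* (the collapsed-repeat
  artifact), using the Levene–Haldane conditional distribution; variants
  violating it (p < 1e-4) in at least half the populations are removed.
* **LD** — r² from unphased genotypes via EM haplotype-frequency
  estimation; windowed max-LD scans; and the ceiling
  `r²max(pa, pb) = pa(1−pb) / ((1−pa) pb)` for minor allele frequencies
  `pa ≤ pb`, which produces the characteristic peaks at 1, 0.497, 0.330 in
  empirical max-LD distributions of rare variants.
* **Scan** — individuals are mixtures of K ancestry components
  (`g ~ Binom(2, Σ q·f)`); component frequency deviations follow
  `d_j ~ N(0, c_j C)` with genome-wide covariance C; the selection
  hypothesis inflates one component's variance by a scalar of 10, and the
  likelihood ratio statistic `LRS = 2 Δlog L` (maximized over an
  interpolation weight α ∈ [0, 1]) is compared to χ²₁ and to the 99.9th
  percentile of frequency-matched background variants.
* **Introgression** — candidates need r² > 0.5 with a putative introgressed
  marker within 100 kb *and* allele frequency < 0.01 in the non-admixed
  outgroup populations; a 48 bp breakpoint-spanning diagnostic sequence
  (11 bp flank + 33 bp insertion + 4 bp flank) supports exact-match
  presence calls in raw reads.
* **Demography + ABC** — a five-population Wright–Fisher model (CEU, CHB,
  JPT, KHV, CDX; splits at 46/9.8/9.0/1.7 kya, N from 2831 growing at
  1.25e-3/generation to 17,883) with selection on the KHV/CDX lineage;
  sequential ABC (stopping rule p_accmin = 0.05) infers (s, T_adaptive,
  p0) from the five observed end frequencies.

## Worked example

```r
library(svadapt)

# the r2 ceiling for a singleton-doubleton pair in 198 chromosomes
r2_max(1/198, 2/198)
#> [1] 0.4974619

# a synthetic two-population cohort with an introgressed SV + linked marker
spec <- cohort_spec(populations = c("ESN", "CDX"), n_samples_per_pop = 60,
                    K = 2, n_variants = 5, seed = 1)
cohort <- generate_cohort(spec)
gm <- inject_variant(cohort$gm, cohort$truth,
                     injection_spec("introgressed", target = "CDX",
                                    target_af = 0.7, background_af = 0.002,
                                    ld_partner_r2 = 0.9, pos = 50000L,
                                    id = "sv1"),
                     popmap = cohort$popmap, seed = 2)
cohort$popmap$superpopulation <- rep(c("AFR", "EAS"), each = 60)
markers <- data.frame(chrom = "chr1", pos = 50500L)
tag_candidates("sv1", markers, gm, cohort$popmap, focal_pop = "CDX")
#>   sv_id population best_marker      r2 outgroup_af candidate reason
#> 1   sv1        CDX sv1_partner 0.96139           0      TRUE   <NA>
```

The injected SV is tagged as an introgression candidate: it is in strong LD
(r² = 0.96) with the marker in the focal population and absent from the
outgroup (AF = 0), passing both gates.

```r
# infer selection parameters for the canonical adaptive insertion profile
model <- demographic_model()
post <- abc_sequential(make_wf_simulator(model), ighg4_observed_af(),
                       prior_spec(), n_particles = 2000, seed = 1)
posterior_summary(post)
#>    parameter        point        lower       upper
#> 1          s   0.07337810  0.014759176   0.1968379
#> 2 T_adaptive 100.05432905 38.235038987 375.3587155
#> 3         p0   0.09367573  0.008178525   0.3114291
joint_dependence(post)   # -0.82
```

The posterior puts the selection coefficient near 0.07 with onset around
100 generations (~2900 years) ago from a starting frequency near 0.09, and
the negative s–T correlation shows the usual trade-off: older, weaker
selection explains the same frequency differences as recent, stronger
selection.

## Layout

* `R/` — implementation; `vignettes/svadapt-methods.Rmd` — models,
  assumptions, defaults, and design decisions.
* `inst/scripts/svadapt.R` — thin command-line wrapper
  (`run`, `simulate`, `abc`, `kmer-scan`) over the package functions.
* `tests/testthat/` — unit, property, and end-to-end suites with
  independent oracles (enumeration, grid search, analytic recursions).
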