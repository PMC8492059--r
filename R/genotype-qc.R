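#' Per-variant genotyping call rate
#'
#' Fraction of samples with a non-missing dosage for each variant.
#'
#' @param gm genotype_matrix
#' @param variants optional variant ids or indices to restrict to
#' @return named numeric vector in \[0, 1\].
#' @export
call_rate <- function(gm, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, gm$variants$id)
    d <- d[, variants, drop = FALSE]
  }
  colMeans(!is.na(d))
}

#' One-sided exact Hardy-Weinberg test for heterozygote excess
#'
#' Exact conditional test of Hardy-Weinberg equilibrium against an excess of
#' heterozygotes, the genotyping artifact signature left by collapsed
#' paralogous repeats (nearly every sample called heterozygous). Conditional
#' on the minor-allele count \eqn{n_m} in \eqn{n} diploids, the number of
#' heterozygotes under random mating follows the Levene-Haldane distribution
#' \deqn{P(n_{AB} \mid n, n_m) = \frac{n!}{n_{AA}!\,n_{AB}!\,n_{BB}!}
#'       \; 2^{n_{AB}} \Big/ \binom{2n}{n_m},}
#' and the one-sided p-value is the upper tail \eqn{P(N_{AB} \ge n_{AB})}.
#'
#' @param n_AA,n_AB,n_BB genotype counts (vectors recycle together)
#' @return p-values in (0, 1\].
#' @examples
#' hwe_excess_het_p(0, 2, 0)  # 2/3
#' hwe_excess_het_p(1, 0, 1)  # 1
#' @export
hwe_excess_het_p <- function(n_AA, n_AB, n_BB) {
  n <- cbind(n_AA, n_AB, n_BB)
  if (any(n < 0)) stop("genotype counts must be non-negative")
  apply(n, 1L, function(cnt) {
    if (sum(cnt) == 0L) stop("all genotype counts are zero")
    hwe_upper_tail(cnt[1L], cnt[2L], cnt[3L])
  })
}

# log pmf of the Levene-Haldane distribution over its heterozygote support
hwe_log_pmf <- function(n, n_minor) {
  support <- seq.int(n_minor %% 2L, min(n_minor, 2L * n - n_minor), by = 2L)
  n_a <- (n_minor - support) / 2L       # minor homozygotes
  n_b <- n - n_a - support              # major homozygotes
  lp <- lgamma(n + 1) - lgamma(n_a + 1) - lgamma(support + 1) -
    lgamma(n_b + 1) + support * log(2) -
    (lgamma(2 * n + 1) - lgamma(n_minor + 1) - lgamma(2 * n - n_minor + 1))
  list(support = support, log_pmf = lp)
}

hwe_upper_tail <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_minor <- min(2L * n_AA + n_AB, 2L * n_BB + n_AB)
  pmf <- hwe_log_pmf(n, n_minor)
  p <- sum(exp(pmf$log_pmf[pmf$support >= n_AB]))
  min(p, 1)
}

#' Filter structural variants on call rate and heterozygote excess
#'
#' Removes variants genotyped in fewer than `min_call_rate` of samples, and
#' variants showing significant heterozygote excess
#' (\code{\link{hwe_excess_het_p}} below `hwe_alpha`) in at least
#' `min_violating_pops` populations. Output order follows input order.
#'
#' @param gm genotype_matrix
#' @param popmap popmap (see \code{\link{population_map}})
#' @param min_call_rate minimum fraction of genotyped samples (default 0.5)
#' @param hwe_alpha per-population significance level (default 1e-4)
#' @param min_violating_pops number of populations that must violate HWE for
#'   removal; default `NULL` = more than half, i.e. `ceiling(P / 2)` over the
#'   P populations present (13 for the canonical 26-population cohort)
#' @return list of class `qc_report`: `kept` (ids), `removed`
#'   (data.frame id/reason), `call_rate` (per variant), `hwe_violations`
#'   (per-variant count of violating populations),
#'   `hwe_p` (variants x populations matrix).
#' @export
filter_svs <- function(gm, popmap, min_call_rate = 0.5, hwe_alpha = 1e-4,
                       min_violating_pops = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- pop_sample_index(gm, popmap)
  if (is.null(min_violating_pops))
    min_violating_pops <- ceiling(length(pops) / 2)
  if (min_violating_pops > length(pops))
    stop("min_violating_pops (", min_violating_pops,
         ") exceeds the number of populations (", length(pops), ")")
  m <- nrow(gm$variants)
  if (m == 0L) {
    return(structure(list(kept = character(0),
                          removed = data.frame(id = character(0),
                                               reason = character(0)),
                          call_rate = numeric(0),
                          hwe_violations = integer(0),
                          hwe_p = matrix(NA_real_, 0, length(pops))),
                     class = "qc_report"))
  }
  cr <- call_rate(gm)
  hwe_p <- matrix(NA_real_, m, length(pops),
                  dimnames = list(gm$variants$id, names(pops)))
  for (p in seq_along(pops)) {
    d <- gm$dosages[pops[[p]], , drop = FALSE]
    n_AA <- colSums(d == 0L, na.rm = TRUE)
    n_AB <- colSums(d == 1L, na.rm = TRUE)
    n_BB <- colSums(d == 2L, na.rm = TRUE)
    ok <- (n_AA + n_AB + n_BB) > 0L
    hwe_p[ok, p] <- hwe_excess_het_p(n_AA[ok], n_AB[ok], n_BB[ok])
  }
  n_viol <- rowSums(hwe_p < hwe_alpha, na.rm = TRUE)
  fail_cr <- cr < min_call_rate
  fail_hwe <- n_viol >= min_violating_pops & hwe_alpha > 0
  # call-rate failure takes precedence in the recorded reason
  reason <- ifelse(fail_cr, "call_rate",
                   ifelse(fail_hwe, "hwe_excess_het", NA_character_))
  removed <- !is.na(reason)
  structure(list(kept = gm$variants$id[!removed],
                 removed = data.frame(id = gm$variants$id[removed],
                                      reason = reason[removed],
                                      stringsAsFactors = FALSE),
                 call_rate = cr,
                 hwe_violations = n_viol,
                 hwe_p = hwe_p),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", length(x$kept), "kept,", nrow(x$removed), "removed\n")
  if (nrow(x$removed) > 0L)
    print(table(x$removed$reason))
  invisible(x)
}

#' Per-population unfolded allele frequencies
#'
#' Alternative-allele count, observed chromosome count, and frequency per
#' variant and population, ignoring missing genotypes, plus a pooled "ALL"
#' row per variant. Frequencies are unfolded (always the alternative allele,
#' whether minor or major).
#'
#' @param gm genotype_matrix
#' @param popmap popmap; if `NULL` only the pooled rows are produced
#' @return data.frame of class `af_table` with columns `variant_id`,
#'   `population`, `sum_AC`, `sum_NCHROBS`, `AF` (NA when no chromosomes
#'   observed).
#' @export
compute_af <- function(gm, popmap = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  groups <- list(ALL = seq_len(nrow(gm$dosages)))
  if (!is.null(popmap))
    groups <- c(pop_sample_index(gm, popmap), groups)
  out <- lapply(names(groups), function(p) {
    d <- gm$dosages[groups[[p]], , drop = FALSE]
    ac <- colSums(d, na.rm = TRUE)
    nobs <- 2L * colSums(!is.na(d))
    data.frame(variant_id = gm$variants$id, population = p,
               sum_AC = as.integer(ac), sum_NCHROBS = as.integer(nobs),
               AF = ifelse(nobs > 0L, ac / nobs, NA_real_),
               stringsAsFactors = FALSE)
  })
  af <- do.call(rbind, out)
  rownames(af) <- NULL
  class(af) <- c("af_table", "data.frame")
  af
}

#' Classify the pooled allele-frequency spectrum
#'
#' Counts variants that are absent (AF = 0), fixed (AF = 1), nearly fixed
#' (AF >= `fixed_hi`, inclusive of fixed) or segregating (anything else with
#' 0 < AF < `fixed_hi`) on the pooled ("ALL") frequency.
#'
#' @param af af_table from \code{\link{compute_af}}
#' @param fixed_hi near-fixation threshold (default 0.9)
#' @return named integer vector: absent, segregating, fixed, nearly_fixed.
#' @export
classify_af_spectrum <- function(af, fixed_hi = 0.9) {
  global <- af[af$population == "ALL" & !is.na(af$AF), ]
  x <- global$AF
  c(absent = sum(x == 0),
    segregating = sum(x > 0 & x < fixed_hi),
    fixed = sum(x == 1),
    nearly_fixed = sum(x >= fixed_hi))
}

#' Match two structural variants by position and length
#'
#' Two SV records are considered the same call when their start positions
#' lie within `max_start_dist` bp and their lengths differ by at most
#' `max_len_frac` of the longer of the two. Type and strand are deliberately
#' not compared.
#'
#' @param a,b lists or single-row data.frames with `pos` and `svlen`
#' @param max_start_dist maximum start distance in bp (default 500)
#' @param max_len_frac maximum relative length difference (default 0.10)
#' @return logical.
#' @export
sv_match <- function(a, b, max_start_dist = 500, max_len_frac = 0.10) {
  la <- abs(a$svlen); lb <- abs(b$svlen)
  if (la <= 0 || lb <= 0) stop("SV lengths must be positive")
  abs(a$pos - b$pos) <= max_start_dist &&
    abs(la - lb) <= max_len_frac * max(la, lb)
}
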