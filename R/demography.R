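#' Five-population demographic model for East Asian / European history
#'
#' A labeled population tree with exponential growth, spanning the history
#' of five present-day populations (CEU, CHB, JPT, KHV, CDX). The
#' simulation starts at the CEU / East Asian divergence (46 kya); the East
#' Asian branch splits into the CHB/JPT and KHV/CDX ancestors at 9.8 kya,
#' which in turn split at 9.0 kya and 1.7 kya. Each daughter population is
#' founded at its parent's current size and frequency. All populations grow
#' exponentially from `N0` at rate `growth_rate` per generation, capped at
#' `N_cap` (the growth rate and span do not exactly compose to the final
#' size, so the cap enforces it).
#'
#' @param N0 initial diploid size (default 2831)
#' @param growth_rate per-generation exponential growth (default 1.25e-3)
#' @param N_cap maximum diploid size (default 17883)
#' @param generation_time_years years per generation (default 29)
#' @param total_generations simulated time span in generations (default
#'   1686, the prior upper bound on selection onset; 46 kya at 29 yr/gen is
#'   about 1586, and both are accepted here)
#' @param split_times_gen named vector of split times in generations before
#'   present: `t1` (CEU|EAS, defaults to `total_generations`), `t2`
#'   (CHBJPT|KHVCDX, 9.8 kya), `t3` (CHB|JPT, 9.0 kya), `t4` (KHV|CDX,
#'   1.7 kya); defaults round years / generation_time
#' @return list of class `demographic_model`.
#' @export
demographic_model <- function(N0 = 2831, growth_rate = 1.25e-3,
                              N_cap = 17883, generation_time_years = 29,
                              total_generations = 1686,
                              split_times_gen = NULL) {
  if (is.null(split_times_gen)) {
    split_times_gen <- c(t1 = total_generations,
                         t2 = round(9800 / generation_time_years),
                         t3 = round(9000 / generation_time_years),
                         t4 = round(1700 / generation_time_years))
  }
  t <- split_times_gen
  if (!(t["t1"] >= t["t2"] && t["t2"] > t["t3"] && t["t2"] > t["t4"] &&
        t["t4"] > 0))
    stop("split times must satisfy t1 >= t2 > t3, t2 > t4 > 0")
  if (N0 < 2 || N_cap < N0) stop("need N_cap >= N0 >= 2")
  structure(list(N0 = N0, growth_rate = growth_rate, N_cap = N_cap,
                 generation_time_years = generation_time_years,
                 total_generations = as.integer(total_generations),
                 split_times_gen = t),
            class = "demographic_model")
}

#' Selection regime acting on a subset of the population tree
#'
#' @param s selection coefficient (fitnesses 1+s, 1+hs, 1 for the
#'   alt-homozygote, heterozygote and ref-homozygote)
#' @param T_adaptive onset of selection, generations before present;
#'   selection acts in every generation at or after the onset
#' @param h dominance coefficient (default 0.5, genic selection)
#' @param selected_lineages branches under selection; any of "CEU", "EAS",
#'   "CHBJPT", "KHVCDX", "CHB", "JPT", "KHV", "CDX". Default: the KHV/CDX
#'   ancestral branch and its descendants.
#' @param trace_ancestry when the onset predates a selected branch's origin,
#'   apply selection to that branch's ancestral population (default TRUE);
#'   with FALSE, selection before the branch exists is simply inert
#' @return list of class `selection_regime`.
#' @export
selection_regime <- function(s = 0, T_adaptive = 1, h = 0.5,
                             selected_lineages = c("KHVCDX", "KHV", "CDX"),
                             trace_ancestry = TRUE) {
  pops <- c("CEU", "EAS", "CHBJPT", "KHVCDX", "CHB", "JPT", "KHV", "CDX")
  if (!all(selected_lineages %in% pops))
    stop("unknown lineage labels: ",
         paste(setdiff(selected_lineages, pops), collapse = ", "))
  if (h < 0 || h > 1) stop("dominance h must lie in [0, 1]")
  structure(list(s = s, T_adaptive = T_adaptive, h = h,
                 selected_lineages = selected_lineages,
                 trace_ancestry = trace_ancestry),
            class = "selection_regime")
}

.tree_children <- list(EAS = c("CHBJPT", "KHVCDX"),
                       CHBJPT = c("CHB", "JPT"),
                       KHVCDX = c("KHV", "CDX"))

.tree_descendants <- list(
  CEU = character(0),
  EAS = c("CHBJPT", "KHVCDX", "CHB", "JPT", "KHV", "CDX"),
  CHBJPT = c("CHB", "JPT"), KHVCDX = c("KHV", "CDX"),
  CHB = character(0), JPT = character(0),
  KHV = character(0), CDX = character(0))

# is population `pop` under selection, given the regime? (time-independent
# part; the T_adaptive gate is applied by the caller)
.pop_selected <- function(pop, regime) {
  if (pop %in% regime$selected_lineages) return(TRUE)
  regime$trace_ancestry &&
    any(.tree_descendants[[pop]] %in% regime$selected_lineages)
}

# deterministic one-generation selection update, vectorized over p and s
.sel_update <- function(p, s, h) {
  wAA <- 1 + s; wAa <- 1 + h * s
  num <- p^2 * wAA + p * (1 - p) * wAa
  den <- p^2 * wAA + 2 * p * (1 - p) * wAa + (1 - p)^2
  ifelse(den > 0, num / den, p)
}

#' Forward Wright-Fisher simulation over the five-population model
#'
#' Vectorized over a batch of parameter triplets: each row of
#' (`s`, `T_adaptive`, `p0`) is one independent single-locus simulation.
#' Every generation applies the deterministic selection update (on lineages
#' covered by the regime, once the onset has been reached) followed by
#' binomial drift at the current population size. Daughter populations
#' inherit the parent's frequency and size at each split.
#'
#' @param model demographic_model
#' @param s,T_adaptive,p0 numeric vectors (recycled to a common length):
#'   selection coefficient, onset time in generations before present, and
#'   starting allele frequency
#' @param regime selection_regime giving dominance and the selected
#'   lineages; its `s` and `T_adaptive` are overridden by the vectors
#' @param seed RNG seed
#' @param deterministic skip binomial drift (for split/selection
#'   bookkeeping checks)
#' @return matrix with one row per simulation and columns CEU, CHB, JPT,
#'   KHV, CDX holding end-of-simulation allele frequencies.
#' @export
wf_simulate_batch <- function(model, s, T_adaptive, p0,
                              regime = selection_regime(), seed = 1,
                              deterministic = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  nb <- max(length(s), length(T_adaptive), length(p0))
  s <- rep_len(s, nb); Tadp <- rep_len(T_adaptive, nb); p0 <- rep_len(p0, nb)
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tt <- model$split_times_gen
  t1 <- tt["t1"]; t2 <- tt["t2"]; t3 <- tt["t3"]; t4 <- tt["t4"]
  # active populations during the generation ending at time `te`
  active_at <- function(te) {
    pops <- c("CEU", if (te >= t2) "EAS",
              if (te < t2 && te >= t3) "CHBJPT",
              if (te < t2 && te >= t4) "KHVCDX",
              if (te < t3) c("CHB", "JPT"),
              if (te < t4) c("KHV", "CDX"))
    pops
  }
  state <- list(CEU = p0, EAS = p0)
  sel_flag <- vapply(names(.tree_descendants), .pop_selected,
                     logical(1), regime = regime)
  for (te in seq(t1 - 1L, 0L)) {
    # splits occurring at the parent time te + 1 feed the daughters
    for (parent in names(.tree_children)) {
      birth <- switch(parent, EAS = t2, CHBJPT = t3, KHVCDX = t4)
      if (te == birth - 1L) {
        for (ch in .tree_children[[parent]]) state[[ch]] <- state[[parent]]
        state[[parent]] <- NULL
      }
    }
    age <- t1 - te                       # generations elapsed since start
    N <- min(round(model$N0 * (1 + model$growth_rate)^age), model$N_cap)
    for (pop in active_at(te)) {
      p <- state[[pop]]
      if (sel_flag[[pop]]) {
        s_eff <- s * ((te + 1L) <= Tadp)  # onset gate, per particle
        p <- .sel_update(p, s_eff, regime$h)
      }
      if (!deterministic)
        p <- stats::rbinom(nb, 2L * N, p) / (2L * N)
      state[[pop]] <- p
    }
  }
  out <- cbind(CEU = state$CEU, CHB = state$CHB, JPT = state$JPT,
               KHV = state$KHV, CDX = state$CDX)
  out
}

#' Single Wright-Fisher simulation
#'
#' Convenience wrapper around \code{\link{wf_simulate_batch}} for one
#' parameter triplet, optionally recording the full frequency trajectory of
#' every branch.
#'
#' @param model demographic_model
#' @param regime selection_regime (its `s` and `T_adaptive` are used)
#' @param p0 starting allele frequency
#' @param seed RNG seed
#' @param keep_trajectory record per-generation frequencies (default FALSE)
#' @return list of class `sim_result`: `end` (named frequencies for CEU,
#'   CHB, JPT, KHV, CDX), `seed`, and optionally `trajectory` (data.frame
#'   time/population/frequency, time in generations before present).
#' @export
wf_simulate <- function(model, regime, p0, seed = 1,
                        keep_trajectory = FALSE) {
  if (!keep_trajectory) {
    end <- wf_simulate_batch(model, regime$s, regime$T_adaptive, p0,
                             regime = regime, seed = seed)[1L, ]
    return(structure(list(end = end, seed = seed), class = "sim_result"))
  }
  # trajectory mode: scalar re-implementation sharing the batch machinery
  # via nb = 1 would hide the per-generation states, so walk explicitly
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tt <- model$split_times_gen
  t1 <- tt["t1"]; t2 <- tt["t2"]; t3 <- tt["t3"]; t4 <- tt["t4"]
  state <- list(CEU = p0, EAS = p0)
  sel_flag <- vapply(names(.tree_descendants), .pop_selected,
                     logical(1), regime = regime)
  rows <- list()
  for (te in seq(t1 - 1L, 0L)) {
    for (parent in names(.tree_children)) {
      birth <- switch(parent, EAS = t2, CHBJPT = t3, KHVCDX = t4)
      if (te == birth - 1L) {
        for (ch in .tree_children[[parent]]) state[[ch]] <- state[[parent]]
        state[[parent]] <- NULL
      }
    }
    age <- t1 - te
    N <- min(round(model$N0 * (1 + model$growth_rate)^age), model$N_cap)
    for (pop in names(state)) {
      p <- state[[pop]]
      if (sel_flag[[pop]] && (te + 1L) <= regime$T_adaptive)
        p <- .sel_update(p, regime$s, regime$h)
      p <- stats::rbinom(1L, 2L * N, p) / (2L * N)
      state[[pop]] <- p
      rows[[length(rows) + 1L]] <- data.frame(time = te, population = pop,
                                              frequency = p, N = N)
    }
  }
  end <- c(CEU = state$CEU, CHB = state$CHB, JPT = state$JPT,
           KHV = state$KHV, CDX = state$CDX)
  structure(list(end = end, seed = seed,
                 trajectory = do.call(rbind, rows)),
            class = "sim_result")
}

#' Hudson's FST estimator for two populations
#'
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) -
#'   p_2(1-p_2)/(n_2-1)}{p_1(1-p_2) + p_2(1-p_1)}}
#' with sampled chromosome counts \eqn{n_1, n_2}. May be negative at low
#' differentiation; returns NA (flagged via attribute) when the denominator
#' is zero (both populations fixed for the same allele).
#'
#' @param p1,p2 allele frequencies
#' @param n1,n2 sampled chromosome counts (>= 2)
#' @return numeric FST estimate (vectorized).
#' @export
hudson_fst <- function(p1, p2, n1, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("need at least 2 sampled chromosomes")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den > 0, num / den, NA_real_)
}

#' Population branch statistic
#'
#' Isolates allele-frequency differentiation on population A's branch from
#' three pairwise FST values, via the branch-length transform
#' \eqn{T(x) = -\log(1 - x)}:
#' \deqn{PBS = (T(F_{AB}) + T(F_{AC}) - T(F_{BC})) / 2.}
#' Negative FST estimates are truncated to 0 before the transform.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise FST values (A is the focal branch)
#' @return numeric PBS (vectorized).
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  cl <- function(x) pmax(x, 0)
  if (any(cl(fst_bc) >= 1)) stop("FST = 1 on the subtracted branch")
  Tr <- function(x) -log(1 - cl(x))
  (Tr(fst_ab) + Tr(fst_ac) - Tr(fst_bc)) / 2
}

#' Neutral simulation background for PBS and FST
#'
#' Runs `n_sims` neutral (s = 0) simulations of the demographic model from
#' a common starting frequency and summarizes each by the end-of-simulation
#' PBS of CDX against JPT and CEU, plus the three pairwise FST values.
#' Sample sizes for the FST estimator default to the whole-population
#' census (2N at simulation end).
#'
#' @param model demographic_model
#' @param p0 starting allele frequency
#' @param n_sims number of simulations
#' @param seed RNG seed
#' @param sample_chromosomes chromosome count per population for the FST
#'   estimator (default 2 * final census size)
#' @return list of class `neutral_background`: `pbs` (vector), `fst`
#'   (matrix with columns cdx_jpt, cdx_ceu, jpt_ceu), `end` (frequency
#'   matrix), and `empirical_p(observed)` giving
#'   (1 + #\{PBS_sim >= observed\}) / (n_sims + 1).
#' @export
neutral_background <- function(model, p0, n_sims, seed = 1,
                               sample_chromosomes = NULL) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  end <- wf_simulate_batch(model, s = 0, T_adaptive = 1,
                           p0 = rep(p0, n_sims), seed = seed)
  if (is.null(sample_chromosomes)) {
    Nend <- min(round(model$N0 *
                        (1 + model$growth_rate)^model$total_generations),
                model$N_cap)
    sample_chromosomes <- 2L * Nend
  }
  nch <- sample_chromosomes
  fst <- cbind(cdx_jpt = hudson_fst(end[, "CDX"], end[, "JPT"], nch, nch),
               cdx_ceu = hudson_fst(end[, "CDX"], end[, "CEU"], nch, nch),
               jpt_ceu = hudson_fst(end[, "JPT"], end[, "CEU"], nch, nch))
  ok <- stats::complete.cases(fst) & pmax(fst[, "jpt_ceu"], 0) < 1
  pbs_vals <- rep(NA_real_, n_sims)
  pbs_vals[ok] <- pbs(fst[ok, "cdx_jpt"], fst[ok, "cdx_ceu"],
                      fst[ok, "jpt_ceu"])
  # monomorphic outcomes (shared fixation) carry zero differentiation
  pbs_vals[!ok & rowSums(is.na(fst)) > 0] <- 0
  structure(list(pbs = pbs_vals, fst = fst, end = end,
                 empirical_p = function(observed) {
                   (1 + sum(pbs_vals >= observed, na.rm = TRUE)) /
                     (n_sims + 1)
                 }),
            class = "neutral_background")
}
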