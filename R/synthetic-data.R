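#' Specification of a synthetic admixed cohort
#'
#' Describes a cohort drawn from the generative model the downstream
#' analyses assume: each individual's ancestry proportions come from a
#' population-specific Dirichlet over K components; each component's allele
#' frequencies drift from a shared ancestral frequency under the
#' Balding-Nichols model
#' \eqn{f_{kj} \sim Beta(a_j(1-F_k)/F_k,\; (1-a_j)(1-F_k)/F_k)}
#' with ancestral frequency \eqn{a_j \sim U(0.05, 0.95)}; genotype dosages
#' are Binomial(2, \eqn{\sum_k q_{ik} f_{kj}}).
#'
#' @param populations character vector of population labels
#' @param n_samples_per_pop integer count per population (recycled)
#' @param K number of ancestry components (>= 1)
#' @param dirichlet_conc Dirichlet concentration: a length-K vector shared
#'   by all populations, or a P x K matrix (one row per population). The
#'   default anchors population p on component `1 + (p-1) %% K` with
#'   concentration 10 against 0.3 elsewhere, giving sharp but non-degenerate
#'   admixture.
#' @param fst_per_component Balding-Nichols drift parameter per component,
#'   each in (0, 1) (default 0.05)
#' @param n_variants number of variants
#' @param missing_rate probability a genotype call is missing (default 0)
#' @param seed RNG seed
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(populations, n_samples_per_pop, K = 2,
                        dirichlet_conc = NULL, fst_per_component = 0.05,
                        n_variants = 100, missing_rate = 0, seed = 1) {
  P <- length(populations)
  if (K < 1) stop("K must be >= 1")
  n_samples_per_pop <- rep_len(as.integer(n_samples_per_pop), P)
  if (any(n_samples_per_pop <= 0L)) stop("sample counts must be positive")
  fst_per_component <- rep_len(fst_per_component, K)
  if (any(fst_per_component <= 0 | fst_per_component >= 1))
    stop("drift parameters must lie in (0, 1)")
  if (is.null(dirichlet_conc)) {
    dirichlet_conc <- matrix(0.3, P, K)
    for (p in seq_len(P)) dirichlet_conc[p, 1 + (p - 1) %% K] <- 10
  }
  if (is.vector(dirichlet_conc))
    dirichlet_conc <- matrix(dirichlet_conc, P, K, byrow = TRUE)
  if (!all(dim(dirichlet_conc) == c(P, K)))
    stop("dirichlet_conc must be length K or a P x K matrix")
  if (any(dirichlet_conc <= 0)) stop("Dirichlet concentrations must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")
  structure(list(populations = populations,
                 n_samples_per_pop = n_samples_per_pop, K = K,
                 dirichlet_conc = dirichlet_conc,
                 fst_per_component = fst_per_component,
                 n_variants = as.integer(n_variants),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic admixed cohort
#'
#' Draws a cohort from the model described in \code{\link{cohort_spec}} and
#' returns the genotypes together with the generating truth, so estimator
#' recovery can be tested. Fully reproducible from the spec's seed.
#'
#' @param spec cohort_spec
#' @return list: `gm` (genotype_matrix), `popmap` (popmap), `truth` (list
#'   with `Q` samples x K, `F` K x variants, `anc` ancestral frequencies,
#'   `fst` drift parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  P <- length(spec$populations)
  n <- sum(spec$n_samples_per_pop)
  m <- spec$n_variants
  K <- spec$K
  anc <- stats::runif(m, 0.05, 0.95)
  F <- matrix(NA_real_, K, m)
  for (k in seq_len(K)) {
    Fk <- spec$fst_per_component[k]
    F[k, ] <- stats::rbeta(m, anc * (1 - Fk) / Fk, (1 - anc) * (1 - Fk) / Fk)
  }
  pop_of <- rep(spec$populations, spec$n_samples_per_pop)
  Q <- matrix(NA_real_, n, K)
  for (p in seq_len(P)) {
    rows <- which(pop_of == spec$populations[p])
    Q[rows, ] <- rdirichlet(length(rows), spec$dirichlet_conc[p, ])
  }
  pij <- Q %*% F
  G <- matrix(stats::rbinom(n * m, 2L, pij), n, m)
  if (spec$missing_rate > 0)
    G[stats::runif(n * m) < spec$missing_rate] <- NA_integer_
  ids <- sprintf("var%0*d", nchar(m), seq_len(m))
  samples <- sprintf("%s_%03d", pop_of, stats::ave(seq_len(n), pop_of,
                                                   FUN = seq_along))
  dimnames(G) <- list(samples, ids)
  variants <- data.frame(chrom = "chr1",
                         pos = seq_len(m) * 1000L,
                         id = ids, ref = "A", alt = "C",
                         svtype = "SNP", svlen = 0L,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(variants, G)
  popmap <- population_map(samples, pop_of)
  rownames(Q) <- samples
  colnames(F) <- ids
  list(gm = gm, popmap = popmap,
       truth = list(Q = Q, F = F, anc = anc, fst = spec$fst_per_component))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of an injected variant
#'
#' @param kind "differentiated" (frequency elevated in one ancestry
#'   component), "introgressed" (frequency elevated in target populations,
#'   rare everywhere else), or "neutral"
#' @param target either a component index (differentiated) or a character
#'   vector of population labels (introgressed); ignored for neutral
#' @param target_af allele frequency in the target component/populations
#' @param background_af allele frequency elsewhere
#' @param ld_partner_r2 optional target r-squared for a linked partner
#'   variant generated alongside (haplotype-level correlation)
#' @param chrom,pos optional placement; defaults to appending after the last
#'   variant on its chromosome
#' @param id id for the injected variant (default "inj")
#' @return list of class `injection_spec`.
#' @export
injection_spec <- function(kind = c("differentiated", "introgressed",
                                    "neutral"),
                           target = NULL, target_af = 0.9,
                           background_af = 0.05, ld_partner_r2 = NULL,
                           chrom = NULL, pos = NULL, id = "inj") {
  kind <- match.arg(kind)
  if (target_af < 0 || target_af > 1 || background_af < 0 || background_af > 1)
    stop("frequencies must lie in [0, 1]")
  if (!is.null(ld_partner_r2) && (ld_partner_r2 < 0 || ld_partner_r2 > 1))
    stop("ld_partner_r2 must lie in [0, 1]")
  structure(list(kind = kind, target = target, target_af = target_af,
                 background_af = background_af,
                 ld_partner_r2 = ld_partner_r2,
                 chrom = chrom, pos = pos, id = id),
            class = "injection_spec")
}

#' Inject a variant with controlled frequency structure into a cohort
#'
#' Appends a variant whose per-sample allele probability follows the
#' requested pattern, sampling two haplotypes per individual so that linked
#' partner variants have a well-defined haplotype-level r-squared. For a
#' differentiated variant each haplotype first draws its ancestry component
#' from the individual's admixture proportions, then its allele from that
#' component's target/background frequency; introgressed and neutral
#' variants use per-population frequencies directly.
#'
#' @param gm genotype_matrix to extend
#' @param truth truth list from \code{\link{generate_cohort}} (needs `Q` for
#'   differentiated injections)
#' @param spec injection_spec
#' @param popmap popmap; required for `kind = "introgressed"`
#' @param seed RNG seed
#' @return genotype_matrix with the injected variant (and optional
#'   `<id>_partner`) appended.
#' @export
inject_variant <- function(gm, truth, spec, popmap = NULL, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "injection_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(gm$dosages)
  hap <- matrix(NA_integer_, n, 2L)
  if (spec$kind == "differentiated") {
    Q <- truth$Q
    K <- ncol(Q)
    if (is.null(spec$target) || spec$target < 1 || spec$target > K)
      stop("target component out of range")
    f <- rep(spec$background_af, K)
    f[spec$target] <- spec$target_af
    for (h in 1:2) {
      comp <- apply(Q, 1L, function(q) sample.int(K, 1L, prob = q))
      hap[, h] <- stats::rbinom(n, 1L, f[comp])
    }
    p_hap <- as.numeric(Q %*% f)
  } else {
    if (spec$kind == "introgressed") {
      if (is.null(popmap)) stop("introgressed injection requires a popmap")
      if (!all(spec$target %in% popmap$population))
        stop("target populations absent from popmap")
      pop_of <- popmap$population[match(rownames(gm$dosages),
                                        popmap$sample_id)]
      p_hap <- ifelse(pop_of %in% spec$target,
                      spec$target_af, spec$background_af)
    } else {
      p_hap <- rep(spec$background_af, n)
    }
    hap[, 1L] <- stats::rbinom(n, 1L, p_hap)
    hap[, 2L] <- stats::rbinom(n, 1L, p_hap)
  }
  new_variant <- function(vid) {
    chrom <- if (is.null(spec$chrom)) gm$variants$chrom[nrow(gm$variants)]
             else spec$chrom
    pos0 <- if (is.null(spec$pos))
      max(gm$variants$pos[gm$variants$chrom == chrom]) + 1000L else spec$pos
    data.frame(chrom = chrom, pos = as.integer(pos0), id = vid, ref = "A",
               alt = "<INS>", svtype = "INS", svlen = 100L,
               stringsAsFactors = FALSE)
  }
  add <- function(g, vrow, doses) {
    d <- matrix(as.integer(doses), ncol = 1,
                dimnames = list(rownames(g$dosages), vrow$id))
    cbind_gm(g, genotype_matrix(vrow, d))
  }
  out <- add(gm, new_variant(spec$id), hap[, 1L] + hap[, 2L])
  if (!is.null(spec$ld_partner_r2)) {
    # partner allele drawn per haplotype given the focal allele, with the
    # conditional probabilities that give correlation r at equal frequencies:
    # P(b=1 | a=1) = p + r(1-p), P(b=1 | a=0) = p(1-r)
    r <- sqrt(spec$ld_partner_r2)
    partner <- matrix(NA_integer_, n, 2L)
    for (h in 1:2) {
      pr <- ifelse(hap[, h] == 1L, p_hap + r * (1 - p_hap), p_hap * (1 - r))
      partner[, h] <- stats::rbinom(n, 1L, pr)
    }
    vrow <- new_variant(paste0(spec$id, "_partner"))
    vrow$pos <- vrow$pos + 500L
    out <- add(out, vrow, partner[, 1L] + partner[, 2L])
  }
  out
}

#' Simulate breakpoint-spanning reads from an insertion locus
#'
#' Samples reads uniformly from the carrier haplotype (upstream flank +
#' insertion + downstream flank) or the non-carrier haplotype (the two
#' flanks joined), for testing diagnostic-sequence read scans.
#'
#' @param ref_flank_up,insertion,ref_flank_down nucleotide strings (ACGT)
#' @param carrier draw reads from the insertion-carrying haplotype?
#' @param read_length read length in bp
#' @param depth number of reads to draw
#' @param seed RNG seed
#' @return character vector of reads, named `read_1` ... `read_depth`.
#' @export
generate_breakpoint_reads <- function(ref_flank_up, insertion, ref_flank_down,
                                      carrier, read_length, depth, seed = 1) {
  for (s in c(ref_flank_up, insertion, ref_flank_down))
    if (nchar(s) > 0 && grepl("[^ACGT]", s)) stop("invalid nucleotide characters")
  hap <- if (carrier) paste0(ref_flank_up, insertion, ref_flank_down)
         else paste0(ref_flank_up, ref_flank_down)
  L <- nchar(hap)
  if (read_length > L)
    stop("read_length (", read_length, ") exceeds haplotype length (", L, ")")
  if (depth == 0L) return(stats::setNames(character(0), character(0)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- sample.int(L - read_length + 1L, depth, replace = TRUE)
  reads <- substring(hap, starts, starts + read_length - 1L)
  names(reads) <- sprintf("read_%d", seq_len(depth))
  reads
}
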