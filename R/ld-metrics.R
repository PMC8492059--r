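#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies (p_AB, p_Ab, p_aB, p_ab) under
#' random mating, with the phase of double heterozygotes resolved by
#' expectation-maximization. "A"/"B" denote the alternative alleles at the
#' two loci. Pairs with a missing genotype at either locus are dropped
#' (pairwise complete-case).
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) of equal length
#' @param tol convergence tolerance on the haplotype frequencies
#' @param max_iter maximum EM iterations
#' @return named numeric vector `c(p_AB, p_Ab, p_aB, p_ab)` with attributes
#'   `n` (complete cases), `iterations`, `loglik`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  if (length(g1) != length(g2)) stop("g1 and g2 must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0L) stop("no complete-case genotype pairs")
  # unambiguous haplotype counts from the 8 phase-determined cells
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  n_dh <- tab[2, 2]                      # double heterozygotes
  # fixed counts: AB, Ab, aB, ab (A = alt at locus 1, B = alt at locus 2)
  c_AB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  c_Ab <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  c_aB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  c_ab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  p <- pmax(p, 1e-12); p <- p / sum(p)
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- p["AB"] * p["ab"]
    trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- c(c_AB + w * n_dh, c_Ab + (1 - w) * n_dh,
             c_aB + (1 - w) * n_dh, c_ab + w * n_dh) / (2 * n)
    names(new) <- names(p)
    delta <- max(abs(new - p))
    p <- new
    if (delta < tol || it >= max_iter) break
  }
  ll <- em_pair_loglik(p, tab)
  structure(p, n = n, iterations = it, loglik = ll)
}

# multinomial log-likelihood of the 3x3 genotype-pair table given haplotype
# frequencies under random mating (Hardy-Weinberg pairing of haplotypes)
em_pair_loglik <- function(p, tab) {
  h <- c(p["ab"], p["aB"], p["Ab"], p["AB"])  # index by (alt1, alt2) bits
  cellp <- matrix(0, 3, 3)
  for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
    i <- a1 + a2; j <- b1 + b2
    cellp[i + 1, j + 1] <- cellp[i + 1, j + 1] +
      h[1 + a1 * 2 + b1] * h[1 + a2 * 2 + b2]
  }
  sum(ifelse(tab > 0, tab * log(pmax(cellp, 1e-300)), 0))
}

#' Pairwise r-squared between two variants from unphased genotypes
#'
#' Squared allelic correlation \eqn{r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))} with
#' \eqn{D = p_{AB} - p_A p_B} from the EM haplotype-frequency estimate
#' (\code{\link{em_haplotype_freqs}}). A composite (genotype-correlation)
#' estimator is available for comparison.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA)
#' @param method "em" (default) or "composite" (squared Pearson correlation
#'   of dosages)
#' @return numeric r-squared in \[0, 1\]; 0 with attribute
#'   `monomorphic = TRUE` when either variant is monomorphic among complete
#'   cases.
#' @export
ld_r2 <- function(g1, g2, method = c("em", "composite")) {
  method <- match.arg(method)
  ok <- !is.na(g1) & !is.na(g2)
  v1 <- g1[ok]; v2 <- g2[ok]
  if (length(v1) == 0L) stop("no complete-case genotype pairs")
  if (length(unique(v1)) < 2L || length(unique(v2)) < 2L)
    return(structure(0, monomorphic = TRUE))
  if (method == "composite")
    return(min(1, stats::cor(v1, v2)^2))
  p <- em_haplotype_freqs(v1, v2)
  pA <- p[["AB"]] + p[["Ab"]]
  pB <- p[["AB"]] + p[["aB"]]
  D <- p[["AB"]] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(structure(0, monomorphic = TRUE))
  min(1, D^2 / denom)
}

#' Closed-form upper bound on r-squared for a pair of allele frequencies
#'
#' For minor-allele frequencies \eqn{p_a \le p_b} the maximum attainable
#' value of \eqn{r^2} is
#' \deqn{r^2_{max}(p_a, p_b) = \frac{p_a (1 - p_b)}{(1 - p_a)\, p_b}.}
#' Inputs are folded to the minor allele and sorted internally, so any
#' frequency pair in (0, 1) is accepted. With 198 chromosomes sampled, a
#' pair of singletons attains 1, a singleton-doubleton pair 0.497, and a
#' singleton-tripleton pair 0.330 - which is why empirical max-LD
#' distributions show peaks at discrete values.
#'
#' @param p_a,p_b allele frequencies in (0, 1); vectors recycle
#' @return r-squared upper bound in (0, 1\].
#' @examples
#' r2_max(1/198, 1/198)  # 1
#' r2_max(1/198, 2/198)  # 0.497...
#' @export
r2_max <- function(p_a, p_b) {
  if (any(p_a <= 0) || any(p_b <= 0) || any(p_a >= 1) || any(p_b >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)")
  a <- pmin(p_a, 1 - p_a)
  b <- pmin(p_b, 1 - p_b)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo * (1 - hi) / ((1 - lo) * hi)
}

# indices of the n_nearest panel variants within window_bp of a focal
# position, same chromosome, ties at equal distance broken by position
nearest_panel <- function(focal_pos, panel_pos, window_bp, n_nearest) {
  d <- abs(panel_pos - focal_pos)
  in_win <- which(d <= window_bp)
  if (length(in_win) == 0L) return(integer(0))
  ord <- in_win[order(d[in_win], panel_pos[in_win])]
  utils::head(ord, n_nearest)
}

#' Maximum-LD scan of focal variants against a panel
#'
#' For each focal variant (typically an SV) and each population, computes
#' r-squared against the `n_nearest` panel variants (typically SNPs/indels)
#' within `window_bp` on the same chromosome and reports the maximum and the
#' argmax partner. The focal variant is excluded from its own panel by id.
#'
#' @param gm genotype_matrix holding focal and panel variants
#' @param focal_ids ids of focal variants
#' @param panel_ids ids of panel variants
#' @param popmap popmap, or `NULL` to scan the pooled cohort
#' @param window_bp window half-width in bp (default 1e6)
#' @param n_nearest number of nearest panel variants to test (default 100)
#' @param per_population compute within each population (default TRUE when a
#'   popmap is given)
#' @param method passed to \code{\link{ld_r2}}
#' @return data.frame: `focal_id`, `population`, `best_partner_id`, `r2`,
#'   `distance`, `n_tested`, `monomorphic`. Focal variants with an empty
#'   window get `NA` partner and `n_tested = 0`.
#' @export
max_ld_scan <- function(gm, focal_ids, panel_ids, popmap = NULL,
                        window_bp = 1e6, n_nearest = 100,
                        per_population = !is.null(popmap),
                        method = "em") {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  fi <- match(focal_ids, v$id)
  pi <- match(panel_ids, v$id)
  if (anyNA(fi) || anyNA(pi)) stop("unknown focal or panel variant ids")
  groups <- if (per_population && !is.null(popmap)) pop_sample_index(gm, popmap)
            else list(ALL = seq_len(nrow(gm$dosages)))
  rows <- list()
  for (f in fi) {
    same_chr <- pi[v$chrom[pi] == v$chrom[f] & v$id[pi] != v$id[f]]
    sel <- same_chr[nearest_panel(v$pos[f], v$pos[same_chr],
                                  window_bp, n_nearest)]
    for (p in names(groups)) {
      if (length(sel) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          focal_id = v$id[f], population = p, best_partner_id = NA_character_,
          r2 = NA_real_, distance = NA_integer_, n_tested = 0L,
          monomorphic = NA, stringsAsFactors = FALSE)
        next
      }
      idx <- groups[[p]]
      gf <- gm$dosages[idx, f]
      r2s <- vapply(sel, function(s) {
        r <- try(ld_r2(gf, gm$dosages[idx, s], method = method), silent = TRUE)
        if (inherits(r, "try-error")) NA_real_ else as.numeric(r)
      }, numeric(1))
      if (all(is.na(r2s))) {
        best <- NA_integer_
      } else best <- which.max(r2s)
      mono <- length(unique(gf[!is.na(gf)])) < 2L
      rows[[length(rows) + 1L]] <- data.frame(
        focal_id = v$id[f], population = p,
        best_partner_id = if (is.na(best)) NA_character_ else v$id[sel[best]],
        r2 = if (is.na(best)) NA_real_ else r2s[best],
        distance = if (is.na(best)) NA_integer_
                   else abs(v$pos[sel[best]] - v$pos[f]),
        n_tested = sum(!is.na(r2s)), monomorphic = mono,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag variants intersecting masked genomic intervals
#'
#' A variant's affected span is `[pos, pos + max(|svlen|, 1))` (1-based,
#' length at least 1 bp); mask intervals are BED-convention 0-based
#' half-open. A variant is flagged when the two intervals intersect at all.
#'
#' @param gm genotype_matrix (or its `variants` data.frame)
#' @param mask data.frame with `chrom`, `start` (0-based), `end` (exclusive)
#' @return list: `flag` (named logical per variant), `n_overlap`, `fraction`.
#' @export
interval_overlap_fraction <- function(gm, mask) {
  v <- if (inherits(gm, "genotype_matrix")) gm$variants else gm
  if (any(mask$end < mask$start)) stop("malformed BED: end < start")
  width <- pmax(abs(v$svlen), 1L)
  flag <- logical(nrow(v))
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    mi <- which(mask$chrom == ch)
    if (length(mi) == 0L) next
    q <- IRanges::IRanges(start = v$pos[vi], width = width[vi])
    s <- IRanges::IRanges(start = mask$start[mi] + 1L, end = mask$end[mi])
    flag[vi] <- IRanges::overlapsAny(q, s)
  }
  names(flag) <- v$id
  list(flag = flag, n_overlap = sum(flag), fraction = mean(flag))
}
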