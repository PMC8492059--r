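#' Fit an admixture model by expectation-maximization
#'
#' Maximizes the binomial admixture likelihood
#' \deqn{\sum_{ij} \log \mathrm{Binom}(g_{ij};\, 2,\, \sum_k q_{ik} f_{kj})}
#' over admixture proportions Q (rows on the simplex) and component allele
#' frequencies F, by the standard alternating EM updates. The log-likelihood
#' is non-decreasing across iterations; missing genotypes simply drop out of
#' the sums. Component labels are arbitrary (identified up to permutation).
#'
#' @param gm genotype_matrix
#' @param K number of ancestry components
#' @param max_iter maximum EM iterations (default 200)
#' @param tol relative log-likelihood convergence tolerance (default 1e-8)
#' @param seed RNG seed for the random initialization
#' @return list of class `ancestry_fit`: `Q` (samples x K), `F`
#'   (K x variants), `loglik_trace`, `converged`, `K`.
#' @export
fit_admixture <- function(gm, K, max_iter = 200, tol = 1e-8, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  G <- gm$dosages
  n <- nrow(G); m <- ncol(G)
  if (K >= 2 && m < K) stop("need at least K variants")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (K == 1L) {
    F <- matrix(colMeans(G, na.rm = TRUE) / 2, 1L, m,
                dimnames = list(NULL, colnames(G)))
    Q <- matrix(1, n, 1L, dimnames = list(rownames(G), NULL))
    ll <- admix_loglik(G, Q, F)
    return(structure(list(Q = Q, F = F, loglik_trace = ll, converged = TRUE,
                          K = 1L), class = "ancestry_fit"))
  }
  # uniform Q start keeps identical samples identical at every iterate;
  # the random F start breaks the component-label symmetry
  Q <- matrix(1 / K, n, K)
  F <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  obs <- !is.na(G)
  Gn <- ifelse(obs, G, 0)           # alt-allele counts, 0 where missing
  Gc <- ifelse(obs, 2L - G, 0)      # ref-allele counts, 0 where missing
  Mi <- rowSums(obs)                # informative variants per sample
  trace <- numeric(0)
  converged <- FALSE
  eps <- 1e-9
  for (it in seq_len(max_iter)) {
    P <- Q %*% F
    P <- pmin(pmax(P, eps), 1 - eps)
    RA <- Gn / P                    # g / pi, zero at missing entries
    RB <- Gc / (1 - P)              # (2 - g) / (1 - pi)
    A <- Q * (RA %*% t(F))          # expected alt-allele origins per (i, k)
    B <- Q * (RB %*% t(1 - F))
    Q <- (A + B) / (2 * Mi)
    Q <- Q / rowSums(Q)             # guard against numerical drift
    numer <- F * (t(Q) %*% RA)
    denom <- numer + (1 - F) * (t(Q) %*% RB)
    F <- ifelse(denom > 0, numer / denom, F)
    F <- pmin(pmax(F, eps), 1 - eps)
    trace <- c(trace, admix_loglik(G, Q, F))
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) < tol * (abs(trace[it - 1L]) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("admixture EM did not converge in ", max_iter,
            " iterations; returning current estimate")
  rownames(Q) <- rownames(G)
  colnames(F) <- colnames(G)
  structure(list(Q = Q, F = F, loglik_trace = trace, converged = converged,
                 K = K), class = "ancestry_fit")
}

#' Component allele frequencies for new variants under a fixed admixture fit
#'
#' Estimates per-variant component frequencies by maximizing the binomial
#' admixture likelihood with the admixture proportions Q held fixed - the
#' standard way to score variants (e.g. SVs) that were not part of the
#' genome-wide admixture inference. This is the F-update of
#' \code{\link{fit_admixture}} iterated to convergence.
#'
#' @param gm genotype_matrix holding the variants to score
#' @param Q samples x K admixture proportions (rows must cover the samples
#'   of `gm`, matched by name)
#' @param max_iter maximum iterations (default 200)
#' @param tol convergence tolerance on the frequencies (default 1e-8)
#' @return K x variants frequency matrix.
#' @export
component_freqs <- function(gm, Q, max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(gm, "genotype_matrix"))
  G <- gm$dosages
  if (!is.null(rownames(Q)) && !is.null(rownames(G))) {
    idx <- match(rownames(G), rownames(Q))
    if (anyNA(idx)) stop("Q is missing rows for some samples")
    Q <- Q[idx, , drop = FALSE]
  }
  K <- ncol(Q)
  m <- ncol(G)
  obs <- !is.na(G)
  Gn <- ifelse(obs, G, 0)
  Gc <- ifelse(obs, 2L - G, 0)
  F <- matrix(pmin(pmax(colMeans(G, na.rm = TRUE) / 2, 1e-3), 1 - 1e-3),
              K, m, byrow = TRUE)
  eps <- 1e-9
  for (it in seq_len(max_iter)) {
    P <- pmin(pmax(Q %*% F, eps), 1 - eps)
    RA <- Gn / P
    RB <- Gc / (1 - P)
    numer <- F * (t(Q) %*% RA)
    denom <- numer + (1 - F) * (t(Q) %*% RB)
    Fn <- ifelse(denom > 0, numer / denom, F)
    Fn <- pmin(pmax(Fn, eps), 1 - eps)
    delta <- max(abs(Fn - F))
    F <- Fn
    if (delta < tol) break
  }
  colnames(F) <- colnames(G)
  F
}

admix_loglik <- function(G, Q, F) {
  P <- pmin(pmax(Q %*% F, 1e-12), 1 - 1e-12)
  obs <- !is.na(G)
  sum(ifelse(obs, G * log(P) + (2 - G) * log(1 - P), 0), na.rm = TRUE) +
    sum(lchoose(2, G[obs]))
}

#' Genome-wide covariance matrix of ancestry-component frequencies
#'
#' Estimates the (K-1) x (K-1) covariance matrix C describing how component
#' allele frequencies co-vary around a reference component: with
#' \eqn{d_j = (f_{kj} - f_{rj})_{k \ne r}} and
#' \eqn{c_j = f_{rj}(1 - f_{rj})}, the estimator is
#' \eqn{\hat C = M^{-1} \sum_j d_j d_j^T / c_j}. Variants whose reference
#' frequency sits within `boundary_tol` of 0 or 1 are dropped (degenerate
#' scaling). The result is projected to the nearest positive semi-definite
#' matrix if sampling noise takes it outside the cone.
#'
#' @param F K x variants component frequency matrix
#' @param reference_component index of the reference component (default 1)
#' @param boundary_tol exclusion tolerance at the frequency boundary
#' @return C matrix with attributes `reference_component`, `n_variants`.
#' @export
estimate_covariance <- function(F, reference_component = 1,
                                boundary_tol = 1e-6) {
  K <- nrow(F)
  r <- reference_component
  keep <- F[r, ] > boundary_tol & F[r, ] < 1 - boundary_tol
  M <- sum(keep)
  if (M < K - 1) stop("fewer informative variants (", M, ") than K-1")
  D <- F[-r, keep, drop = FALSE] -
    matrix(F[r, keep], K - 1, M, byrow = TRUE)
  cj <- F[r, keep] * (1 - F[r, keep])
  Ds <- sweep(D, 2L, sqrt(cj), "/")
  C <- tcrossprod(Ds) / M
  ev <- eigen(C, symmetric = TRUE)
  if (any(ev$values < 0))
    C <- ev$vectors %*% diag(pmax(ev$values, 0), K - 1) %*% t(ev$vectors)
  dimnames(C) <- list(setdiff(seq_len(K), r), setdiff(seq_len(K), r))
  structure(C, reference_component = r, n_variants = M)
}

#' Selection-hypothesis covariance matrix for one component
#'
#' Builds the alternative covariance matrix that lets allele frequencies
#' deviate freely in one ancestry component: a scalar (default 10,
#' representing the furthest deviation a selected variant could attain) is
#' added to the focal component's diagonal entry, or to every entry when the
#' focal component is the reference (a shift of the root is equivalent to
#' inflating all entries jointly).
#'
#' @param C neutral covariance matrix from \code{\link{estimate_covariance}}
#' @param component focal component index (in the full 1..K labeling)
#' @param scalar non-negative inflation (default 10)
#' @param reference_component reference component index
#' @return matrix C_s of the same shape as C.
#' @export
selection_matrix <- function(C, component, scalar = 10,
                             reference_component =
                               attr(C, "reference_component") %||% 1) {
  if (scalar < 0) stop("scalar must be non-negative")
  Cs <- unclass(C)
  attributes(Cs) <- attributes(Cs)["dim"]
  dimnames(Cs) <- dimnames(C)
  if (component == reference_component) {
    Cs <- Cs + scalar
  } else {
    i <- match(as.character(component), rownames(C))
    if (is.na(i)) {
      nonref <- setdiff(seq_len(nrow(C) + 1L), reference_component)
      i <- match(component, nonref)
    }
    if (is.na(i)) stop("component index out of range")
    Cs[i, i] <- Cs[i, i] + scalar
  }
  Cs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log MVN density terms for all variants at a single covariance Sigma:
# ll_j = -0.5 * (p log(2 pi) + p log(c_j) + log|Sigma| + d_j' Sigma^-1 d_j / c_j)
mvn_ll_all <- function(D, cj, Sigma) {
  p <- nrow(D)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Z <- backsolve(R, D, transpose = TRUE)
  quad <- colSums(Z^2) / cj
  -0.5 * (p * log(2 * pi) + p * log(cj) + 2 * sum(log(diag(R))) + quad)
}

#' Likelihood-ratio scan for component-specific frequency differentiation
#'
#' For each variant, compares the likelihood of its ancestry-component
#' frequency deviations \eqn{d_j \sim MVN(0, c_j \Sigma)} under the neutral
#' genome-wide covariance (\eqn{\Sigma = C}) against a selection hypothesis
#' in which the focal component's variance is inflated
#' (\eqn{\Sigma = (1-\alpha) C + \alpha C_s}, maximized over
#' \eqn{\alpha \in [0, 1]}), and reports the likelihood ratio statistic
#' LRS = 2 (ll_selection - ll_neutral). Including \eqn{\alpha = 0} in the
#' search makes the LRS non-negative by construction. P-values compare the
#' LRS to a chi-square distribution with one degree of freedom; Bonferroni
#' correction is over the scored variants.
#'
#' @param F K x variants component frequency matrix
#' @param C neutral covariance matrix
#' @param component focal component (1..K)
#' @param scalar selection inflation added to C (default 10)
#' @param optimize_alpha maximize over the interpolation weight alpha
#'   (default TRUE); if FALSE, alpha is fixed at 1
#' @param reference_component reference component index
#' @param boundary_tol variants with reference frequency this close to 0/1
#'   are flagged unscored
#' @return data.frame of class `scan_result`: `variant_id`, `ll_neutral`,
#'   `ll_selection`, `lrs`, `alpha_hat`, `chi2_p`, `bonferroni_p`, `scored`.
#' @export
lrs_scan <- function(F, C, component, scalar = 10, optimize_alpha = TRUE,
                     reference_component =
                       attr(C, "reference_component") %||% 1,
                     boundary_tol = 1e-6) {
  K <- nrow(F)
  r <- reference_component
  m <- ncol(F)
  ids <- colnames(F) %||% as.character(seq_len(m))
  scored <- F[r, ] > boundary_tol & F[r, ] < 1 - boundary_tol
  D <- F[-r, , drop = FALSE] - matrix(F[r, ], K - 1, m, byrow = TRUE)
  cj <- pmax(F[r, ] * (1 - F[r, ]), 1e-12)
  Cs <- selection_matrix(C, component, scalar, r)
  Dk <- D[, scored, drop = FALSE]
  ck <- cj[scored]
  ll0 <- mvn_ll_all(Dk, ck, ridge_if_needed(unclass(C)))
  if (is.null(ll0)) stop("neutral covariance matrix is not positive definite")
  interp <- function(a) ridge_if_needed((1 - a) * unclass(C) + a * Cs)
  if (!optimize_alpha) {
    ll1 <- mvn_ll_all(Dk, ck, interp(1))
    if (is.null(ll1)) stop("selection covariance matrix is singular")
    a_hat <- rep(1, length(ck))
  } else {
    # staged grid search, vectorized over variants: a coarse pass over
    # [0, 1] followed by two zoom passes shrinks the step to 1e-6, so the
    # maximized log-likelihood matches a dense-grid search to ~1e-9
    eval_grid <- function(agrid, idx) {
      LL <- vapply(agrid, function(a) {
        v <- mvn_ll_all(Dk[, idx, drop = FALSE], ck[idx], interp(a))
        if (is.null(v)) rep(-Inf, length(idx)) else v
      }, numeric(length(idx)))
      if (length(idx) == 1L) LL <- matrix(LL, nrow = 1L)
      LL
    }
    all_idx <- seq_along(ck)
    agrid <- seq(0, 1, by = 0.01)
    LL <- eval_grid(agrid, all_idx)
    best <- max.col(LL, ties.method = "first")
    ll1 <- LL[cbind(all_idx, best)]
    a_hat <- agrid[best]
    step <- 0.01
    for (stage in 1:2) {
      fine_step <- step / 100
      for (u in unique(a_hat)) {
        idx <- which(a_hat == u)
        ag <- pmin(pmax(seq(u - step, u + step, by = fine_step), 0), 1)
        ag <- unique(ag)
        LLf <- eval_grid(ag, idx)
        bf <- max.col(LLf, ties.method = "first")
        better <- LLf[cbind(seq_along(idx), bf)] > ll1[idx]
        ll1[idx[better]] <- LLf[cbind(seq_along(idx), bf)][better]
        a_hat[idx[better]] <- ag[bf][better]
      }
      step <- fine_step
    }
  }
  lrs <- pmax(0, 2 * (ll1 - ll0))
  chi2_p <- stats::pchisq(lrs, df = 1, lower.tail = FALSE)
  out <- data.frame(variant_id = ids, ll_neutral = NA_real_,
                    ll_selection = NA_real_, lrs = NA_real_,
                    alpha_hat = NA_real_, chi2_p = NA_real_,
                    bonferroni_p = NA_real_, scored = scored,
                    stringsAsFactors = FALSE)
  out$ll_neutral[scored] <- ll0
  out$ll_selection[scored] <- ll1
  out$lrs[scored] <- lrs
  out$alpha_hat[scored] <- a_hat
  out$chi2_p[scored] <- chi2_p
  out$bonferroni_p[scored] <- pmin(1, chi2_p * sum(scored))
  attr(out, "component") <- component
  attr(out, "scalar") <- scalar
  class(out) <- c("scan_result", "data.frame")
  out
}

# tiny ridge keeps a PSD-but-singular covariance invertible
ridge_if_needed <- function(S) {
  if (is.null(tryCatch(chol(S), error = function(e) NULL)))
    S + diag(1e-10, nrow(S))
  else S
}

#' Flag variants whose neutral log-likelihood is an extreme outlier
#'
#' Variants whose neutral-model log-likelihood falls below `min_lle` mark a
#' failure of the null model (typically rare variants where the fit did not
#' converge) and are excluded from outlier calling.
#'
#' @param results scan_result from \code{\link{lrs_scan}}
#' @param min_lle threshold (default -1000)
#' @return scan_result with a logical `lle_filtered` column added.
#' @export
lle_filter <- function(results, min_lle = -1000) {
  results$lle_filtered <- !is.na(results$ll_neutral) &
    results$ll_neutral < min_lle
  results
}

#' Empirical outlier calling against a frequency-matched background
#'
#' Flags focal variants (SVs) whose LRS exceeds the given percentile of the
#' background LRS distribution (SNPs/short indels) within the same global
#' minor-allele-frequency bin. Bins are `[0, w), [w, 2w), ...` on the folded
#' frequency; a focal bin with fewer than `1 / (1 - percentile)` background
#' values is widened symmetrically (with a warning) until it has enough.
#' The comparison is strict (`>` the empirical percentile, computed as the
#' inverse empirical CDF), so a focal value tied with the bin maximum of an
#' adequately sized background is not an outlier.
#'
#' @param focal_lrs,background_lrs LRS vectors
#' @param focal_maf,background_maf global minor allele frequencies (folded)
#' @param bin_width frequency bin width (default 0.01)
#' @param percentile empirical percentile (default 0.999)
#' @return logical outlier flags (NA focal LRS gives NA), with the
#'   per-focal thresholds as attribute `threshold`.
#' @export
matched_empirical_threshold <- function(focal_lrs, background_lrs,
                                        focal_maf, background_maf,
                                        bin_width = 0.01,
                                        percentile = 0.999) {
  if (length(background_lrs) == 0L) stop("empty background")
  fold <- function(p) pmin(p, 1 - p)
  fb <- floor(fold(focal_maf) / bin_width)
  bb <- floor(fold(background_maf) / bin_width)
  need <- ceiling(1 / (1 - percentile))
  thr <- rep(NA_real_, length(focal_lrs))
  for (b in unique(fb[!is.na(fb)])) {
    width <- 0L
    repeat {
      sel <- abs(bb - b) <= width & !is.na(background_lrs)
      if (sum(sel) >= need || width > max(bb, na.rm = TRUE) + 1L) break
      width <- width + 1L
    }
    if (width > 0L)
      warning("MAF bin ", b * bin_width, " widened by ", width,
              " bins to reach ", need, " background variants")
    bg <- background_lrs[sel]
    thr[fb == b] <- stats::quantile(bg, percentile, type = 1, names = FALSE)
  }
  out <- focal_lrs > thr
  attr(out, "threshold") <- thr
  out
}
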