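# Shared fixture builders and independent oracles. Oracles deliberately
# re-derive quantities from first principles (enumeration, brute-force grid
# search) so they share no code with the implementation under test.

# genotype matrix from a bare dosage matrix (samples x variants)
make_gm <- function(G, chrom = "chr1", pos = NULL, svtype = "SNP",
                    svlen = 0L) {
  m <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("v%d", seq_len(m))
  if (is.null(rownames(G))) rownames(G) <- sprintf("s%d", seq_len(nrow(G)))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(data.frame(chrom = chrom, pos = as.integer(pos),
                             id = colnames(G), ref = "A", alt = "C",
                             svtype = svtype, svlen = as.integer(svlen),
                             stringsAsFactors = FALSE), G)
}

# exact Levene-Haldane upper tail by direct enumeration with choose()
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  nm <- min(2 * n_AA + n_AB, 2 * n_BB + n_AB)
  het <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  pr <- vapply(het, function(h) {
    na <- (nm - h) / 2
    nb <- n - na - h
    exp(lfactorial(n) - lfactorial(na) - lfactorial(h) - lfactorial(nb)) *
      2^h / choose(2 * n, nm)
  }, numeric(1))
  sum(pr[het >= n_AB]) / sum(pr)
}

# genotype-pair cell probabilities under random union of haplotypes, built
# from scratch for the EM oracle
pair_cell_probs <- function(pAB, pAb, paB, pab) {
  hap <- list(c(0, 0, pab), c(0, 1, paB), c(1, 0, pAb), c(1, 1, pAB))
  cp <- matrix(0, 3, 3)
  for (h1 in hap) for (h2 in hap) {
    i <- h1[1] + h2[1]; j <- h1[2] + h2[2]
    cp[i + 1, j + 1] <- cp[i + 1, j + 1] + h1[3] * h2[3]
  }
  cp
}

# brute-force haplotype-frequency MLE over a 1-D grid in p_AB, margins at
# the sample allele frequencies (sufficient statistics for the margins)
em_grid_oracle <- function(g1, g2, grid_n = 200001L) {
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = grid_n)
  ll <- vapply(grid, function(pAB) {
    cp <- pair_cell_probs(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    sum(ifelse(tab > 0, tab * log(pmax(cp, 1e-300)), 0))
  }, numeric(1))
  best <- which.max(ll)
  c(p_AB = grid[best], loglik = ll[best])
}

# weighted quantile oracle: sort, accumulate, pick first crossing
wq_oracle <- function(x, w, p) {
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  xs[min(which(cw >= p))]
}

# cohort used by several diffscan tests: 3 anchored populations, K = 3
scan_test_cohort <- function(seed = 42, fst = 0.01, n_per_pop = 100,
                             n_variants = 800) {
  spec <- cohort_spec(c("A", "B", "C"), n_per_pop, K = 3,
                      n_variants = n_variants, fst_per_component = fst,
                      seed = seed)
  generate_cohort(spec)
}

# background SNPs drawn from the cohort's generative model given its truth
# ancestry, plus one component-differentiated variant appended
scan_background <- function(cohort, m_bg, f_by_component, seed) {
  set.seed(seed)
  Q <- cohort$truth$Q
  n <- nrow(Q)
  K <- ncol(Q)
  anc <- runif(m_bg, 0.05, 0.95)
  fstpar <- cohort$truth$fst[1]
  a <- (1 - fstpar) / fstpar
  Fbg <- sapply(seq_len(K), function(k) rbeta(m_bg, anc * a, (1 - anc) * a))
  P <- tcrossprod(Q, Fbg)
  G <- matrix(rbinom(n * m_bg, 2, P), n, m_bg)
  comp1 <- apply(Q, 1, function(q) sample.int(K, 1, prob = q))
  comp2 <- apply(Q, 1, function(q) sample.int(K, 1, prob = q))
  ginj <- rbinom(n, 1, f_by_component[comp1]) +
    rbinom(n, 1, f_by_component[comp2])
  G <- cbind(G, ginj)
  colnames(G) <- c(sprintf("bg%d", seq_len(m_bg)), "inj")
  rownames(G) <- rownames(cohort$gm$dosages)
  make_gm(G)
}
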