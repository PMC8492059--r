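test_that("admixture EM increases the likelihood and stays on the simplex", {
  ch <- generate_cohort(cohort_spec(c("A", "B"), 40, K = 2,
                                    n_variants = 150,
                                    fst_per_component = 0.1, seed = 4))
  fit <- suppressWarnings(fit_admixture(ch$gm, K = 2, seed = 2,
                                        max_iter = 120))
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, nrow(fit$Q)), tolerance = 1e-8)
  expect_true(all(fit$Q >= 0))
  expect_true(all(fit$F >= 0 & fit$F <= 1))
})

test_that("K = 1 admixture returns sample frequencies, duplicates agree", {
  G <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 2L, 2L), 4, 2)
  gm <- make_gm(G)
  fit <- fit_admixture(gm, K = 1)
  expect_equal(unname(fit$Q), matrix(1, 4, 1))
  expect_equal(unname(fit$F[1, ]), unname(colMeans(G) / 2))
  # duplicated samples receive identical ancestry estimates
  ch <- generate_cohort(cohort_spec(c("A", "B"), 25, K = 2,
                                    n_variants = 120,
                                    fst_per_component = 0.2, seed = 6))
  Gd <- ch$gm$dosages
  Gd <- rbind(Gd, dup1 = Gd[1, ])
  gm2 <- make_gm(Gd)
  fit2 <- suppressWarnings(fit_admixture(gm2, K = 2, seed = 3,
                                         max_iter = 150))
  expect_equal(fit2$Q[1, ], fit2$Q[nrow(Gd), ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("two divergent homogeneous groups are separated", {
  set.seed(2)
  n1 <- 40; n2 <- 40; m <- 500
  f1 <- runif(m, 0.05, 0.95); f2 <- runif(m, 0.05, 0.95)
  G <- rbind(matrix(rbinom(n1 * m, 2, rep(f1, each = n1)), n1),
             matrix(rbinom(n2 * m, 2, rep(f2, each = n2)), n2))
  gm <- make_gm(G)
  fit <- suppressWarnings(fit_admixture(gm, K = 2, seed = 1,
                                        max_iter = 1000))
  grp <- rep(1:2, c(n1, n2))
  k1 <- which.max(colMeans(fit$Q[grp == 1, ]))
  expect_true(all(fit$Q[grp == 1, k1] > 0.5))
  expect_true(all(fit$Q[grp == 2, k1] < 0.5))
  expect_gt(min(pmax(fit$Q[, 1], fit$Q[, 2])), 0.8)
})

test_that("covariance estimation is consistent and equivariant", {
  # identical components leave no deviation
  F0 <- rbind(rep(0.4, 50), rep(0.4, 50), rep(0.4, 50))
  C0 <- estimate_covariance(F0)
  expect_equal(unname(unclass(C0))[1:2, 1:2], matrix(0, 2, 2))
  # K = 2 with d_j / sqrt(c_j) ~ N(0, sigma^2): Chat converges to sigma^2
  set.seed(8)
  M <- 1e4; sigma2 <- 0.04
  fr <- runif(M, 0.2, 0.8)
  d <- rnorm(M, 0, sqrt(sigma2 * fr * (1 - fr)))
  F2 <- rbind(fr, fr + d)
  C2 <- estimate_covariance(F2)
  expect_lt(abs(as.numeric(C2[1, 1]) - sigma2) / sigma2, 0.05)
  # swapping non-reference components 3 and 4 swaps C rows/cols 2 and 3
  set.seed(9)
  F3 <- rbind(runif(200, 0.2, 0.8), runif(200), runif(200), runif(200))
  C3 <- unname(unclass(estimate_covariance(F3)))
  C3p <- unname(unclass(estimate_covariance(F3[c(1, 2, 4, 3), ])))
  expect_equal(C3p, C3[c(1, 3, 2), c(1, 3, 2)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("selection matrices inflate exactly the intended entries", {
  C <- matrix(c(0.05, 0.01, 0.01, 0.02, 0.06, 0.015, 0.01, 0.015, 0.04),
              3, 3)
  C <- (C + t(C)) / 2
  attr(C, "reference_component") <- 1
  expect_equal(selection_matrix(C, component = 2, scalar = 0),
               unclass(C), ignore_attr = TRUE)
  Cs <- selection_matrix(C, component = 2, scalar = 10)
  delta <- Cs - unclass(C)
  expect_equal(sum(delta != 0), 1)
  expect_equal(delta[1, 1], 10)
  Cr <- selection_matrix(C, component = 1, scalar = 10)
  expect_equal(Cr - unclass(C), matrix(10, 3, 3), ignore_attr = TRUE)
  expect_error(selection_matrix(C, component = 2, scalar = -1),
               "non-negative")
})

test_that("LRS matches a dense-grid oracle and honours trivial cases", {
  # K = 2 toy: one variant strongly shifted against a tight background
  C <- matrix(0.02, 1, 1)
  F <- rbind(0.5, 0.95)
  res <- lrs_scan(F, C, component = 2, reference_component = 1)
  agrid <- seq(0, 1, by = 1e-4)
  d <- 0.45; cc <- 0.25
  ll_a <- vapply(agrid, function(a) {
    S <- (1 - a) * 0.02 + a * 10.02
    -0.5 * (log(2 * pi) + log(cc * S) + d^2 / (cc * S))
  }, numeric(1))
  ll0 <- -0.5 * (log(2 * pi) + log(cc * 0.02) + d^2 / (cc * 0.02))
  expect_equal(res$lrs, 2 * (max(ll_a) - ll0), tolerance = 1e-6)
  # zero deviation: alpha = 0, LRS = 0, p = 1
  Fz <- rbind(c(0.5, 0.3), c(0.5, 0.3))
  rz <- lrs_scan(Fz, C, component = 2, reference_component = 1)
  expect_equal(rz$lrs, c(0, 0))
  expect_equal(rz$alpha_hat, c(0, 0))
  expect_equal(rz$chi2_p, c(1, 1))
  # zero scalar: selection model equals the neutral model
  r0 <- lrs_scan(F, C, component = 2, scalar = 0, reference_component = 1)
  expect_equal(r0$lrs, 0)
  # boundary reference frequencies are flagged, not scored
  Fb <- rbind(c(1e-9, 0.5), c(0.2, 0.9))
  rb <- lrs_scan(Fb, C, component = 2, reference_component = 1)
  expect_false(rb$scored[1])
  expect_true(is.na(rb$lrs[1]))
  expect_true(rb$scored[2])
})

test_that("LRS is non-negative across random data", {
  set.seed(10)
  fr <- runif(100, 0.1, 0.9)
  F <- rbind(fr, fr + rnorm(100, 0, 0.1), fr + rnorm(100, 0, 0.1))
  F <- pmin(pmax(F, 0.01), 0.99)
  C <- estimate_covariance(F)
  res <- lrs_scan(F, C, component = 3)
  expect_true(all(res$lrs >= 0))
  expect_true(all(res$chi2_p > 0 & res$chi2_p <= 1))
  expect_true(all(res$bonferroni_p >= res$chi2_p))
})

test_that("extreme null log-likelihoods are filtered by threshold", {
  res <- data.frame(variant_id = c("a", "b", "c"),
                    ll_neutral = c(-5, -1001, -999.9))
  out <- lle_filter(res)
  expect_equal(out$lle_filtered, c(FALSE, TRUE, FALSE))
  out2 <- lle_filter(res, min_lle = -Inf)
  expect_false(any(out2$lle_filtered))
})

test_that("matched empirical thresholding follows the percentile rule", {
  # flat-zero background: any positive LRS is an outlier
  out <- suppressWarnings(
    matched_empirical_threshold(5, rep(0, 2000), 0.25, rep(0.25, 2000)))
  expect_true(out)
  # a focal value tied with the background maximum is not an outlier
  bg <- c(seq_len(500) / 10)
  out2 <- suppressWarnings(
    matched_empirical_threshold(max(bg), bg, 0.25, rep(0.25, 500)))
  expect_false(out2)
  # neutral focal values are flagged at ~0.1%
  set.seed(12)
  bg3 <- runif(1e4); fo <- runif(4000)
  out3 <- matched_empirical_threshold(fo, bg3, rep(0.25, 4000),
                                      rep(0.25, 1e4))
  expect_lte(mean(out3), 0.004)
  expect_error(matched_empirical_threshold(1, numeric(0), 0.2, numeric(0)),
               "empty")
})

test_that("component frequencies with fixed Q track known mixtures", {
  ch <- generate_cohort(cohort_spec(c("A", "B"), 150, K = 2,
                                    n_variants = 100,
                                    fst_per_component = 0.2, seed = 14))
  F <- component_freqs(ch$gm, ch$truth$Q)
  expect_equal(dim(F), dim(ch$truth$F))
  expect_lt(mean(abs(F - ch$truth$F)), 0.05)
})
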