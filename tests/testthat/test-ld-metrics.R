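test_that("EM haplotype frequencies match a brute-force grid oracle", {
  # one double heterozygote among six samples makes the phase ambiguous
  g1 <- c(0L, 0L, 1L, 1L, 2L, 2L)
  g2 <- c(0L, 1L, 1L, 2L, 1L, 2L)
  p <- em_haplotype_freqs(g1, g2)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  oracle <- em_grid_oracle(g1, g2)
  expect_equal(unname(p["AB"]), unname(oracle["p_AB"]), tolerance = 1e-6)
  expect_equal(attr(p, "loglik"), unname(oracle["loglik"]), tolerance = 1e-6)
})

test_that("EM fixed point is stationary under one further update", {
  set.seed(3)
  g1 <- rbinom(40, 2, 0.4); g2 <- rbinom(40, 2, 0.6)
  p <- em_haplotype_freqs(g1, g2)
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  ndh <- tab[2, 2]
  cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  cAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  caB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  cab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  w <- p["AB"] * p["ab"] / (p["AB"] * p["ab"] + p["Ab"] * p["aB"])
  step <- c(cAB + w * ndh, cAb + (1 - w) * ndh, caB + (1 - w) * ndh,
            cab + w * ndh) / (2 * length(g1))
  expect_equal(unname(step), unname(p), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("r-squared handles identical, independent and monomorphic pairs", {
  g <- c(0L, 2L, 0L, 2L, 1L, 1L, 2L, 0L)
  expect_equal(ld_r2(g, g), 1, ignore_attr = TRUE)
  # zero sample covariance gives D = 0
  g1 <- c(0L, 0L, 2L, 2L)
  g2 <- c(0L, 2L, 0L, 2L)
  expect_equal(ld_r2(g1, g2), 0, tolerance = 1e-9, ignore_attr = TRUE)
  mono <- ld_r2(g1, rep(0L, 4))
  expect_equal(as.numeric(mono), 0)
  expect_true(attr(mono, "monomorphic"))
  expect_error(ld_r2(c(NA, NA), c(0L, 1L)), "complete-case")
})

test_that("r-squared is symmetric and bounded by the closed-form maximum", {
  set.seed(5)
  for (rep in 1:20) {
    g1 <- rbinom(60, 2, runif(1, 0.05, 0.95))
    g2 <- rbinom(60, 2, runif(1, 0.05, 0.95))
    if (length(unique(g1)) < 2 || length(unique(g2)) < 2) next
    r12 <- ld_r2(g1, g2)
    expect_equal(as.numeric(r12), as.numeric(ld_r2(g2, g1)),
                 tolerance = 1e-9)
    expect_lte(as.numeric(r12),
               r2_max(mean(g1) / 2, mean(g2) / 2) + 1e-9)
  }
})

test_that("r2 upper bound folds frequencies and peaks at equal MAF", {
  expect_equal(r2_max(0.1, 0.1), 1)
  expect_equal(r2_max(0.9, 0.1), 1)  # folded to (0.1, 0.1)
  for (p in c(0.01, 0.2, 0.5)) expect_equal(r2_max(p, p), 1)
  expect_error(r2_max(0, 0.1), "strictly inside")
  # argument order is irrelevant
  expect_equal(r2_max(0.02, 0.4), r2_max(0.4, 0.02))
})

test_that("max-LD scan finds duplicated partners and flags empty windows", {
  set.seed(9)
  n <- 40
  base <- rbinom(n, 2, 0.4)
  G <- cbind(sv = base, snp1 = base, snp2 = rbinom(n, 2, 0.5),
             far = rbinom(n, 2, 0.5))
  gm <- make_gm(G, pos = c(10000L, 10500L, 12000L, 900000L))
  res <- max_ld_scan(gm, "sv", c("snp1", "snp2", "far"), window_bp = 5e4,
                     n_nearest = 10)
  expect_equal(res$best_partner_id, "snp1")
  expect_equal(res$r2, 1)
  expect_equal(res$distance, 500L)
  # empty window: no panel variant within reach
  res2 <- max_ld_scan(gm, "sv", "far", window_bp = 1e4, n_nearest = 10)
  expect_true(is.na(res2$best_partner_id))
  expect_equal(res2$n_tested, 0L)
  # the focal variant never partners itself
  res3 <- max_ld_scan(gm, "sv", c("sv", "snp2"), window_bp = 5e4,
                      n_nearest = 10)
  expect_false(identical(res3$best_partner_id, "sv"))
})

test_that("injected LD partners are recovered near their target r2", {
  spec <- cohort_spec(c("P1", "P2"), 100, K = 2, n_variants = 20, seed = 21)
  ch <- generate_cohort(spec)
  gm <- inject_variant(ch$gm, ch$truth,
                       injection_spec("neutral", background_af = 0.4,
                                      ld_partner_r2 = 0.8, id = "focal"),
                       seed = 31)
  idx <- match(c("focal", "focal_partner"), gm$variants$id)
  r2 <- ld_r2(gm$dosages[, idx[1]], gm$dosages[, idx[2]])
  expect_gt(as.numeric(r2), 0.6)
  expect_lte(as.numeric(r2), 1)
  # a perfectly linked partner duplicates the column
  gm2 <- inject_variant(ch$gm, ch$truth,
                        injection_spec("neutral", background_af = 0.4,
                                       ld_partner_r2 = 1, id = "dup"),
                        seed = 32)
  j <- match(c("dup", "dup_partner"), gm2$variants$id)
  expect_identical(gm2$dosages[, j[1]], unname(gm2$dosages[, j[2]]),
                   ignore_attr = TRUE)
})

test_that("mask overlap respects half-open BED coordinates", {
  G <- matrix(0:2, 3, 4)
  gm <- make_gm(G, pos = c(5L, 11L, 50L, 100L), svtype = "DEL",
                svlen = c(3L, 1L, 10L, 20L))
  mask <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  ov <- interval_overlap_fraction(gm, mask)
  # v1 spans [5,8), v2 is exactly at the first masked base (0-based 10 ->
  # 1-based 11), v3 and v4 are beyond
  expect_equal(unname(ov$flag), c(FALSE, TRUE, FALSE, FALSE))
  # a variant ending exactly where the mask starts does not overlap
  gm2 <- make_gm(matrix(0L, 1, 1), pos = 6L, svtype = "DEL", svlen = 5L)
  expect_false(interval_overlap_fraction(gm2, mask)$flag[[1]])
  # variant fully inside
  gm3 <- make_gm(matrix(0L, 1, 1), pos = 13L, svtype = "DEL", svlen = 2L)
  expect_true(interval_overlap_fraction(gm3, mask)$flag[[1]])
  expect_error(interval_overlap_fraction(gm, data.frame(chrom = "chr1",
                                                        start = 5L,
                                                        end = 2L)),
               "malformed")
})

test_that("mask overlap agrees with a brute-force all-pairs check", {
  set.seed(13)
  pos <- sort(sample.int(1000, 10))
  len <- sample(1:50, 10, replace = TRUE)
  gm <- make_gm(matrix(0L, 2, 10), pos = pos, svtype = "DEL", svlen = len)
  mask <- data.frame(chrom = "chr1", start = c(100L, 600L),
                     end = c(250L, 640L))
  ov <- interval_overlap_fraction(gm, mask)
  brute <- vapply(seq_along(pos), function(i) {
    s <- pos[i]; e <- pos[i] + max(len[i], 1) - 1   # closed 1-based span
    any(e >= mask$start + 1 & s <= mask$end)
  }, logical(1))
  expect_equal(unname(ov$flag), brute)
  expect_equal(ov$n_overlap, sum(brute))
})
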