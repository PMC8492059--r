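test_that("cohort generation is reproducible and respects the model", {
  spec <- cohort_spec(c("A", "B"), 30, K = 2, n_variants = 60, seed = 17)
  ch1 <- generate_cohort(spec)
  ch2 <- generate_cohort(spec)
  expect_identical(ch1$gm$dosages, ch2$gm$dosages)
  expect_true(all(ch1$gm$dosages %in% c(0L, 1L, 2L)))
  expect_equal(unname(rowSums(ch1$truth$Q)), rep(1, 60), tolerance = 1e-12)
  expect_equal(dim(ch1$gm), c(60L, 60L))
  expect_error(cohort_spec("A", 0), "positive")
  expect_error(cohort_spec("A", 5, fst_per_component = 1.2), "0, 1")
})

test_that("a single ancestry component degenerates to one population", {
  ch <- generate_cohort(cohort_spec(c("A", "B"), 20, K = 1,
                                    n_variants = 30, seed = 3))
  expect_equal(unname(ch$truth$Q), matrix(1, 40, 1))
})

test_that("component frequencies collapse to ancestral as drift vanishes", {
  ch <- generate_cohort(cohort_spec("A", 10, K = 2, n_variants = 300,
                                    fst_per_component = 1e-5, seed = 5))
  dev <- abs(sweep(ch$truth$F, 2L, ch$truth$anc))
  expect_lt(max(dev), 0.05)
})

test_that("missing genotypes appear at the configured rate", {
  ch <- generate_cohort(cohort_spec(c("A", "B"), 100, K = 2,
                                    n_variants = 100, missing_rate = 0.07,
                                    seed = 9))
  expect_lt(abs(mean(is.na(ch$gm$dosages)) - 0.07), 0.01)
})

test_that("injected variants hit their target frequencies", {
  spec <- cohort_spec(c("P1", "P2", "P3"), 80, K = 3, n_variants = 10,
                      seed = 11)
  ch <- generate_cohort(spec)
  # introgressed: high in P3, rare elsewhere, across several seeds
  for (sd in 1:5) {
    gm <- inject_variant(ch$gm, ch$truth,
                         injection_spec("introgressed", target = "P3",
                                        target_af = 0.6,
                                        background_af = 0.005),
                         popmap = ch$popmap, seed = sd)
    af <- compute_af(gm, ch$popmap)
    inj <- af[af$variant_id == "inj", ]
    tgt <- inj$AF[inj$population == "P3"]
    se <- sqrt(0.6 * 0.4 / 160)
    expect_lt(abs(tgt - 0.6), 3 * se)
    expect_lt(inj$AF[inj$population == "P1"], 0.05)
  }
  # all-reference when the target frequency is zero everywhere
  gm0 <- inject_variant(ch$gm, ch$truth,
                        injection_spec("neutral", background_af = 0,
                                       id = "null"), seed = 2)
  expect_true(all(gm0$dosages[, "null"] == 0L))
  # differentiated variants follow the admixture-weighted expectation
  gmd <- inject_variant(ch$gm, ch$truth,
                        injection_spec("differentiated", target = 2,
                                       target_af = 0.9,
                                       background_af = 0.05, id = "diff"),
                        seed = 3)
  f <- c(0.05, 0.9, 0.05)
  expected <- mean(ch$truth$Q %*% f)
  realized <- mean(gmd$dosages[, "diff"]) / 2
  se <- sqrt(expected * (1 - expected) / (2 * nrow(ch$truth$Q)))
  expect_lt(abs(realized - expected), 4 * se)
  expect_error(inject_variant(ch$gm, ch$truth,
                              injection_spec("introgressed", target = "ZZ"),
                              popmap = ch$popmap),
               "absent")
})

test_that("breakpoint reads come from the requested haplotype", {
  up <- strrep("A", 60); down <- strrep("G", 60)
  ins <- paste(rep(c("C", "T"), 17)[1:33], collapse = "")
  non <- generate_breakpoint_reads(up, ins, down, carrier = FALSE,
                                   read_length = 50, depth = 100, seed = 1)
  expect_length(non, 100)
  expect_false(any(grepl(ins, non, fixed = TRUE)))
  # carrier reads at saturating depth must span the breakpoint
  car <- generate_breakpoint_reads(up, ins, down, carrier = TRUE,
                                   read_length = 50, depth = 400, seed = 2)
  km <- build_diagnostic_kmer(substr(up, 50, 60), ins,
                              substr(down, 1, 4))
  expect_gte(scan_reads(car, km)$n_match, 1)
  expect_length(generate_breakpoint_reads(up, ins, down, TRUE, 50, 0), 0)
  expect_error(generate_breakpoint_reads(up, ins, down, TRUE, 1000, 10),
               "exceeds")
  expect_error(generate_breakpoint_reads("ANA", ins, down, TRUE, 10, 1),
               "invalid")
  # reproducibility
  expect_identical(generate_breakpoint_reads(up, ins, down, TRUE, 50, 30,
                                             seed = 5),
                   generate_breakpoint_reads(up, ins, down, TRUE, 50, 30,
                                             seed = 5))
})

test_that("admixture fitting recovers generated ancestry proportions", {
  spec <- cohort_spec(c("A", "B"), 60, K = 2, n_variants = 600,
                      fst_per_component = 0.15,
                      dirichlet_conc = rbind(c(30, 0.1), c(0.1, 30)),
                      seed = 9)
  ch <- generate_cohort(spec)
  fit <- suppressWarnings(fit_admixture(ch$gm, K = 2, seed = 5,
                                        max_iter = 800))
  mae <- min(mean(abs(fit$Q - ch$truth$Q)),
             mean(abs(fit$Q[, 2:1] - ch$truth$Q)))
  expect_lt(mae, 0.05)
})
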