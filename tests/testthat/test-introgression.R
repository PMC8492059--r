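# shared fixture: an outgroup population plus a focal population carrying a
# differentiated SV in perfect LD with a nearby marker SNP
introgression_fixture <- function(seed = 23, sv_outgroup_af = 0) {
  set.seed(seed)
  n_af <- 60; n_eas <- 60
  hap_af <- rbinom(n_af, 2, sv_outgroup_af)
  hap_eas <- rbinom(n_eas, 2, 0.7)
  sv <- c(hap_af, hap_eas)
  marker <- sv                        # duplicated column: r2 = 1
  other <- rbinom(n_af + n_eas, 2, 0.5)
  G <- cbind(sv = sv, mk = marker, mk2 = other)
  rownames(G) <- sprintf("s%03d", seq_len(n_af + n_eas))
  gm <- make_gm(G, pos = c(50000L, 60000L, 70000L))
  pm <- population_map(rownames(G),
                       rep(c("ESN", "CDX"), c(n_af, n_eas)),
                       superpopulation = rep(c("AFR", "EAS"),
                                             c(n_af, n_eas)))
  markers <- data.frame(chrom = "chr1", pos = c(60000L, 70000L),
                        allele = "C", population = "CDX")
  list(gm = gm, pm = pm, markers = markers)
}

test_that("candidate tagging requires both LD and outgroup rarity", {
  fx <- introgression_fixture()
  tab <- tag_candidates("sv", fx$markers, fx$gm, fx$pm, focal_pop = "CDX")
  expect_true(tab$candidate)
  expect_equal(tab$r2, 1)
  expect_equal(tab$best_marker, "mk")
  expect_equal(tab$outgroup_af, 0)
  # common in the outgroup: the frequency gate rejects it
  fx2 <- introgression_fixture(sv_outgroup_af = 0.05)
  tab2 <- tag_candidates("sv", fx2$markers, fx2$gm, fx2$pm,
                         focal_pop = "CDX")
  expect_false(tab2$candidate)
  expect_equal(tab2$reason, "outgroup_af")
  # no marker within the window
  tab3 <- tag_candidates("sv", fx$markers, fx$gm, fx$pm,
                         focal_pop = "CDX", window_bp = 100)
  expect_false(tab3$candidate)
  expect_equal(tab3$reason, "no_marker_in_window")
})

test_that("candidate tagging is invariant to marker and SV order", {
  fx <- introgression_fixture()
  # two SVs scanned in both orders, markers shuffled
  G <- cbind(fx$gm$dosages, sv2 = rbinom(120, 2, 0.5))
  gm <- make_gm(G, pos = c(50000L, 60000L, 70000L, 55000L))
  t1 <- tag_candidates(c("sv", "sv2"), fx$markers, gm, fx$pm,
                       focal_pop = "CDX")
  t2 <- tag_candidates(c("sv2", "sv"), fx$markers[2:1, ], gm, fx$pm,
                       focal_pop = "CDX")
  expect_equal(t1, t2)
})

test_that("synthetic introgression scenarios are recovered end to end", {
  hits <- 0L
  for (sd in 1:8) {
    spec <- cohort_spec(c("ESN", "CDX"), 60, K = 2, n_variants = 5,
                        seed = sd)
    ch <- generate_cohort(spec)
    ch$popmap$superpopulation <- rep(c("AFR", "EAS"), each = 60)
    gm <- inject_variant(ch$gm, ch$truth,
                         injection_spec("introgressed", target = "CDX",
                                        target_af = 0.7,
                                        background_af = 0.002,
                                        ld_partner_r2 = 0.9,
                                        pos = 50000L, id = "sv"),
                         popmap = ch$popmap, seed = sd + 100)
    markers <- data.frame(chrom = "chr1", pos = 50500L)
    tab <- tag_candidates("sv", markers, gm, ch$popmap, focal_pop = "CDX")
    neutral <- tag_candidates("var1", markers, gm, ch$popmap,
                              focal_pop = "CDX", window_bp = 1e6)
    hits <- hits + as.integer(tab$candidate && !neutral$candidate)
  }
  expect_gte(hits, 7L)
})

test_that("archaic allele matching counts read-supported calls", {
  hap <- setNames(rep(1L, 93), sprintf("site%02d", 1:93))
  counts <- setNames(rep(5L, 93), names(hap))
  counts[1:4] <- 0L   # four sites fail the 2-read support threshold
  res <- archaic_allele_matching(hap, list(vindija = counts))
  expect_equal(res$n_match, 89L)
  expect_equal(res$n_sites, 93L)
  expect_equal(res$percent, 96)
  # identical profile: full matching
  res2 <- archaic_allele_matching(hap, list(x = setNames(rep(2L, 93),
                                                         names(hap))))
  expect_equal(res2$fraction, 1)
  # all counts below threshold against an all-alternative haplotype
  res3 <- archaic_allele_matching(hap, list(x = setNames(rep(1L, 93),
                                                         names(hap))))
  expect_equal(res3$n_match, 0L)
  # fraction is monotone non-increasing in min_reads for all-alt haplotypes
  fr <- vapply(1:4, function(mr)
    archaic_allele_matching(hap, list(x = counts), min_reads = mr)$fraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(archaic_allele_matching(setNames(integer(0), character(0)),
                                       list(x = counts)), "zero")
})

test_that("diagnostic sequences concatenate with length bookkeeping", {
  km <- build_diagnostic_kmer("ACGTACGTACG", strrep("T", 33), "GGCC")
  expect_equal(nchar(km$sequence), 48)
  expect_equal(km$up_flank_len + km$insertion_len + km$down_flank_len, 48)
  km0 <- build_diagnostic_kmer("ACGTACGTACG", "", "GGCC")
  expect_equal(km0$sequence, "ACGTACGTACGGGCC")
  expect_equal(nchar(km0$sequence), 15)
  expect_error(build_diagnostic_kmer("ACGU", "A", "C"), "invalid")
})

test_that("read scans count unique exact matches", {
  km <- build_diagnostic_kmer("AACCGGTTAAC", strrep("CT", 10), "GGAA")
  q <- km$sequence
  reads <- c(r1 = q, r2 = paste0("AAAA", q, "TTTT"), r3 = strrep("A", 60),
             dup = q)
  sc <- scan_reads(reads, km)
  expect_equal(sc$n_match, 2L)  # r1 == dup counted once
  expect_true(sc$carrier)
  expect_equal(sc$n_unique_reads, 3L)
  expect_equal(scan_reads(character(0), km)$n_match, 0L)
  # forward-only by default; reverse complement needs both_strands
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  expect_equal(scan_reads(c(x = rc), km)$n_match, 0L)
  expect_equal(scan_reads(c(x = rc), km, both_strands = TRUE)$n_match, 1L)
})

test_that("spanning-read counts match the closed-form expectation", {
  up <- strrep("A", 300); down <- strrep("G", 300)
  ins <- paste(rep(c("C", "T"), 17)[1:33], collapse = "")
  km <- build_diagnostic_kmer(substr(up, 290, 300), ins,
                              substr(down, 1, 4))
  depth <- 30; rl <- 100
  L <- 300 + 33 + 300
  n_starts <- L - rl + 1
  n_span <- rl - 48 + 1      # starts whose read contains the full 48-mer
  p_span <- n_span / n_starts
  counts <- vapply(1:10, function(sd) {
    reads <- generate_breakpoint_reads(up, ins, down, TRUE, rl, depth,
                                       seed = sd)
    scan_reads(reads, km)$n_match
  }, numeric(1))
  expected <- depth * p_span
  se <- sqrt(depth * p_span * (1 - p_span) / 10)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
  # reads from the reference haplotype never contain the insertion interior
  ref_reads <- generate_breakpoint_reads(up, ins, down, FALSE, rl, 200,
                                         seed = 3)
  expect_equal(scan_reads(ref_reads, km)$n_match, 0L)
})
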