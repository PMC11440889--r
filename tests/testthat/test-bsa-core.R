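# Per-SNP bulk statistics, smoothing, CI simulation, G' p-values and
# region calling.

test_that("per-SNP frequency statistics follow their definitions", {
  expect_equal(refAlleleFrequency(75, 25, 75, 25), 0.75)
  expect_equal(refAlleleFrequency(10, 0, 10, 0), 1.0)
  expect_error(refAlleleFrequency(0, 0, 0, 0), "zero total read depth")

  expect_equal(snpIndex(30, 10), 0.25)
  expect_equal(snpIndex(0, 50), 1.0)
  expect_equal(snpIndex(50, 0), 0.0)
  expect_error(snpIndex(0, 0), "zero read depth")

  expect_equal(deltaSnpIndex(0.25, 0.25), 0)
  expect_equal(deltaSnpIndex(0.5, 0.0), 0.5)
  expect_equal(deltaSnpIndex(0.0, 0.5), -0.5)
})

test_that("G statistic matches hand-expanded and oracle values", {
  expect_equal(gStatistic(10, 10, 10, 10), 0)
  expect_equal(gStatistic(30, 10, 10, 30), 20.93, tolerance = 1e-3)
  expect_equal(gStatistic(20, 0, 0, 20), 80 * log(2))
  # degenerate tables (a zero margin) return 0 by convention
  expect_equal(gStatistic(0, 0, 10, 20), 0)
  expect_equal(gStatistic(10, 0, 20, 0), 0)
})

test_that("G equals the generic 2x2 log-likelihood-ratio statistic", {
  set.seed(42)
  for (i in 1:250) {
    n <- rpois(4, lambda = sample(5:80, 1)) + 1L
    # oracle: LLR from the chi-square machinery's expected counts
    tab <- matrix(n, 2, 2)
    e <- suppressWarnings(chisq.test(tab, correct = FALSE))$expected
    oracle <- 2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
    expect_equal(gStatistic(n[1], n[3], n[2], n[4]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("bulk swap negates delta(SNP-index) and leaves G unchanged", {
  set.seed(1)
  d <- data.frame(chrom = "chr1", pos = seq(1e5, 1e6, by = 1e5),
                  ref_H = rpois(10, 60), alt_H = rpois(10, 20),
                  ref_L = rpois(10, 60), alt_L = rpois(10, 20))
  swapped <- d
  swapped[, c("ref_H", "alt_H", "ref_L", "alt_L")] <-
    d[, c("ref_L", "alt_L", "ref_H", "alt_H")]
  s1 <- adData(computeBulkStats(AlleleDepthTable(d)))
  s2 <- adData(computeBulkStats(AlleleDepthTable(swapped)))
  expect_equal(s2$delta_snp_index, -s1$delta_snp_index)
  expect_equal(s2$G, s1$G)
})

test_that("tricube smoothing behaves on constants, isolated points and a hand case", {
  pos <- c(1, 2, 3) * 1e5
  expect_equal(tricubeSmooth(pos, c(4, 4, 4), 1e6), c(4, 4, 4))
  # isolated SNP: no neighbour within the window keeps its own value
  expect_equal(tricubeSmooth(c(1e5, 9e6), c(1, 7), windowBp = 1e6),
               c(1, 7))
  # explicit kernel arithmetic for the centre of three equally spaced SNPs
  D <- 5e5
  w <- (1 - (1e5 / D)^3)^3
  expect_equal(tricubeSmooth(pos, c(0, 1, 0), 1e6)[2],
               1 / (1 + 2 * w), tolerance = 1e-12)
  # bounded by the local min/max and idempotent on the result's constants
  set.seed(3)
  v <- runif(50)
  p <- sort(sample.int(5e6, 50))
  sm <- tricubeSmooth(p, v, 1e6)
  expect_true(all(sm >= min(v) - 1e-12 & sm <= max(v) + 1e-12))
})

test_that("filterSites retains passing sites and attributes removals in rule order", {
  # 5-site toy: one low per-bulk depth, one extreme pooled ref frequency,
  # three passing
  d <- data.frame(
    chrom = "chr1", pos = c(1e5, 2e5, 3e5, 4e5, 5e5),
    ref_H = c(90, 95, 12, 100, 120), alt_H = c(30, 35, 8, 3, 40),
    ref_L = c(85, 90, 70, 95, 110), alt_L = c(35, 30, 20, 2, 35),
    gq_H = 99L, gq_L = 99L)
  # site 3: depth_H = 20 < 40 (all other rules pass);
  # site 4: pooled ref freq = 195/200 > 0.9
  out <- filterSites(AlleleDepthTable(d), FilterSpec())
  expect_equal(nSites(out), 3)
  rc <- removedCounts(out)
  expect_equal(rc[["min_sample_depth"]], 1L)
  expect_equal(rc[["ref_allele_freq"]], 1L)
  # all passing -> identity
  clean <- toyAdt()[c(1, 2, 3, 5)]
  out2 <- filterSites(clean, FilterSpec())
  expect_equal(adData(out2), adData(clean))
})

test_that("removal attribution matches a brute-force first-failed-rule oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 40
    d <- data.frame(
      chrom = "chr1", pos = sort(sample.int(1e7, n)),
      ref_H = rpois(n, sample(c(5, 40, 90, 200), n, replace = TRUE)),
      alt_H = rpois(n, 25),
      ref_L = rpois(n, sample(c(5, 40, 90, 200), n, replace = TRUE)),
      alt_L = rpois(n, 25),
      gq_H = sample(c(30L, 99L), n, replace = TRUE),
      gq_L = 99L)
    spec <- FilterSpec()
    out <- filterSites(AlleleDepthTable(d), spec)
    dSorted <- adData(AlleleDepthTable(d))
    oracle <- filterOracle(dSorted, spec)
    expect_equal(nSites(out), sum(is.na(oracle)))
    oc <- table(oracle)
    for (rule in names(oc))
      expect_equal(removedCounts(out)[[rule]], as.integer(oc[[rule]]))
  }
})

test_that("simulated CI thresholds are ordered, centred and narrow with depth", {
  des <- BulkDesign(nPopulation = 1600, bulkSize = 160, depthPerBulk = 160)
  delta <- simulateNullDelta(des, depth = 200, n = 20000)
  expect_lt(abs(mean(delta)), 0.005)  # bulks exchangeable under the null
  ci <- simulateCI(des, depths = c(100, 200, 400), reps = 10000, seed = 2)
  tab <- ciTable(ci)
  expect_true(all(tab$CI_99 >= tab$CI_95))
  expect_lt(tab$CI_95[tab$depth == 400], tab$CI_95[tab$depth == 100])
  # interpolation: exact on grid points, monotone in between, constant
  # beyond the ends
  expect_equal(interpolateCI(ci, c(100, 200, 400), 0.95), tab$CI_95)
  mid <- interpolateCI(ci, 150, 0.95)
  expect_true(mid <= tab$CI_95[1] && mid >= tab$CI_95[2])
  expect_equal(interpolateCI(ci, 1e4, 0.99), tab$CI_99[3])
  expect_error(simulateCI(des, depths = -5), "positive")
  expect_error(simulateCI(des, depths = 100, reps = 10), "at least 100")
})

test_that("G' p-values: BH arithmetic, flat input, and outlier detection", {
  expect_equal(p.adjust(c(0.001, 0.01, 0.02, 0.8), method = "BH"),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.8))
  expect_error(gprimePvalues(rep(1, 10)), "fewer than 50")
  flat <- gprimePvalues(rep(2.5, 100))
  expect_true(all(flat$pvalue == flat$pvalue[1]))
  expect_equal(max(flat$pvalue), 1)
  # one injected G' at 100x the null median must reach q < 0.01 while the
  # background stays non-significant
  set.seed(8)
  g <- rlnorm(10000, meanlog = 1, sdlog = 0.5)
  g[5000] <- 100 * median(g)
  pq <- gprimePvalues(g)
  expect_lt(pq$qvalue[5000], 0.01)
  expect_gt(median(pq$qvalue[-5000]), 0.5)
})

test_that("QTL regions are maximal runs of consecutive significant SNPs", {
  des <- smallDesign()
  dummyCi <- simulateCI(des, depths = c(50, 400), reps = 100, seed = 1)
  mkTable <- function(delta) {
    n <- length(delta)
    AlleleDepthTable(data.frame(
      chrom = "chr1", pos = seq_len(n) * 1e5,
      ref_H = 100, alt_H = 100, ref_L = 100, alt_L = 100,
      snp_index_H = 0.5, snp_index_L = 0.5,
      delta_snp_index = delta, delta_smooth = delta))
  }
  thr <- interpolateCI(dummyCi, 200, 0.99)
  # no SNP above threshold -> empty
  empty <- callQtlRegions(mkTable(rep(0, 10)), dummyCi,
                          methods = "deltaIndex_CI99")
  expect_length(empty, 0)
  # one contiguous run of 5 significant SNPs -> one region of 5 SNPs
  delta <- rep(0, 12); delta[4:8] <- thr + 0.2
  reg <- callQtlRegions(mkTable(delta), dummyCi,
                        methods = "deltaIndex_CI99")
  expect_length(reg, 1)
  expect_equal(reg$nSnps, 5L)
  expect_equal(GenomicRanges::start(reg), 4e5)
  expect_equal(GenomicRanges::end(reg), 8e5)
  expect_true(reg$peak >= 4e5 && reg$peak <= 8e5)
  # two runs separated by a non-significant SNP -> two regions
  delta2 <- rep(0, 12); delta2[c(3, 4, 6, 7)] <- thr + 0.2
  reg2 <- callQtlRegions(mkTable(delta2), dummyCi,
                         methods = "deltaIndex_CI99")
  expect_length(reg2, 2)
})

test_that("region calling is invariant to input SNP order", {
  des <- smallDesign()
  ci <- simulateCI(des, depths = c(50, 400), reps = 100, seed = 1)
  set.seed(12)
  n <- 60
  d <- data.frame(chrom = rep(c("chr1", "chr2"), each = n / 2),
                  pos = rep(seq_len(n / 2) * 1e5, 2),
                  ref_H = rpois(n, 80), alt_H = rpois(n, 80),
                  ref_L = rpois(n, 80), alt_L = rpois(n, 20))
  shuffled <- d[sample.int(n), ]
  r1 <- callQtlRegions(computeBulkStats(AlleleDepthTable(d)), ci,
                       methods = "deltaIndex_CI95")
  r2 <- callQtlRegions(computeBulkStats(AlleleDepthTable(shuffled)), ci,
                       methods = "deltaIndex_CI95")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
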