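# Windowed pi / F_ST / ROD statistics and sweep-segment calling.

test_that("missingness filter removes sites strictly above the threshold", {
  a <- matrix(c(0L, 1L, NA, NA, NA,    # 60% missing in 5 haplotypes? no:
                0L, 1L, 0L, 1L, NA,
                0L, 1L, 1L, 0L, 1L), nrow = 3, byrow = TRUE)
  # per-site missing fractions: 3/5 = 0.6, 1/5 = 0.2, 0
  h <- HaplotypeMatrix("p", c(100L, 200L, 300L), a)
  out <- filterMissing(h, maxMissing = 0.5)
  expect_equal(sitePositions(out), c(200L, 300L))
  # boundary: exactly 50% missing is kept
  b <- matrix(c(0L, 1L, NA, NA), nrow = 1)
  h2 <- HaplotypeMatrix("p", 100L, b)
  expect_equal(nrow(alleleMatrix(filterMissing(h2, 0.5))), 1)
})

test_that("windowed pi matches the mean-pairwise-difference oracle", {
  win <- data.frame(chrom = "chr1", start = 1, end = 1000)
  # monomorphic window
  mono <- HaplotypeMatrix("p", c(100L, 500L), matrix(0L, 2, 6))
  expect_equal(windowPi(mono, win)$pi, 0)
  # one site, 4 haplotypes with allele counts 2/2 in a 1000-bp window:
  # mean pairwise difference 4/6 per site -> 6.667e-4 per bp
  four <- HaplotypeMatrix("p", 500L, matrix(c(0L, 0L, 1L, 1L), 1, 4))
  expect_equal(windowPi(four, win)$pi, (4 / 3 * 0.5) / 1000,
               tolerance = 1e-12)
  expect_equal(windowPi(four, win)$pi, (4 / 6) / 1000, tolerance = 1e-12)
  # doubling window length halves per-bp pi for the same sites
  win2 <- data.frame(chrom = "chr1", start = 1, end = 2000)
  expect_equal(windowPi(four, win2)$pi, windowPi(four, win)$pi / 2)
})

test_that("pi is invariant to relabeling and consistent across window halves", {
  set.seed(4)
  p <- runif(40, 0.1, 0.9)
  pos <- sort(sample.int(10000, 40))
  h <- panelFromFreq(p, 30, pos)
  perm <- HaplotypeMatrix("p", pos,
                          alleleMatrix(h)[, sample.int(30)])
  whole <- data.frame(chrom = "chr1", start = 1, end = 10000)
  halves <- data.frame(chrom = "chr1", start = c(1, 5001),
                       end = c(5000, 10000))
  expect_equal(windowPi(h, whole)$pi, windowPi(perm, whole)$pi)
  pw <- windowPi(h, whole)$pi
  ph <- windowPi(h, halves)$pi
  expect_equal(pw, (5000 * ph[1] + 5000 * ph[2]) / 10000,
               tolerance = 1e-12)
})

test_that("Hudson F_ST matches a per-site brute-force oracle", {
  set.seed(5)
  pos <- c(100L, 200L, 300L)
  hA <- panelFromFreq(runif(3, 0.2, 0.8), 20, pos)
  hB <- panelFromFreq(runif(3, 0.2, 0.8), 24, pos)
  win <- data.frame(chrom = "chr1", start = 1, end = 1000)
  got <- windowFst(hA, hB, win)$fst_raw
  # brute force directly from the allele matrices
  pA <- rowMeans(alleleMatrix(hA)); nA <- 20
  pB <- rowMeans(alleleMatrix(hB)); nB <- 24
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  expect_equal(got, sum(num) / sum(den), tolerance = 1e-12)
})

test_that("F_ST hits its anchor points", {
  pos <- c(100L, 200L)
  win <- data.frame(chrom = "chr1", start = 1, end = 1000)
  # fixed difference -> 1
  fixA <- HaplotypeMatrix("a", pos, matrix(1L, 2, 10))
  fixB <- HaplotypeMatrix("b", pos, matrix(0L, 2, 12))
  expect_equal(windowFst(fixA, fixB, win)$fst, 1)
  # a population against itself is ~0 (slightly negative raw is fine)
  set.seed(6)
  h <- panelFromFreq(runif(30, 0.2, 0.8), 50)
  winBig <- data.frame(chrom = "chr1", start = 1, end = 4000)
  self <- windowFst(h, h, winBig)$fst_raw
  expect_lt(abs(self), 2 / 50)
  # Weir-Cockerham mode agrees at the anchors
  expect_equal(windowFst(fixA, fixB, win, estimator = "wc")$fst, 1)
  expect_lt(abs(windowFst(h, h, winBig, estimator = "wc")$fst_raw), 2 / 50)
})

test_that("ROD follows its definition and propagates missing values", {
  expect_equal(rod(0.002, 0.0005), 0.75)
  expect_equal(rod(0.001, 0.001), 0)
  expect_equal(rod(0.001, 0.002), -1)  # no clamping
  expect_true(is.na(rod(0, 0.001)))
  # monotone in decreasing derived diversity
  r <- rod(0.002, seq(0.002, 0, by = -0.0005))
  expect_true(all(diff(r) > 0))
})

test_that("window harmonization keeps jointly supported windows only", {
  t1 <- data.frame(start = c(1, 501, 1001), n_snps = c(5L, 0L, 4L),
                   pi = c(1, NA, 3) * 1e-3)
  t2 <- data.frame(start = c(1, 501, 1001), n_snps = c(5L, 6L, 4L),
                   pi = c(1, 2, 3) * 1e-3)
  out <- harmonizeWindows(list(a = t1, b = t2), minSnps = 3)
  expect_equal(out$a$start, c(1, 1001))
  expect_equal(attr(out, "dropped"), 1L)
  # all tracks complete -> identity
  out2 <- harmonizeWindows(list(a = t2, b = t2), minSnps = 3)
  expect_equal(out2$a, t2)
  # brute-force intersection count on a synthetic gap pattern
  set.seed(7)
  n1 <- sample(0:6, 50, replace = TRUE)
  n2 <- sample(0:6, 50, replace = TRUE)
  ta <- data.frame(start = seq_len(50), n_snps = n1)
  tb <- data.frame(start = seq_len(50), n_snps = n2)
  expected <- sum(n1 >= 3 & n2 >= 3)
  got <- suppressMessages(harmonizeWindows(list(ta, tb), minSnps = 3))
  expect_equal(nrow(got[[1]]), expected)
})

test_that("sweep calling applies joint quantile cutoffs and the merging rule", {
  n <- 120
  ws <- data.frame(chrom = "chr1",
                   start = 1 + (seq_len(n) - 1) * 500,
                   end = 1 + (seq_len(n) - 1) * 500 + 4999,
                   pi_der = 0.002, fst = 0, rod = 0)
  sig <- c(50, 51, 53)   # two adjacent, one separated by a step-window
  ws$fst[sig] <- 1; ws$pi_der[sig] <- 0; ws$rod[sig] <- 1
  segsStrict <- callSweeps(ws, "domestication", gap = 0)
  expect_length(segsStrict, 2)
  segsGap <- callSweeps(ws, "domestication", gap = 1)
  expect_length(segsGap, 1)
  expect_equal(GenomicRanges::start(segsGap), ws$start[50])
  expect_equal(GenomicRanges::end(segsGap), ws$end[53])
  # no window passing all three: the top-FST windows are also the most
  # diverse, so the joint criterion is never met
  ws2 <- ws
  ws2$fst <- seq(0, 1, length.out = n)
  ws2$pi_der <- seq(0, 0.004, length.out = n)
  ws2$rod <- seq(1, -1, length.out = n)
  expect_length(callSweeps(ws2, "domestication"), 0)
  # too few windows for stable quantiles
  expect_error(callSweeps(ws[1:50, ], "domestication"), "fewer than 100")
})

test_that("quantile cutoffs are order-free", {
  set.seed(9)
  n <- 150
  ws <- data.frame(chrom = "chr1",
                   start = 1 + (seq_len(n) - 1) * 500,
                   end = 1 + (seq_len(n) - 1) * 500 + 4999,
                   pi_der = runif(n, 0, 0.004),
                   fst = runif(n), rod = runif(n, -1, 1))
  perm <- ws[sample.int(n), ]
  c1 <- S4Vectors::metadata(callSweeps(ws, "improvement"))$cutoffs
  c2 <- S4Vectors::metadata(callSweeps(perm, "improvement"))$cutoffs
  expect_equal(c1, c2)
})

test_that("a simulated complete sweep yields one segment overlapping the truth", {
  pans <- simulateThreePopulations(
    nWild = 60, nLocal = 80, nImproved = 60, seqLength = 2e5,
    mutRate = 0.01, sweepInterval = c(50001, 60000), sweepStrength = 1,
    seed = 77)
  ws <- sweepScan(pans$wild, pans$local)
  segs <- callSweeps(ws, "domestication", gap = 1)
  expect_length(segs, 1)
  truth <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 60000))
  expect_true(GenomicRanges::countOverlaps(segs, truth) == 1)
})
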