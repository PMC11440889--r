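# Candidate-gene assignment, expression specificity rule, and
# allele-frequency divergence tests.

test_that("genes are assigned from variant positions and regulatory flanks", {
  genes <- toyGenes()
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 80000))
  # variant inside geneB's body
  v1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(25000, 25000))
  hit <- assignGenes(seg, genes, v1)
  expect_equal(hit$gene_id, "geneB")
  expect_equal(hit$assignment, "variant_hit")
  # variant 1500 bp upstream of geneC (+ strand, start 60000)
  v2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(58500, 58500))
  expect_equal(assignGenes(seg, genes, v2)$gene_id, "geneC")
  # 1500 bp beyond geneC's end is downstream: not a hit for + strand
  v3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(71500, 71500))
  near <- assignGenes(seg, genes, v3)
  expect_equal(near$assignment, "nearest")
  expect_equal(near$gene_id, "geneC")  # 1.5 kb from geneC's end
  # with symmetric flanks the same variant does hit
  expect_equal(assignGenes(seg, genes, v3, upstreamOnly = FALSE)$assignment,
               "variant_hit")
})

test_that("intergenic segments fall back to the single nearest gene", {
  genes <- toyGenes()
  # segment at 40000-42000: geneB ends 30000 (10 kb left), geneC starts
  # 60000 (18 kb right) -> geneB only
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40000, 42000))
  novar <- GenomicRanges::GRanges()
  out <- assignGenes(seg, genes, novar)
  expect_equal(out$gene_id, "geneB")
  expect_false(out$nearest_tie)
  # nearest-gene choice matches exhaustive distance minimisation on
  # random fixtures
  set.seed(10)
  for (i in 1:20) {
    starts <- sort(sample.int(9e5, 6))
    g <- GenomicRanges::GRanges("chr1",
           IRanges::IRanges(starts, starts + 2000),
           strand = "+", gene_id = paste0("g", 1:6))
    s0 <- sample.int(9e5, 1)
    seg2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s0, s0 + 100))
    got <- assignGenes(seg2, g, novar)
    dist <- GenomicRanges::distance(g, seg2)
    expect_setequal(got$gene_id, g$gene_id[dist == min(dist)])
  }
  # no genes on the chromosome -> empty with warning
  segX <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 100))
  expect_warning(outX <- assignGenes(segX, genes, novar), "no genes")
  expect_equal(nrow(outX), 0)
})

test_that("equidistant nearest genes are both reported and flagged", {
  g <- GenomicRanges::GRanges("chr1",
         IRanges::IRanges(c(1000, 9001), c(2000, 10000)),
         strand = "+", gene_id = c("left", "right"))
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000))
  out <- assignGenes(seg, g, GenomicRanges::GRanges())
  expect_setequal(out$gene_id, c("left", "right"))
  expect_true(all(out$nearest_tie))
})

test_that("silk-gland rule is a conjunction of level and specificity", {
  silk <- c("ASG", "MSG", "PSG")
  # max 15 > 10 and fraction 18/68 >= 0.20 -> pass
  expect_true(silkGlandFilter(c(ASG = 15, MSG = 2, PSG = 1, FB = 30,
                                MG = 20), silk))
  # perfectly specific but below the level threshold -> fail
  expect_false(silkGlandFilter(c(ASG = 9, MSG = 9, PSG = 9, FB = 0,
                                 MG = 0), silk))
  # all-zero gene -> fail
  expect_false(silkGlandFilter(c(ASG = 0, MSG = 0, PSG = 0, FB = 0,
                                 MG = 0), silk))
  expect_error(silkGlandFilter(c(A = 1, B = 2), silk), "not found")
  # monotone: raising a silk FPKM never flips pass -> fail
  base <- c(ASG = 15, MSG = 2, PSG = 1, FB = 30, MG = 20)
  for (tissue in silk) {
    up <- base; up[tissue] <- up[tissue] + 50
    expect_true(silkGlandFilter(up, silk))
  }
})

test_that("allele-frequency chi-square matches hand and oracle values", {
  flat <- afChisq(50, 50, 50, 50)
  expect_equal(flat$chi2, 0)
  expect_equal(flat$pvalue, 1)
  opp <- afChisq(90, 10, 10, 90)
  expect_equal(opp$chi2, 128)
  expect_lt(opp$pvalue, 0.001)
  # oracle: Pearson chi-square without continuity correction
  set.seed(11)
  for (i in 1:50) {
    cts <- rpois(4, 30) + 1L
    got <- afChisq(cts[1], cts[2], cts[3], cts[4])
    ora <- suppressWarnings(
      chisq.test(matrix(cts, 2, 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$chi2, unname(ora$statistic), tolerance = 1e-9)
    expect_equal(got$pvalue, ora$p.value, tolerance = 1e-9)
  }
  # symmetric under group swap and ref/alt relabeling
  a <- afChisq(30, 12, 18, 40)
  expect_equal(afChisq(18, 40, 30, 12)$chi2, a$chi2)
  expect_equal(afChisq(12, 30, 40, 18)$chi2, a$chi2)
  # zero margin carries no information
  zm <- afChisq(10, 0, 20, 0)
  expect_equal(zm$chi2, 0)
  expect_equal(zm$pvalue, 1)
})

test_that("the screening pipeline ranks dual-pass genes first", {
  genes <- toyGenes()
  expr <- rbind(
    geneA = c(ASG = 50, MSG = 5, PSG = 5, FB = 10, MG = 10),  # pass
    geneB = c(ASG = 1, MSG = 1, PSG = 1, FB = 50, MG = 50),   # fail
    geneC = c(ASG = 30, MSG = 30, PSG = 30, FB = 5, MG = 5))  # pass
  segs <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(1500, 59000), c(26000, 66000)))
  variants <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1500, 25000, 65000), width = 1),
    ref_1 = c(90L, 50L, 88L), alt_1 = c(10L, 50L, 12L),
    ref_2 = c(10L, 50L, 90L), alt_2 = c(90L, 50L, 10L))
  report <- screenPipeline(segs, genes, expr, variants,
                        silkTissues = c("ASG", "MSG", "PSG"))
  # geneA: silk pass + significant exonic variant -> first
  expect_equal(report$gene_id[1], "geneA")
  expect_true(report$silk_pass[1] && report$n_significant[1] >= 1)
  # geneC passes expression but its variant is non-divergent: after geneA
  rowC <- report[report$gene_id == "geneC", ]
  expect_true(rowC$silk_pass && rowC$n_significant == 0)
  expect_gt(which(report$gene_id == "geneC"), which(report$gene_id == "geneA"))
  # geneB fails expression: ranked last
  expect_equal(report$gene_id[nrow(report)], "geneB")
  # empty segment list -> empty report
  expect_equal(nrow(screenPipeline(GenomicRanges::GRanges(), genes, expr,
                                   variants,
                                   silkTissues = c("ASG", "MSG", "PSG"))),
               0)
})

test_that("assignment is independent of gene input order", {
  genes <- toyGenes()
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 80000))
  v <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1500, 25000, 65000), width = 1))
  a1 <- assignGenes(seg, genes, v)
  a2 <- assignGenes(seg, rev(genes), v)
  expect_equal(a1, a2)
})
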