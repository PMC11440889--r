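# Fixture builders shared across test files. Everything is generated in
# code; no binary or stored data.

toyAdt <- function(df = NULL) {
  if (is.null(df))
    df <- data.frame(
      chrom = "chr1", pos = c(1e5, 2e5, 3e5, 4e5, 5e5),
      ref_H = c(90, 95, 100, 15, 120), alt_H = c(30, 35, 30, 5, 40),
      ref_L = c(85, 90, 95, 80, 110), alt_L = c(35, 30, 35, 30, 35),
      gq_H = 99L, gq_L = 99L)
  AlleleDepthTable(df)
}

smallDesign <- function(...) {
  BulkDesign(nPopulation = 400L, bulkSize = 40L, depthPerBulk = 120, ...)
}

## direct (loop-based) re-implementation of the filter rules in declared
## order, used as an independent oracle for attribution
filterOracle <- function(d, spec) {
  firstRule <- rep(NA_character_, nrow(d))
  for (i in seq_len(nrow(d))) {
    dH <- d$ref_H[i] + d$alt_H[i]; dL <- d$ref_L[i] + d$alt_L[i]
    tot <- dH + dL
    raf <- if (tot > 0) (d$ref_H[i] + d$ref_L[i]) / tot else NA
    rules <- c(
      ref_allele_freq = is.na(raf) || raf < spec@refAlleleFreqBound ||
        raf > 1 - spec@refAlleleFreqBound,
      min_total_depth = tot < spec@minTotalDepth,
      max_total_depth = tot > spec@maxTotalDepth,
      depth_difference = abs(dH - dL) > spec@maxDepthDifference,
      min_sample_depth = dH < spec@minSampleDepth || dL < spec@minSampleDepth,
      min_gq = d$gq_H[i] < spec@minGQ || d$gq_L[i] < spec@minGQ)
    if (any(rules)) firstRule[i] <- names(rules)[which(rules)[1]]
  }
  firstRule
}

## a tiny plain-text VCF with two bulk samples, two multiallelic records
## and one indel among 10 records
writeFixtureVcf <- function(path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "HIGH", "LOW", sep = "\t"))
  rec <- function(pos, ref, alt, adH, adL)
    paste("chr1", pos, ".", ref, alt, ".", "PASS", ".", "AD:GQ",
          paste0(adH, ":99"), paste0(adL, ":99"), sep = "\t")
  body <- c(
    rec(100, "A", "T", "30,10", "20,20"),
    rec(200, "C", "G,T", "10,5,5", "10,5,5"),     # multiallelic: skipped
    rec(300, "G", "A", "50,0", "40,10"),
    rec(400, "T", "C", "25,25", "30,20"),
    rec(500, "A", "AT", "30,10", "30,10"),        # indel: skipped
    rec(600, "C", "T", "60,20", "55,25"),
    rec(700, "G", "C", "45,15", "40,20"),
    rec(800, "A", "G", "70,10", "65,15"),
    rec(900, "T", "A", "35,5", "30,10"),
    rec(1000, "C", "A,G", "20,10,10", "20,10,10") # multiallelic: skipped
  )
  writeLines(c(hdr, body), path)
  path
}

toyGenes <- function() {
  GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(1000, 20000, 60000),
                     end = c(5000, 30000, 70000)),
    strand = c("+", "-", "+"),
    gene_id = c("geneA", "geneB", "geneC"))
}

panelFromFreq <- function(p, n, pos = NULL, population = "pop",
                          seqLength = NULL) {
  if (is.null(pos)) pos <- seq_along(p) * 100L
  a <- matrix(rbinom(length(p) * n, 1L, rep(p, n)), length(p), n)
  HaplotypeMatrix(population, pos, a,
                  seqLengths = if (is.null(seqLength)) NULL
                               else c(chr1 = seqLength))
}
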