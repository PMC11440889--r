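#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom stats rnorm rbinom rnbinom rpois rbeta p.adjust
#'   plnorm pchisq approx setNames
#' @importFrom utils write.table read.table packageVersion
#' @importFrom graphics par plot lines
#' @importFrom SummarizedExperiment rowRanges
NULL

# ---------------------------------------------------------------------------
# BulkDesign
# ---------------------------------------------------------------------------

#' Experimental design of a bulk-segregant sequencing experiment
#'
#' A \code{BulkDesign} describes the cross and pooling design used both to
#' simulate bulk-segregant experiments and to parameterise the Monte-Carlo
#' null used for delta(SNP-index) confidence intervals: the cross type, the
#' number of phenotyped individuals, the fraction of each phenotypic extreme
#' that is bulked, the number of individuals actually pooled per bulk, and
#' the sequencing depth model for each bulk.
#'
#' @slot crossType \code{"BC1"} (first backcross; each locus homozygous
#'   recurrent or heterozygous with probability 1/2) or \code{"F2"}.
#' @slot nPopulation number of phenotyped individuals.
#' @slot tailFraction fraction of each phenotypic tail eligible for bulking
#'   (default 0.10).
#' @slot bulkSize number of individuals pooled per bulk.
#' @slot depthPerBulk mean total read depth per site in each bulk.
#' @slot depthModel \code{"nbinom"} (default) or \code{"poisson"}; per-site
#'   per-bulk total depth distribution.
#' @slot depthDispersion negative-binomial size parameter (ignored for
#'   \code{"poisson"}).
#' @slot cmPerMb recombination map density used to link markers along a
#'   chromosome (Haldane map function), in centimorgan per megabase.
#' @slot seqError symmetric per-read base-flip probability (default 0).
#' @slot seed integer RNG seed used by simulators when no explicit seed is
#'   passed (\code{NA} for none).
#' @export
setClass("BulkDesign",
  representation(
    crossType       = "character",
    nPopulation     = "integer",
    tailFraction    = "numeric",
    bulkSize        = "integer",
    depthPerBulk    = "numeric",
    depthModel      = "character",
    depthDispersion = "numeric",
    cmPerMb         = "numeric",
    seqError        = "numeric",
    seed            = "integer"
  )
)

setValidity("BulkDesign", function(object) {
  msg <- character()
  if (!object@crossType %in% c("BC1", "F2"))
    msg <- c(msg, "crossType must be 'BC1' or 'F2'")
  if (!(object@tailFraction > 0 && object@tailFraction <= 0.5))
    msg <- c(msg, "tailFraction must be in (0, 0.5]")
  if (object@bulkSize > ceiling(object@tailFraction * object@nPopulation))
    msg <- c(msg, "bulkSize exceeds the number of individuals in a phenotypic tail")
  if (object@depthPerBulk <= 0)
    msg <- c(msg, "depthPerBulk must be positive")
  if (!object@depthModel %in% c("nbinom", "poisson"))
    msg <- c(msg, "depthModel must be 'nbinom' or 'poisson'")
  if (object@seqError < 0 || object@seqError > 0.5)
    msg <- c(msg, "seqError must be in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Construct a BulkDesign
#'
#' @param crossType cross type, \code{"BC1"} or \code{"F2"}.
#' @param nPopulation number of phenotyped individuals.
#' @param tailFraction fraction of each phenotypic extreme bulked.
#' @param bulkSize individuals pooled per bulk; defaults to the full tail.
#' @param depthPerBulk mean sequencing depth per bulk.
#' @param depthModel per-site depth distribution, \code{"nbinom"} or
#'   \code{"poisson"}.
#' @param depthDispersion negative-binomial size parameter.
#' @param cmPerMb recombination density in cM/Mb (Haldane map).
#' @param seqError symmetric sequencing-error (base flip) probability.
#' @param seed default RNG seed for simulators (\code{NA} for none).
#' @return A \code{\linkS4class{BulkDesign}} object.
#' @examples
#' BulkDesign(nPopulation = 1600, bulkSize = 160, depthPerBulk = 160)
#' @export
BulkDesign <- function(crossType = "BC1", nPopulation = 1600L,
                       tailFraction = 0.10,
                       bulkSize = as.integer(floor(tailFraction * nPopulation)),
                       depthPerBulk = 160, depthModel = "nbinom",
                       depthDispersion = 50, cmPerMb = 3, seqError = 0,
                       seed = NA_integer_) {
  new("BulkDesign",
      crossType = crossType,
      nPopulation = as.integer(nPopulation),
      tailFraction = tailFraction,
      bulkSize = as.integer(bulkSize),
      depthPerBulk = depthPerBulk,
      depthModel = depthModel,
      depthDispersion = depthDispersion,
      cmPerMb = cmPerMb,
      seqError = seqError,
      seed = as.integer(seed))
}

setMethod("show", "BulkDesign", function(object) {
  cat("BulkDesign:", object@crossType, "cross\n")
  cat("  individuals scored :", object@nPopulation, "\n")
  cat("  tail fraction      :", object@tailFraction, "\n")
  cat("  bulk size          :", object@bulkSize, "per bulk\n")
  cat("  depth per bulk     :", object@depthPerBulk, "x (", object@depthModel,
      if (object@depthModel == "nbinom")
        paste0(", size=", object@depthDispersion) else "", ")\n", sep = "")
  cat("  recombination      :", object@cmPerMb, "cM/Mb (Haldane)\n")
})

# ---------------------------------------------------------------------------
# AlleleDepthTable
# ---------------------------------------------------------------------------

#' Per-SNP allele depths for two phenotypic bulks
#'
#' Container for a sorted table of biallelic sites with reference and
#' alternate read depths in the high and low phenotypic bulk, optional
#' genotype qualities, and (once computed) derived per-SNP statistics:
#' \code{snp_index_H}, \code{snp_index_L}, \code{delta_snp_index},
#' \code{delta_smooth}, \code{G}, \code{Gprime}, \code{pvalue},
#' \code{qvalue}.
#'
#' @slot data \code{data.frame} with at least \code{chrom}, \code{pos},
#'   \code{ref_H}, \code{alt_H}, \code{ref_L}, \code{alt_L}; sorted by
#'   (chrom, pos); all depths non-negative.
#' @slot removed named integer vector logging how many sites each filtering
#'   or cleaning rule removed (empty until filtering has run).
#' @export
setClass("AlleleDepthTable",
  representation(data = "data.frame", removed = "integer"))

.adt_required <- c("chrom", "pos", "ref_H", "alt_H", "ref_L", "alt_L")

setValidity("AlleleDepthTable", function(object) {
  d <- object@data
  msg <- character()
  miss <- setdiff(.adt_required, names(d))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  depth_cols <- c("ref_H", "alt_H", "ref_L", "alt_L")
  if (nrow(d)) {
    if (any(vapply(d[depth_cols], function(x) any(x < 0, na.rm = TRUE), logical(1))))
      msg <- c(msg, "read depths must be non-negative")
    o <- order(d$chrom, d$pos)
    if (!identical(o, seq_len(nrow(d))))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
    idx_cols <- intersect(c("snp_index_H", "snp_index_L"), names(d))
    for (cc in idx_cols)
      if (any(d[[cc]] < 0 | d[[cc]] > 1, na.rm = TRUE))
        msg <- c(msg, paste(cc, "must lie in [0, 1]"))
    if ("delta_snp_index" %in% names(d) &&
        any(abs(d$delta_snp_index) > 1, na.rm = TRUE))
      msg <- c(msg, "delta_snp_index must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleDepthTable
#'
#' @param data \code{data.frame} of sites; see
#'   \code{\linkS4class{AlleleDepthTable}} for required columns. Rows are
#'   sorted by (chrom, pos) on construction.
#' @return An \code{AlleleDepthTable}.
#' @export
AlleleDepthTable <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data)) {
    data <- data[order(data$chrom, data$pos), , drop = FALSE]
    rownames(data) <- NULL
  }
  new("AlleleDepthTable", data = data, removed = integer())
}

#' @describeIn AlleleDepthTable number of sites in the table.
#' @param x,object an \code{AlleleDepthTable}.
#' @export
nSites <- function(x) nrow(x@data)

#' Extract the site table of an AlleleDepthTable
#'
#' @param x an \code{AlleleDepthTable}.
#' @return The underlying \code{data.frame} of sites and statistics.
#' @export
adData <- function(x) x@data

#' Per-rule removal log of an AlleleDepthTable
#'
#' @param x an \code{AlleleDepthTable} returned by \code{\link{filterSites}}
#'   or \code{\link{computeBulkStats}}.
#' @return Named integer vector of sites removed per rule.
#' @export
removedCounts <- function(x) x@removed

setMethod("show", "AlleleDepthTable", function(object) {
  d <- object@data
  cat("AlleleDepthTable with", nrow(d), "sites on",
      length(unique(d$chrom)), "chromosome(s)\n")
  stat_cols <- intersect(
    c("snp_index_H", "snp_index_L", "delta_snp_index", "delta_smooth",
      "G", "Gprime", "pvalue", "qvalue"), names(d))
  if (length(stat_cols))
    cat("  statistics:", paste(stat_cols, collapse = ", "), "\n")
  if (length(object@removed))
    cat("  removed:", paste(names(object@removed), object@removed,
                            sep = "=", collapse = ", "), "\n")
  if (nrow(d)) {
    cat("  head:\n")
    print(head(d, 3))
  }
})

setMethod("as.data.frame", "AlleleDepthTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

#' @export
setMethod("[", "AlleleDepthTable", function(x, i, j, ..., drop = TRUE) {
  initialize(x, data = {
    d <- x@data[i, , drop = FALSE]; rownames(d) <- NULL; d
  })
})

# ---------------------------------------------------------------------------
# FilterSpec
# ---------------------------------------------------------------------------

#' Site-filtering rules for bulk allele-depth tables
#'
#' Hard filters applied by \code{\link{filterSites}}, mirroring the standard
#' depth/quality filtering of pooled bulk-segregant variant tables. Rules are
#' applied in a fixed declared order (pooled reference-allele frequency,
#' minimum total depth, maximum total depth, bulk depth difference, minimum
#' per-bulk depth, minimum genotype quality, then variant-call hard filters
#' when those annotation columns exist) and each removed site is attributed
#' to the first rule it fails.
#'
#' @slot refAlleleFreqBound pooled reference-allele frequency must lie in
#'   \code{[bound, 1 - bound]}.
#' @slot minTotalDepth,maxTotalDepth bounds on combined depth of both bulks.
#' @slot maxDepthDifference maximum |depth_H - depth_L| per site.
#' @slot minSampleDepth minimum total depth in each bulk separately.
#' @slot minGQ minimum genotype quality in both bulks (applied when
#'   \code{gq_H}/\code{gq_L} columns are present).
#' @slot hardFilters named numeric vector of variant-call annotation cutoffs
#'   (\code{QUAL}, \code{QD}, \code{MQ}, \code{MQRankSum},
#'   \code{ReadPosRankSum} are minima; \code{FS}, \code{SOR} are maxima),
#'   applied only for columns present in the table.
#' @export
setClass("FilterSpec",
  representation(
    refAlleleFreqBound = "numeric",
    minTotalDepth      = "numeric",
    maxTotalDepth      = "numeric",
    maxDepthDifference = "numeric",
    minSampleDepth     = "numeric",
    minGQ              = "numeric",
    hardFilters        = "numeric"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (!(object@refAlleleFreqBound > 0 && object@refAlleleFreqBound < 0.5))
    msg <- c(msg, "refAlleleFreqBound must be in (0, 0.5)")
  if (object@minTotalDepth > object@maxTotalDepth)
    msg <- c(msg, "minTotalDepth must not exceed maxTotalDepth")
  if (length(msg)) msg else TRUE
})

#' Construct a FilterSpec
#'
#' Defaults follow common pooled-BSA practice: pooled reference-allele
#' frequency within [0.10, 0.90], combined depth in [100, 500], bulk depth
#' difference at most 100, at least 40 reads per bulk, and genotype quality
#' at least 99 in both bulks.
#'
#' @param refAlleleFreqBound,minTotalDepth,maxTotalDepth,maxDepthDifference,minSampleDepth,minGQ
#'   see \code{\linkS4class{FilterSpec}}.
#' @param hardFilters named numeric vector of variant-call annotation
#'   cutoffs; defaults to the conventional short-variant hard filters
#'   (QUAL >= 30, QD >= 2, MQ >= 40, MQRankSum >= -12.5,
#'   ReadPosRankSum >= -8, FS <= 60, SOR <= 3).
#' @return A \code{FilterSpec}.
#' @export
FilterSpec <- function(refAlleleFreqBound = 0.10, minTotalDepth = 100,
                       maxTotalDepth = 500, maxDepthDifference = 100,
                       minSampleDepth = 40, minGQ = 99,
                       hardFilters = c(QUAL = 30, QD = 2, MQ = 40,
                                       MQRankSum = -12.5,
                                       ReadPosRankSum = -8,
                                       FS = 60, SOR = 3)) {
  new("FilterSpec",
      refAlleleFreqBound = refAlleleFreqBound,
      minTotalDepth = minTotalDepth, maxTotalDepth = maxTotalDepth,
      maxDepthDifference = maxDepthDifference,
      minSampleDepth = minSampleDepth, minGQ = minGQ,
      hardFilters = hardFilters)
}

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec:\n")
  cat("  pooled ref allele frequency in [",
      object@refAlleleFreqBound, ", ", 1 - object@refAlleleFreqBound, "]\n",
      sep = "")
  cat("  total depth in [", object@minTotalDepth, ", ",
      object@maxTotalDepth, "], |depth_H - depth_L| <= ",
      object@maxDepthDifference, "\n", sep = "")
  cat("  per-bulk depth >=", object@minSampleDepth,
      ", GQ >=", object@minGQ, "\n")
  if (length(object@hardFilters))
    cat("  variant-call hard filters:",
        paste(names(object@hardFilters), object@hardFilters,
              sep = "=", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# CiTable
# ---------------------------------------------------------------------------

#' Simulated delta(SNP-index) confidence-interval table
#'
#' Two-sided null thresholds on |delta(SNP-index)| as a function of per-bulk
#' read depth, obtained by Monte-Carlo simulation of bulk composition and
#' read sampling under the cross design (see \code{\link{simulateCI}}).
#'
#' @slot depths per-bulk total depth grid.
#' @slot ci95,ci99 the 95th / 99th percentile of |delta(SNP-index)| under
#'   the null at each grid depth.
#' @slot reps Monte-Carlo replicates per depth.
#' @slot design the \code{\linkS4class{BulkDesign}} simulated under.
#' @export
setClass("CiTable",
  representation(depths = "numeric", ci95 = "numeric", ci99 = "numeric",
                 reps = "integer", design = "BulkDesign"))

setValidity("CiTable", function(object) {
  msg <- character()
  if (length(object@depths) != length(object@ci95) ||
      length(object@depths) != length(object@ci99))
    msg <- c(msg, "depths, ci95 and ci99 must have equal length")
  if (any(object@depths <= 0))
    msg <- c(msg, "depths must be positive")
  if (any(object@ci95 < 0 | object@ci95 > 1) ||
      any(object@ci99 < 0 | object@ci99 > 1))
    msg <- c(msg, "confidence bounds must lie in [0, 1]")
  if (any(object@ci99 < object@ci95))
    msg <- c(msg, "ci99 must be >= ci95 at every depth")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CiTable", function(object) {
  cat("CiTable (", object@reps, " replicates, ", object@design@crossType,
      " design, bulk size ", object@design@bulkSize, ")\n", sep = "")
  print(data.frame(depth = object@depths, CI_95 = object@ci95,
                   CI_99 = object@ci99))
})

#' @describeIn CiTable the CI table as a data.frame.
#' @param x a \code{CiTable}.
#' @export
ciTable <- function(x) data.frame(depth = x@depths, CI_95 = x@ci95,
                                  CI_99 = x@ci99)

# ---------------------------------------------------------------------------
# HaplotypeMatrix
# ---------------------------------------------------------------------------

#' Biallelic haplotype panel for one population
#'
#' Alleles (0 = reference, 1 = alternate, \code{NA} = missing) at sorted
#' sites for a set of haplotypes sampled from one population. Diploid
#' genotype calls contribute one allele per haplotype column (phase is
#' irrelevant for frequency-based statistics).
#'
#' @slot population population label.
#' @slot chrom chromosome of each site.
#' @slot positions 1-based bp position of each site, strictly increasing
#'   within a chromosome.
#' @slot alleles integer matrix, sites x haplotypes, entries 0/1/NA.
#' @slot seqLengths named numeric vector of chromosome lengths (used to lay
#'   out window grids); defaults to the maximum observed position.
#' @export
setClass("HaplotypeMatrix",
  representation(population = "character", chrom = "character",
                 positions = "integer", alleles = "matrix",
                 seqLengths = "numeric"))

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  if (length(object@positions) != nrow(object@alleles) ||
      length(object@chrom) != nrow(object@alleles))
    msg <- c(msg, "positions/chrom length must equal nrow(alleles)")
  sp <- split(object@positions, object@chrom)
  if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1))))
    msg <- c(msg, "positions must be strictly increasing within chromosome")
  a <- object@alleles
  if (length(a) && !all(a %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "alleles must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeMatrix
#'
#' @param population population label.
#' @param positions site positions (1-based bp).
#' @param alleles sites x haplotypes matrix of 0/1/NA.
#' @param chrom chromosome per site (recycled if scalar).
#' @param seqLengths named chromosome lengths; defaults to max position per
#'   chromosome.
#' @return A \code{HaplotypeMatrix}.
#' @export
HaplotypeMatrix <- function(population, positions, alleles, chrom = "chr1",
                            seqLengths = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  chrom <- rep_len(as.character(chrom), length(positions))
  o <- order(chrom, positions)
  positions <- positions[o]; chrom <- chrom[o]
  alleles <- alleles[o, , drop = FALSE]
  if (is.null(seqLengths)) {
    seqLengths <- vapply(split(positions, chrom), max, numeric(1))
  }
  new("HaplotypeMatrix", population = population, chrom = chrom,
      positions = positions, alleles = alleles,
      seqLengths = seqLengths)
}

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix '", object@population, "': ",
      nrow(object@alleles), " sites x ", ncol(object@alleles),
      " haplotypes on ", length(unique(object@chrom)),
      " chromosome(s)\n", sep = "")
  mf <- mean(is.na(object@alleles))
  cat("  missing fraction:", signif(mf, 3), "\n")
})

#' Number of haplotypes in a panel
#' @param x a \code{HaplotypeMatrix}.
#' @export
nHaplotypes <- function(x) ncol(x@alleles)

#' Site positions of a haplotype panel
#' @param x a \code{HaplotypeMatrix}.
#' @export
sitePositions <- function(x) x@positions

#' Allele matrix of a haplotype panel
#' @param x a \code{HaplotypeMatrix}.
#' @export
alleleMatrix <- function(x) x@alleles
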