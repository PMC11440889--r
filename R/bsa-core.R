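# Per-SNP bulk statistics, tricube smoothing, Monte-Carlo confidence
# intervals for delta(SNP-index), G' p-values and QTL region calling.

#' Pooled reference-allele frequency across both bulks
#'
#' \deqn{(ref_H + ref_L) / (ref_H + alt_H + ref_L + alt_L)}
#' In a BC1 experiment (recurrent-parent backcross) this is expected to be
#' enriched to 0.75 genome-wide, a standard sanity check on bulk data.
#'
#' @param refH,altH,refL,altL read depths per bulk (vectorised).
#' @return Pooled reference-allele frequency in [0, 1].
#' @examples
#' refAlleleFrequency(75, 25, 75, 25)  # 0.75
#' @export
refAlleleFrequency <- function(refH, altH, refL, altL) {
  total <- refH + altH + refL + altL
  if (any(total == 0))
    stop("reference-allele frequency undefined: zero total read depth")
  (refH + refL) / total
}

#' SNP-index of one bulk
#'
#' The fraction of reads carrying the alternate allele:
#' \code{alt / (ref + alt)}.
#'
#' @param ref,alt read depths (vectorised).
#' @return SNP-index in [0, 1].
#' @examples
#' snpIndex(30, 10)  # 0.25
#' @export
snpIndex <- function(ref, alt) {
  total <- ref + alt
  if (any(total == 0))
    stop("SNP-index undefined: zero read depth")
  alt / total
}

#' delta(SNP-index): high-bulk minus low-bulk SNP-index
#'
#' @param indexH,indexL per-bulk SNP-index values in [0, 1].
#' @return Difference in [-1, 1]; near 0 at unlinked loci, large in
#'   magnitude near a QTL.
#' @examples
#' deltaSnpIndex(0.5, 0.0)  # 0.5, the BC1 fully penetrant ceiling
#' @export
deltaSnpIndex <- function(indexH, indexL) {
  stopifnot(all(indexH >= 0 & indexH <= 1), all(indexL >= 0 & indexL <= 1))
  indexH - indexL
}

#' G statistic of the 2x2 bulk-by-allele read-count table
#'
#' The log-likelihood-ratio statistic
#' \deqn{G = 2 \sum_i n_i \ln(obs(n_i)/exp(n_i))}
#' with expected counts from the table margins (rows: reference/alternate
#' allele; columns: high/low bulk) and the convention
#' \eqn{0 \cdot \ln(0/e) = 0}. A zero margin gives a degenerate table and
#' returns 0.
#'
#' @param n1,n2,n3,n4 read counts: reference allele in the high and low
#'   bulk, then alternate allele in the high and low bulk (vectorised).
#' @return Non-negative G values.
#' @examples
#' gStatistic(30, 10, 10, 30)  # 20.93
#' gStatistic(20, 0, 0, 20)    # 80 * log(2)
#' @export
gStatistic <- function(n1, n2, n3, n4) {
  stopifnot(all(n1 >= 0), all(n2 >= 0), all(n3 >= 0), all(n4 >= 0))
  N <- n1 + n2 + n3 + n4
  e1 <- (n1 + n2) * (n1 + n3) / N
  e2 <- (n1 + n2) * (n2 + n4) / N
  e3 <- (n3 + n4) * (n1 + n3) / N
  e4 <- (n3 + n4) * (n2 + n4) / N
  term <- function(n, e) ifelse(n > 0 & e > 0, n * log(n / e), 0)
  g <- 2 * (term(n1, e1) + term(n2, e2) + term(n3, e3) + term(n4, e4))
  degenerate <- (n1 + n2) == 0 | (n3 + n4) == 0 |
                (n1 + n3) == 0 | (n2 + n4) == 0 | N == 0
  g[degenerate] <- 0
  pmax(g, 0)
}

#' Tricube kernel smoothing over a physical window
#'
#' At each focal SNP the smoothed value is the weighted mean of values at
#' SNPs within +/- \code{windowBp/2}, with tricube weights
#' \eqn{(1 - (|d|/D)^3)^3}, \eqn{D = windowBp/2}, normalised to sum to 1.
#' An isolated SNP keeps its own value. Positions must belong to a single
#' chromosome and be sorted.
#'
#' @param positions sorted bp positions of one chromosome.
#' @param values statistic values at those positions.
#' @param windowBp full window width in bp (default 1e6).
#' @return Smoothed values, same length as input.
#' @examples
#' tricubeSmooth(c(1, 2, 3) * 1e5, c(0, 1, 0), windowBp = 1e6)
#' @export
tricubeSmooth <- function(positions, values, windowBp = 1e6) {
  stopifnot(windowBp > 0, length(positions) == length(values))
  n <- length(positions)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(positions)) stop("positions must be sorted")
  D <- windowBp / 2
  lo <- findInterval(positions - D, positions, left.open = TRUE) + 1L
  hi <- findInterval(positions + D, positions)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    d <- abs(positions[j] - positions[i])
    w <- (1 - (d / D)^3)^3
    keep <- !is.na(values[j]) & w > 0
    if (!any(keep)) { out[i] <- NA_real_; next }
    w <- w[keep]
    out[i] <- sum(w * values[j][keep]) / sum(w)
  }
  out
}

.smoothByChrom <- function(chrom, pos, values, windowBp, method = "tricube") {
  out <- numeric(length(values))
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    out[j] <- if (method == "tricube")
      tricubeSmooth(pos[j], values[j], windowBp)
    else {
      # plain sliding-window mean over the same +/- windowBp/2 neighbourhood
      D <- windowBp / 2
      lo <- findInterval(pos[j] - D, pos[j], left.open = TRUE) + 1L
      hi <- findInterval(pos[j] + D, pos[j])
      vapply(seq_along(j), function(i)
        mean(values[j][lo[i]:hi[i]], na.rm = TRUE), numeric(1))
    }
  }
  out
}

#' Compute per-SNP bulk statistics and window-smoothed tracks
#'
#' Drops sites with zero read depth in either bulk (logged under rule
#' \code{"zero_depth"}), then adds the per-SNP columns \code{snp_index_H},
#' \code{snp_index_L}, \code{delta_snp_index}, \code{G}, and the smoothed
#' tracks \code{delta_smooth} and \code{Gprime} obtained by applying the
#' same kernel per chromosome over a physical window.
#'
#' @param x an \code{\linkS4class{AlleleDepthTable}}.
#' @param windowBp smoothing window width in bp (default 1e6).
#' @param smoothMethod \code{"tricube"} (default) or \code{"mean"}.
#' @return The table with derived columns added.
#' @export
computeBulkStats <- function(x, windowBp = 1e6,
                             smoothMethod = c("tricube", "mean")) {
  stopifnot(is(x, "AlleleDepthTable"))
  smoothMethod <- match.arg(smoothMethod)
  d <- x@data
  degenerate <- (d$ref_H + d$alt_H) == 0 | (d$ref_L + d$alt_L) == 0
  if (any(degenerate)) {
    message("dropping ", sum(degenerate),
            " site(s) with zero depth in a bulk")
    d <- d[!degenerate, , drop = FALSE]
    rownames(d) <- NULL
  }
  d$snp_index_H <- snpIndex(d$ref_H, d$alt_H)
  d$snp_index_L <- snpIndex(d$ref_L, d$alt_L)
  d$delta_snp_index <- deltaSnpIndex(d$snp_index_H, d$snp_index_L)
  d$G <- gStatistic(d$ref_H, d$ref_L, d$alt_H, d$alt_L)
  d$delta_smooth <- .smoothByChrom(d$chrom, d$pos, d$delta_snp_index,
                                   windowBp, smoothMethod)
  d$Gprime <- .smoothByChrom(d$chrom, d$pos, d$G, windowBp, smoothMethod)
  removed <- x@removed
  if (any(degenerate))
    removed["zero_depth"] <- sum(degenerate) +
      if ("zero_depth" %in% names(removed)) removed[["zero_depth"]] else 0L
  new("AlleleDepthTable", data = d, removed = removed)
}

#' Filter sites of an allele-depth table by depth and quality rules
#'
#' Applies the rules of a \code{\linkS4class{FilterSpec}} in declared order
#' (pooled reference-allele frequency bound, minimum/maximum combined
#' depth, bulk depth difference, per-bulk minimum depth, genotype quality,
#' then variant-call hard filters for annotation columns present in the
#' table). Each removed site is attributed to the first rule it fails; the
#' per-rule counts are available via \code{\link{removedCounts}}.
#'
#' @param x an \code{\linkS4class{AlleleDepthTable}}.
#' @param spec a \code{\linkS4class{FilterSpec}}.
#' @return The filtered table (order preserved) with the removal log set.
#' @export
filterSites <- function(x, spec = FilterSpec()) {
  stopifnot(is(x, "AlleleDepthTable"), is(spec, "FilterSpec"))
  d <- x@data
  n <- nrow(d)
  dH <- d$ref_H + d$alt_H
  dL <- d$ref_L + d$alt_L
  total <- dH + dL
  raf <- ifelse(total > 0, (d$ref_H + d$ref_L) / total, NA_real_)

  fails <- list(
    ref_allele_freq = is.na(raf) | raf < spec@refAlleleFreqBound |
                      raf > 1 - spec@refAlleleFreqBound,
    min_total_depth = total < spec@minTotalDepth,
    max_total_depth = total > spec@maxTotalDepth,
    depth_difference = abs(dH - dL) > spec@maxDepthDifference,
    min_sample_depth = dH < spec@minSampleDepth | dL < spec@minSampleDepth
  )
  if (all(c("gq_H", "gq_L") %in% names(d)))
    fails$min_gq <- !is.na(d$gq_H) & !is.na(d$gq_L) &
                    (d$gq_H < spec@minGQ | d$gq_L < spec@minGQ)
  hf <- spec@hardFilters
  minima <- c("QUAL", "QD", "MQ", "MQRankSum", "ReadPosRankSum")
  for (nm in names(hf)) {
    if (!nm %in% names(d)) next
    bad <- if (nm %in% minima) d[[nm]] < hf[[nm]] else d[[nm]] > hf[[nm]]
    fails[[paste0("hard_", nm)]] <- !is.na(bad) & bad
  }

  attributed <- rep(NA_character_, n)
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(attributed)
    attributed[hit] <- rule
  }
  removed <- table(factor(attributed, levels = names(fails)))
  removed <- stats::setNames(as.integer(removed), names(fails))
  keep <- is.na(attributed)
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("AlleleDepthTable", data = out, removed = removed[removed > 0])
}

# ---------------------------------------------------------------------------
# Monte-Carlo confidence intervals
# ---------------------------------------------------------------------------

.bulkFreqNull <- function(design, n) {
  m <- design@bulkSize
  switch(design@crossType,
    BC1 = rbinom(n, m, 0.5) / (2 * m),       # each individual hom-ref or het
    F2  = rbinom(n, 2L * m, 0.5) / (2 * m))  # alleles drawn independently
}

#' Independent null draws of delta(SNP-index) at a fixed per-bulk depth
#'
#' Simulates, for each draw, the composition of both bulks under the cross
#' design (BC1: \code{bulkSize} individuals each homozygous-reference or
#' heterozygous with probability 1/2), the resulting true bulk allele
#' frequencies, binomial read sampling at the given per-bulk depth, and the
#' resulting delta(SNP-index). This is the null distribution used to build
#' confidence-interval thresholds.
#'
#' @param design a \code{\linkS4class{BulkDesign}}.
#' @param depth total read depth per bulk for every draw.
#' @param n number of draws.
#' @return Numeric vector of \code{n} simulated delta(SNP-index) values.
#' @export
simulateNullDelta <- function(design, depth, n) {
  stopifnot(is(design, "BulkDesign"), n >= 1)
  if (depth <= 0) stop("depth must be positive")
  fH <- .bulkFreqNull(design, n)
  fL <- .bulkFreqNull(design, n)
  iH <- rbinom(n, depth, fH) / depth
  iL <- rbinom(n, depth, fL) / depth
  iH - iL
}

#' Simulate delta(SNP-index) confidence intervals over a depth grid
#'
#' For each depth on the grid, draws \code{reps} independent null
#' delta(SNP-index) values (\code{\link{simulateNullDelta}}) and records the
#' two-sided thresholds as the 95th and 99th percentiles of the absolute
#' simulated values. Thresholds at a SNP's observed depth are obtained by
#' linear interpolation with \code{\link{interpolateCI}}.
#'
#' @param design a \code{\linkS4class{BulkDesign}}.
#' @param depths per-bulk total depth grid (positive).
#' @param reps replicates per depth (default 10000, minimum 100).
#' @param levels percentile levels (fixed slots for 0.95 and 0.99).
#' @param seed optional integer seed.
#' @return A \code{\linkS4class{CiTable}}.
#' @examples
#' des <- BulkDesign(nPopulation = 400, bulkSize = 40, depthPerBulk = 100)
#' simulateCI(des, depths = c(50, 100, 200), reps = 500, seed = 1)
#' @export
simulateCI <- function(design, depths, reps = 10000L,
                       levels = c(0.95, 0.99), seed = NULL) {
  stopifnot(is(design, "BulkDesign"))
  if (reps < 100) stop("reps must be at least 100")
  if (any(depths <= 0)) stop("depths must be positive")
  if (!is.null(seed)) set.seed(seed)
  depths <- sort(unique(depths))
  ci <- vapply(depths, function(dp) {
    delta <- simulateNullDelta(design, dp, reps)
    quantile(abs(delta), levels, names = FALSE, type = 7)
  }, numeric(2))
  new("CiTable", depths = as.numeric(depths), ci95 = ci[1L, ],
      ci99 = ci[2L, ], reps = as.integer(reps), design = design)
}

#' Interpolate confidence-interval thresholds to observed depths
#'
#' Linear interpolation of the simulated threshold grid at each SNP's
#' per-bulk depth; constant extrapolation beyond the grid ends.
#'
#' @param ci a \code{\linkS4class{CiTable}}.
#' @param depth per-bulk depths to evaluate at (for a SNP with bulk depths
#'   dH and dL, use \code{(dH + dL) / 2}).
#' @param level 0.95 or 0.99.
#' @return Threshold values on |delta(SNP-index)|.
#' @export
interpolateCI <- function(ci, depth, level = 0.95) {
  stopifnot(is(ci, "CiTable"))
  bounds <- if (isTRUE(all.equal(level, 0.99))) ci@ci99
            else if (isTRUE(all.equal(level, 0.95))) ci@ci95
            else stop("level must be 0.95 or 0.99")
  if (length(ci@depths) == 1L) return(rep(bounds, length(depth)))
  approx(ci@depths, bounds, xout = depth, rule = 2)$y
}

# ---------------------------------------------------------------------------
# G' p-values
# ---------------------------------------------------------------------------

#' P-values and Benjamini-Hochberg q-values for smoothed G' statistics
#'
#' Estimates the null distribution of G' from the data themselves: sites
#' whose G' exceeds a Hampel outlier bound (median + 5.2 * MAD) are set
#' aside as putative QTL signal, a log-normal null is fitted to the
#' remainder by the method of moments on the log scale, and right-tail
#' p-values are taken from the fitted null. Q-values are genome-wide
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param gprime non-negative smoothed G' values (at least 50).
#' @return \code{data.frame} with columns \code{pvalue}, \code{qvalue},
#'   both in (0, 1].
#' @export
gprimePvalues <- function(gprime) {
  stopifnot(all(gprime >= 0, na.rm = TRUE))
  n <- length(gprime)
  if (n < 50) stop("fewer than 50 SNPs: G' null not estimable")
  bound <- median(gprime, na.rm = TRUE) + 5.2 * mad(gprime, na.rm = TRUE)
  null_set <- gprime[!is.na(gprime) & gprime <= bound & gprime > 0]
  lg <- log(null_set)
  meanlog <- mean(lg)
  sdlog <- sd(lg)
  if (!is.finite(sdlog) || sdlog < .Machine$double.eps^0.5) {
    p <- rep(1, n)  # no dispersion: nothing stands out of the fitted null
  } else {
    p <- plnorm(gprime, meanlog, sdlog, lower.tail = FALSE)
    p[is.na(gprime) | gprime <= 0] <- 1
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
  }
  data.frame(pvalue = p, qvalue = p.adjust(p, method = "BH"))
}

#' Add G' p-values and q-values to a statistics table
#'
#' @param x an \code{\linkS4class{AlleleDepthTable}} with a \code{Gprime}
#'   column (see \code{\link{computeBulkStats}}).
#' @return The table with \code{pvalue} and \code{qvalue} columns.
#' @export
addGprimePvalues <- function(x) {
  stopifnot(is(x, "AlleleDepthTable"), "Gprime" %in% names(x@data))
  pq <- gprimePvalues(x@data$Gprime)
  d <- x@data
  d$pvalue <- pq$pvalue
  d$qvalue <- pq$qvalue
  initialize(x, data = d)
}

# ---------------------------------------------------------------------------
# QTL region calling
# ---------------------------------------------------------------------------

.runsToRegions <- function(chrom, pos, sig, stat, method) {
  sig[is.na(sig)] <- FALSE
  regions <- list()
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    r <- rle(sig[j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- j[starts[k]:ends[k]]
      peak <- idx[which.max(abs(stat[idx]))]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = pos[idx[1L]], end = pos[idx[length(idx)]],
        peak = pos[peak], peakValue = stat[peak],
        nSnps = length(idx), method = method)
    }
  }
  if (!length(regions)) return(NULL)
  do.call(rbind, regions)
}

#' Call QTL regions from per-SNP statistics
#'
#' A QTL region is a maximal run of consecutive SNPs (within a chromosome)
#' that all exceed the chosen significance threshold: the smoothed
#' |delta(SNP-index)| above the depth-interpolated simulated CI_95/CI_99
#' threshold, or the G' q-value below \code{fdr}. Region start/end are the
#' first/last SNP of the run and the peak is the SNP with the largest
#' statistic.
#'
#' @param x an \code{\linkS4class{AlleleDepthTable}} with computed
#'   statistics (and \code{qvalue} for the FDR method).
#' @param ci a \code{\linkS4class{CiTable}} (required for the CI methods).
#' @param methods any of \code{"deltaIndex_CI95"}, \code{"deltaIndex_CI99"},
#'   \code{"Gprime_FDR"}.
#' @param fdr q-value threshold for the G' method (default 0.01).
#' @param useSmoothed apply CI thresholds to the smoothed delta track
#'   (default) rather than the raw per-SNP delta(SNP-index).
#' @return A \code{GRanges} of regions with metadata columns \code{peak},
#'   \code{peakValue}, \code{nSnps}, \code{method}; empty if nothing is
#'   significant.
#' @export
callQtlRegions <- function(x, ci = NULL,
                           methods = c("deltaIndex_CI95", "deltaIndex_CI99",
                                       "Gprime_FDR"),
                           fdr = 0.01, useSmoothed = TRUE) {
  stopifnot(is(x, "AlleleDepthTable"))
  methods <- match.arg(methods, several.ok = TRUE)
  d <- x@data
  res <- list()
  delta <- if (useSmoothed && "delta_smooth" %in% names(d))
    d$delta_smooth else d$delta_snp_index
  meanDepth <- (d$ref_H + d$alt_H + d$ref_L + d$alt_L) / 2
  for (m in methods) {
    if (m %in% c("deltaIndex_CI95", "deltaIndex_CI99")) {
      if (is.null(ci)) stop("CI methods require a CiTable ('ci')")
      level <- if (m == "deltaIndex_CI99") 0.99 else 0.95
      thr <- interpolateCI(ci, meanDepth, level)
      sig <- abs(delta) > thr
      res[[m]] <- .runsToRegions(d$chrom, d$pos, sig, delta, m)
    } else {
      if (!"qvalue" %in% names(d))
        stop("Gprime_FDR requires q-values; run addGprimePvalues() first")
      sig <- d$qvalue <= fdr
      res[[m]] <- .runsToRegions(d$chrom, d$pos, sig, d$Gprime, m)
    }
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res) || !nrow(res))
    return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = res$chrom,
    ranges = IRanges::IRanges(start = res$start, end = res$end),
    peak = res$peak, peakValue = res$peakValue,
    nSnps = res$nSnps, method = res$method)
  names(gr) <- NULL
  sort(gr, ignore.strand = TRUE)
}
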