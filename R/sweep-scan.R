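# Windowed nucleotide diversity, Hudson F_ST and reduction-of-diversity
# scans between population panels, with empirical quantile thresholds and
# merging of significant windows into sweep segments.

#' Remove sites with excessive missingness
#'
#' Sites with a missing-genotype fraction strictly greater than
#' \code{maxMissing} are removed (a site missing in exactly half the
#' haplotypes is kept).
#'
#' @param x a \code{\linkS4class{HaplotypeMatrix}}.
#' @param maxMissing maximum tolerated missing fraction (default 0.5).
#' @return The filtered \code{HaplotypeMatrix}.
#' @export
filterMissing <- function(x, maxMissing = 0.5) {
  stopifnot(is(x, "HaplotypeMatrix"))
  mf <- rowMeans(is.na(x@alleles))
  keep <- mf <= maxMissing
  new("HaplotypeMatrix", population = x@population,
      chrom = x@chrom[keep], positions = x@positions[keep],
      alleles = x@alleles[keep, , drop = FALSE],
      seqLengths = x@seqLengths)
}

#' Sliding window grid over chromosomes
#'
#' Windows of fixed width on a regular step grid anchored at position 1,
#' kept only while fully inside the chromosome; reported 1-based inclusive.
#'
#' @param seqLengths named numeric vector of chromosome lengths.
#' @param window window width in bp (default 5000).
#' @param step step between window starts in bp (default 500).
#' @return \code{data.frame} with \code{chrom}, \code{start}, \code{end}.
#' @examples
#' head(slidingWindowGrid(c(chr1 = 10000)))
#' @export
slidingWindowGrid <- function(seqLengths, window = 5000, step = 500) {
  stopifnot(window > 0, step > 0)
  res <- lapply(names(seqLengths), function(ch) {
    L <- seqLengths[[ch]]
    if (L < window) return(NULL)
    starts <- seq(1, L - window + 1, by = step)
    data.frame(chrom = ch, start = starts, end = starts + window - 1)
  })
  do.call(rbind, res)
}

## Per-site allele frequency summaries: observed allele count n and
## alternate frequency p, NA where fewer than 2 alleles observed.
.siteFreq <- function(x) {
  a <- x@alleles
  n <- rowSums(!is.na(a))
  p <- ifelse(n > 0, rowSums(a, na.rm = TRUE) / n, NA_real_)
  p[n < 2] <- NA_real_
  list(n = n, p = p)
}

.windowIndex <- function(chrom, pos, windows) {
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$start, windows$end))
  GenomicRanges::findOverlaps(sites, win, ignore.strand = TRUE)
}

.windowSum <- function(hits, values, nWindows) {
  v <- values[S4Vectors::queryHits(hits)]
  w <- S4Vectors::subjectHits(hits)
  keep <- !is.na(v)
  out <- numeric(nWindows)
  s <- rowsum(v[keep], w[keep])
  out[as.integer(rownames(s))] <- s
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Per window, the sum over usable sites (at least 2 observed alleles) of
#' the unbiased per-site heterozygosity \eqn{2p(1-p) \cdot n/(n-1)} divided
#' by the window length in bp. Windows with no usable site get \code{NA}.
#'
#' @param x a \code{\linkS4class{HaplotypeMatrix}}.
#' @param windows window grid (\code{data.frame} with \code{chrom},
#'   \code{start}, \code{end}), e.g. from \code{\link{slidingWindowGrid}}.
#' @return \code{data.frame}: \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps} (usable sites in window), \code{pi} (per bp).
#' @export
windowPi <- function(x, windows) {
  stopifnot(is(x, "HaplotypeMatrix"))
  f <- .siteFreq(x)
  usable <- !is.na(f$p)
  h <- ifelse(usable, 2 * f$p * (1 - f$p) * f$n / (f$n - 1), NA_real_)
  hits <- .windowIndex(x@chrom, x@positions, windows)
  nW <- nrow(windows)
  nsnp <- .windowSum(hits, as.numeric(usable), nW)
  hsum <- .windowSum(hits, h, nW)
  pi <- ifelse(nsnp > 0, hsum / (windows$end - windows$start + 1), NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = as.integer(nsnp), pi = pi)
}

.fstSiteTerms <- function(pA, nA, pB, nB, estimator) {
  if (estimator == "hudson") {
    num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
    den <- pA * (1 - pB) + pB * (1 - pA)
  } else {  # Weir-Cockerham (two populations, allele-count data)
    r <- 2
    nbar <- (nA + nB) / 2
    nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (nA + nB)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
    num <- (nbar / nc) * (s2 - inner / (nbar - 1))
    den <- num + (nbar / (nbar - 1)) * inner
  }
  list(num = num, den = den)
}

#' Windowed F_ST between two populations
#'
#' Ratio-of-averages estimator over the usable shared sites in each window
#' (both populations with at least 2 observed alleles). The default is the
#' Hudson estimator:
#' numerator \eqn{(p_A-p_B)^2 - p_A(1-p_A)/(n_A-1) - p_B(1-p_B)/(n_B-1)},
#' denominator \eqn{p_A(1-p_B) + p_B(1-p_A)}, summed over sites before the
#' ratio is taken. A Weir-Cockerham mode is provided for comparability.
#' Raw values are retained in \code{fst_raw}; \code{fst} is clipped to
#' [0, 1] for reporting.
#'
#' @param a,b \code{\linkS4class{HaplotypeMatrix}} objects sharing a site
#'   set (positions are matched by chrom/pos; unshared sites are ignored).
#' @param windows window grid \code{data.frame}.
#' @param estimator \code{"hudson"} (default) or \code{"wc"}.
#' @return \code{data.frame}: \code{chrom}, \code{start}, \code{end},
#'   \code{n_snps}, \code{fst}, \code{fst_raw}.
#' @export
windowFst <- function(a, b, windows, estimator = c("hudson", "wc")) {
  stopifnot(is(a, "HaplotypeMatrix"), is(b, "HaplotypeMatrix"))
  estimator <- match.arg(estimator)
  keyA <- paste(a@chrom, a@positions)
  keyB <- paste(b@chrom, b@positions)
  shared <- intersect(keyA, keyB)
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  fa <- .siteFreq(x = a); fb <- .siteFreq(x = b)
  pA <- fa$p[ia]; nA <- fa$n[ia]
  pB <- fb$p[ib]; nB <- fb$n[ib]
  ok <- !is.na(pA) & !is.na(pB)
  terms <- .fstSiteTerms(pA, nA, pB, nB, estimator)
  terms$num[!ok] <- NA_real_; terms$den[!ok] <- NA_real_
  hits <- .windowIndex(a@chrom[ia], a@positions[ia], windows)
  nW <- nrow(windows)
  nsnp <- .windowSum(hits, as.numeric(ok), nW)
  num <- .windowSum(hits, terms$num, nW)
  den <- .windowSum(hits, terms$den, nW)
  fst_raw <- ifelse(nsnp > 0 & den != 0, num / den, NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, n_snps = as.integer(nsnp),
             fst = pmin(pmax(fst_raw, 0), 1), fst_raw = fst_raw)
}

#' Reduction of diversity (ROD)
#'
#' \deqn{ROD = 1 - \pi_{derived} / \pi_{ancestral}}
#' Near 1 inside a selective sweep in the derived population; negative
#' values (derived more diverse) are reported as-is; missing when the
#' ancestral diversity is 0 or either input is missing.
#'
#' @param piAncestral,piDerived per-window diversity values (vectorised).
#' @return ROD values (\code{<= 1} where defined).
#' @examples
#' rod(0.002, 0.0005)  # 0.75
#' @export
rod <- function(piAncestral, piDerived) {
  stopifnot(all(piAncestral >= 0, na.rm = TRUE))
  ifelse(is.na(piAncestral) | is.na(piDerived) | piAncestral == 0,
         NA_real_, 1 - piDerived / piAncestral)
}

#' Harmonize window tracks onto a common supported grid
#'
#' Keeps only windows with at least \code{minSnps} usable sites in every
#' track, so that pi values of different populations correspond and ROD is
#' computed on jointly supported windows; drops the rest with a logged
#' count. This formalises the manual deletion/filling of sparse windows
#' that sweep scans otherwise require.
#'
#' @param tracks list of per-window \code{data.frame}s sharing a grid, each
#'   with an \code{n_snps} column (e.g. from \code{\link{windowPi}} /
#'   \code{\link{windowFst}}).
#' @param minSnps minimum usable sites per window per track (default 3).
#' @return The list of tracks restricted to the common supported windows,
#'   with attribute \code{"dropped"} (number of windows removed).
#' @export
harmonizeWindows <- function(tracks, minSnps = 3) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  nW <- unique(vapply(tracks, nrow, integer(1)))
  if (length(nW) != 1)
    stop("tracks must share one window grid")
  keep <- Reduce(`&`, lapply(tracks, function(t) t$n_snps >= minSnps))
  if (!any(keep)) stop("no window is supported in every track")
  dropped <- sum(!keep)
  if (dropped)
    message("harmonizeWindows: dropping ", dropped,
            " window(s) with < ", minSnps, " usable sites in some track")
  out <- lapply(tracks, function(t) {
    t <- t[keep, , drop = FALSE]; rownames(t) <- NULL; t
  })
  attr(out, "dropped") <- dropped
  out
}

#' Windowed sweep scan between an ancestral and a derived population
#'
#' Computes pi for both panels, F_ST between them, harmonizes the window
#' grid (\code{\link{harmonizeWindows}}), and derives ROD
#' \code{= 1 - pi_derived / pi_ancestral} on the supported windows.
#'
#' @param ancestral,derived \code{\linkS4class{HaplotypeMatrix}} panels.
#' @param window,step window width and step in bp (defaults 5000 / 500).
#' @param minSnps minimum usable sites per window in each panel.
#' @param estimator F_ST estimator passed to \code{\link{windowFst}}.
#' @param maxMissing per-site missingness filter applied to both panels.
#' @return \code{data.frame} per supported window: \code{chrom},
#'   \code{start}, \code{end}, \code{n_snps_anc}, \code{n_snps_der},
#'   \code{pi_anc}, \code{pi_der}, \code{fst}, \code{fst_raw}, \code{rod}.
#' @export
sweepScan <- function(ancestral, derived, window = 5000, step = 500,
                      minSnps = 3, estimator = "hudson", maxMissing = 0.5) {
  ancestral <- filterMissing(ancestral, maxMissing)
  derived <- filterMissing(derived, maxMissing)
  seqLengths <- pmax(ancestral@seqLengths,
                     derived@seqLengths[names(ancestral@seqLengths)])
  windows <- slidingWindowGrid(seqLengths, window, step)
  piA <- windowPi(ancestral, windows)
  piD <- windowPi(derived, windows)
  fst <- windowFst(ancestral, derived, windows, estimator)
  tr <- harmonizeWindows(list(anc = piA, der = piD, fst = fst), minSnps)
  data.frame(chrom = tr$anc$chrom, start = tr$anc$start, end = tr$anc$end,
             n_snps_anc = tr$anc$n_snps, n_snps_der = tr$der$n_snps,
             pi_anc = tr$anc$pi, pi_der = tr$der$pi,
             fst = tr$fst$fst, fst_raw = tr$fst$fst_raw,
             rod = rod(tr$anc$pi, tr$der$pi))
}

#' Call selective-sweep segments from windowed statistics
#'
#' Computes genome-wide empirical quantile cutoffs (type-7 quantiles) and
#' flags windows meeting all three criteria simultaneously. For the
#' domestication stage: F_ST in the top 1%, derived-population pi in the
#' bottom 5%, ROD in the top 5%; for the improvement (breeding) stage the
#' F_ST cutoff relaxes to the top 5%. Significant windows that are adjacent
#' or overlapping on the step grid (allowing up to \code{gap} intervening
#' non-significant steps) are merged into segments.
#'
#' @param windows per-window statistics from \code{\link{sweepScan}}.
#' @param stage \code{"domestication"} or \code{"improvement"}.
#' @param quantiles optional named list overriding the stage cutoff
#'   quantiles: \code{fst} (upper tail), \code{pi} (lower tail), \code{rod}
#'   (upper tail).
#' @param gap number of intervening non-significant step-windows tolerated
#'   inside one segment (default 0 = strict adjacency).
#' @return \code{GRanges} of merged segments with metadata \code{nWindows}
#'   and \code{stage}; the cutoff values used are in
#'   \code{metadata()$cutoffs}. Empty when no window passes.
#' @export
callSweeps <- function(windows, stage = c("domestication", "improvement"),
                       quantiles = NULL, gap = 0) {
  stage <- match.arg(stage)
  if (nrow(windows) < 100)
    stop("fewer than 100 windows: quantile cutoffs unstable")
  q <- switch(stage,
              domestication = list(fst = 0.99, pi = 0.05, rod = 0.95),
              improvement   = list(fst = 0.95, pi = 0.05, rod = 0.95))
  if (!is.null(quantiles)) q[names(quantiles)] <- quantiles
  cutoffs <- c(
    fst = quantile(windows$fst, q$fst, na.rm = TRUE, names = FALSE, type = 7),
    pi  = quantile(windows$pi_der, q$pi, na.rm = TRUE, names = FALSE, type = 7),
    rod = quantile(windows$rod, q$rod, na.rm = TRUE, names = FALSE, type = 7))
  sig <- !is.na(windows$fst) & windows$fst >= cutoffs[["fst"]] &
         !is.na(windows$pi_der) & windows$pi_der <= cutoffs[["pi"]] &
         !is.na(windows$rod) & windows$rod >= cutoffs[["rod"]]
  if (!any(sig)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$cutoffs <- cutoffs
    return(gr)
  }
  segs <- list()
  for (ch in unique(windows$chrom)) {
    j <- which(windows$chrom == ch)
    idx <- j[sig[j]]
    if (!length(idx)) next
    pos_in_chrom <- match(idx, j)
    breaks <- c(0, which(diff(pos_in_chrom) > gap + 1), length(idx))
    for (k in seq_len(length(breaks) - 1L)) {
      grp <- idx[(breaks[k] + 1L):breaks[k + 1L]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = min(windows$start[grp]),
        end = max(windows$end[grp]), nWindows = length(grp))
    }
  }
  segs <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(
    seqnames = segs$chrom,
    ranges = IRanges::IRanges(segs$start, segs$end),
    nWindows = segs$nWindows, stage = stage)
  S4Vectors::metadata(gr)$cutoffs <- cutoffs
  sort(gr, ignore.strand = TRUE)
}
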