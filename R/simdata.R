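# Forward simulation of BC1 bulk-segregant experiments and three-population
# haplotype panels. These generators exist so the full mapping pipeline can
# be exercised, calibrated and unit-tested at desk scale with a known truth.

#' Lay out an evenly spaced marker map
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param spacing distance between adjacent markers in bp.
#' @return \code{data.frame} with columns \code{chrom}, \code{pos}, sorted.
#' @examples
#' markerMap(c(chr1 = 1e6, chr2 = 5e5), spacing = 1e5)
#' @export
markerMap <- function(chromLengths, spacing) {
  stopifnot(length(chromLengths) > 0, spacing > 0)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  res <- lapply(names(chromLengths), function(ch) {
    pos <- seq(from = spacing, to = chromLengths[[ch]], by = spacing)
    data.frame(chrom = ch, pos = as.integer(pos))
  })
  do.call(rbind, res)
}

## Simulate linked het/hom genotype indicators along one chromosome for a
## BC1 population: the F1 gamete is a two-state Markov chain over markers
## with switch probability given by the Haldane map function.
.simChromGenotypes <- function(n, pos, cmPerMb) {
  m <- length(pos)
  d_morgans <- diff(pos) * 1e-6 * cmPerMb / 100
  r <- 0.5 * (1 - exp(-2 * d_morgans))
  first <- rbinom(n, 1L, 0.5)
  if (m == 1L) return(matrix(first, n, 1L))
  switches <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), n, m - 1L)
  state <- cbind(first, switches)
  t(apply(state, 1L, cumsum)) %% 2L
}

.drawDepths <- function(m, design) {
  dp <- switch(design@depthModel,
    nbinom  = rnbinom(m, size = design@depthDispersion, mu = design@depthPerBulk),
    poisson = rpois(m, design@depthPerBulk))
  as.integer(dp)
}

#' Simulate a BC1 bulk-segregant sequencing experiment
#'
#' Simulates a backcross (F1 x recurrent parent) population in which each
#' individual is, at every marker, either homozygous for the recurrent
#' (reference) allele or heterozygous, with Mendelian probability 1/2 and
#' linkage along chromosomes (Haldane map at \code{design@cmPerMb}).
#' Phenotype is the sum of major-QTL effects over heterozygous QTL
#' genotypes, a polygenic background built from random small effects at all
#' markers (variance fraction \code{h2Background}), and Gaussian noise. The
#' extreme \code{tailFraction} tails are bulked (\code{bulkSize} most
#' extreme individuals each) and per-bulk allele read depths are drawn
#' binomially from the true bulk allele frequencies at per-site depths drawn
#' around \code{depthPerBulk}.
#'
#' Under the null (no QTL) the expected donor-allele frequency in a bulk is
#' 0.25, so the pooled reference-allele frequency is enriched to 0.75 and
#' each bulk's SNP-index is centred on 0.25 — the diagnostic signatures of a
#' well-formed BC1 pooling experiment.
#'
#' @param design a \code{\linkS4class{BulkDesign}}.
#' @param markers marker map (\code{data.frame} with \code{chrom},
#'   \code{pos}), sorted.
#' @param qtls \code{NULL} or \code{data.frame} with \code{chrom},
#'   \code{pos}, \code{effect} (additive effect of a heterozygous donor
#'   genotype, in phenotype SD units). Each QTL must fall within the marker
#'   span of its chromosome and is simulated at the nearest marker.
#' @param h2Background fraction of (non-major-QTL) phenotypic variance from
#'   the polygenic background spread over all markers with random signs.
#' @param familyEffectSd standard deviation of an optional shared rearing
#'   block ("moth area") effect; 0 disables it.
#' @param nFamilies number of rearing blocks when \code{familyEffectSd > 0}.
#' @param keepGenotypes retain the full individual x marker genotype matrix
#'   in the truth output.
#' @param seed integer seed; defaults to \code{design@seed}.
#' @return A list with elements \code{table}
#'   (\code{\linkS4class{AlleleDepthTable}} with \code{gq_H = gq_L = 99}),
#'   \code{truth} (\code{data.frame} of per-marker true bulk donor-allele
#'   frequencies \code{freq_H}, \code{freq_L}), \code{qtls}, \code{design},
#'   and optionally \code{genotypes}.
#' @examples
#' des <- BulkDesign(nPopulation = 200, bulkSize = 20, depthPerBulk = 100)
#' mm <- markerMap(c(chr1 = 2e6), spacing = 2e5)
#' sim <- simulateBc1Bulks(des, mm, seed = 1)
#' nSites(sim$table)
#' @export
simulateBc1Bulks <- function(design, markers, qtls = NULL,
                             h2Background = 0.3, familyEffectSd = 0,
                             nFamilies = 12L, keepGenotypes = FALSE,
                             seed = design@seed) {
  stopifnot(is(design, "BulkDesign"))
  if (design@crossType != "BC1")
    stop("only the BC1 cross is implemented for bulk simulation")
  markers <- as.data.frame(markers)
  o <- order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  if (!is.na(seed)) set.seed(seed)

  n <- design@nPopulation
  m <- nrow(markers)
  chroms <- unique(markers$chrom)

  qtl_idx <- integer(0)
  qtl_eff <- numeric(0)
  if (!is.null(qtls) && nrow(as.data.frame(qtls))) {
    qtls <- as.data.frame(qtls)
    for (k in seq_len(nrow(qtls))) {
      ch <- qtls$chrom[k]
      sel <- which(markers$chrom == ch)
      if (!length(sel))
        stop("QTL chromosome '", ch, "' is not on the marker map")
      p <- markers$pos[sel]
      if (qtls$pos[k] < min(p) || qtls$pos[k] > max(p))
        stop("QTL position ", qtls$pos[k], " lies outside the marker span of ", ch)
      qtl_idx[k] <- sel[which.min(abs(p - qtls$pos[k]))]
      qtl_eff[k] <- qtls$effect[k]
    }
    if (any(!is.finite(qtl_eff))) stop("QTL effects must be finite")
  }

  # genotype indicator matrix: 1 = heterozygous (carries one donor allele)
  G <- matrix(0L, n, m)
  for (ch in chroms) {
    j <- which(markers$chrom == ch)
    G[, j] <- .simChromGenotypes(n, markers$pos[j], design@cmPerMb)
  }

  stopifnot(h2Background >= 0, h2Background < 1)
  poly <- 0
  if (h2Background > 0) {
    beta <- rnorm(m, 0, sqrt(h2Background * 4 / m))  # Var(het indicator)=1/4
    poly <- as.numeric(G %*% beta)
  }
  fam <- 0
  if (familyEffectSd > 0) {
    block <- sample(rep_len(seq_len(nFamilies), n))
    fam <- rnorm(nFamilies, 0, familyEffectSd)[block]
  }
  noise <- rnorm(n, 0, sqrt(max(1 - h2Background, 1e-12)))
  major <- if (length(qtl_idx))
    as.numeric(G[, qtl_idx, drop = FALSE] %*% qtl_eff) else 0
  phenotype <- major + poly + fam + noise

  nTail <- floor(design@tailFraction * n)
  if (design@bulkSize > nTail)
    stop("bulkSize (", design@bulkSize, ") exceeds the tail count (", nTail, ")")
  ord <- order(phenotype, seq_len(n))   # stable: ties broken by index
  low_bulk  <- ord[seq_len(design@bulkSize)]
  high_bulk <- rev(ord)[seq_len(design@bulkSize)]

  freq_H <- colMeans(G[high_bulk, , drop = FALSE]) / 2  # donor = alt allele
  freq_L <- colMeans(G[low_bulk,  , drop = FALSE]) / 2

  dp_H <- .drawDepths(m, design)
  dp_L <- .drawDepths(m, design)
  fH <- freq_H; fL <- freq_L
  if (design@seqError > 0) {
    e <- design@seqError
    fH <- fH * (1 - e) + (1 - fH) * e
    fL <- fL * (1 - e) + (1 - fL) * e
  }
  alt_H <- rbinom(m, dp_H, fH)
  alt_L <- rbinom(m, dp_L, fL)

  tab <- AlleleDepthTable(data.frame(
    chrom = markers$chrom, pos = markers$pos,
    ref_H = dp_H - alt_H, alt_H = alt_H,
    ref_L = dp_L - alt_L, alt_L = alt_L,
    gq_H = 99L, gq_L = 99L))

  truth <- data.frame(chrom = markers$chrom, pos = markers$pos,
                      freq_H = freq_H, freq_L = freq_L)
  out <- list(table = tab, truth = truth,
              qtls = if (length(qtl_idx))
                data.frame(chrom = markers$chrom[qtl_idx],
                           pos = markers$pos[qtl_idx], effect = qtl_eff)
              else NULL,
              design = design)
  if (keepGenotypes) out$genotypes <- G
  out
}

#' Simulate Wild / Local / Improved haplotype panels with an engineered sweep
#'
#' Generates three haplotype panels sharing one set of biallelic sites
#' scattered uniformly along a chromosome. Site frequencies start from a
#' shared ancestral frequency distribution; each population drifts
#' independently around it. Inside \code{sweepInterval}, minor-allele
#' frequencies of the populations named in \code{sweepPops} are shrunk
#' toward fixation of the locally major allele by \code{sweepStrength}
#' (1 = complete sweep, diversity removed; 0 = no sweep), emulating the
#' footprint of domestication/improvement selection that windowed pi, F_ST
#' and reduction-of-diversity scans are designed to detect.
#'
#' @param nWild,nLocal,nImproved haplotype counts per panel.
#' @param seqLength chromosome length in bp.
#' @param mutRate expected polymorphic-site density per bp.
#' @param sweepInterval length-2 vector, bp interval of the swept segment.
#' @param sweepStrength diversity-reduction factor in [0, 1].
#' @param sweepPops which populations carry the sweep (default the derived
#'   Local and Improved panels, as a domestication sweep persists through
#'   later breeding).
#' @param driftConcentration Beta concentration for per-population drift
#'   around the ancestral frequency (larger = less drift).
#' @param chrom chromosome name.
#' @param seed integer RNG seed.
#' @return Named list of three \code{\linkS4class{HaplotypeMatrix}} objects
#'   (\code{wild}, \code{local}, \code{improved}) with attribute
#'   \code{"sweepInterval"}.
#' @examples
#' pans <- simulateThreePopulations(seqLength = 5e4, sweepInterval = c(2e4, 3e4),
#'                                  sweepStrength = 1, seed = 1)
#' sapply(pans, nHaplotypes)
#' @export
simulateThreePopulations <- function(nWild = 102, nLocal = 410,
                                     nImproved = 388, seqLength = 2e5,
                                     mutRate = 0.01,
                                     sweepInterval = c(50001, 60000),
                                     sweepStrength = 0.9,
                                     sweepPops = c("local", "improved"),
                                     driftConcentration = 60,
                                     chrom = "chr1", seed = NULL) {
  stopifnot(sweepStrength >= 0, sweepStrength <= 1,
            length(sweepInterval) == 2)
  if (sweepInterval[1] < 1 || sweepInterval[2] > seqLength ||
      sweepInterval[1] > sweepInterval[2])
    stop("sweepInterval must lie within [1, seqLength]")
  if (!is.null(seed)) set.seed(seed)

  nSites <- max(2L, round(seqLength * mutRate))
  pos <- sort(sample.int(seqLength, nSites))
  p0 <- rbeta(nSites, 0.8, 0.8)
  p0 <- pmin(pmax(p0, 0.02), 0.98)   # condition on segregating ancestrally

  drift <- function(p) {
    k <- driftConcentration
    q <- rbeta(length(p), p * k, (1 - p) * k)
    pmin(pmax(q, 0), 1)
  }
  inSweep <- pos >= sweepInterval[1] & pos <= sweepInterval[2]
  sweep <- function(p) {
    s <- sweepStrength
    ifelse(inSweep,
           ifelse(p <= 0.5, p * (1 - s), 1 - (1 - p) * (1 - s)),
           p)
  }
  sizes <- c(wild = nWild, local = nLocal, improved = nImproved)
  freqs <- lapply(stats::setNames(names(sizes), names(sizes)),
                  function(nm) {
    p <- drift(p0)
    if (nm %in% sweepPops) p <- sweep(p)
    p
  })
  out <- lapply(names(sizes), function(nm) {
    n <- sizes[[nm]]
    a <- matrix(rbinom(nSites * n, 1L, rep(freqs[[nm]], n)), nSites, n)
    HaplotypeMatrix(population = nm, positions = pos, alleles = a,
                    chrom = chrom,
                    seqLengths = stats::setNames(seqLength, chrom))
  })
  names(out) <- names(sizes)
  attr(out, "sweepInterval") <- sweepInterval
  out
}
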