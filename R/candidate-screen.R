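# Candidate-gene screening: map sweep segments to genes, apply the
# silk-gland expression-specificity rule, and test allele-frequency
# divergence between population groups.

.geneHitRegions <- function(genes, regulatoryBp, upstreamOnly) {
  if (upstreamOnly) {
    up <- GenomicRanges::flank(genes, regulatoryBp, start = TRUE,
                               ignore.strand = FALSE)
    GenomicRanges::punion(genes, up)
  } else {
    GenomicRanges::resize(genes,
                          GenomicRanges::width(genes) + 2L * regulatoryBp,
                          fix = "center")
  }
}

#' Assign candidate genes to a genomic segment
#'
#' For each variant inside the segment, genes whose body or regulatory
#' flank (default: strand-aware upstream \code{regulatoryBp}; symmetric
#' flanks with \code{upstreamOnly = FALSE}) contains the variant are
#' candidates. If no variant in the segment hits any gene, the single
#' nearest gene to the segment (by bp distance) is emitted instead;
#' equidistant left/right genes are both reported and flagged as ties.
#'
#' @param segment a length-1 \code{GRanges} (e.g. one sweep segment).
#' @param genes \code{GRanges} of gene spans with a \code{gene_id} metadata
#'   column (strand used for upstream flanks).
#' @param variants \code{GRanges} of variant positions (may be empty).
#' @param regulatoryBp regulatory flank width in bp (default 2000).
#' @param upstreamOnly extend only the strand-aware upstream flank
#'   (default) or both sides.
#' @return \code{data.frame}: \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{assignment} (\code{"variant_hit"} /
#'   \code{"nearest"}), \code{n_variants}, \code{nearest_tie}. Empty (with
#'   a warning) when the chromosome has no genes.
#' @export
assignGenes <- function(segment, genes, variants,
                        regulatoryBp = 2000, upstreamOnly = TRUE) {
  stopifnot(is(segment, "GRanges"), length(segment) == 1,
            is(genes, "GRanges"))
  if (is.null(genes$gene_id))
    stop("'genes' must carry a gene_id metadata column")
  onChrom <- genes[GenomicRanges::seqnames(genes) ==
                   as.character(GenomicRanges::seqnames(segment))]
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), assignment = character(),
                      n_variants = integer(), nearest_tie = logical())
  if (!length(onChrom)) {
    warning("no genes on chromosome ",
            as.character(GenomicRanges::seqnames(segment)))
    return(empty)
  }
  segVars <- IRanges::subsetByOverlaps(variants, segment,
                                       ignore.strand = TRUE)
  asDf <- function(g, assignment, nv, tie = FALSE) {
    data.frame(gene_id = g$gene_id,
               chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g), end = GenomicRanges::end(g),
               strand = as.character(GenomicRanges::strand(g)),
               assignment = assignment, n_variants = nv,
               nearest_tie = tie)
  }
  if (length(segVars)) {
    hitRegions <- .geneHitRegions(onChrom, regulatoryBp, upstreamOnly)
    ov <- GenomicRanges::findOverlaps(segVars, hitRegions,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      counts <- table(S4Vectors::subjectHits(ov))
      idx <- as.integer(names(counts))
      out <- asDf(onChrom[idx], "variant_hit", as.integer(counts))
      out <- out[order(out$start), , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
  }
  # intergenic-only variants: single nearest gene by bp distance to the
  # variants themselves (to the segment when it holds no variants)
  target <- if (length(segVars)) segVars else segment
  dist <- vapply(seq_along(onChrom), function(i)
    min(GenomicRanges::distance(target, onChrom[i], ignore.strand = TRUE),
        na.rm = TRUE), numeric(1))
  dmin <- min(dist, na.rm = TRUE)
  idx <- which(dist == dmin)
  out <- asDf(onChrom[idx], "nearest", 0L, tie = length(idx) > 1)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Silk-gland expression specificity rule
#'
#' A gene passes when (a) its mean FPKM exceeds \code{fpkmMin} in at least
#' one silk-gland section (anterior / middle / posterior) and (b) the sum
#' of its silk-gland FPKM values accounts for at least
#' \code{silkFractionMin} of its total FPKM over all tissues. A gene with
#' zero expression everywhere fails.
#'
#' @param expression numeric matrix or \code{data.frame} of mean FPKM,
#'   genes in rows, tissues in columns (a single named vector is treated
#'   as one gene).
#' @param silkTissues column names of the silk-gland sections.
#' @param fpkmMin minimum FPKM in at least one silk section (default 10,
#'   strict inequality).
#' @param silkFractionMin minimum silk fraction of total expression
#'   (default 0.20, inclusive).
#' @return Logical vector, one verdict per gene.
#' @examples
#' silkGlandFilter(c(ASG = 15, MSG = 2, PSG = 1, FB = 30, MG = 20),
#'                 silkTissues = c("ASG", "MSG", "PSG"))
#' @export
silkGlandFilter <- function(expression, silkTissues,
                            fpkmMin = 10, silkFractionMin = 0.20) {
  if (is.null(dim(expression)))
    expression <- matrix(expression, nrow = 1,
                         dimnames = list(NULL, names(expression)))
  expression <- as.matrix(expression)
  if (any(expression < 0, na.rm = TRUE)) stop("FPKM values must be >= 0")
  missing <- setdiff(silkTissues, colnames(expression))
  if (length(missing))
    stop("silk-gland tissue column(s) not found: ",
         paste(missing, collapse = ", "))
  silk <- expression[, silkTissues, drop = FALSE]
  totals <- rowSums(expression, na.rm = TRUE)
  maxSilk <- apply(silk, 1L, max, na.rm = TRUE)
  silkSum <- rowSums(silk, na.rm = TRUE)
  pass <- maxSilk > fpkmMin &
    ifelse(totals > 0, silkSum / totals >= silkFractionMin, FALSE)
  unname(pass)
}

#' Chi-square test of allele-frequency divergence between two groups
#'
#' Pearson chi-square statistic (1 df, no continuity correction) on the
#' 2x2 allele-count table of two population groups at one variant,
#' computed in closed form as \eqn{N(ad - bc)^2} over the product of the
#' margins. A zero margin carries no information: chi2 = 0, p = 1.
#'
#' @param ref1,alt1 reference/alternate allele counts in group 1
#'   (vectorised over variants).
#' @param ref2,alt2 counts in group 2.
#' @return \code{data.frame}: \code{chi2}, \code{pvalue}, \code{af1},
#'   \code{af2} (per-group alternate-allele frequencies),
#'   \code{significant} (p < 0.05).
#' @examples
#' afChisq(90, 10, 10, 90)  # chi2 = 128
#' @export
afChisq <- function(ref1, alt1, ref2, alt2) {
  stopifnot(all(ref1 >= 0), all(alt1 >= 0), all(ref2 >= 0), all(alt2 >= 0))
  n1 <- ref1 + alt1
  n2 <- ref2 + alt2
  if (any(n1 == 0 | n2 == 0))
    stop("both group allele totals must be positive")
  N <- n1 + n2
  colRef <- ref1 + ref2
  colAlt <- alt1 + alt2
  denom <- as.numeric(n1) * n2 * colRef * colAlt
  chi2 <- ifelse(denom > 0,
                 N * (as.numeric(ref1) * alt2 - as.numeric(alt1) * ref2)^2 / denom,
                 0)
  p <- ifelse(denom > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  data.frame(chi2 = chi2, pvalue = p,
             af1 = alt1 / n1, af2 = alt2 / n2,
             significant = p < 0.05)
}

#' Build per-group allele counts from haplotype panels
#'
#' @param a,b \code{\linkS4class{HaplotypeMatrix}} panels sharing sites.
#' @return \code{GRanges} of shared sites with metadata \code{ref_1},
#'   \code{alt_1}, \code{ref_2}, \code{alt_2}.
#' @export
alleleCountsFromPanels <- function(a, b) {
  keyA <- paste(a@chrom, a@positions)
  keyB <- paste(b@chrom, b@positions)
  shared <- intersect(keyA, keyB)
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  cntA <- rowSums(a@alleles[ia, , drop = FALSE], na.rm = TRUE)
  nA <- rowSums(!is.na(a@alleles[ia, , drop = FALSE]))
  cntB <- rowSums(b@alleles[ib, , drop = FALSE], na.rm = TRUE)
  nB <- rowSums(!is.na(b@alleles[ib, , drop = FALSE]))
  GenomicRanges::GRanges(
    seqnames = a@chrom[ia],
    ranges = IRanges::IRanges(a@positions[ia], a@positions[ia]),
    ref_1 = as.integer(nA - cntA), alt_1 = as.integer(cntA),
    ref_2 = as.integer(nB - cntB), alt_2 = as.integer(cntB))
}

#' Screen sweep segments for candidate genes
#'
#' Runs \code{\link{assignGenes}} on every segment, annotates each gene
#' with the silk-gland expression verdict, and tests allele-frequency
#' divergence (\code{\link{afChisq}}) at every exonic variant of the gene
#' (positional classification against the supplied exons, or the gene body
#' when exons are not given). The report is sorted by expression verdict
#' (passing genes first) and then by the minimum variant p-value; a
#' Benjamini-Hochberg adjusted column over all tested variants is added.
#'
#' @param segments \code{GRanges} of sweep segments (or QTL regions).
#' @param genes \code{GRanges} of genes with \code{gene_id}.
#' @param expression FPKM matrix, rownames = gene ids, columns = tissues.
#' @param variants \code{GRanges} of variants with allele-count metadata
#'   columns \code{ref_1}, \code{alt_1}, \code{ref_2}, \code{alt_2} (see
#'   \code{\link{alleleCountsFromPanels}}).
#' @param silkTissues silk-gland tissue column names in \code{expression}.
#' @param exons optional \code{GRanges} of exons with \code{gene_id}.
#' @param regulatoryBp,upstreamOnly passed to \code{\link{assignGenes}}.
#' @return \code{data.frame}, one row per (segment, gene): \code{gene_id},
#'   \code{segment}, \code{assignment}, \code{silk_pass},
#'   \code{n_exonic_variants}, \code{n_significant}, \code{min_p},
#'   \code{min_q}, sorted candidates first.
#' @export
screenPipeline <- function(segments, genes, expression, variants,
                           silkTissues, exons = NULL,
                           regulatoryBp = 2000, upstreamOnly = TRUE) {
  stopifnot(is(segments, "GRanges"), is(genes, "GRanges"))
  if (!length(segments))
    return(data.frame(gene_id = character(), segment = character(),
                      assignment = character(), silk_pass = logical(),
                      n_exonic_variants = integer(),
                      n_significant = integer(),
                      min_p = numeric(), min_q = numeric()))
  silkPass <- silkGlandFilter(expression, silkTissues)
  names(silkPass) <- rownames(expression)

  af <- afChisq(variants$ref_1, variants$alt_1,
                variants$ref_2, variants$alt_2)
  af$qvalue <- p.adjust(af$pvalue, method = "BH")

  rows <- list()
  for (k in seq_along(segments)) {
    seg <- segments[k]
    segLab <- sprintf("%s:%d-%d",
                      as.character(GenomicRanges::seqnames(seg)),
                      GenomicRanges::start(seg), GenomicRanges::end(seg))
    hits <- assignGenes(seg, genes, variants, regulatoryBp, upstreamOnly)
    if (!nrow(hits)) next
    for (r in seq_len(nrow(hits))) {
      gid <- hits$gene_id[r]
      gene <- genes[genes$gene_id == gid]
      coding <- if (!is.null(exons)) exons[exons$gene_id == gid] else gene
      ex_idx <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(variants, coding, ignore.strand = TRUE)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, segment = segLab,
        assignment = hits$assignment[r],
        silk_pass = isTRUE(silkPass[gid]),
        n_exonic_variants = length(ex_idx),
        n_significant = sum(af$significant[ex_idx]),
        min_p = if (length(ex_idx)) min(af$pvalue[ex_idx]) else NA_real_,
        min_q = if (length(ex_idx)) min(af$qvalue[ex_idx]) else NA_real_)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), segment = character(),
                      assignment = character(), silk_pass = logical(),
                      n_exonic_variants = integer(),
                      n_significant = integer(),
                      min_p = numeric(), min_q = numeric()))
  report <- do.call(rbind, rows)
  ord <- order(!report$silk_pass,
               ifelse(is.na(report$min_p), 2, report$min_p),
               report$gene_id)
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  report
}
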