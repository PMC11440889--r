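# Readers/writers for the formats the pipeline touches (VCF, GFF3, BED,
# TSV, YAML config) and the end-to-end pipeline driver.

#' Read per-bulk allele depths from a VCF
#'
#' Parses biallelic SNV records of a VCF carrying per-sample \code{AD}
#' (and optionally \code{GQ}) into an
#' \code{\linkS4class{AlleleDepthTable}}. Multiallelic and non-SNV records
#' and records with malformed \code{AD} are skipped with logged counts
#' (available via \code{\link{removedCounts}}).
#'
#' @param path VCF file path (plain or bgzipped).
#' @param highBulk,lowBulk sample names of the high and low phenotypic
#'   bulk.
#' @return An \code{AlleleDepthTable} with columns \code{gq_H}/\code{gq_L}
#'   when GQ is present.
#' @export
readVcfAlleleDepths <- function(path, highBulk, lowBulk) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  samples <- colnames(vcf)
  missing <- setdiff(c(highBulk, lowBulk), samples)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  removed <- integer()
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  if (any(!snv)) removed["not_biallelic_snv"] <- sum(!snv)
  vcf <- vcf[snv]
  if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop("VCF has no AD FORMAT field")
  ad <- VariantAnnotation::geno(vcf)$AD
  getAD <- function(sample, el) {
    vapply(ad[, sample], function(x) {
      if (length(x) < 2 || any(is.na(x[1:2]))) NA_integer_
      else as.integer(x[el])
    }, integer(1))
  }
  refH <- getAD(highBulk, 1L); altH <- getAD(highBulk, 2L)
  refL <- getAD(lowBulk, 1L);  altL <- getAD(lowBulk, 2L)
  bad <- is.na(refH) | is.na(altH) | is.na(refL) | is.na(altL)
  if (any(bad)) removed["malformed_AD"] <- sum(bad)
  rr <- SummarizedExperiment::rowRanges(vcf)[!bad]
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref_H = refH[!bad], alt_H = altH[!bad],
    ref_L = refL[!bad], alt_L = altL[!bad])
  gq <- tryCatch(VariantAnnotation::geno(vcf)$GQ, error = function(e) NULL)
  if (!is.null(gq)) {
    d$gq_H <- as.integer(gq[!bad, highBulk])
    d$gq_L <- as.integer(gq[!bad, lowBulk])
  }
  out <- AlleleDepthTable(d)
  out@removed <- removed
  out
}

#' Write an allele-depth table as a minimal two-sample VCF
#'
#' Emits a VCFv4.2 file with one record per site, fixed \code{REF=A} /
#' \code{ALT=T} placeholder alleles (the table carries depths, not
#' sequence), and per-bulk \code{AD} (ref,alt) plus \code{GQ} when
#' available. Round-trips through \code{\link{readVcfAlleleDepths}}.
#'
#' @param x an \code{\linkS4class{AlleleDepthTable}}.
#' @param path output file path.
#' @param sampleNames the two sample names written (high, low).
#' @return \code{path}, invisibly.
#' @export
writeAlleleDepthVcf <- function(x, path,
                                sampleNames = c("BULK_H", "BULK_L")) {
  stopifnot(is(x, "AlleleDepthTable"), length(sampleNames) == 2)
  d <- x@data
  hasGQ <- all(c("gq_H", "gq_L") %in% names(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bulkQTL",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    if (hasGQ) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    if (nrow(d)) paste0("##contig=<ID=", unique(d$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames), collapse = "\t")), con)
  if (nrow(d)) {
    fmt <- if (hasGQ) "AD:GQ" else "AD"
    sampH <- paste0(d$ref_H, ",", d$alt_H,
                    if (hasGQ) paste0(":", d$gq_H) else "")
    sampL <- paste0(d$ref_L, ",", d$alt_L,
                    if (hasGQ) paste0(":", d$gq_L) else "")
    writeLines(paste(d$chrom, d$pos, ".", "A", "T", ".", "PASS", ".",
                     fmt, sampH, sampL, sep = "\t"), con)
  }
  invisible(path)
}

#' Read population haplotype panels from a VCF and a sample map
#'
#' Diploid genotype calls (\code{GT}) of each sample contribute two
#' haplotype columns; missing calls become \code{NA} alleles. Only
#' biallelic SNVs are used.
#'
#' @param path VCF file path.
#' @param sampleMap \code{data.frame} with columns \code{sample},
#'   \code{population} (or a TSV path; see \code{\link{readSampleMap}}).
#' @param seqLengths optional named chromosome lengths for window layout.
#' @return Named list of \code{\linkS4class{HaplotypeMatrix}} objects, one
#'   per population.
#' @export
readPopulationHaplotypes <- function(path, sampleMap, seqLengths = NULL) {
  if (is.character(sampleMap)) sampleMap <- readSampleMap(sampleMap)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- vcf[VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)]
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  missing <- setdiff(sampleMap$sample, colnames(gt))
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  code <- function(a) c("0" = 0L, "1" = 1L)[a]   # others -> NA
  alleleCols <- function(g)
    cbind(unname(code(substr(g, 1L, 1L))), unname(code(substr(g, 3L, 3L))))
  pops <- split(sampleMap$sample, sampleMap$population)
  out <- lapply(names(pops), function(popName) {
    mats <- lapply(pops[[popName]], function(s) alleleCols(gt[, s]))
    HaplotypeMatrix(population = popName, positions = pos,
                    alleles = do.call(cbind, mats), chrom = chrom,
                    seqLengths = seqLengths)
  })
  names(out) <- names(pops)
  out
}

#' Read a sample-to-population map
#'
#' @param path TSV with columns \code{sample}, \code{population} (header
#'   optional; two unnamed columns are taken in that order).
#' @return \code{data.frame} with \code{sample} and \code{population}.
#' @export
readSampleMap <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("sample", first, ignore.case = TRUE)
  d <- read.table(path, header = header, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!header) names(d)[1:2] <- c("sample", "population")
  d[, c("sample", "population")]
}

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 file.
#' @param featureType feature type to keep (default \code{"gene"}).
#' @param idAttribute attribute used as \code{gene_id} (default
#'   \code{"ID"}).
#' @return \code{GRanges} with a \code{gene_id} metadata column.
#' @export
readGeneModels <- function(path, featureType = "gene", idAttribute = "ID") {
  gff <- rtracklayer::import(path, format = "gff3")
  g <- gff[!is.na(gff$type) & gff$type == featureType]
  id <- S4Vectors::mcols(g)[[idAttribute]]
  if (is.null(id)) stop("attribute '", idAttribute, "' not found in GFF3")
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = as.character(id))
  sort(g, ignore.strand = TRUE)
}

#' Read a gene x tissue FPKM expression matrix
#'
#' @param path tab-delimited file, first column gene ids, remaining
#'   columns tissue FPKM means.
#' @return Numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  as.matrix(d)
}

#' Write genomic regions as a BED file
#'
#' Converts from the internal 1-based inclusive coordinates to BED's
#' 0-based half-open convention and writes sorted lines.
#'
#' @param regions \code{GRanges}; a \code{method} or \code{stage} metadata
#'   column (if present) becomes the BED name field.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRegionBed <- function(regions, path) {
  stopifnot(is(regions, "GRanges"))
  if (!length(regions)) {
    file.create(path)
    return(invisible(path))
  }
  o <- order(as.character(GenomicRanges::seqnames(regions)),
             GenomicRanges::start(regions))
  regions <- regions[o]
  name <- if (!is.null(regions$method)) as.character(regions$method)
          else if (!is.null(regions$stage)) as.character(regions$stage)
          else "."
  lines <- paste(as.character(GenomicRanges::seqnames(regions)),
                 GenomicRanges::start(regions) - 1L,
                 GenomicRanges::end(regions),
                 name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation truth table
#'
#' @param truth the \code{truth} data.frame of
#'   \code{\link{simulateBc1Bulks}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pipeline driver
# ---------------------------------------------------------------------------

.defaultConfig <- function() {
  list(highBulk = NULL, lowBulk = NULL, outDir = ".",
       windowBp = 1e6, reps = 10000L, fdr = 0.01, seed = 1L,
       ciDepths = NULL, filter = list(), design = list())
}

#' Read or normalise a pipeline run configuration
#'
#' @param config a YAML file path or a named list. Recognised fields:
#'   \code{vcf}, \code{highBulk}, \code{lowBulk}, \code{outDir},
#'   \code{windowBp}, \code{reps}, \code{fdr}, \code{seed},
#'   \code{ciDepths}, \code{filter} (FilterSpec arguments), \code{design}
#'   (BulkDesign arguments), \code{sweep} (\code{vcf}, \code{popMap},
#'   \code{ancestral}, \code{derived}, \code{window}, \code{step},
#'   \code{stage}), \code{candidates} (\code{gff}, \code{expression},
#'   \code{silkTissues}).
#' @return Normalised configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out <- .defaultConfig()
  out[names(config)] <- config
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full bulk-segregant mapping pipeline
#'
#' Executes: read VCF allele depths, filter sites, compute per-SNP and
#' smoothed statistics, simulate confidence intervals, derive G' p-values,
#' call QTL regions; then optionally a population sweep scan and
#' candidate-gene screen. All tables are written under
#' \code{config$outDir} together with a JSON run manifest recording the
#' seed, parameters and per-stage record counts. A failing stage aborts
#' with the stage name; outputs of completed stages are preserved.
#'
#' @param config a YAML path or configuration list (see
#'   \code{\link{readRunConfig}}).
#' @return Invisibly, a list with \code{table} (statistics), \code{ci},
#'   \code{regions}, optional \code{sweepWindows} / \code{sweepSegments} /
#'   \code{candidates}, and \code{manifest}.
#' @export
runPipeline <- function(config) {
  config <- readRunConfig(config)
  for (f in c("vcf", "highBulk", "lowBulk"))
    if (is.null(config[[f]]))
      stop("pipeline configuration is missing required field '", f, "'")
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  counts <- list()

  adt <- .stage("read", readVcfAlleleDepths(config$vcf, config$highBulk,
                                            config$lowBulk))
  counts$read <- c(kept = nSites(adt), removedCounts(adt))

  spec <- do.call(FilterSpec, config$filter)
  flt <- .stage("filter", filterSites(adt, spec))
  counts$filter <- c(kept = nSites(flt), removedCounts(flt))

  stats <- .stage("stats", computeBulkStats(flt, windowBp = config$windowBp))
  counts$stats <- c(kept = nSites(stats))

  design <- do.call(BulkDesign, config$design)
  d <- adData(stats)
  meanDepth <- (d$ref_H + d$alt_H + d$ref_L + d$alt_L) / 2
  depths <- config$ciDepths
  if (is.null(depths)) {
    rng <- range(meanDepth)
    depths <- unique(round(seq(max(rng[1], 10), max(rng[2], 20),
                               length.out = 10)))
  }
  ci <- .stage("ci", simulateCI(design, depths, reps = config$reps,
                                seed = config$seed))

  stats <- .stage("gprime", addGprimePvalues(stats))
  regions <- .stage("regions",
                    callQtlRegions(stats, ci, fdr = config$fdr))
  counts$regions <- c(called = length(regions))

  write.table(adData(stats), file.path(config$outDir, "snp_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ciTable(ci), file.path(config$outDir, "ci_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(regions),
              file.path(config$outDir, "qtl_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeRegionBed(regions, file.path(config$outDir, "qtl_regions.bed"))

  result <- list(table = stats, ci = ci, regions = regions)

  if (!is.null(config$sweep)) {
    sw <- config$sweep
    pans <- .stage("sweep", readPopulationHaplotypes(sw$vcf, sw$popMap))
    ws <- .stage("sweep", sweepScan(
      pans[[sw$ancestral]], pans[[sw$derived]],
      window = if (is.null(sw$window)) 5000 else sw$window,
      step = if (is.null(sw$step)) 500 else sw$step))
    segs <- .stage("sweep", callSweeps(
      ws, stage = if (is.null(sw$stage)) "domestication" else sw$stage))
    counts$sweep <- c(windows = nrow(ws), segments = length(segs))
    write.table(ws, file.path(config$outDir, "sweep_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeRegionBed(segs, file.path(config$outDir, "sweep_segments.bed"))
    result$sweepWindows <- ws
    result$sweepSegments <- segs

    if (!is.null(config$candidates)) {
      cd <- config$candidates
      genes <- .stage("candidates", readGeneModels(cd$gff))
      expr <- .stage("candidates", readExpressionMatrix(cd$expression))
      variants <- .stage("candidates", alleleCountsFromPanels(
        pans[[sw$ancestral]], pans[[sw$derived]]))
      report <- .stage("candidates", screenPipeline(
        segs, genes, expr, variants, silkTissues = cd$silkTissues))
      counts$candidates <- c(genes = nrow(report))
      write.table(report, file.path(config$outDir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      result$candidates <- report
    }
  }

  manifest <- list(
    package = "bulkQTL",
    version = as.character(utils::packageVersion("bulkQTL")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "outDir")],
    stages = lapply(counts, as.list))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  result$manifest <- manifest
  invisible(result)
}

#' Plot per-chromosome statistic tracks
#'
#' Basic per-chromosome panels of a smoothed statistic with optional CI
#' threshold lines, for quick inspection of a scan.
#'
#' @param x an \code{\linkS4class{AlleleDepthTable}} with computed
#'   statistics.
#' @param statistic column to plot (default \code{"delta_smooth"}).
#' @param ci optional \code{\linkS4class{CiTable}} whose interpolated
#'   CI_95/CI_99 thresholds are drawn for delta tracks.
#' @return Invisibly, \code{NULL}; draws on the current device.
#' @export
plotScanTrack <- function(x, statistic = "delta_smooth", ci = NULL) {
  d <- adData(x)
  stopifnot(statistic %in% names(d))
  chroms <- unique(d$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    j <- d$chrom == ch
    graphics::plot(d$pos[j] / 1e6, d[[statistic]][j], type = "l",
                   xlab = "position (Mb)", ylab = statistic, main = ch)
    if (!is.null(ci) && grepl("delta", statistic)) {
      md <- (d$ref_H + d$alt_H + d$ref_L + d$alt_L)[j] / 2
      graphics::lines(d$pos[j] / 1e6, interpolateCI(ci, md, 0.95),
                      lty = 2, col = "blue")
      graphics::lines(d$pos[j] / 1e6, interpolateCI(ci, md, 0.99),
                      lty = 2, col = "red")
    }
  }
  invisible(NULL)
}
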