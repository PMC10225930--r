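#' @include detect.R
NULL

#' Alu editing index (AEI)
#'
#' Transcriptome-wide A-to-I activity: the number of quality-filtered
#' G-mismatch read observations at transcribed-strand adenosines inside Alu
#' territory, divided by the total filtered read coverage of those
#' adenosines.  The denominator counts all adenosine coverage in Alu
#' intervals, including positions with no mismatch at all, so the index is
#' an activity-weighted average rather than a per-site mean.  Adenosines
#' are taken on the strand recorded in the Alu BED; unstranded intervals
#' fall back to counting forward A-to-G plus reverse T-to-C, summed.
#'
#' @param tally a [PileupTally-class] (its quality thresholds define the
#'   filtered counts used here).
#' @param aluIntervals \code{GRanges} of Alu elements.
#' @param reference \code{DNAStringSet}; unused when the tally already
#'   carries reference bases, kept for interface symmetry.
#' @return list with \code{aei} (fraction, NA when no adenosine coverage),
#'   \code{numerator} and \code{denominator}.
#' @export
computeAei <- function(tally, aluIntervals, reference = NULL) {
  counts <- tallyCounts(tally)
  if (!nrow(counts)) {
    warning("no adenosine coverage in Alu territory; AEI is NA")
    return(list(aei = NA_real_, numerator = 0, denominator = 0))
  }
  posGr <- GRanges(counts$chrom, IRanges(counts$pos, counts$pos))
  num <- 0; den <- 0
  total <- counts$fA + counts$fC + counts$fG + counts$fT
  for (s in c("+", "-", "*")) {
    iv <- aluIntervals[as.character(strand(aluIntervals)) == s]
    if (!length(iv)) next
    iv <- GenomicRanges::reduce(iv, ignore.strand = TRUE)
    inIv <- IRanges::overlapsAny(posGr, iv, ignore.strand = TRUE)
    if (s %in% c("+", "*")) {
      rows <- inIv & counts$ref == "A"
      num <- num + sum(counts$fG[rows])
      den <- den + sum(total[rows])
    }
    if (s %in% c("-", "*")) {
      rows <- inIv & counts$ref == "T"
      num <- num + sum(counts$fC[rows])
      den <- den + sum(total[rows])
    }
  }
  if (den == 0) {
    warning("no adenosine coverage in Alu territory; AEI is NA")
    return(list(aei = NA_real_, numerator = 0, denominator = 0))
  }
  list(aei = num / den, numerator = num, denominator = den)
}

#' Named preset regions for region editing indices
#'
#' Currently ships the MAVS 3'UTR interval (hg19 chr20:3848102-3855844),
#' the region whose editing index summarizes hyper-editing of the MAVS
#' transcript.  Note the assembly: this preset is an hg19 interval and only
#' makes sense against an hg19-aligned input.
#'
#' @return named \code{GRanges}.
#' @export
editingRegionPresets <- function() {
  gr <- GRanges("chr20", IRanges(3848102, 3855844), strand = "+")
  names(gr) <- "MAVS_3UTR"
  gr
}

#' Editing index of an arbitrary region
#'
#' The ratio of the number of read observations carrying A-to-G at any
#' adenosine in the region to the total read coverage of those adenosines,
#' using the tally's quality-filtered counts.  Adenosines are taken on the
#' transcribed strand: reference A with G mismatches on \code{"+"},
#' reference T with C mismatches on \code{"-"}.
#'
#' @param tally a [PileupTally-class].
#' @param region a single-interval \code{GRanges}, or the name of a preset
#'   from [editingRegionPresets()].
#' @param strand override for the region strand; defaults to the region's
#'   own strand, or \code{"+"} when unstranded.
#' @return list with \code{index} (NA when the region has no covered
#'   adenosine), \code{numerator}, \code{denominator}.
#' @export
regionEditingIndex <- function(tally, region, strand = NULL) {
  if (is.character(region)) {
    presets <- editingRegionPresets()
    if (!region %in% names(presets))
      stop("unknown preset region: ", region)
    region <- presets[region]
  }
  stopifnot(length(region) == 1)
  if (is.null(strand)) {
    strand <- as.character(GenomicRanges::strand(region))
    if (strand == "*") strand <- "+"
  }
  counts <- tallyCounts(tally)
  rows <- counts$chrom == as.character(seqnames(region)) &
    counts$pos >= start(region) & counts$pos <= end(region) &
    counts$ref == (if (strand == "+") "A" else "T")
  sub <- counts[rows, , drop = FALSE]
  den <- sum(sub$fA + sub$fC + sub$fG + sub$fT)
  num <- if (strand == "+") sum(sub$fG) else sum(sub$fC)
  if (den == 0) return(list(index = NA_real_, numerator = 0,
                            denominator = 0))
  list(index = num / den, numerator = num, denominator = den)
}

#' Gene-level editing frequency (read-aggregated)
#'
#' Aggregates all reads covering at least one listed editing site of a gene
#' and passing the read filters (base quality > 20, mapping quality > 30,
#' site at least 7 bp from the raw read ends); the gene's editing level is
#' the fraction of those reads carrying the edited base at one or more
#' listed sites.  A read covering several listed sites counts once.  The
#' caller supplies the site list already restricted to the cohort-level
#' rules (A-to-G sites of the gene reported in at least two samples,
#' non-intergenic).
#'
#' @param reads alignment data.frame from [readAlignments()].
#' @param sites \code{GRanges} with an \code{alt} metadata column
#'   (forward-strand edited base); duplicate entries are ignored.
#' @param geneId optional; when given, sites are subset to
#'   \code{mcols(sites)$geneId == geneId}.
#' @param qBase,qMap,minEndDistance read filters (strict for the quality
#'   thresholds: quality must exceed them).
#' @return list with \code{level} (NA when no read passes), \code{editedReads},
#'   \code{filteredReads} and \code{reason} (\code{"ok"},
#'   \code{"no_sites"} or \code{"no_covering_reads"}).
#' @export
geneEditingLevel <- function(reads, sites, geneId = NULL, qBase = 20,
                             qMap = 30, minEndDistance = 7) {
  if (!is.null(geneId))
    sites <- sites[!is.na(mcols(sites)$geneId) &
                   mcols(sites)$geneId == geneId]
  if (!length(sites))
    return(list(level = NA_real_, editedReads = 0L, filteredReads = 0L,
                reason = "no_sites"))
  key <- paste(as.character(seqnames(sites)), start(sites),
               mcols(sites)$alt)
  sites <- sites[!duplicated(key)]
  den <- 0L; num <- 0L
  for (chrom in unique(as.character(seqnames(sites)))) {
    ss <- sites[as.character(seqnames(sites)) == chrom]
    ord <- order(start(ss))
    ss <- ss[ord]
    sel <- reads$chrom == chrom
    if (!any(sel)) next
    res <- .gene_editing_reads(
      as.integer(reads$pos[sel]), as.integer(reads$flag[sel]),
      as.integer(reads$mapq[sel]), reads$cigar[sel], reads$seq[sel],
      reads$qual[sel], as.integer(start(ss)),
      as.character(mcols(ss)$alt), as.integer(qBase), as.integer(qMap),
      as.integer(minEndDistance))
    den <- den + res[["filtered_reads"]]
    num <- num + res[["edited_reads"]]
  }
  if (den == 0)
    return(list(level = NA_real_, editedReads = 0L, filteredReads = 0L,
                reason = "no_covering_reads"))
  list(level = num / den, editedReads = num, filteredReads = den,
       reason = "ok")
}

#' Assemble a sample's editing profile
#'
#' Convenience constructor bundling called sites with the sample's AEI and
#' any requested region indices into a [SampleEditingProfile-class].
#'
#' @param sampleId sample identifier.
#' @param sites \code{GRanges} of called (optionally classifier-filtered)
#'   sites.
#' @param tally the sample's [PileupTally-class].
#' @param aluIntervals \code{GRanges} of Alu elements.
#' @param regions optional named \code{GRanges} of extra regions to index.
#' @param geneLevels optional named numeric vector of gene editing levels.
#' @return a [SampleEditingProfile-class].
#' @export
buildSampleProfile <- function(sampleId, sites, tally, aluIntervals,
                               regions = NULL, geneLevels = NULL) {
  aeiRes <- computeAei(tally, aluIntervals)
  ri <- setNames(numeric(0), character(0))
  if (!is.null(regions) && length(regions)) {
    ri <- vapply(seq_along(regions), function(i)
      regionEditingIndex(tally, regions[i])$index, numeric(1))
    names(ri) <- names(regions)
  }
  new("SampleEditingProfile", sampleId = sampleId, sites = sites,
      aei = aeiRes$aei,
      aeiCounts = c(numerator = aeiRes$numerator,
                    denominator = aeiRes$denominator),
      regionIndices = ri,
      geneLevels = geneLevels %||% setNames(numeric(0), character(0)))
}
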