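#' @include AllGenerics.R
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString subseq reverseComplement replaceLetterAt extractAt
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamWhat BamFile
#' @importFrom rtracklayer import
#' @importFrom VariantAnnotation readVcf ref alt info
#' @importFrom GenomeInfoDb seqnames seqlevels
#' @importFrom utils read.table write.table
NULL

## ---- reference ----

#' Read an indexed reference genome
#'
#' Loads a FASTA file into memory as a \code{DNAStringSet}.  Sequence names
#' are taken as the first whitespace-delimited token of each header and must
#' be unique.  Use [fetchSequence()] for 1-based inclusive subsequence
#' retrieval.
#'
#' @param fastaPath path to a FASTA file.
#' @return a named \code{DNAStringSet}.
#' @export
readReference <- function(fastaPath) {
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Fetch a reference subsequence (1-based, inclusive)
#'
#' @param reference a \code{DNAStringSet} from [readReference()].
#' @param chrom sequence name.
#' @param start,end 1-based inclusive coordinates.
#' @return upper-case character string of length \code{end - start + 1}.
#' @export
fetchSequence <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference))
    stop("sequence not found in reference: ", chrom)
  if (start < 1 || end > length(reference[[chrom]]) || end < start)
    stop("coordinates out of range for ", chrom, ": ", start, "-", end)
  toupper(as.character(subseq(reference[[chrom]], start, end)))
}

## ---- intervals ----

#' Read a BED file of intervals (Alu elements, simple repeats, ...)
#'
#' BED records are 0-based half-open on disk; they are converted to the
#' package's internal 1-based inclusive convention.  Records whose start is
#' not strictly less than their end are rejected with a warning.  A strand
#' column (BED6) is honored when present; otherwise strand is \code{"*"}.
#'
#' @param bedPath path to a BED3+ file.
#' @return a \code{GRanges} (1-based inclusive).
#' @export
readAluBed <- function(bedPath) {
  bed <- read.table(bedPath, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  bad <- bed[[2]] >= bed[[3]]
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with start >= end rejected")
    bed <- bed[!bad, , drop = FALSE]
  }
  strand <- if (ncol(bed) >= 6) bed[[6]] else rep("*", nrow(bed))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(bed[[1]], IRanges(bed[[2]] + 1L, bed[[3]]), strand = strand)
  if (ncol(bed) >= 4) mcols(gr)$name <- bed[[4]]
  gr
}

#' Write intervals back to BED (inverse of [readAluBed()])
#' @param gr a \code{GRanges} in internal 1-based inclusive coordinates.
#' @param bedPath output path.
#' @return \code{bedPath}, invisibly.
#' @export
writeBed <- function(gr, bedPath) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = mcols(gr)$name %||% ".",
                   score = 0L, strand = as.character(strand(gr)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, bedPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bedPath)
}

#' Does any interval contain a point?
#' @param gr a \code{GRanges}.
#' @param chrom,pos point coordinates (1-based).
#' @return logical scalar.
#' @export
containsPoint <- function(gr, chrom, pos) {
  any(as.character(seqnames(gr)) == chrom & start(gr) <= pos & end(gr) >= pos)
}

## ---- gene models ----

#' Read gene models from a GTF file
#'
#' Uses \code{exon} and, when present, \code{three_prime_utr} /
#' \code{five_prime_utr} features grouped by \code{gene_id}.  Gene spans are
#' the range of each gene's exons; introns are the gaps between consecutive
#' exons.
#'
#' @param gtfPath path to a GTF file.
#' @return a list with \code{GRanges} elements \code{genes}, \code{exons},
#'   \code{utr3}, \code{utr5} and \code{introns}, each carrying a
#'   \code{geneId} metadata column.
#' @export
readGeneModels <- function(gtfPath) {
  gtf <- rtracklayer::import(gtfPath, format = "gtf")
  if (is.null(mcols(gtf)$gene_id)) stop("GTF lacks gene_id attributes")
  exons <- gtf[mcols(gtf)$type == "exon"]
  if (!length(exons)) stop("GTF contains no exon features")
  pick <- function(type) {
    g <- gtf[mcols(gtf)$type == type]
    out <- granges(g)
    mcols(out)$geneId <- mcols(g)$gene_id
    out
  }
  ex <- pick("exon")
  utr3 <- pick("three_prime_utr")
  utr5 <- pick("five_prime_utr")
  byGene <- S4Vectors::split(ex, mcols(ex)$geneId)
  genes <- unlist(range(byGene))
  mcols(genes)$geneId <- names(genes)
  names(genes) <- NULL
  introns <- unlist(GenomicRanges::psetdiff(
    unlist(range(byGene)), GenomicRanges::reduce(byGene)))
  mcols(introns)$geneId <- names(introns)
  names(introns) <- NULL
  list(genes = genes, exons = ex, utr3 = utr3, utr5 = utr5,
       introns = introns)
}

#' Classify positions against gene models
#'
#' Assigns each position a region class (\code{utr3}, \code{utr5},
#' \code{exon_cds}, \code{intron} or \code{intergenic}), the overlapping
#' gene(s) and the transcribed strand.  When several genes overlap a
#' position, all gene ids are recorded (comma-separated) but the canonical
#' gene is the one with the longest span; positions covered by genes on both
#' strands are flagged ambiguous.
#'
#' @param geneModels list from [readGeneModels()].
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 1-based positions.
#' @return \code{data.frame} with columns \code{region}, \code{geneId}
#'   (canonical), \code{allGeneIds}, \code{strand} and \code{ambiguous}.
#' @export
classifyRegions <- function(geneModels, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  q <- GRanges(chrom, IRanges(pos, pos))
  n <- length(q)
  region <- rep("intergenic", n)
  geneId <- rep(NA_character_, n)
  allIds <- rep(NA_character_, n)
  str <- rep(".", n)
  ambiguous <- rep(FALSE, n)
  g <- geneModels$genes
  ov <- GenomicRanges::findOverlaps(q, g, ignore.strand = TRUE)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    width <- end(g) - start(g) + 1
    for (i in unique(qh)) {
      hits <- sh[qh == i]
      canonical <- hits[which.max(width[hits])]
      geneId[i] <- mcols(g)$geneId[canonical]
      allIds[i] <- paste(mcols(g)$geneId[hits], collapse = ",")
      strands <- unique(as.character(strand(g))[hits])
      ambiguous[i] <- length(strands) > 1
      str[i] <- if (length(strands) == 1) strands else
        as.character(strand(g))[canonical]
    }
    inAny <- function(track) {
      if (!length(track)) return(rep(FALSE, n))
      IRanges::overlapsAny(q, track, ignore.strand = TRUE)
    }
    genic <- !is.na(geneId)
    in3 <- inAny(geneModels$utr3)
    in5 <- inAny(geneModels$utr5)
    inEx <- inAny(geneModels$exons)
    region[genic] <- "intron"
    region[genic & inEx] <- "exon_cds"
    region[genic & in5] <- "utr5"
    region[genic & in3] <- "utr3"
  }
  data.frame(region = region, geneId = geneId, allGeneIds = allIds,
             strand = str, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

## ---- DNA variants ----

#' Read matched-DNA variants (SNVs) from a VCF file
#'
#' Single-nucleotide substitutions only; indels and multi-allelic records
#' are dropped with a message reporting the count.  The \code{SRC} INFO
#' field (\code{germline}/\code{somatic}) is kept when present.
#'
#' @param vcfPath path to a VCF v4.x file.
#' @return \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{source}.
#' @export
readDnaVariants <- function(vcfPath) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcfPath))
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- vapply(VariantAnnotation::alt(vcf), function(a)
    if (length(a) == 1) as.character(a) else "", character(1))
  snv <- nchar(refs) == 1 & nchar(alts) == 1 &
    refs %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T")
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) ignored in ", basename(vcfPath))
  src <- rep("germline", length(refs))
  inf <- VariantAnnotation::info(vcf)
  if ("SRC" %in% colnames(inf)) {
    got <- as.character(inf$SRC)
    src[!is.na(got)] <- got[!is.na(got)]
  }
  data.frame(chrom = as.character(seqnames(rr))[snv],
             pos = start(rr)[snv], ref = refs[snv], alt = alts[snv],
             source = src[snv], stringsAsFactors = FALSE)
}

## ---- alignments ----

#' Read RNA-seq alignments from SAM or BAM
#'
#' SAM input is converted to BAM internally (in a temporary directory) and
#' read through \code{Rsamtools}.  Optionally truncates reads to a fixed
#' length, as is done for Alu-editing-index calculations to remove
#' read-length bias; truncation is only supported for ungapped (single-M
#' CIGAR) alignments.
#'
#' @param path path to a SAM or BAM file.
#' @param cutReadLength integer or NULL; when set, reads longer than this
#'   are truncated to their first \code{cutReadLength} bases.
#' @return \code{data.frame} with columns \code{qname}, \code{flag},
#'   \code{chrom}, \code{pos}, \code{mapq}, \code{cigar}, \code{seq},
#'   \code{qual}.
#' @export
readAlignments <- function(path, cutReadLength = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    bam <- suppressMessages(
      Rsamtools::asBam(path, sub("\\.bam$", "", dest), overwrite = TRUE,
                       indexDestination = FALSE))
  }
  res <- Rsamtools::scanBam(BamFile(bam), param = ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual")))[[1]]
  reads <- data.frame(qname = res$qname, flag = res$flag,
                      chrom = as.character(res$rname), pos = res$pos,
                      mapq = res$mapq, cigar = res$cigar,
                      seq = as.character(res$seq),
                      qual = as.character(res$qual),
                      stringsAsFactors = FALSE)
  reads <- reads[!is.na(reads$pos), , drop = FALSE]
  if (!is.null(cutReadLength)) {
    long <- nchar(reads$seq) > cutReadLength
    if (any(long & !grepl("^[0-9]+M$", reads$cigar)))
      stop("read-length cutting supports only ungapped (single-M) CIGARs")
    reads$seq[long] <- substr(reads$seq[long], 1L, cutReadLength)
    reads$qual[long] <- substr(reads$qual[long], 1L, cutReadLength)
    reads$cigar[long] <- paste0(cutReadLength, "M")
  }
  reads
}

## ---- pileup ----

#' Tally alignments into per-position base counts
#'
#' Converts one sample's alignments into a [PileupTally-class]: raw and
#' quality-filtered counts of every read base at every covered reference
#' position, plus a per-observation record of all mismatching bases (base
#' quality, mapping quality, distance to the nearer raw read end, read
#' strand).  Unmapped, secondary, supplementary and duplicate-flagged reads
#' are excluded; insertions and soft clips contribute no aligned bases but
#' count toward raw-read-end distances; N bases never count as mismatches.
#'
#' @param reads alignment \code{data.frame} from [readAlignments()].
#' @param reference \code{DNAStringSet} from [readReference()].
#' @param regions optional \code{GRanges}; only positions inside are kept.
#' @param qBase,qMap phred thresholds defining the filtered counts
#'   (observation kept when base quality >= \code{qBase} and mapping
#'   quality >= \code{qMap}).
#' @param sampleId sample identifier stored in the tally.
#' @return a [PileupTally-class].
#' @export
pileupAlignments <- function(reads, reference, regions = NULL, qBase = 20,
                             qMap = 30, sampleId = NA_character_) {
  chroms <- unique(reads$chrom)
  unknown <- setdiff(chroms, names(reference))
  if (length(unknown))
    stop("alignment sequence(s) absent from reference: ",
         paste(unknown, collapse = ", "))
  countsL <- list()
  mmL <- list()
  for (chrom in chroms) {
    sel <- reads$chrom == chrom
    refStr <- as.character(reference[[chrom]])
    out <- .pileup_engine(as.integer(reads$pos[sel]),
                          as.integer(reads$flag[sel]),
                          as.integer(reads$mapq[sel]),
                          reads$cigar[sel], reads$seq[sel], reads$qual[sel],
                          refStr, 1L, nchar(refStr),
                          as.integer(qBase), as.integer(qMap))
    m <- out$counts
    covered <- which(rowSums(m[, 1:5, drop = FALSE]) > 0)
    if (length(covered)) {
      refBases <- strsplit(toupper(refStr), "")[[1]][covered]
      countsL[[chrom]] <- data.frame(
        chrom = chrom, pos = covered, ref = refBases,
        A = m[covered, 1], C = m[covered, 2], G = m[covered, 3],
        T = m[covered, 4], N = m[covered, 5],
        fA = m[covered, 6], fC = m[covered, 7], fG = m[covered, 8],
        fT = m[covered, 9], fN = m[covered, 10],
        refFwd = m[covered, 11], refRev = m[covered, 12],
        stringsAsFactors = FALSE)
    }
    if (length(out$mm_pos))
      mmL[[chrom]] <- data.frame(
        chrom = chrom, pos = out$mm_pos, base = out$mm_base,
        bq = out$mm_bq, mq = out$mm_mq, distEnd = out$mm_dist,
        rev = as.logical(out$mm_rev), stringsAsFactors = FALSE)
  }
  counts <- if (length(countsL)) do.call(rbind, countsL) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               A = integer(0), C = integer(0), G = integer(0),
               T = integer(0), N = integer(0), fA = integer(0),
               fC = integer(0), fG = integer(0), fT = integer(0),
               fN = integer(0), refFwd = integer(0), refRev = integer(0))
  mism <- if (length(mmL)) do.call(rbind, mmL) else
    data.frame(chrom = character(0), pos = integer(0), base = character(0),
               bq = integer(0), mq = integer(0), distEnd = integer(0),
               rev = logical(0))
  rownames(counts) <- NULL
  rownames(mism) <- NULL
  if (!is.null(regions)) {
    keepC <- IRanges::overlapsAny(
      GRanges(counts$chrom, IRanges(counts$pos, counts$pos)), regions,
      ignore.strand = TRUE)
    counts <- counts[keepC, , drop = FALSE]
    if (nrow(mism)) {
      keepM <- IRanges::overlapsAny(
        GRanges(mism$chrom, IRanges(mism$pos, mism$pos)), regions,
        ignore.strand = TRUE)
      mism <- mism[keepM, , drop = FALSE]
    }
  }
  new("PileupTally", sampleId = sampleId, counts = counts,
      mismatches = mism, params = list(qBase = qBase, qMap = qMap))
}

#' Sum several tallies into a pooled tally
#'
#' Adds the count tables position-wise and concatenates the mismatch
#' observation tables.  All tallies must share quality parameters.
#'
#' @param tallies list of [PileupTally-class] objects.
#' @param sampleId identifier for the pooled tally.
#' @return a [PileupTally-class].
#' @export
poolTallies <- function(tallies, sampleId = "pooled") {
  stopifnot(length(tallies) >= 1)
  p1 <- tallies[[1]]@params
  for (t in tallies)
    if (!identical(t@params, p1))
      stop("tallies were built with different quality parameters")
  allCounts <- do.call(rbind, lapply(tallies, function(t) t@counts))
  key <- paste(allCounts$chrom, allCounts$pos)
  numCols <- c("A", "C", "G", "T", "N", "fA", "fC", "fG", "fT", "fN",
               "refFwd", "refRev")
  agg <- rowsum(as.matrix(allCounts[, numCols]), key)
  first <- allCounts[!duplicated(key), c("chrom", "pos", "ref")]
  rownames(first) <- paste(first$chrom, first$pos)
  merged <- cbind(first[rownames(agg), ], as.data.frame(agg))
  merged <- merged[order(merged$chrom, merged$pos), ]
  rownames(merged) <- NULL
  mism <- do.call(rbind, lapply(tallies, function(t) t@mismatches))
  rownames(mism) <- NULL
  new("PileupTally", sampleId = sampleId, counts = merged,
      mismatches = mism, params = p1)
}

#' Write a pileup tally as a debugging TSV
#' @param tally a [PileupTally-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePileupTsv <- function(tally, path) {
  write.table(tally@counts[, c("chrom", "pos", "ref", "A", "C", "G", "T")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
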