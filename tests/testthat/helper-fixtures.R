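## Shared fixture builders: tiny references, hand-built SAM files and
## brute-force oracles.  Everything is constructed in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# write a reference FASTA from named character sequences, return its path
writeTestRef <- function(seqs, dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
  path <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

# reads: data.frame(qname, flag, chrom, pos, mapq, cigar, seq, qual)
# defaults give ungapped forward reads at mapq 60 with phred-40 bases
makeReads <- function(chrom, pos, seq, qual = NULL, flag = 0L, mapq = 60L,
                      cigar = NULL, qname = NULL) {
  n <- length(pos)
  seq <- rep_len(seq, n)
  if (is.null(qual)) qual <- vapply(nchar(seq), function(l)
    strrep("I", l), character(1))
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  data.frame(qname = qname %||% sprintf("r%04d", seq_len(n)),
             flag = rep_len(flag, n), chrom = rep_len(chrom, n),
             pos = pos, mapq = rep_len(mapq, n),
             cigar = rep_len(cigar, n), seq = seq,
             qual = rep_len(qual, n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a SAM file (coordinate-sorted) for the given reads and chrom sizes
writeTestSam <- function(reads, chromLens,
                         dir = withr::local_tempdir(.local_envir =
                                                      parent.frame())) {
  path <- file.path(dir, "reads.sam")
  ord <- order(match(reads$chrom, names(chromLens)), reads$pos)
  reads <- reads[ord, , drop = FALSE]
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLens),
                     as.integer(chromLens)),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     reads$qname, reads$flag, reads$chrom, reads$pos,
                     reads$mapq, reads$cigar, reads$seq, reads$qual))
  writeLines(lines, path)
  path
}

# brute-force pileup oracle for ungapped reads: per-base counts at one pos
naiveBaseCounts <- function(reads, chrom, pos) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    L <- nchar(reads$seq[i])
    if (pos < reads$pos[i] || pos > reads$pos[i] + L - 1) next
    b <- substr(reads$seq[i], pos - reads$pos[i] + 1, pos - reads$pos[i] + 1)
    if (!b %in% names(counts)) b <- "N"
    counts[b] <- counts[b] + 1L
  }
  counts
}

# minimal gene-models list (same shape as readGeneModels()) from a
# single-exon gene spanning [start, end]
simpleGeneModels <- function(chrom, start, end, strand = "+",
                             geneId = "gTest") {
  span <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(span)$geneId <- geneId
  empty <- GRanges()
  mcols(empty)$geneId <- character(0)
  list(genes = span, exons = span, utr3 = empty, utr5 = empty,
       introns = empty)
}

# a cached small simulated cohort shared by several test files
.simCache <- new.env(parent = emptyenv())
sharedSmallCohort <- function() {
  if (!is.null(.simCache$truth)) return(.simCache$truth)
  dir <- file.path(tempdir(), "editscape-shared-sim")
  cfg <- simConfig(seed = 421L, nTumor = 3L, nControl = 2L, nChroms = 1L,
                   chromLength = 30000L, nGenes = 12L, nEditSites = 600L,
                   coverage = 35)
  .simCache$truth <- simulateCohort(cfg, dir)
  .simCache$truth
}

# two-sided Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration (the independent oracle used against stats::fisher.test)
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
rankSumOracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  ranks <- rank(vals)
  uObs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(vals), n1)
  us <- apply(combs, 2, function(idx)
    sum(rank(vals)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-9)
}

## profile holding named sites (catalog-level fixtures)
mkProfile <- function(id, pos = integer(0), gene = character(0),
                      region = "utr3", isA2I = TRUE, freq = 0.3,
                      chrom = "chr1") {
  n <- length(pos)
  gr <- GRanges(rep(chrom, n), IRanges(pos, pos), strand = rep("+", n))
  mcols(gr) <- S4Vectors::DataFrame(
    ref = rep("A", n), alt = rep("G", n),
    editedReads = rep(3L, n), coverage = rep(10L, n),
    frequency = rep_len(freq, n), isA2I = rep_len(isA2I, n),
    region = rep_len(region, n), geneId = rep_len(gene, n))
  new("SampleEditingProfile", sampleId = id, sites = gr)
}

## differential-editing fixture: one chromosome of adenosines
deTally <- function(gCounts, cov, id = "p") {
  # gCounts/cov: per-position G-read and total-read counts
  stopifnot(length(gCounts) == length(cov))
  ref <- readReference(writeTestRef(
    c(chrA = strrep("A", 20 * length(cov) + 40))))
  reads <- NULL
  for (i in seq_along(cov)) {
    p <- 20L * i
    if (cov[i] == 0) next
    seqs <- rep(strrep("A", 10), cov[i])
    if (gCounts[i] > 0)
      for (j in seq_len(gCounts[i])) substr(seqs[j], 10, 10) <- "G"
    reads <- rbind(reads, makeReads("chrA", rep(p - 9L, cov[i]), seqs,
                                    qname = sprintf("%s_%d_%d", id, i,
                                                    seq_len(cov[i]))))
  }
  pileupAlignments(reads, ref, sampleId = id)
}
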