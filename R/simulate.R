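#' @include io-formats.R
#' @importFrom stats rbinom rgamma rlnorm runif rbeta setNames
NULL

#' Configuration for the synthetic cohort simulator
#'
#' Returns the default simulation configuration, optionally overridden.  The
#' defaults describe a small tumor/control RNA-seq cohort with
#' ADAR1-style A-to-I editing: sites concentrated in Alu elements
#' (\code{aluSiteFraction}), dominated by the A-to-I type
#' (\code{a2gFraction}), with the characteristic preference for U as the 5'
#' and G as the 3' neighbor of the edited adenosine (\code{motifBias}), and
#' per-sample editing activity multipliers whose tumor mean is three times
#' the control mean (controls retain some editing, they are not
#' editing-free).  A configurable fraction of sites is shared between the
#' groups; the rest are tumor-exclusive, so recurrence filters have true
#' positives to find.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list with class checks applied; fields:
#' \describe{
#'   \item{seed}{integer RNG seed; the entire cohort is a deterministic
#'     function of the configuration.}
#'   \item{nTumor,nControl}{cohort sizes.}
#'   \item{nChroms,chromLength}{genome shape (bp).}
#'   \item{nGenes}{number of simulated genes, tiled across the genome.}
#'   \item{aluDensity}{fraction of gene territory covered by Alu elements.}
#'   \item{aluLength}{length of one Alu element (bp).}
#'   \item{nEditSites}{planted sites; \code{NA} plants an edit at every
#'     transcribed-strand adenosine inside Alu territory (used for
#'     editing-index calibration).}
#'   \item{aluSiteFraction}{probability a planted site lies in an Alu.}
#'   \item{a2gFraction}{probability a planted site is A-to-I (the rest are
#'     C-to-U type).}
#'   \item{motifBias}{list \code{five}/\code{three}: sampling weights over
#'     the transcribed-strand neighbor bases of planted adenosines.}
#'   \item{baseFreqShape}{Beta shape parameters of per-site baseline
#'     editing frequency.}
#'   \item{baseFreqConstant}{when non-NULL, all sites use this baseline
#'     frequency instead of Beta draws.}
#'   \item{tumorActivity,controlActivity,activityCv}{mean per-sample
#'     activity multipliers and their coefficient of variation (Gamma
#'     distributed; \code{activityCv = 0} gives constant multipliers).}
#'   \item{sharedSiteFraction}{fraction of sites editable in controls too.}
#'   \item{coverage}{mean read depth over gene territory.}
#'   \item{readLength}{read length (bp); reads are ungapped.}
#'   \item{seqErrorRate}{mean per-base sequencing error rate; 0 disables
#'     errors, otherwise must be >= 1e-4 (errors are phred-faithful draws
#'     from a high/low quality two-point mixture).}
#'   \item{nGermlineSnv,nSomaticSnv}{DNA variants per sample.}
#'   \item{somaticVaf}{fraction of overlapping reads carrying a somatic
#'     variant (germline variants appear in all reads).}
#'   \item{mapqLowFraction}{fraction of reads with low mapping quality.}
#'   \item{nSimpleRepeats,simpleRepeatLength}{homopolymer runs embedded in
#'     the reference and reported in the simple-repeat BED.}
#'   \item{utr3Fraction}{fraction of each gene forming its 3'UTR.}
#'   \item{nExonsRange}{min/max exons per gene.}
#'   \item{tpmLogSd}{log-scale SD of per-gene expression.}
#' }
#' @export
simConfig <- function(...) {
  cfg <- list(
    seed = 1L, nTumor = 10L, nControl = 4L,
    nChroms = 2L, chromLength = 50000L, nGenes = 40L,
    aluDensity = 0.25, aluLength = 300L,
    nEditSites = 1000L, aluSiteFraction = 0.9, a2gFraction = 0.9,
    motifBias = list(
      five = c(A = 0.15, C = 0.15, G = 0.20, T = 0.50),
      three = c(A = 0.15, C = 0.15, G = 0.50, T = 0.20)),
    baseFreqShape = c(2, 3), baseFreqConstant = NULL,
    tumorActivity = 1.2, controlActivity = 0.4, activityCv = 0.3,
    sharedSiteFraction = 0.5,
    coverage = 30, readLength = 100L, seqErrorRate = 0.001,
    nGermlineSnv = 200L, nSomaticSnv = 20L, somaticVaf = 0.4,
    mapqLowFraction = 0.03,
    nSimpleRepeats = 4L, simpleRepeatLength = 60L,
    utr3Fraction = 0.25, nExonsRange = c(2L, 4L),
    tpmLogSd = 0.7)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown simConfig field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  fr <- c("aluDensity", "aluSiteFraction", "a2gFraction",
          "sharedSiteFraction", "somaticVaf", "mapqLowFraction",
          "utr3Fraction")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0,1]")
  if (cfg$nTumor < 1 || cfg$nControl < 1)
    stop("nTumor and nControl must be >= 1")
  if (cfg$coverage <= 0) stop("coverage must be positive")
  if (cfg$seqErrorRate != 0 && cfg$seqErrorRate < 1e-4)
    stop("seqErrorRate must be 0 or >= 1e-4")
  invisible(TRUE)
}

#' Read / write a simulator configuration as YAML
#' @param path YAML file path.
#' @return [readSimConfig()] returns a full configuration (file values
#'   override defaults); [writeSimConfig()] returns \code{path} invisibly.
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$motifBias))
    vals$motifBias <- lapply(vals$motifBias, unlist)
  do.call(simConfig, vals)
}

#' @rdname readSimConfig
#' @param config a list from [simConfig()].
#' @export
writeSimConfig <- function(config, path) {
  # named atomic vectors must become YAML maps, not bare sequences
  if (!is.null(config$motifBias))
    config$motifBias <- lapply(config$motifBias, as.list)
  yaml::write_yaml(config, path)
  invisible(path)
}

## ---- internal genome layout ----

.layoutGenome <- function(cfg) {
  chromNames <- sprintf("chr%d", seq_len(cfg$nChroms))
  seqs <- lapply(chromNames, function(cn)
    sample(c("A", "C", "G", "T"), cfg$chromLength, replace = TRUE))
  names(seqs) <- chromNames

  # simple repeats: homopolymer runs embedded into the reference
  repeats <- NULL
  if (cfg$nSimpleRepeats > 0) {
    rl <- list()
    for (i in seq_len(cfg$nSimpleRepeats)) {
      cn <- sample(chromNames, 1)
      st <- sample.int(cfg$chromLength - cfg$simpleRepeatLength - 10L, 1)
      base <- sample(c("A", "C", "G", "T"), 1)
      seqs[[cn]][st:(st + cfg$simpleRepeatLength - 1L)] <- base
      rl[[i]] <- data.frame(chrom = cn, start = st,
                            end = st + cfg$simpleRepeatLength - 1L)
    }
    repeats <- do.call(rbind, rl)
  }

  # genes tiled chromosome by chromosome inside fixed-size units
  perChrom <- diff(floor(seq(0, cfg$nGenes, length.out = cfg$nChroms + 1)))
  genes <- list(); exons <- list(); utr3 <- list(); gi <- 0L
  for (ci in seq_len(cfg$nChroms)) {
    ng <- perChrom[ci]
    if (ng == 0) next
    unit <- (cfg$chromLength - 200L) %/% ng
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      geneLen <- floor(unit * runif(1, 0.60, 0.85))
      offset <- sample.int(max(unit - geneLen - 20L, 1L), 1)
      gStart <- 100L + (k - 1L) * unit + offset
      gEnd <- gStart + geneLen - 1L
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("g%04d", gi)
      nEx <- sample(seq(cfg$nExonsRange[1], cfg$nExonsRange[2]), 1)
      props <- runif(2L * nEx - 1L, 0.7, 1.3)
      segLen <- floor(props / sum(props) * geneLen)
      segLen[1] <- segLen[1] + geneLen - sum(segLen)
      bounds <- gStart + cumsum(c(0L, segLen))
      exIdx <- seq(1L, 2L * nEx - 1L, by = 2L)
      exDf <- data.frame(geneId = gid, chrom = chromNames[ci],
                         start = bounds[exIdx],
                         end = bounds[exIdx + 1L] - 1L, strand = strand)
      termExon <- if (strand == "+") nrow(exDf) else 1L
      termLen <- exDf$end[termExon] - exDf$start[termExon] + 1L
      utrLen <- min(floor(0.8 * termLen),
                    max(floor(cfg$utr3Fraction * geneLen), 30L))
      u <- if (strand == "+")
        data.frame(geneId = gid, chrom = chromNames[ci],
                   start = exDf$end[termExon] - utrLen + 1L,
                   end = exDf$end[termExon], strand = strand)
      else
        data.frame(geneId = gid, chrom = chromNames[ci],
                   start = exDf$start[termExon],
                   end = exDf$start[termExon] + utrLen - 1L, strand = strand)
      genes[[gi]] <- data.frame(geneId = gid, chrom = chromNames[ci],
                                start = gStart, end = gEnd, strand = strand)
      exons[[gi]] <- exDf
      utr3[[gi]] <- u
    }
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  utr3 <- do.call(rbind, utr3)

  # Alu elements: non-overlapping fixed-length slots inside each gene
  alu <- list()
  for (i in seq_len(nrow(genes))) {
    gLen <- genes$end[i] - genes$start[i] + 1L
    slots <- gLen %/% cfg$aluLength
    nAlu <- min(round(cfg$aluDensity * gLen / cfg$aluLength), slots)
    if (nAlu < 1) next
    chosen <- sort(sample.int(slots, nAlu))
    alu[[i]] <- data.frame(
      chrom = genes$chrom[i],
      start = genes$start[i] + (chosen - 1L) * cfg$aluLength,
      end = genes$start[i] + chosen * cfg$aluLength - 1L,
      strand = genes$strand[i])
  }
  alu <- do.call(rbind, alu)

  list(seqs = seqs, chromNames = chromNames, genes = genes, exons = exons,
       utr3 = utr3, alu = alu, repeats = repeats)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Candidate transcribed-strand positions of a given transcribed base within
# the genes, with Alu membership and motif weights for adenosines.
.candidatePositions <- function(layout, transcribedBase, cfg) {
  out <- list()
  for (i in seq_len(nrow(layout$genes))) {
    g <- layout$genes[i, ]
    chromSeq <- layout$seqs[[g$chrom]]
    span <- (g$start + 1L):(g$end - 1L)
    fwdBase <- if (g$strand == "+") transcribedBase else
      .complement[[transcribedBase]]
    hits <- span[chromSeq[span] == fwdBase]
    if (!length(hits)) next
    if (g$strand == "+") {
      five <- chromSeq[hits - 1L]; three <- chromSeq[hits + 1L]
    } else {
      five <- .complement[chromSeq[hits + 1L]]
      three <- .complement[chromSeq[hits - 1L]]
    }
    out[[i]] <- data.frame(chrom = g$chrom, pos = hits, strand = g$strand,
                           geneId = g$geneId, five = unname(five),
                           three = unname(three), stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, out)
  if (is.null(cand)) return(cand)
  if (!is.null(layout$repeats)) {
    inRep <- rep(FALSE, nrow(cand))
    for (j in seq_len(nrow(layout$repeats)))
      inRep <- inRep | (cand$chrom == layout$repeats$chrom[j] &
                        cand$pos >= layout$repeats$start[j] &
                        cand$pos <= layout$repeats$end[j])
    cand <- cand[!inRep, , drop = FALSE]
  }
  inAlu <- rep(FALSE, nrow(cand))
  for (j in seq_len(nrow(layout$alu)))
    inAlu <- inAlu | (cand$chrom == layout$alu$chrom[j] &
                      cand$pos >= layout$alu$start[j] &
                      cand$pos <= layout$alu$end[j])
  cand$alu <- inAlu
  cand$w <- cfg$motifBias$five[cand$five] * cfg$motifBias$three[cand$three]
  cand
}

.sampleSites <- function(cand, n, weighted = TRUE) {
  if (n == 0) return(cand[0, , drop = FALSE])
  if (n > nrow(cand))
    stop("requested ", n, " sites but only ", nrow(cand),
         " eligible positions are available")
  idx <- sample.int(nrow(cand), n,
                    prob = if (weighted) cand$w else NULL)
  cand[idx, , drop = FALSE]
}

## ---- the simulator ----

#' Simulate a tumor/control RNA-seq cohort with planted A-to-I editing
#'
#' Writes a complete synthetic data set to \code{outDir}: reference FASTA,
#' gene-model GTF (exon and three_prime_utr features), Alu and
#' simple-repeat BEDs, one VCF of DNA variants and one coordinate-sorted
#' SAM of ungapped fixed-length reads per sample, a TPM expression matrix,
#' and machine-readable truth tables.  Reads are drawn over gene territory
#' in proportion to expression; each read picks up the sample's germline
#' variants (all copies), somatic variants (a configured fraction of
#' copies), planted edits (per-site per-sample Bernoulli at the true
#' frequency, strand-aware: A-to-I on a minus-strand gene appears as T-to-C
#' on the forward reference), and finally sequencing errors whose rate per
#' base is phred-faithful to the emitted quality string.
#'
#' @param config list from [simConfig()].
#' @param outDir output directory (created if needed).
#' @return a [SimTruth-class] object.
#' @seealso [simConfig()], [expressionFromTruth()], [readSimTruth()]
#' @export
simulateCohort <- function(config, outDir) {
  .validateSimConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  layout <- .layoutGenome(config)

  ## --- planted sites ---
  candA <- .candidatePositions(layout, "A", config)
  if (is.na(config$nEditSites)) {
    sites <- candA[candA$alu, , drop = FALSE]
    sites$type <- "a2i"
  } else {
    nA2I <- round(config$nEditSites * config$a2gFraction)
    nOther <- config$nEditSites - nA2I
    nAlu <- round(nA2I * config$aluSiteFraction)
    sA <- rbind(.sampleSites(candA[candA$alu, , drop = FALSE], nAlu),
                .sampleSites(candA[!candA$alu, , drop = FALSE], nA2I - nAlu))
    sA$type <- "a2i"
    sites <- sA
    if (nOther > 0) {
      candC <- .candidatePositions(layout, "C", config)
      candC <- candC[!candC$pos %in% sA$pos | !candC$chrom %in% sA$chrom, ,
                     drop = FALSE]
      sC <- .sampleSites(candC, nOther, weighted = FALSE)
      sC$type <- "c2u"
      sites <- rbind(sA, sC)
    }
  }
  rownames(sites) <- NULL
  # forward-strand ref/alt representation of the transcribed-strand edit
  sites$refFwd <- ifelse(sites$type == "a2i",
                         ifelse(sites$strand == "+", "A", "T"),
                         ifelse(sites$strand == "+", "C", "G"))
  sites$altFwd <- ifelse(sites$type == "a2i",
                         ifelse(sites$strand == "+", "G", "C"),
                         ifelse(sites$strand == "+", "T", "A"))
  sites$baseFreq <- if (!is.null(config$baseFreqConstant))
    rep(config$baseFreqConstant, nrow(sites)) else
    rbeta(nrow(sites), config$baseFreqShape[1], config$baseFreqShape[2])
  sites$shared <- runif(nrow(sites)) < config$sharedSiteFraction
  # region class from the layout itself
  reg <- rep("intron", nrow(sites))
  ovl <- function(df, tab) {
    hit <- rep(FALSE, nrow(df))
    for (j in seq_len(nrow(tab)))
      hit <- hit | (df$chrom == tab$chrom[j] & df$pos >= tab$start[j] &
                    df$pos <= tab$end[j])
    hit
  }
  reg[ovl(sites, layout$exons)] <- "exon_cds"
  reg[ovl(sites, layout$utr3)] <- "utr3"
  sites$region <- reg

  ## --- samples ---
  sampleIds <- c(sprintf("tumor%02d", seq_len(config$nTumor)),
                 sprintf("control%02d", seq_len(config$nControl)))
  groups <- c(rep("tumor", config$nTumor), rep("control", config$nControl))
  actMean <- ifelse(groups == "tumor", config$tumorActivity,
                    config$controlActivity)
  activity <- if (config$activityCv > 0) {
    shp <- 1 / config$activityCv^2
    rgamma(length(actMean), shape = shp, scale = actMean / shp)
  } else actMean
  samples <- data.frame(sampleId = sampleIds, group = groups,
                        activity = activity, stringsAsFactors = FALSE)

  # per-site per-sample true frequency
  freqMat <- matrix(0, nrow(sites), length(sampleIds),
                    dimnames = list(NULL, sampleIds))
  for (s in seq_along(sampleIds)) {
    f <- pmin(0.95, sites$baseFreq * activity[s])
    if (groups[s] == "control") f[!sites$shared] <- 0
    freqMat[, s] <- f
  }

  ## --- expression ---
  geneMeans <- rlnorm(nrow(layout$genes), meanlog = 3,
                      sdlog = config$tpmLogSd)
  expr <- matrix(0, nrow(layout$genes), length(sampleIds),
                 dimnames = list(layout$genes$geneId, sampleIds))
  for (s in seq_along(sampleIds)) {
    raw <- geneMeans * rlnorm(nrow(layout$genes), 0, 0.3)
    expr[, s] <- raw / sum(raw) * 1e6
  }

  ## --- DNA variants (positions never collide with planted sites) ---
  siteKey <- paste(sites$chrom, sites$pos)
  variants <- vector("list", length(sampleIds))
  emptyVariants <- data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              source = character(0),
                              stringsAsFactors = FALSE)
  for (s in seq_along(sampleIds)) {
    nv <- config$nGermlineSnv + config$nSomaticSnv
    if (nv == 0L) { variants[[s]] <- emptyVariants; next }
    vl <- list()
    got <- 0L
    while (got < nv) {
      cn <- sample(layout$chromNames, 1)
      p <- sample.int(config$chromLength - 2L, 1) + 1L
      if (paste(cn, p) %in% siteKey) next
      rb <- layout$seqs[[cn]][p]
      if (rb == "N") next
      got <- got + 1L
      vl[[got]] <- data.frame(chrom = cn, pos = p, ref = rb,
                              alt = sample(setdiff(c("A", "C", "G", "T"),
                                                   rb), 1))
    }
    v <- do.call(rbind, vl)
    v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
    v$source <- c(rep("germline", min(config$nGermlineSnv, nrow(v))),
                  rep("somatic",
                      max(nrow(v) - config$nGermlineSnv, 0L)))
    variants[[s]] <- v[order(match(v$chrom, layout$chromNames), v$pos), ,
                       drop = FALSE]
  }

  ## --- write static files ---
  paths <- list(
    fasta = file.path(outDir, "reference.fa"),
    gtf = file.path(outDir, "genes.gtf"),
    aluBed = file.path(outDir, "alu.bed"),
    repeatsBed = file.path(outDir, "repeats.bed"),
    expression = file.path(outDir, "expression.tsv"),
    truthSites = file.path(outDir, "truth_sites.tsv"),
    truthSamples = file.path(outDir, "truth_samples.tsv"))
  refSet <- DNAStringSet(vapply(layout$seqs, paste, character(1),
                                collapse = ""))
  writeXStringSet(refSet, paths$fasta, width = 80L)
  .writeGtf(layout, paths$gtf)
  .writeBedDf(cbind(layout$alu,
                    name = sprintf("alu%04d", seq_len(nrow(layout$alu)))),
              paths$aluBed)
  if (!is.null(layout$repeats))
    .writeBedDf(cbind(layout$repeats,
                      name = sprintf("rep%02d",
                                     seq_len(nrow(layout$repeats))),
                      strand = "."), paths$repeatsBed)
  else writeLines(character(0), paths$repeatsBed)

  ## --- reads + per-sample files ---
  genicBp <- sum(layout$genes$end - layout$genes$start + 1L)
  nReads <- round(config$coverage * genicBp / config$readLength)
  samPaths <- vcfPaths <- character(length(sampleIds))
  for (s in seq_along(sampleIds)) {
    samPaths[s] <- file.path(outDir, paste0(sampleIds[s], ".sam"))
    vcfPaths[s] <- file.path(outDir, paste0(sampleIds[s], ".vcf"))
    .writeVcf(variants[[s]], layout, vcfPaths[s])
    .simulateSampleReads(layout, config, sites, freqMat[, s],
                         variants[[s]], expr[, s], nReads,
                         sampleIds[s], samPaths[s])
  }
  paths$sam <- setNames(as.list(samPaths), sampleIds)
  paths$vcf <- setNames(as.list(vcfPaths), sampleIds)

  ## --- truth tables + expression matrix ---
  truthSites <- cbind(
    sites[, c("chrom", "pos", "strand", "geneId", "type", "refFwd",
              "altFwd", "alu", "region", "baseFreq", "shared")],
    setNames(as.data.frame(freqMat), paste0("freq_", sampleIds)))
  .writeTsv(truthSites, paths$truthSites)
  .writeTsv(samples, paths$truthSamples)
  exprDf <- data.frame(geneId = rownames(expr),
                       as.data.frame(expr, check.names = FALSE),
                       check.names = FALSE)
  .writeTsv(exprDf, paths$expression)

  new("SimTruth", sites = truthSites, samples = samples, expression = expr,
      paths = paths, config = config)
}

## per-sample read generation (one ungapped SAM, coordinate-sorted)
.simulateSampleReads <- function(layout, cfg, sites, siteFreq, variants,
                                 tpm, nReads, sampleId, samPath) {
  L <- cfg$readLength
  genes <- layout$genes
  gLen <- genes$end - genes$start + 1L
  prob <- tpm * gLen
  geneIdx <- sample.int(nrow(genes), nReads, replace = TRUE,
                        prob = prob / sum(prob))
  maxStart <- pmax(genes$end[geneIdx] - L + 1L, genes$start[geneIdx])
  starts <- genes$start[geneIdx] +
    floor(runif(nReads) * (maxStart - genes$start[geneIdx] + 1L))
  starts <- pmin(starts, cfg$chromLength - L + 1L)
  chrom <- genes$chrom[geneIdx]

  con <- file(samPath, "w")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", layout$chromNames,
                       cfg$chromLength)), con)
  qHi <- 40L; qLo <- 13L
  pHi <- 10^(-qHi / 10); pLo <- 10^(-qLo / 10)
  fLow <- if (cfg$seqErrorRate == 0) 0 else
    min(1, max(0, (cfg$seqErrorRate - pHi) / (pLo - pHi)))
  readNo <- 0L
  for (cn in layout$chromNames) {
    sel <- which(chrom == cn)
    if (!length(sel)) next
    st <- sort(starts[sel])
    n <- length(st)
    chromSeq <- Biostrings::DNAString(paste(layout$seqs[[cn]],
                                            collapse = ""))
    big <- unlist(Biostrings::extractAt(chromSeq, IRanges(st, width = L)))

    readRanges <- IRanges(st, width = L)
    gpos <- integer(0); glet <- character(0)
    addHits <- function(pos, alt, keepProb) {
      ov <- IRanges::findOverlaps(IRanges(pos, width = 1L), readRanges)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      if (!is.null(keepProb)) {
        keep <- runif(length(qh)) < keepProb[qh]
        qh <- qh[keep]; sh <- sh[keep]
      }
      list(g = (sh - 1L) * L + (pos[qh] - st[sh] + 1L), l = alt[qh])
    }
    v <- variants[variants$chrom == cn, , drop = FALSE]
    if (nrow(v)) {
      keepProb <- ifelse(v$source == "germline", 1, cfg$somaticVaf)
      h <- addHits(v$pos, v$alt, keepProb)
      gpos <- c(gpos, h$g); glet <- c(glet, h$l)
    }
    ss <- sites[sites$chrom == cn, , drop = FALSE]
    sf <- siteFreq[sites$chrom == cn]
    if (nrow(ss)) {
      h <- addHits(ss$pos, ss$altFwd, sf)
      gpos <- c(gpos, h$g); glet <- c(glet, h$l)
    }
    if (length(gpos)) {
      keep <- !duplicated(gpos, fromLast = TRUE)
      big <- replaceLetterAt(big, gpos[keep], glet[keep])
    }

    # phred-faithful sequencing errors on a two-point quality mixture
    total <- n * L
    qualChar <- rep(rawToChar(as.raw(qHi + 33L)), 1L)
    chars <- rep.int(qualChar, total)
    if (fLow > 0) {
      nLow <- rbinom(1, total, fLow)
      lowPos <- if (nLow) sample.int(total, nLow) else integer(0)
      chars[lowPos] <- rawToChar(as.raw(qLo + 33L))
      errLow <- lowPos[runif(length(lowPos)) < pLo]
      nErrHi <- rbinom(1, total, pHi)
      errHi <- if (nErrHi) sample.int(total, nErrHi) else integer(0)
      errHi <- setdiff(errHi, lowPos)
      errPos <- c(errLow, errHi)
      if (length(errPos)) {
        cur <- as.character(Biostrings::extractAt(
          big, IRanges(errPos, width = 1L)))
        newBase <- vapply(cur, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        big <- replaceLetterAt(big, errPos, unname(newBase))
      }
    }

    readSeq <- as.character(Biostrings::DNAStringSet(
      Biostrings::Views(big, IRanges((seq_len(n) - 1L) * L + 1L,
                                     width = L))))
    quals <- do.call(paste0,
                     lapply(seq_len(L), function(j)
                       chars[(seq_len(n) - 1L) * L + j]))
    mapq <- ifelse(runif(n) < cfg$mapqLowFraction, 10L, 60L)
    flag <- ifelse(runif(n) < 0.5, 16L, 0L)
    lines <- sprintf("%s_r%07d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                     sampleId, readNo + seq_len(n), flag, cn, st, mapq, L,
                     readSeq, quals)
    writeLines(lines, con)
    readNo <- readNo + n
  }
  close(con)
  invisible(samPath)
}

.writeGtf <- function(layout, path) {
  att <- function(gid) sprintf('gene_id "%s"; transcript_id "%s.t1";',
                               gid, gid)
  mk <- function(df, type)
    sprintf("%s\teditscape_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$chrom, type, df$start, df$end, df$strand, att(df$geneId))
  writeLines(c(mk(layout$genes, "gene"), mk(layout$exons, "exon"),
               mk(layout$utr3, "three_prime_utr")), path)
  invisible(path)
}

.writeBedDf <- function(df, path) {
  strand <- if ("strand" %in% colnames(df)) df$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom, df$start - 1L,
                     df$end, df$name, strand), path)
  invisible(path)
}

.writeVcf <- function(variants, layout, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", layout$chromNames,
                   length(layout$seqs[[1]])),
           paste0("##INFO=<ID=SRC,Number=1,Type=String,",
                  'Description="Variant origin (germline or somatic)">'),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSRC=%s", variants$chrom,
                  variants$pos, variants$ref, variants$alt,
                  variants$source)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract (and optionally write) the true TPM matrix of a simulated cohort
#'
#' @param simTruth a [SimTruth-class] from [simulateCohort()].
#' @param path optional TSV output path (genes as rows, samples as columns;
#'   each column sums to 1e6).
#' @return the numeric TPM matrix.
#' @export
expressionFromTruth <- function(simTruth, path = NULL) {
  m <- simTruth@expression
  if (!is.null(path)) {
    df <- data.frame(geneId = rownames(m),
                     as.data.frame(m, check.names = FALSE),
                     check.names = FALSE)
    .writeTsv(df, path)
  }
  m
}

#' Read an expression TSV written by the simulator
#' @param path TSV path with a \code{geneId} column.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Re-read truth tables written by [simulateCohort()]
#' @param dir the simulator output directory.
#' @return list with \code{sites} and \code{samples} data frames.
#' @export
readSimTruth <- function(dir) {
  list(sites = read.table(file.path(dir, "truth_sites.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE),
       samples = read.table(file.path(dir, "truth_samples.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE))
}
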