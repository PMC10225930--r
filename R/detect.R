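#' @include io-formats.R
#' @importFrom stats binom.test glm predict plogis sd na.omit
NULL

#' Detection thresholds for editing-site calling
#'
#' Defaults follow common practice for RNA-editing candidate extraction:
#' a site needs at least \code{minAltReads} alternate observations passing
#' the base/mapping quality filters, \code{minCoverage} filtered coverage,
#' at least one alternate observation at least \code{endDistance} bp from
#' the raw read ends (mismatches confined to read ends are typical
#' artifacts), and must not show significant read-strand bias (two-sided
#' Fisher's exact test of alternate versus reference reads by strand, at
#' level \code{biasAlpha}).  Base/mapping quality cutoffs reuse
#' the package-wide read filters (phred 20 / 30).
#'
#' @param ... named overrides.
#' @return named list of thresholds.
#' @export
detectConfig <- function(...) {
  cfg <- list(minAltReads = 2L, minCoverage = 10L, qBase = 20L, qMap = 30L,
              endDistance = 5L, biasAlpha = 0.01,
              excludeSimpleRepeats = FALSE, requireDna = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown detectConfig field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Call candidate RNA editing sites from a pileup tally
#'
#' Applies the filter cascade to every mismatching position: (i) at least
#' \code{minAltReads} alternate observations with base quality >=
#' \code{qBase} and mapping quality >= \code{qMap}, and filtered coverage
#' >= \code{minCoverage}; (ii) the position is absent from the sample's
#' matched-DNA variant table (skipped with a warning when no table is
#' supplied, unless \code{requireDna}); (iii) at least one alternate
#' observation lies \code{endDistance} bp or more from the raw read ends;
#' (iv) no significant read-strand bias of the alternate observations; (v)
#' optionally, exclusion of simple-repeat regions.  Retained sites carry
#' their full feature vector, gene/region annotation and strand-aware
#' A-to-I status (reference A with G reads on plus-strand genes, reference
#' T with C reads on minus-strand genes).  Sites inside genes on both
#' strands are flagged ambiguous and get \code{NA} A-to-I status.
#'
#' @param tally a [PileupTally-class].
#' @param reference \code{DNAStringSet} from [readReference()].
#' @param dnaVariants optional data.frame from [readDnaVariants()].
#' @param geneModels optional list from [readGeneModels()].
#' @param aluIntervals,repeatIntervals optional \code{GRanges}.
#' @param config list from [detectConfig()].
#' @return \code{GRanges} of candidate sites with metadata columns
#'   \code{ref}, \code{alt}, \code{editedReads}, \code{coverage},
#'   \code{frequency}, \code{meanBq}, \code{meanMq}, \code{minDistEnd},
#'   \code{strandBiasP}, \code{inSimpleRepeat}, \code{alu}, \code{isA2I},
#'   \code{fivePrime}, \code{threePrime}, \code{region}, \code{geneId},
#'   \code{ambiguous}.  \code{metadata()} records filter attrition and
#'   whether the DNA filter ran.
#' @export
callCandidateSites <- function(tally, reference, dnaVariants = NULL,
                               geneModels = NULL, aluIntervals = NULL,
                               repeatIntervals = NULL,
                               config = detectConfig()) {
  mism <- mismatchObs(tally)
  counts <- tallyCounts(tally)
  empty <- GRanges()
  attrition <- c(rawCandidates = 0L, afterSupport = 0L, afterDna = 0L,
                 afterEndDistance = 0L, afterStrandBias = 0L,
                 afterRepeats = 0L)
  if (!nrow(mism)) {
    S4Vectors::metadata(empty) <- list(dnaFilterApplied = !is.null(dnaVariants),
                                       attrition = attrition)
    return(empty)
  }
  ok <- mism$bq >= config$qBase & mism$mq >= config$qMap
  fm <- mism[ok, , drop = FALSE]
  key <- paste(fm$chrom, fm$pos, fm$base, sep = ":")
  grp <- split(seq_len(nrow(fm)), key)
  cand <- data.frame(
    key = names(grp),
    altReads = lengths(grp),
    meanBq = vapply(grp, function(i) mean(fm$bq[i]), numeric(1)),
    meanMq = vapply(grp, function(i) mean(fm$mq[i]), numeric(1)),
    minDistEnd = vapply(grp, function(i) min(fm$distEnd[i]), numeric(1)),
    maxDistEnd = vapply(grp, function(i) max(fm$distEnd[i]), numeric(1)),
    altFwd = vapply(grp, function(i) sum(!fm$rev[i]), numeric(1)),
    stringsAsFactors = FALSE)
  parts <- strsplit(cand$key, ":", fixed = TRUE)
  cand$chrom <- vapply(parts, `[`, character(1), 1)
  cand$pos <- as.integer(vapply(parts, `[`, character(1), 2))
  cand$alt <- vapply(parts, `[`, character(1), 3)
  attrition["rawCandidates"] <- nrow(cand)

  ck <- paste(counts$chrom, counts$pos)
  idx <- match(paste(cand$chrom, cand$pos), ck)
  cand$coverage <- with(counts[idx, ], fA + fC + fG + fT)
  cand$ref <- counts$ref[idx]
  cand$refFwdN <- counts$refFwd[idx]
  cand$refRevN <- counts$refRev[idx]
  cand$frequency <- cand$altReads / cand$coverage

  # (i) support and coverage
  cand <- cand[cand$altReads >= config$minAltReads &
               cand$coverage >= config$minCoverage, , drop = FALSE]
  attrition["afterSupport"] <- nrow(cand)

  # (ii) matched-DNA exclusion
  dnaApplied <- !is.null(dnaVariants)
  if (!dnaApplied) {
    if (isTRUE(config$requireDna))
      stop("matched-DNA variants required but none supplied")
    warning("no DNA variant table supplied; ",
            "genomic-variant filtering skipped")
  } else if (nrow(cand)) {
    vkey <- paste(dnaVariants$chrom, dnaVariants$pos)
    cand <- cand[!paste(cand$chrom, cand$pos) %in% vkey, , drop = FALSE]
  }
  attrition["afterDna"] <- nrow(cand)

  # (iii) end-distance: >= 1 alternate observation away from read ends
  cand <- cand[cand$maxDistEnd >= config$endDistance, , drop = FALSE]
  attrition["afterEndDistance"] <- nrow(cand)

  # (iv) read-strand bias: exact test of the alt-read strand composition
  # against the reference-read strand composition (2x2 Fisher, so a noisy
  # reference-strand estimate at high editing frequency is not treated as
  # a known proportion)
  if (nrow(cand)) {
    biasP <- vapply(seq_len(nrow(cand)), function(i)
      stats::fisher.test(matrix(c(cand$refFwdN[i], cand$refRevN[i],
                                  cand$altFwd[i],
                                  cand$altReads[i] - cand$altFwd[i]),
                                nrow = 2))$p.value, numeric(1))
    cand$strandBiasP <- biasP
    cand <- cand[cand$strandBiasP >= config$biasAlpha, , drop = FALSE]
  } else cand$strandBiasP <- numeric(0)
  attrition["afterStrandBias"] <- nrow(cand)

  # (v) simple repeats
  if (nrow(cand) && !is.null(repeatIntervals)) {
    cand$inSimpleRepeat <- IRanges::overlapsAny(
      GRanges(cand$chrom, IRanges(cand$pos, cand$pos)), repeatIntervals,
      ignore.strand = TRUE)
    if (isTRUE(config$excludeSimpleRepeats))
      cand <- cand[!cand$inSimpleRepeat, , drop = FALSE]
  } else cand$inSimpleRepeat <- rep(FALSE, nrow(cand))
  attrition["afterRepeats"] <- nrow(cand)

  if (!nrow(cand)) {
    S4Vectors::metadata(empty) <- list(dnaFilterApplied = dnaApplied,
                                       attrition = attrition)
    return(empty)
  }

  # annotation: gene, region, transcribed strand, Alu, motif context
  if (!is.null(geneModels)) {
    ann <- classifyRegions(geneModels, cand$chrom, cand$pos)
  } else {
    ann <- data.frame(region = NA_character_, geneId = NA_character_,
                      allGeneIds = NA_character_, strand = ".",
                      ambiguous = FALSE)[rep(1, nrow(cand)), ]
  }
  cand$alu <- if (!is.null(aluIntervals))
    IRanges::overlapsAny(GRanges(cand$chrom, IRanges(cand$pos, cand$pos)),
                         aluIntervals, ignore.strand = TRUE)
  else rep(FALSE, nrow(cand))

  isA2I <- ifelse(ann$strand == "+", cand$ref == "A" & cand$alt == "G",
           ifelse(ann$strand == "-", cand$ref == "T" & cand$alt == "C",
                  (cand$ref == "A" & cand$alt == "G") |
                  (cand$ref == "T" & cand$alt == "C")))
  isA2I[ann$ambiguous] <- NA

  neighbors <- t(vapply(seq_len(nrow(cand)), function(i) {
    chromLen <- length(reference[[cand$chrom[i]]])
    p <- cand$pos[i]
    left <- if (p > 1) fetchSequence(reference, cand$chrom[i], p - 1, p - 1)
            else "N"
    right <- if (p < chromLen)
      fetchSequence(reference, cand$chrom[i], p + 1, p + 1) else "N"
    if (identical(ann$strand[i], "-"))
      c(unname(.complement[right]), unname(.complement[left]))
    else c(left, right)
  }, character(2)))

  gr <- GRanges(cand$chrom, IRanges(cand$pos, cand$pos),
                strand = ifelse(ann$strand %in% c("+", "-"), ann$strand,
                                "*"))
  mcols(gr) <- DataFrame(
    ref = cand$ref, alt = cand$alt, editedReads = cand$altReads,
    coverage = cand$coverage, frequency = cand$frequency,
    meanBq = cand$meanBq, meanMq = cand$meanMq,
    minDistEnd = cand$minDistEnd, strandBiasP = cand$strandBiasP,
    inSimpleRepeat = cand$inSimpleRepeat, alu = cand$alu, isA2I = isA2I,
    fivePrime = neighbors[, 1], threePrime = neighbors[, 2],
    region = ann$region, geneId = ann$geneId,
    allGeneIds = ann$allGeneIds, ambiguous = ann$ambiguous)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr) <- list(dnaFilterApplied = dnaApplied,
                                  attrition = attrition)
  gr
}

#' Numeric feature matrix of candidate sites
#'
#' Encodes each site's feature vector for the logistic classifier:
#' alternate-read support, coverage, putative frequency, mean base and
#' mapping quality of alternate observations, minimum raw-read-end
#' distance, strand-bias p-value, simple-repeat and Alu membership, A-to-I
#' type, and indicators for the canonical ADAR motif context (5' U, 3' G on
#' the transcribed strand).
#'
#' @param sites \code{GRanges} from [callCandidateSites()].
#' @return numeric matrix with one row per site.
#' @export
siteFeatureMatrix <- function(sites) {
  m <- mcols(sites)
  out <- cbind(
    altReads = m$editedReads, coverage = m$coverage,
    frequency = m$frequency, meanBq = m$meanBq, meanMq = m$meanMq,
    minDistEnd = m$minDistEnd, strandBiasP = m$strandBiasP,
    inSimpleRepeat = as.numeric(m$inSimpleRepeat),
    inAlu = as.numeric(m$alu),
    isA2I = ifelse(is.na(m$isA2I), 0, as.numeric(m$isA2I)),
    fiveIsU = as.numeric(m$fivePrime == "T"),
    threeIsG = as.numeric(m$threePrime == "G"))
  rownames(out) <- NULL
  out
}

#' Train the logistic editing-site classifier
#'
#' Fits a logistic regression on standardized site features against
#' known labels (planted sites versus artifact candidates on simulated
#' data), using a stratified 50/50 train/held-out split, and reports the
#' held-out AUC.
#'
#' @param features numeric matrix from [siteFeatureMatrix()].
#' @param labels 0/1 vector (1 = authentic editing site).
#' @return an object of class \code{siteClassifier}: list with elements
#'   \code{coef}, \code{center}, \code{scale}, \code{auc},
#'   \code{featureNames}.
#' @export
trainSiteClassifier <- function(features, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class")
  if (min(table(labels)) < 50)
    warning("fewer than 50 examples in the smaller class; ",
            "classifier may be unstable")
  stopifnot(nrow(features) == length(labels))
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(features, 2, center), 2, scale, "/")

  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  train <- c(idx1[seq_len(ceiling(length(idx1) / 2))],
             idx0[seq_len(ceiling(length(idx0) / 2))])
  test <- setdiff(seq_along(labels), train)

  df <- data.frame(y = labels, X)
  fit <- suppressWarnings(glm(y ~ ., data = df[train, , drop = FALSE],
                              family = "binomial"))
  coefs <- stats::coef(fit)
  coefs[is.na(coefs)] <- 0
  predTest <- plogis(cbind(1, X[test, , drop = FALSE]) %*% coefs)
  aucVal <- if (length(unique(labels[test])) == 2)
    as.numeric(pROC::auc(pROC::roc(labels[test], as.numeric(predTest),
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  else NA_real_
  structure(list(coef = coefs, center = center, scale = scale,
                 auc = aucVal, featureNames = colnames(features)),
            class = "siteClassifier")
}

#' @export
print.siteClassifier <- function(x, ...) {
  cat("siteClassifier:", length(x$featureNames), "features, held-out AUC",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Score sites with a trained classifier and filter by confidence
#'
#' @param sites \code{GRanges} from [callCandidateSites()].
#' @param classifier object from [trainSiteClassifier()].
#' @param threshold confidence cutoff in [0,1]; sites with confidence >=
#'   \code{threshold} are retained.
#' @return the retained sites with a \code{confidence} metadata column.
#' @export
scoreSites <- function(sites, classifier, threshold = 0.9) {
  if (!length(sites)) return(sites)
  X <- siteFeatureMatrix(sites)
  if (!identical(colnames(X), classifier$featureNames))
    stop("feature/weight mismatch: classifier was trained on features (",
         paste(classifier$featureNames, collapse = ", "), ")")
  Xs <- sweep(sweep(X, 2, classifier$center), 2, classifier$scale, "/")
  conf <- as.numeric(plogis(cbind(1, Xs) %*% classifier$coef))
  mcols(sites)$confidence <- conf
  sites[conf >= threshold]
}
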