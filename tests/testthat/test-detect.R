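## a reusable hand fixture: reference-A position covered by ref and alt reads
refA <- function() {
  # chr1: all C except an A at position 30
  s <- strrep("C", 100)
  substr(s, 30, 30) <- "A"
  readReference(writeTestRef(c(chr1 = s)))
}
altRead <- function(start, len = 60) {
  s <- strrep("C", len)
  substr(s, 30 - start + 1, 30 - start + 1) <- "G"
  s
}
refRead <- function(start, len = 60) {
  s <- strrep("C", len)
  substr(s, 30 - start + 1, 30 - start + 1) <- "A"
  s
}

test_that("a supported mid-read A-to-G candidate is called with its features", {
  ref <- refA()
  reads <- rbind(makeReads("chr1", rep(1L, 7), refRead(1)),
                 makeReads("chr1", rep(1L, 3), altRead(1)))
  tly <- pileupAlignments(reads, ref, sampleId = "s")
  gm <- simpleGeneModels("chr1", 1, 100, "+")
  sites <- callCandidateSites(tly, ref, dnaVariants = data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), source = character(0)), geneModels = gm)
  expect_equal(length(sites), 1)
  m <- mcols(sites)
  expect_equal(start(sites), 30)
  expect_equal(m$ref, "A"); expect_equal(m$alt, "G")
  expect_equal(m$editedReads, 3); expect_equal(m$coverage, 10)
  expect_equal(m$frequency, 0.3)
  expect_true(m$isA2I)
  expect_equal(m$region, "exon_cds")
  expect_equal(m$geneId, "gTest")
  expect_equal(m$minDistEnd, 29)   # site sits mid-read
})

test_that("a matching DNA variant removes the candidate", {
  ref <- refA()
  reads <- rbind(makeReads("chr1", rep(1L, 7), refRead(1)),
                 makeReads("chr1", rep(1L, 3), altRead(1)))
  tly <- pileupAlignments(reads, ref)
  vcf <- data.frame(chrom = "chr1", pos = 30L, ref = "A", alt = "G",
                    source = "germline")
  sites <- callCandidateSites(tly, ref, dnaVariants = vcf,
                              geneModels = simpleGeneModels("chr1", 1, 100))
  expect_equal(length(sites), 0)
  # without any table the filter is skipped, with a warning
  expect_warning(
    sites2 <- callCandidateSites(tly, ref,
                                 geneModels = simpleGeneModels("chr1", 1,
                                                               100)),
    "skipped")
  expect_equal(length(sites2), 1)
  expect_false(S4Vectors::metadata(sites2)$dnaFilterApplied)
})

test_that("alternate observations confined to read ends are rejected", {
  ref <- refA()
  # alt reads start so the site is 2-4 bp from the raw 5' end
  reads <- rbind(makeReads("chr1", rep(1L, 10), refRead(1)),
                 makeReads("chr1", c(26L, 27L, 28L),
                           vapply(c(26L, 27L, 28L), altRead,
                                  character(1))))
  tly <- pileupAlignments(reads, ref)
  noDna <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      source = character(0))
  sites <- callCandidateSites(tly, ref, dnaVariants = noDna,
                              geneModels = simpleGeneModels("chr1", 1, 100))
  expect_equal(length(sites), 0)
  # the same observations pass once the required distance is lowered
  sites2 <- callCandidateSites(tly, ref, dnaVariants = noDna,
                               geneModels = simpleGeneModels("chr1", 1,
                                                             100),
                               config = detectConfig(endDistance = 2L))
  expect_equal(length(sites2), 1)
})

test_that("minus-strand genes flip the A-to-I polarity", {
  # reference T at 30: on a minus-strand gene, T with C reads is A-to-I
  s <- strrep("G", 100); substr(s, 30, 30) <- "T"
  ref <- readReference(writeTestRef(c(chr1 = s)))
  mk <- function(base) {
    x <- strrep("G", 60); substr(x, 30, 30) <- base; x
  }
  reads <- rbind(makeReads("chr1", rep(1L, 7), mk("T")),
                 makeReads("chr1", rep(1L, 3), mk("C")))
  tly <- pileupAlignments(reads, ref)
  noDna <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      source = character(0))
  sites <- callCandidateSites(tly, ref, dnaVariants = noDna,
                              geneModels = simpleGeneModels("chr1", 1, 100,
                                                            strand = "-"))
  expect_equal(length(sites), 1)
  expect_true(mcols(sites)$isA2I)
  expect_equal(as.character(strand(sites)), "-")
  # transcribed-strand neighbors are the reverse complement of the
  # flanking reference bases (G...G around the T -> C on both sides)
  expect_equal(mcols(sites)$fivePrime, "C")
  expect_equal(mcols(sites)$threePrime, "C")
})

test_that("the cascade matches a brute-force predicate re-evaluation", {
  truth <- sharedSmallCohort()
  ref <- readReference(truth@paths$fasta)
  reads <- readAlignments(truth@paths$sam[["tumor01"]])
  tly <- pileupAlignments(reads, ref, sampleId = "tumor01")
  vcf <- readDnaVariants(truth@paths$vcf[["tumor01"]])
  cfg <- detectConfig()
  sites <- suppressWarnings(callCandidateSites(tly, ref, dnaVariants = vcf))
  got <- sort(paste(as.character(seqnames(sites)), start(sites),
                    mcols(sites)$alt))

  # independent re-evaluation of every predicate from the raw tables
  mm <- mismatchObs(tly)
  counts <- tallyCounts(tly)
  mm <- mm[mm$bq >= cfg$qBase & mm$mq >= cfg$qMap, ]
  keys <- unique(paste(mm$chrom, mm$pos, mm$base))
  keep <- character(0)
  vkey <- paste(vcf$chrom, vcf$pos)
  for (k in keys) {
    p <- strsplit(k, " ")[[1]]
    obs <- mm[mm$chrom == p[1] & mm$pos == as.integer(p[2]) &
              mm$base == p[3], ]
    row <- counts[counts$chrom == p[1] & counts$pos == as.integer(p[2]), ]
    cov <- row$fA + row$fC + row$fG + row$fT
    if (nrow(obs) < cfg$minAltReads) next
    if (cov < cfg$minCoverage) next
    if (paste(p[1], p[2]) %in% vkey) next
    if (max(obs$distEnd) < cfg$endDistance) next
    altFwd <- sum(!obs$rev)
    if (fisher.test(matrix(c(row$refFwd, row$refRev, altFwd,
                             nrow(obs) - altFwd), 2))$p.value <
        cfg$biasAlpha) next
    keep <- c(keep, paste(p[1], p[2], p[3]))
  }
  expect_identical(got, sort(keep))
})

test_that("no planted DNA variant position leaks into called sites", {
  truth <- sharedSmallCohort()
  ref <- readReference(truth@paths$fasta)
  gm <- readGeneModels(truth@paths$gtf)
  for (s in c("tumor01", "control01")) {
    reads <- readAlignments(truth@paths$sam[[s]])
    tly <- pileupAlignments(reads, ref, sampleId = s)
    vcf <- readDnaVariants(truth@paths$vcf[[s]])
    sites <- callCandidateSites(tly, ref, dnaVariants = vcf,
                                geneModels = gm)
    called <- paste(as.character(seqnames(sites)), start(sites))
    expect_length(intersect(called, paste(vcf$chrom, vcf$pos)), 0)
  }
})

test_that("a separable feature cleanly trains to AUC 1", {
  set.seed(1)
  n <- 120
  feat <- cbind(frequency = c(rep(0.5, n), rep(0.01, n)) +
                  runif(2 * n, 0, 0.001),
                coverage = rep(50, 2 * n) + rnorm(2 * n))
  labels <- c(rep(1, n), rep(0, n))
  clf <- trainSiteClassifier(feat, labels)
  expect_equal(clf$auc, 1.0)
})

test_that("shuffled labels give chance-level held-out AUC", {
  set.seed(2)
  n <- 300
  feat <- cbind(frequency = runif(2 * n), coverage = rpois(2 * n, 40))
  labels <- sample(c(rep(1, n), rep(0, n)))
  clf <- suppressWarnings(trainSiteClassifier(feat, labels))
  expect_lt(abs(clf$auc - 0.5), 0.1)
})

test_that("training refuses single-class labels", {
  feat <- cbind(frequency = runif(100))
  expect_error(trainSiteClassifier(feat, rep(1, 100)), "single class")
})

test_that("confidence thresholding is monotone with trivial endpoints", {
  ref <- refA()
  reads <- rbind(makeReads("chr1", rep(1L, 7), refRead(1)),
                 makeReads("chr1", rep(1L, 3), altRead(1)))
  tly <- pileupAlignments(reads, ref)
  noDna <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      source = character(0))
  sites <- callCandidateSites(tly, ref, dnaVariants = noDna,
                              geneModels = simpleGeneModels("chr1", 1, 100))
  set.seed(3)
  n <- 60
  feat <- rbind(siteFeatureMatrix(sites)[rep(1, n), ],
                siteFeatureMatrix(sites)[rep(1, n), ])
  feat[, "frequency"] <- c(runif(n, 0.4, 0.6), runif(n, 0, 0.05))
  clf <- trainSiteClassifier(feat, c(rep(1, n), rep(0, n)))
  counts <- vapply(c(0, 0.5, 0.9, 1),
                   function(th) length(scoreSites(sites, clf, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], length(sites))   # threshold 0 keeps everything
  expect_equal(counts[4], 0)               # finite scores never reach 1
  # dimension mismatch is an error
  clf2 <- clf; clf2$featureNames <- clf$featureNames[-1]
  expect_error(scoreSites(sites, clf2, 0.5), "mismatch")
})
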