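#' @include signatures.R
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
NULL

#' Write a per-sample editing-site table
#'
#' Documented TSV export of called sites: \code{chrom}, \code{pos},
#' \code{strand}, \code{ref}, \code{alt}, \code{editedReads},
#' \code{coverage}, \code{frequency}, \code{region}, \code{alu},
#' \code{geneId}, \code{confidence} (NA when unscored).
#'
#' @param sites \code{GRanges} from [callCandidateSites()] /
#'   [scoreSites()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSitesTsv <- function(sites, path) {
  m <- mcols(sites)
  df <- data.frame(
    chrom = as.character(seqnames(sites)), pos = start(sites),
    strand = as.character(strand(sites)), ref = m$ref, alt = m$alt,
    editedReads = m$editedReads, coverage = m$coverage,
    frequency = m$frequency, region = m$region, alu = m$alu,
    geneId = m$geneId,
    confidence = if (!is.null(m$confidence)) m$confidence else NA_real_,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Assembles the configuration for [runPipeline()]: the simulation
#' parameters, detection thresholds, cohort/statistical thresholds and
#' flags.  Can be serialized to YAML with [writeSimConfig()]-style
#' round-tripping via \code{yaml}.
#'
#' @param outDir output directory of the run.
#' @param seed integer; overrides the simulation seed so one value drives
#'   the whole run.
#' @param sim list of [simConfig()] overrides.
#' @param detect list of [detectConfig()] overrides.
#' @param classifierThreshold confidence cutoff for retained sites.
#' @param minFraction recurrence-catalog tumor-fraction threshold.
#' @param fdr differential-editing FDR.
#' @param maxGap hyper-editing cluster gap (bp).
#' @param cutReadLength optional read-truncation length for index
#'   computation.
#' @param gmt optional path to a GMT of signatures; defaults to the
#'   bundled synthetic placeholder signatures.
#' @return named list.
#' @export
runConfig <- function(outDir, seed = 1L, sim = list(), detect = list(),
                      classifierThreshold = 0.9, minFraction = 0.10,
                      fdr = 0.05, maxGap = 50L, cutReadLength = NULL,
                      gmt = NULL) {
  list(outDir = outDir, seed = as.integer(seed), sim = sim,
       detect = detect, classifierThreshold = classifierThreshold,
       minFraction = minFraction, fdr = fdr, maxGap = maxGap,
       cutReadLength = cutReadLength, gmt = gmt)
}

#' Run the full synthetic-cohort editing pipeline
#'
#' Executes simulate -> pileup -> detect -> classify -> index -> catalog ->
#' differential editing -> clusters -> signature scores as one reproducible
#' run.  Every stage writes a TSV under \code{outDir}; a JSON manifest
#' records the seed, all thresholds actually applied, per-stage row counts,
#' filter attrition and the MD5 checksum of every output, so reruns with
#' the same configuration can be verified byte-for-byte.  The site
#' classifier is trained on the run's own simulated truth labels (planted
#' site versus artifact candidate).
#'
#' @param config list from [runConfig()].
#' @return invisibly, a list with the \code{truth}, per-sample
#'   \code{profiles}, the \code{catalog}, the differential-editing table
#'   and the manifest path.
#' @export
runPipeline <- function(config) {
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  simCfg <- do.call(simConfig, c(config$sim, list(seed = config$seed)))
  simDir <- file.path(out, "sim")
  truth <- stage("simulate", simulateCohort(simCfg, simDir))

  reference <- readReference(truth@paths$fasta)
  geneModels <- readGeneModels(truth@paths$gtf)
  alu <- readAluBed(truth@paths$aluBed)
  repeats <- tryCatch(readAluBed(truth@paths$repeatsBed),
                      error = function(e) NULL)
  detCfg <- do.call(detectConfig, config$detect)
  sampleIds <- truthSamples(truth)$sampleId
  groups <- truthSamples(truth)$group

  vcfTables <- lapply(setNames(sampleIds, sampleIds), function(s)
    readDnaVariants(truth@paths$vcf[[s]]))
  tallies <- list(); rawSites <- list()
  stage("detect", for (s in sampleIds) {
    reads <- readAlignments(truth@paths$sam[[s]],
                            cutReadLength = config$cutReadLength)
    tallies[[s]] <- pileupAlignments(reads, reference, qBase = detCfg$qBase,
                                     qMap = detCfg$qMap, sampleId = s)
    rawSites[[s]] <- callCandidateSites(tallies[[s]], reference,
                                        dnaVariants = vcfTables[[s]],
                                        geneModels = geneModels,
                                        aluIntervals = alu,
                                        repeatIntervals = repeats,
                                        config = detCfg)
  })

  # classifier trained on the run's own truth labels; training candidates
  # come from a relaxed cascade (single-read support, no strand-bias gate)
  # so that sequencing-error candidates provide negative examples
  truthKey <- paste(truthSites(truth)$chrom, truthSites(truth)$pos)
  relaxedCfg <- detCfg
  relaxedCfg$minAltReads <- 1L
  relaxedCfg$biasAlpha <- 0
  trainCand <- stage("classify", do.call(c, unname(lapply(sampleIds,
    function(s) callCandidateSites(
      tallies[[s]], reference, dnaVariants = vcfTables[[s]],
      geneModels = geneModels, aluIntervals = alu,
      repeatIntervals = repeats, config = relaxedCfg)))))
  labels <- as.integer(paste(as.character(seqnames(trainCand)),
                             start(trainCand)) %in% truthKey)
  classifier <- stage("classify",
    trainSiteClassifier(siteFeatureMatrix(trainCand), labels))

  profiles <- list()
  stage("index", for (s in sampleIds) {
    sites <- scoreSites(rawSites[[s]], classifier,
                        threshold = config$classifierThreshold)
    profiles[[s]] <- buildSampleProfile(s, sites, tallies[[s]], alu)
    writeSitesTsv(sites, file.path(out, paste0("sites_", s, ".tsv")))
  })
  indexDf <- data.frame(
    sample = sampleIds, group = groups,
    aei = vapply(profiles, aei, numeric(1)),
    nSites = vapply(profiles, function(p) length(editingSites(p)),
                    numeric(1)),
    nA2I = vapply(profiles, function(p)
      sum(mcols(editingSites(p))$isA2I, na.rm = TRUE), numeric(1)))
  write.table(indexDf, file.path(out, "indices.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  catalog <- stage("catalog",
    buildRecurrenceCatalog(profiles, groups,
                           minFraction = config$minFraction,
                           dnaVariantTables = vcfTables,
                           geneModels = geneModels))
  catSites <- editingSites(catalog)
  catDf <- data.frame(
    chrom = as.character(seqnames(catSites)), pos = start(catSites),
    strand = as.character(strand(catSites)),
    geneId = mcols(catSites)$geneId, region = mcols(catSites)$region,
    tumorCount = mcols(catSites)$tumorCount,
    tumorFraction = mcols(catSites)$tumorFraction)
  write.table(catDf, file.path(out, "catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  diffRes <- stage("diffedit", differentialEditing(
    tallies[groups == "tumor"], tallies[groups == "control"],
    geneModels = geneModels, mode = "pooled", fdr = config$fdr))
  write.table(diffRes, file.path(out, "differential_editing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  clusterDf <- do.call(rbind, lapply(
    unique(as.character(seqnames(catSites))), function(cn) {
      cl <- clusterSites(catSites[as.character(seqnames(catSites)) == cn],
                         maxGap = config$maxGap)
      if (nrow(cl)) cbind(chrom = cn, cl) else NULL
    }))
  if (is.null(clusterDf))
    clusterDf <- data.frame(chrom = character(0), cluster = integer(0),
                            start = integer(0), end = integer(0),
                            n = integer(0))
  write.table(clusterDf, file.path(out, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  gmtPath <- config$gmt %||%
    system.file("extdata", "signatures_synthetic.gmt",
                package = "editscape")
  scores <- stage("score", {
    expr <- normalizeExpression(readExpressionTsv(truth@paths$expression))
    scoreTable(expr, readGmt(gmtPath))
  })
  write.table(cbind(sample = rownames(scores), scores),
              file.path(out, "signature_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  outputs <- list.files(out, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  checksums <- tools::md5sum(sort(outputs))
  names(checksums) <- sub(paste0("^", out, "/?"), "", names(checksums))
  manifest <- list(
    package = "editscape",
    version = as.character(utils::packageVersion("editscape")),
    seed = config$seed,
    thresholds = list(
      detect = detCfg, classifierThreshold = config$classifierThreshold,
      minFraction = config$minFraction, fdr = config$fdr,
      maxGap = config$maxGap),
    sim = simCfg[setdiff(names(simCfg), "motifBias")],
    counts = list(
      samples = length(sampleIds),
      plantedSites = nrow(truthSites(truth)),
      candidateSites = length(trainCand),
      retainedSites = sum(vapply(profiles, function(p)
        length(editingSites(p)), numeric(1))),
      catalogSites = length(catSites),
      differentialTested = nrow(diffRes),
      differentialPassed = sum(diffRes$pass),
      classifierAuc = classifier$auc),
    attrition = lapply(rawSites, function(s)
      as.list(S4Vectors::metadata(s)$attrition)),
    checksums = as.list(checksums))
  manifestPath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(truth = truth, profiles = profiles, catalog = catalog,
                 differential = diffRes, scores = scores,
                 manifest = manifestPath))
}
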