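#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end strand mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Per-position base tally of one sample's alignments
#'
#' A \code{PileupTally} holds, for every covered reference position, raw and
#' quality-filtered counts of each read base, plus the strand composition of
#' reference-matching reads, and a per-observation table of every mismatching
#' read base (with base quality, mapping quality, distance to the nearer raw
#' read end and read strand).  It is the substrate for editing-site detection
#' and for all editing indices.
#'
#' @slot sampleId single character, sample identifier.
#' @slot counts \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, raw counts \code{A,C,G,T,N}, filtered counts
#'   \code{fA,fC,fG,fT,fN} and filtered reference-base strand counts
#'   \code{refFwd,refRev}.  One row per covered position.
#' @slot mismatches \code{data.frame} of individual mismatching observations:
#'   \code{chrom}, \code{pos}, \code{base}, \code{bq}, \code{mq},
#'   \code{distEnd}, \code{rev}.
#' @slot params list with the quality thresholds (\code{qBase}, \code{qMap})
#'   used for the filtered counts.
#'
#' @seealso [pileupAlignments()], [callCandidateSites()], [computeAei()]
#' @export
setClass("PileupTally",
  representation(sampleId = "character", counts = "data.frame",
                 mismatches = "data.frame", params = "list"),
  prototype(sampleId = NA_character_))

setValidity("PileupTally", function(object) {
  need <- c("chrom", "pos", "ref", "A", "C", "G", "T", "N",
            "fA", "fC", "fG", "fT", "fN", "refFwd", "refRev")
  if (!all(need %in% colnames(object@counts)))
    return(paste("counts must have columns:", paste(need, collapse = ", ")))
  needm <- c("chrom", "pos", "base", "bq", "mq", "distEnd", "rev")
  if (!all(needm %in% colnames(object@mismatches)))
    return(paste("mismatches must have columns:",
                 paste(needm, collapse = ", ")))
  if (nrow(object@counts) &&
      any(object@counts$pos < 1))
    return("positions must be 1-based (>= 1)")
  TRUE
})

#' One sample's editing landscape
#'
#' Bundles the editing sites called in one sample (a \code{GRanges} with
#' per-site counts, frequencies and feature annotations) with the sample's
#' transcriptome-level summaries: the Alu editing index (AEI), named
#' per-region editing indices and per-gene editing levels.
#'
#' @slot sampleId single character.
#' @slot sites \code{GRanges} of called editing sites; metadata columns
#'   include \code{ref}, \code{alt}, \code{editedReads}, \code{coverage},
#'   \code{frequency}, \code{isA2I}, \code{alu}, \code{region},
#'   \code{geneId} and (when scored) \code{confidence}.
#' @slot aei numeric scalar in [0,1] or NA.
#' @slot aeiCounts numeric, numerator and denominator behind \code{aei}.
#' @slot regionIndices named numeric vector of region editing indices.
#' @slot geneLevels named numeric vector of gene-level editing frequencies.
#' @export
setClass("SampleEditingProfile",
  representation(sampleId = "character", sites = "GRanges", aei = "numeric",
                 aeiCounts = "numeric", regionIndices = "numeric",
                 geneLevels = "numeric"),
  prototype(aei = NA_real_, aeiCounts = c(numerator = 0, denominator = 0),
            regionIndices = setNames(numeric(0), character(0)),
            geneLevels = setNames(numeric(0), character(0))))

setValidity("SampleEditingProfile", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  if (!is.na(object@aei) && (object@aei < 0 || object@aei > 1))
    return("aei must lie in [0,1]")
  TRUE
})

#' Cohort-level catalog of recurrent tumor-enriched editing sites
#'
#' Holds the retained site set from the recurrence filter (A-to-I, genic,
#' detected in more than a threshold fraction of tumor samples and in no
#' control sample, and seen in at least two samples) together with the
#' site-by-sample frequency matrix and the gene-by-sample edited / mutated
#' status matrices used for editing-versus-mutation landscapes.
#'
#' @slot sites \code{GRanges} of retained sites with recurrence counts.
#' @slot siteFreq numeric matrix, sites x samples; NA where a site was not
#'   reported in a sample.
#' @slot geneEdited logical matrix, genes x samples.
#' @slot geneMutated logical matrix, genes x samples (genic SNVs from the
#'   supplied DNA variant tables).
#' @slot sampleGroups named character vector, \code{"tumor"} or
#'   \code{"control"} per sample.
#' @export
setClass("CohortCatalog",
  representation(sites = "GRanges", siteFreq = "matrix",
                 geneEdited = "matrix", geneMutated = "matrix",
                 sampleGroups = "character"))

setValidity("CohortCatalog", function(object) {
  if (!identical(dim(object@geneEdited), dim(object@geneMutated)))
    return("geneEdited and geneMutated must have identical dimensions")
  if (!identical(dimnames(object@geneEdited), dimnames(object@geneMutated)))
    return("geneEdited and geneMutated must share gene and sample names")
  if (ncol(object@siteFreq) &&
      !identical(colnames(object@siteFreq), names(object@sampleGroups)))
    return("siteFreq columns must match sampleGroups names")
  TRUE
})

#' Ground truth of a simulated cohort
#'
#' Machine-readable record of everything the cohort simulator planted:
#' per-site positions, types and per-sample true editing frequencies;
#' per-sample group and editing-activity multiplier; per-gene true TPM; and
#' the paths of all files written.
#'
#' @slot sites \code{data.frame}, one row per planted site.
#' @slot samples \code{data.frame}, one row per sample (group, activity).
#' @slot expression numeric matrix of true TPM, genes x samples.
#' @slot paths named list of output file paths.
#' @slot config the \code{simConfig()} list used.
#' @export
setClass("SimTruth",
  representation(sites = "data.frame", samples = "data.frame",
                 expression = "matrix", paths = "list", config = "list"))
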