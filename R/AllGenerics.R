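#' @include AllClasses.R
NULL

#' Accessors for editscape objects
#'
#' Small accessor generics for the package's S4 containers: sample
#' identifiers, tally tables, called sites, editing indices and the cohort
#' catalog matrices.
#'
#' @param object a \code{PileupTally}, \code{SampleEditingProfile},
#'   \code{CohortCatalog} or \code{SimTruth}.
#' @return The corresponding slot content; see the class documentation.
#' @name editscape-accessors
NULL

#' @rdname editscape-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname editscape-accessors
#' @export
setGeneric("tallyCounts", function(object) standardGeneric("tallyCounts"))
#' @rdname editscape-accessors
#' @export
setGeneric("mismatchObs", function(object) standardGeneric("mismatchObs"))
#' @rdname editscape-accessors
#' @export
setGeneric("editingSites", function(object) standardGeneric("editingSites"))
#' @rdname editscape-accessors
#' @export
setGeneric("aei", function(object) standardGeneric("aei"))
#' @rdname editscape-accessors
#' @export
setGeneric("regionIndices", function(object) standardGeneric("regionIndices"))
#' @rdname editscape-accessors
#' @export
setGeneric("geneLevels", function(object) standardGeneric("geneLevels"))
#' @rdname editscape-accessors
#' @export
setGeneric("siteFrequencies",
           function(object) standardGeneric("siteFrequencies"))
#' @rdname editscape-accessors
#' @export
setGeneric("geneEditedMatrix",
           function(object) standardGeneric("geneEditedMatrix"))
#' @rdname editscape-accessors
#' @export
setGeneric("geneMutatedMatrix",
           function(object) standardGeneric("geneMutatedMatrix"))
#' @rdname editscape-accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @rdname editscape-accessors
#' @export
setGeneric("truthSites", function(object) standardGeneric("truthSites"))
#' @rdname editscape-accessors
#' @export
setGeneric("truthSamples", function(object) standardGeneric("truthSamples"))

#' @rdname editscape-accessors
#' @export
setMethod("sampleId", "PileupTally", function(object) object@sampleId)
#' @rdname editscape-accessors
#' @export
setMethod("sampleId", "SampleEditingProfile", function(object) object@sampleId)
#' @rdname editscape-accessors
#' @export
setMethod("tallyCounts", "PileupTally", function(object) object@counts)
#' @rdname editscape-accessors
#' @export
setMethod("mismatchObs", "PileupTally", function(object) object@mismatches)
#' @rdname editscape-accessors
#' @export
setMethod("editingSites", "SampleEditingProfile", function(object) object@sites)
#' @rdname editscape-accessors
#' @export
setMethod("editingSites", "CohortCatalog", function(object) object@sites)
#' @rdname editscape-accessors
#' @export
setMethod("aei", "SampleEditingProfile", function(object) object@aei)
#' @rdname editscape-accessors
#' @export
setMethod("regionIndices", "SampleEditingProfile",
          function(object) object@regionIndices)
#' @rdname editscape-accessors
#' @export
setMethod("geneLevels", "SampleEditingProfile",
          function(object) object@geneLevels)
#' @rdname editscape-accessors
#' @export
setMethod("siteFrequencies", "CohortCatalog", function(object) object@siteFreq)
#' @rdname editscape-accessors
#' @export
setMethod("geneEditedMatrix", "CohortCatalog",
          function(object) object@geneEdited)
#' @rdname editscape-accessors
#' @export
setMethod("geneMutatedMatrix", "CohortCatalog",
          function(object) object@geneMutated)
#' @rdname editscape-accessors
#' @export
setMethod("sampleGroups", "CohortCatalog", function(object) object@sampleGroups)
#' @rdname editscape-accessors
#' @export
setMethod("truthSites", "SimTruth", function(object) object@sites)
#' @rdname editscape-accessors
#' @export
setMethod("truthSamples", "SimTruth", function(object) object@samples)

setMethod("show", "PileupTally", function(object) {
  cat("PileupTally for sample", object@sampleId, "\n")
  cat(" ", nrow(object@counts), "covered positions on",
      length(unique(object@counts$chrom)), "sequence(s)\n")
  cat(" ", nrow(object@mismatches), "raw mismatch observations\n")
  cat("  quality filters: base >=", object@params$qBase,
      ", mapping >=", object@params$qMap, "\n")
})

setMethod("show", "SampleEditingProfile", function(object) {
  s <- object@sites
  cat("SampleEditingProfile for sample", object@sampleId, "\n")
  cat(" ", length(s), "editing sites (",
      sum(mcols(s)$isA2I %||% logical(0)), "A-to-I )\n")
  cat("  AEI:", format(object@aei, digits = 4), "\n")
  if (length(object@regionIndices))
    cat("  region indices:",
        paste(names(object@regionIndices),
              format(object@regionIndices, digits = 3), collapse = "; "),
        "\n")
})

setMethod("show", "CohortCatalog", function(object) {
  grp <- table(object@sampleGroups)
  cat("CohortCatalog:", length(object@sites), "retained sites,",
      nrow(object@geneEdited), "genes x", ncol(object@geneEdited),
      "samples\n")
  cat("  samples:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@sites), "planted sites,",
      nrow(object@samples), "samples,", nrow(object@expression), "genes\n")
  if (length(object@paths))
    cat("  output directory:", dirname(object@paths[[1]]), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
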