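#' @include indices.R
#' @importFrom stats fisher.test p.adjust
NULL

.siteKeys <- function(sites)
  paste(as.character(seqnames(sites)), start(sites),
        as.character(strand(sites)), mcols(sites)$alt, sep = ":")

.a2iGenicSites <- function(profile) {
  s <- editingSites(profile)
  m <- mcols(s)
  keep <- !is.na(m$isA2I) & m$isA2I &
    !is.na(m$geneId) &
    (is.na(m$region) | m$region != "intergenic")
  s[keep]
}

#' Build the tumor-enriched recurrence catalog
#'
#' Retains A-to-I genic sites detected in strictly more than
#' \code{minFraction} of the tumor samples, in no control sample, and in at
#' least two samples overall.  By default the recurrence denominator is the
#' full tumor cohort (samples without coverage at the site still count);
#' supplying \code{coveredMatrix} switches to a covered-samples
#' denominator.
#'
#' @param profiles named list of [SampleEditingProfile-class] objects.
#' @param groups character vector (\code{"tumor"}/\code{"control"})
#'   parallel to \code{profiles}.
#' @param minFraction recurrence threshold on the tumor fraction (strict
#'   inequality).
#' @param coveredMatrix optional logical matrix (site keys x samples) of
#'   positions with adequate coverage; when given, the denominator for each
#'   site is the number of covered tumor samples.
#' @param dnaVariantTables optional named list of data.frames from
#'   [readDnaVariants()], used for the gene-by-sample mutation status
#'   matrix (genic SNVs only).
#' @param geneModels optional list from [readGeneModels()] (needed for
#'   mutation status).
#' @param genes optional character vector fixing the gene universe of the
#'   status matrices.
#' @return a [CohortCatalog-class].  The retained sites carry
#'   \code{tumorCount}, \code{controlCount} and \code{tumorFraction}.
#' @export
buildRecurrenceCatalog <- function(profiles, groups, minFraction = 0.10,
                                   coveredMatrix = NULL,
                                   dnaVariantTables = NULL,
                                   geneModels = NULL, genes = NULL) {
  stopifnot(length(profiles) == length(groups))
  if (!any(groups == "tumor")) stop("empty tumor cohort")
  sampleIds <- unname(vapply(profiles, sampleId, character(1)))
  names(profiles) <- sampleIds
  names(groups) <- sampleIds
  nTumor <- sum(groups == "tumor")

  perSample <- lapply(profiles, .a2iGenicSites)
  keyList <- lapply(perSample, .siteKeys)
  allKeys <- unique(unlist(keyList, use.names = FALSE))
  member <- vapply(keyList, function(k) allKeys %in% k,
                   logical(length(allKeys)))
  if (length(allKeys) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL,
                                                              sampleIds))
  tumorCount <- rowSums(member[, groups == "tumor", drop = FALSE])
  controlCount <- rowSums(member[, groups == "control", drop = FALSE])
  denom <- rep(nTumor, length(allKeys))
  if (!is.null(coveredMatrix)) {
    idx <- match(allKeys, rownames(coveredMatrix))
    cm <- coveredMatrix[idx, sampleIds[groups == "tumor"], drop = FALSE]
    denom <- rowSums(cm, na.rm = TRUE)
  }
  tumorFraction <- ifelse(denom > 0, tumorCount / denom, 0)
  retained <- controlCount == 0 & (tumorCount + controlCount) >= 2 &
    tumorFraction > minFraction

  keys <- allKeys[retained]
  # annotation from the first profile reporting each site
  firstSite <- function(k) {
    for (i in seq_along(perSample)) {
      hit <- which(keyList[[i]] == k)
      if (length(hit)) return(perSample[[i]][hit[1]])
    }
    NULL
  }
  siteGr <- if (length(keys)) {
    gr <- do.call(c, lapply(keys, firstSite))
    mcols(gr)$tumorCount <- tumorCount[retained]
    mcols(gr)$controlCount <- controlCount[retained]
    mcols(gr)$tumorFraction <- tumorFraction[retained]
    gr
  } else GRanges()

  freq <- matrix(NA_real_, length(keys), length(sampleIds),
                 dimnames = list(keys, sampleIds))
  for (i in seq_along(perSample)) {
    hit <- match(keyList[[i]], keys)
    got <- !is.na(hit)
    freq[hit[got], i] <- mcols(perSample[[i]])$frequency[got]
  }

  catGenes <- unique(stats::na.omit(
    if (length(siteGr)) mcols(siteGr)$geneId else character(0)))
  mutated <- NULL
  if (!is.null(dnaVariantTables) && !is.null(geneModels)) {
    g <- geneModels$genes
    mutGenes <- lapply(sampleIds, function(s) {
      v <- dnaVariantTables[[s]]
      if (is.null(v) || !nrow(v)) return(character(0))
      ov <- GenomicRanges::findOverlaps(
        GRanges(v$chrom, IRanges(v$pos, v$pos)), g, ignore.strand = TRUE)
      unique(mcols(g)$geneId[S4Vectors::subjectHits(ov)])
    })
    names(mutGenes) <- sampleIds
    geneUniverse <- genes %||%
      sort(unique(c(catGenes, unlist(mutGenes, use.names = FALSE))))
    mutated <- vapply(sampleIds, function(s) geneUniverse %in% mutGenes[[s]],
                      logical(length(geneUniverse)))
    mutated <- matrix(mutated, nrow = length(geneUniverse),
                      dimnames = list(geneUniverse, sampleIds))
  } else {
    geneUniverse <- genes %||% sort(catGenes)
  }
  edited <- matrix(FALSE, length(geneUniverse), length(sampleIds),
                   dimnames = list(geneUniverse, sampleIds))
  if (length(siteGr)) {
    siteGene <- mcols(siteGr)$geneId
    for (s in sampleIds) {
      pos <- !is.na(freq[, s]) & freq[, s] > 0
      edited[intersect(unique(siteGene[pos]), geneUniverse), s] <- TRUE
    }
  }
  if (is.null(mutated))
    mutated <- matrix(FALSE, length(geneUniverse), length(sampleIds),
                      dimnames = list(geneUniverse, sampleIds))

  new("CohortCatalog", sites = siteGr, siteFreq = freq,
      geneEdited = edited, geneMutated = mutated,
      sampleGroups = setNames(unname(groups), sampleIds))
}

#' Editing-versus-mutation landscape matrices per pathway
#'
#' For each gene set, restricts the catalog's gene-by-sample edited and
#' mutated status matrices to the member genes and computes per-gene
#' marginal fractions of samples edited / mutated.
#'
#' @param catalog a [CohortCatalog-class].
#' @param geneSets named list of gene-id vectors (e.g. from [readGmt()]).
#' @return named list; per pathway a list with \code{edited},
#'   \code{mutated} (logical matrices) and \code{marginals} (data.frame
#'   with \code{gene}, \code{fracEdited}, \code{fracMutated}).
#' @export
landscapeMatrices <- function(catalog, geneSets) {
  ed <- geneEditedMatrix(catalog)
  mu <- geneMutatedMatrix(catalog)
  lapply(geneSets, function(members) {
    present <- intersect(members, rownames(ed))
    if (!length(present)) {
      warning("gene set has no genes present in the catalog")
      return(list(edited = ed[0, , drop = FALSE],
                  mutated = mu[0, , drop = FALSE],
                  marginals = data.frame(gene = character(0),
                                         fracEdited = numeric(0),
                                         fracMutated = numeric(0))))
    }
    e <- ed[present, , drop = FALSE]
    m <- mu[present, , drop = FALSE]
    list(edited = e, mutated = m,
         marginals = data.frame(gene = present,
                                fracEdited = rowMeans(e),
                                fracMutated = rowMeans(m),
                                row.names = NULL))
  })
}

#' Mutual exclusivity of editing and mutation for one gene
#'
#' Two-sided Fisher's exact test on the 2x2 table of edited-versus-mutated
#' sample status; an odds ratio below 1 indicates mutual exclusivity.
#' Degenerate margins (a row that is all-true or all-false) are flagged and
#' returned with p = 1 and an NA odds ratio.
#'
#' @param edited,mutated logical vectors over identical samples.
#' @return list with \code{oddsRatio}, \code{p}, \code{table} and
#'   \code{degenerate}.
#' @export
exclusivityTest <- function(edited, mutated) {
  stopifnot(length(edited) == length(mutated))
  tab <- matrix(c(sum(edited & mutated), sum(edited & !mutated),
                  sum(!edited & mutated), sum(!edited & !mutated)),
                nrow = 2,
                dimnames = list(edited = c("yes", "no"),
                                mutated = c("yes", "no")))
  if (all(edited) || !any(edited) || all(mutated) || !any(mutated))
    return(list(oddsRatio = NA_real_, p = 1, table = tab,
                degenerate = TRUE))
  ft <- stats::fisher.test(tab)
  list(oddsRatio = unname(ft$estimate), p = ft$p.value, table = tab,
       degenerate = FALSE)
}

#' Differential editing between two conditions
#'
#' Compares per-position editing between two conditions at
#' transcribed-strand adenosines, with two gating schemes.  In
#' \code{"pooled"} mode replicates are pooled and every position needs at
#' least \code{minReadsPooled} filtered reads in both pools, and at least
#' one read carrying the edited base in either pool.  In
#' \code{"replicate"} mode every replicate of both groups must reach
#' \code{minReadsReplicate} filtered reads and the condition-A (wild-type)
#' pooled editing frequency must reach \code{minWtFreq}.  Gated positions
#' are tested with a two-sided Fisher's exact test on (edited, unedited)
#' read counts and Benjamini-Hochberg adjusted.
#'
#' @param conditionA,conditionB a [PileupTally-class] or list of tallies
#'   (replicates).  Condition A is the wild-type/reference condition in
#'   replicate mode.
#' @param geneModels optional list from [readGeneModels()]; when given,
#'   positions are restricted to genes and the transcribed strand decides
#'   the edited base, otherwise forward-strand A-to-G only.
#' @param mode \code{"pooled"} or \code{"replicate"}.
#' @param minReadsPooled,minReadsReplicate,minWtFreq gate parameters.
#' @param fdr Benjamini-Hochberg threshold for the \code{pass} flag.
#' @return data.frame with per-site counts, frequencies, \code{p},
#'   \code{padj} and \code{pass}; attribute \code{"gateAttrition"} records
#'   how many positions each gate removed.
#' @export
differentialEditing <- function(conditionA, conditionB, geneModels = NULL,
                                mode = c("pooled", "replicate"),
                                minReadsPooled = 10L,
                                minReadsReplicate = 50L, minWtFreq = 0.2,
                                fdr = 0.05) {
  mode <- match.arg(mode)
  asList <- function(x) if (is(x, "PileupTally")) list(x) else x
  repA <- asList(conditionA); repB <- asList(conditionB)
  poolA <- if (length(repA) > 1) poolTallies(repA, "A") else repA[[1]]
  poolB <- if (length(repB) > 1) poolTallies(repB, "B") else repB[[1]]

  siteTable <- function(tally) {
    counts <- tallyCounts(tally)
    rows <- counts$ref %in% c("A", "T")
    df <- counts[rows, , drop = FALSE]
    if (!nrow(df)) return(df[, c("chrom", "pos", "ref")])
    strand <- rep("+", nrow(df))
    if (!is.null(geneModels)) {
      ann <- classifyRegions(geneModels, df$chrom, df$pos)
      genic <- !is.na(ann$geneId) & !ann$ambiguous &
        ann$strand %in% c("+", "-")
      df <- df[genic, , drop = FALSE]
      strand <- ann$strand[genic]
    }
    keep <- (strand == "+" & df$ref == "A") |
            (strand == "-" & df$ref == "T")
    df <- df[keep, , drop = FALSE]
    strand <- strand[keep]
    data.frame(chrom = df$chrom, pos = df$pos, strand = strand,
               edited = ifelse(strand == "+", df$fG, df$fC),
               unedited = ifelse(strand == "+", df$fA, df$fT),
               stringsAsFactors = FALSE)
  }
  ta <- siteTable(poolA); tb <- siteTable(poolB)
  key <- union(paste(ta$chrom, ta$pos), paste(tb$chrom, tb$pos))
  ia <- match(key, paste(ta$chrom, ta$pos))
  ib <- match(key, paste(tb$chrom, tb$pos))
  pick <- function(t, i, col, default = 0)
    ifelse(is.na(i), default, t[[col]][i])
  df <- data.frame(
    chrom = ifelse(is.na(ia), pick(tb, ib, "chrom", NA), ta$chrom[ia]),
    pos = as.integer(ifelse(is.na(ia), pick(tb, ib, "pos", NA),
                            ta$pos[ia])),
    strand = ifelse(is.na(ia), pick(tb, ib, "strand", NA),
                    ta$strand[ia]),
    editedA = pick(ta, ia, "edited"), uneditedA = pick(ta, ia, "unedited"),
    editedB = pick(tb, ib, "edited"), uneditedB = pick(tb, ib, "unedited"),
    stringsAsFactors = FALSE)
  df$covA <- df$editedA + df$uneditedA
  df$covB <- df$editedB + df$uneditedB
  attrition <- c(positions = nrow(df))

  if (mode == "pooled") {
    gate1 <- df$covA >= minReadsPooled & df$covB >= minReadsPooled
    df <- df[gate1, , drop = FALSE]
    attrition["afterCoverage"] <- nrow(df)
    gate2 <- df$editedA + df$editedB >= 1
    df <- df[gate2, , drop = FALSE]
    attrition["afterEditedRead"] <- nrow(df)
  } else {
    covOk <- function(reps) {
      tabs <- lapply(reps, siteTable)
      Reduce(`&`, lapply(tabs, function(t) {
        i <- match(paste(df$chrom, df$pos), paste(t$chrom, t$pos))
        cov <- ifelse(is.na(i), 0, t$edited[i] + t$unedited[i])
        cov >= minReadsReplicate
      }))
    }
    gate1 <- covOk(repA) & covOk(repB)
    df <- df[gate1, , drop = FALSE]
    attrition["afterCoverage"] <- nrow(df)
    gate2 <- df$covA > 0 & df$editedA / df$covA >= minWtFreq
    df <- df[gate2, , drop = FALSE]
    attrition["afterWtFrequency"] <- nrow(df)
  }

  if (!nrow(df)) {
    message("no position passes the gates (",
            paste(names(attrition), attrition, sep = "=", collapse = ", "),
            ")")
    out <- cbind(df, freqA = numeric(0), freqB = numeric(0),
                 p = numeric(0), padj = numeric(0), pass = logical(0))
    attr(out, "gateAttrition") <- attrition
    return(out)
  }
  df$freqA <- df$editedA / df$covA
  df$freqB <- df$editedB / df$covB
  df$p <- vapply(seq_len(nrow(df)), function(i)
    stats::fisher.test(matrix(c(df$editedA[i], df$uneditedA[i],
                                df$editedB[i], df$uneditedB[i]),
                              nrow = 2))$p.value, numeric(1))
  df$padj <- stats::p.adjust(df$p, method = "BH")
  df$pass <- df$padj <= fdr
  rownames(df) <- NULL
  attr(df, "gateAttrition") <- attrition
  df
}

#' Group nearby sites into hyper-editing clusters
#'
#' Single-linkage merging of consecutive sites on one chromosome whose
#' inter-site distance is at most \code{maxGap} bp, producing the short
#' hyper-edited runs (surrounded by unedited stretches) characteristic of
#' ADAR targets such as 3'UTR inverted repeats.
#'
#' @param positions integer vector of site positions on one chromosome, or
#'   a \code{GRanges} on a single chromosome.
#' @param maxGap maximum merged inter-site distance (bp).
#' @return data.frame with \code{cluster}, \code{start}, \code{end},
#'   \code{n}.
#' @export
clusterSites <- function(positions, maxGap = 50L) {
  if (is(positions, "GRanges")) {
    if (length(unique(as.character(seqnames(positions)))) > 1)
      stop("sites must lie on a single chromosome")
    positions <- start(positions)
  }
  if (!length(positions))
    return(data.frame(cluster = integer(0), start = integer(0),
                      end = integer(0), n = integer(0)))
  pos <- sort(unique(as.integer(positions)))
  cl <- cumsum(c(1L, as.integer(diff(pos) > maxGap)))
  data.frame(cluster = unique(cl),
             start = as.integer(tapply(pos, cl, min)),
             end = as.integer(tapply(pos, cl, max)),
             n = as.integer(tapply(pos, cl, length)),
             row.names = NULL)
}
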