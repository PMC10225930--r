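#' @include catalog.R
#' @importFrom stats cor.test wilcox.test phyper median
NULL

#' Log-normalize a TPM expression matrix
#'
#' Elementwise \code{log2(TPM + 1)}.  The returned matrix carries a
#' \code{"logScale"} attribute; normalizing an already-log matrix is an
#' error, so the transform can be applied at most once.
#'
#' @param tpm numeric matrix (genes x samples) of non-negative TPM.
#' @return log-scale matrix with \code{attr(, "logScale") == TRUE}.
#' @export
normalizeExpression <- function(tpm) {
  if (isTRUE(attr(tpm, "logScale")))
    stop("matrix is already log-scaled")
  if (any(tpm < 0)) stop("negative expression values")
  out <- log2(tpm + 1)
  attr(out, "logScale") <- TRUE
  out
}

#' Single-sample signature score (mean of gene z-scores)
#'
#' For each signature gene present in the matrix, expression is z-scored
#' across samples; a sample's score is the mean z-score over the member
#' genes.  Zero-variance genes are dropped (their count is reported).
#' Scores therefore average zero across samples by construction.  This is
#' the package's fixed, versioned score construction for ISG / NF-kB /
#' T-cell-exhaustion style signatures.
#'
#' @param expr log-scale matrix from [normalizeExpression()].
#' @param signature character vector of gene ids (duplicates are ignored).
#' @return named numeric vector of per-sample scores, with attributes
#'   \code{nGenesUsed} and \code{nDropped}.
#' @export
signatureScore <- function(expr, signature) {
  if (ncol(expr) < 2) stop("need at least 2 samples to z-score")
  if (isFALSE(attr(expr, "logScale")))
    warning("expression matrix is not flagged as log-scale")
  genes <- intersect(unique(signature), rownames(expr))
  if (!length(genes)) {
    warning("no signature genes present in the expression matrix")
    out <- setNames(rep(NA_real_, ncol(expr)), colnames(expr))
    attr(out, "nGenesUsed") <- 0L
    attr(out, "nDropped") <- 0L
    return(out)
  }
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  dropped <- sum(sds == 0)
  sub <- sub[sds > 0, , drop = FALSE]
  if (!nrow(sub)) {
    warning("all signature genes have zero variance")
    out <- setNames(rep(NA_real_, ncol(expr)), colnames(expr))
    attr(out, "nGenesUsed") <- 0L
    attr(out, "nDropped") <- dropped
    return(out)
  }
  z <- t(scale(t(sub)))
  out <- colMeans(z)
  attr(out, "nGenesUsed") <- nrow(sub)
  attr(out, "nDropped") <- dropped
  out
}

#' Score several signatures at once
#' @param expr log-scale matrix from [normalizeExpression()].
#' @param signatures named list of gene-id vectors (e.g. [readGmt()]).
#' @return data.frame, samples x signatures.
#' @export
scoreTable <- function(expr, signatures) {
  out <- vapply(signatures, function(s)
    as.numeric(signatureScore(expr, s)), numeric(ncol(expr)))
  out <- as.data.frame(out)
  rownames(out) <- colnames(expr)
  out
}

#' Split samples into high / low halves
#'
#' Top 50\% of values labeled \code{"high"}, bottom 50\% \code{"low"}.
#' With an odd number of samples the median sample goes to the low group;
#' ties at the boundary are broken by input order.
#'
#' @param values named numeric vector (one value per sample).
#' @param by currently only \code{"median"}.
#' @return character vector of labels, aligned with \code{values}.
#' @export
splitHighLow <- function(values, by = "median") {
  stopifnot(by == "median")
  if (length(values) < 2) stop("need at least 2 samples")
  if (length(unique(values)) == 1)
    stop("all values identical; no high/low split exists")
  nHigh <- length(values) %/% 2L
  ord <- order(values, decreasing = TRUE)
  labels <- rep("low", length(values))
  labels[ord[seq_len(nHigh)]] <- "high"
  names(labels) <- names(values)
  labels
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return list with \code{r} and \code{p}; both NA when either vector has
#'   zero variance.
#' @export
correlationTest <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 finite pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum); exact for small
#' tie-free samples, normal approximation with tie correction otherwise
#' (the switch follows [stats::wilcox.test()]: exact below 50 per group
#' without ties).
#'
#' @param values numeric vector.
#' @param labels two-level grouping vector parallel to \code{values}.
#' @return list with \code{U} (statistic for the first group level) and
#'   \code{p}.
#' @export
rankSumTest <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Gene-set over-representation (one-sided Fisher / hypergeometric)
#'
#' Tests each gene set for enrichment of the foreground within the
#' background universe; p-values are the upper hypergeometric tail
#' (equivalently one-sided Fisher's exact) and are Benjamini-Hochberg
#' adjusted across sets.  Sets disjoint from the background are skipped
#' with a warning.
#'
#' @param foreground character vector, must be a subset of
#'   \code{background}.
#' @param background character vector (the gene universe).
#' @param geneSets named list of gene-id vectors.
#' @return data.frame with \code{set}, \code{setSize} (genes in
#'   background), \code{overlap}, \code{p}, \code{q}.
#' @export
overrepresentationTest <- function(foreground, background, geneSets) {
  foreground <- unique(foreground)
  background <- unique(background)
  extra <- setdiff(foreground, background)
  if (length(extra))
    stop("foreground genes missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) " ..." else "")
  rows <- lapply(names(geneSets), function(nm) {
    inBg <- intersect(unique(geneSets[[nm]]), background)
    if (!length(inBg)) {
      warning("gene set '", nm, "' is disjoint from the background; skipped")
      return(NULL)
    }
    k <- length(intersect(foreground, inBg))
    p <- stats::phyper(k - 1, length(inBg),
                       length(background) - length(inBg),
                       length(foreground), lower.tail = FALSE)
    data.frame(set = nm, setSize = length(inBg), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), setSize = integer(0),
                      overlap = integer(0), p = numeric(0),
                      q = numeric(0)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Covariate bias diagnostics for edited genes
#'
#' Compares edited against non-edited genes for each supplied covariate
#' (typically transcript length, GC content and mean expression) with a
#' two-sided Mann-Whitney test plus the rank-biserial effect size, to
#' check that editing calls are not driven by gene length, composition or
#' expression depth.
#'
#' @param editedGenes character vector of edited gene ids.
#' @param allGenes character vector of all assayed gene ids.
#' @param metadata data.frame with a \code{gene} column plus one numeric
#'   column per covariate.
#' @return data.frame with \code{covariate}, \code{p},
#'   \code{rankBiserial}, \code{nEdited}, \code{nOther}.
#' @export
biasDiagnostics <- function(editedGenes, allGenes, metadata) {
  stopifnot("gene" %in% colnames(metadata))
  covs <- setdiff(colnames(metadata), "gene")
  other <- setdiff(allGenes, editedGenes)
  if (!length(other)) stop("no non-edited genes to compare against")
  miss <- mean(!allGenes %in% metadata$gene)
  if (miss > 0.10)
    warning(sprintf("metadata missing for %.0f%% of genes", 100 * miss))
  idxE <- match(intersect(editedGenes, metadata$gene), metadata$gene)
  idxO <- match(intersect(other, metadata$gene), metadata$gene)
  rows <- lapply(covs, function(cv) {
    xe <- metadata[[cv]][idxE]; xo <- metadata[[cv]][idxO]
    xe <- xe[is.finite(xe)]; xo <- xo[is.finite(xo)]
    wt <- suppressWarnings(stats::wilcox.test(xe, xo))
    u <- unname(wt$statistic)
    data.frame(covariate = cv, p = wt$p.value,
               rankBiserial = 1 - 2 * u / (length(xe) * length(xo)),
               nEdited = length(xe), nOther = length(xo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighbor-base composition around edited adenosines
#'
#' Frequencies of the 5' and 3' neighbor bases of each site on the
#' transcribed strand (minus-strand sites are reverse-complemented), in
#' the RNA alphabet.  ADAR editing shows a characteristic preference for U
#' at the 5' and G at the 3' neighbor.  Sites at contig edges contribute N
#' neighbors, which are excluded from the frequencies.
#'
#' @param sites \code{GRanges} with strand (\code{"*"} treated as
#'   \code{"+"}).
#' @param reference \code{DNAStringSet}.
#' @return list with numeric vectors \code{five} and \code{three} over
#'   \code{A,C,G,U}, each summing to 1.
#' @export
motifProfile <- function(sites, reference) {
  if (!length(sites)) stop("no sites supplied")
  five <- character(length(sites)); three <- character(length(sites))
  for (i in seq_along(sites)) {
    chrom <- as.character(seqnames(sites))[i]
    p <- start(sites)[i]
    chromLen <- length(reference[[chrom]])
    left <- if (p > 1) fetchSequence(reference, chrom, p - 1, p - 1) else "N"
    right <- if (p < chromLen) fetchSequence(reference, chrom, p + 1, p + 1)
             else "N"
    if (as.character(strand(sites))[i] == "-") {
      five[i] <- unname(.complement[right])
      three[i] <- unname(.complement[left])
    } else {
      five[i] <- left; three[i] <- right
    }
  }
  freqs <- function(b) {
    b <- b[b != "N"]
    b[b == "T"] <- "U"
    tab <- table(factor(b, levels = c("A", "C", "G", "U")))
    as.numeric(tab) / sum(tab) -> f
    setNames(f, c("A", "C", "G", "U"))
  }
  list(five = freqs(five), three = freqs(three))
}

#' Read / write gene sets in GMT format
#' @param path GMT file path.
#' @return [readGmt()]: named list of gene-id vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param geneSets named list of gene-id vectors.
#' @param description optional per-set description column.
#' @export
writeGmt <- function(geneSets, path, description = "na") {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, description, geneSets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
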