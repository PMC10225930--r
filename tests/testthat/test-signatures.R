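test_that("TPM log-normalization is exact and single-shot", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lg <- normalizeExpression(m)
  expect_equal(unname(lg[1, 1]), 0)      # log2(0+1)
  expect_equal(unname(lg[2, 1]), 1)      # log2(1+1)
  expect_equal(unname(lg[1, 2]), 3)      # log2(7+1)
  expect_true(attr(lg, "logScale"))
  expect_error(normalizeExpression(lg), "already")
  expect_error(normalizeExpression(-m), "negative")
})

test_that("signature scores are mean z-scores with zero cohort mean", {
  set.seed(5)
  m <- matrix(rlnorm(60, 3), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  lg <- normalizeExpression(m)
  sc <- signatureScore(lg, sprintf("g%02d", 1:5))
  expect_lt(abs(mean(sc)), 1e-9)
  expect_equal(attr(sc, "nGenesUsed"), 5L)
  # single-gene signature equals that gene's z-score
  s1 <- signatureScore(lg, "g03")
  z <- (lg["g03", ] - mean(lg["g03", ])) / sd(lg["g03", ])
  expect_equal(unname(s1[1:6]), unname(z), tolerance = 1e-12)
  # hand-computed 3x3 check
  hm <- matrix(c(1, 2, 3,
                 2, 4, 6,
                 10, 10, 13), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  attr(hm, "logScale") <- TRUE
  hz <- t(apply(hm, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(unname(signatureScore(hm, c("a", "b", "c"))[1:3]),
               unname(colMeans(hz)))
  # invariance to ordering and duplicate gene ids
  expect_equal(as.numeric(signatureScore(lg, c("g05", "g01", "g03"))),
               as.numeric(signatureScore(lg, c("g01", "g03", "g05",
                                               "g03"))))
  # absent signatures give NA with a warning
  expect_warning(bad <- signatureScore(lg, c("nope1", "nope2")), "no sig")
  expect_true(all(is.na(bad)))
})

test_that("zero-variance genes are dropped from scores", {
  m <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "var"), c("s1", "s2", "s3")))
  attr(m, "logScale") <- TRUE
  sc <- signatureScore(m, c("flat", "var"))
  expect_equal(attr(sc, "nDropped"), 1L)
  expect_equal(attr(sc, "nGenesUsed"), 1L)
  expect_equal(as.numeric(sc), as.numeric(scale(c(1, 2, 3))))
})

test_that("high/low split halves the cohort with the documented tie rule", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(splitHighLow(v),
               c(a = "low", b = "low", c = "high", d = "high"))
  v5 <- c(a = 5, b = 1, c = 3, d = 2, e = 4)
  lab5 <- splitHighLow(v5)
  expect_equal(sum(lab5 == "high"), 2)   # median sample goes low
  expect_equal(sum(lab5 == "low"), 3)
  expect_equal(unname(lab5[c("a", "e")]), c("high", "high"))
  # permuting samples permutes labels identically
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(splitHighLow(v5[perm])), unname(lab5[perm]))
  expect_error(splitHighLow(c(1, 1, 1)), "identical")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlationTest(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-6)
  # orthogonal-by-construction vectors give r = 0
  y <- c(1, -1, 0, -1, 1)   # centered, dot(x - mean(x), y) == 0
  expect_equal(sum((x - mean(x)) * y), 0)
  expect_equal(correlationTest(x, y)$r, 0)
  expect_true(is.na(correlationTest(x, rep(3, 5))$r))
  expect_error(correlationTest(c(1, 2), c(3, 4)), "3 finite")
})

test_that("a planted expression shift is detected at cohort size 60", {
  # editing index drives expression with moderate noise, n = 60 samples
  set.seed(60)
  idx <- runif(60, 0, 0.3)
  expr <- 5 + 4 * idx + rnorm(60, sd = 0.5)
  res <- correlationTest(idx, expr)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.05)
})

test_that("rank-sum test matches exhaustive enumeration for small n", {
  res <- rankSumTest(c(1, 2, 3, 4, 5, 6),
                     c(rep("a", 3), rep("b", 3)))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2/20 arrangements as extreme
  expect_equal(res$p, rankSumOracle(c(1, 2, 3), c(4, 5, 6)))
  set.seed(6)
  for (i in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    vals <- sample(100, n1 + n2)                 # one pool: tie-free
    x <- vals[seq_len(n1)]; y <- vals[n1 + seq_len(n2)]
    got <- rankSumTest(c(x, y), rep(c("a", "b"), c(n1, n2)))
    expect_equal(got$p, rankSumOracle(x, y), tolerance = 1e-12)
  }
  # identical groups sit at the null, label swap changes nothing
  same <- rankSumTest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gte(same$p, 0.9)
  swap <- rankSumTest(c(1, 2, 3, 4, 5, 6), rep(c("b", "a"), each = 3))
  expect_equal(swap$p, res$p)
  expect_error(rankSumTest(1:3, rep("a", 3)), "two levels")
})

test_that("over-representation equals the hypergeometric tail", {
  bg <- sprintf("g%03d", 1:100)
  fg <- bg[1:10]
  sets <- list(hit = c(bg[6:20], bg[90:94]),   # 20 genes, 5 in foreground
               none = c("x1", "x2"),
               all = bg)
  expect_warning(res <- overrepresentationTest(fg, bg, sets), "disjoint")
  hitRow <- res[res$set == "hit", ]
  expect_equal(hitRow$overlap, 5)
  # oracle: exact sum of the hypergeometric upper tail
  oracle <- sum(dhyper(5:10, 20, 80, 10))
  expect_equal(hitRow$p, oracle, tolerance = 1e-12)
  # foreground == background makes every p exactly 1
  resAll <- overrepresentationTest(bg, bg, list(s = bg[1:30]))
  expect_equal(resAll$p, 1)
  expect_error(overrepresentationTest(c(fg, "zzz"), bg, sets), "missing")
})

test_that("bias diagnostics flag planted covariate bias only", {
  set.seed(8)
  meta <- data.frame(gene = sprintf("g%03d", 1:200),
                     length = rlnorm(200, 7, 0.5),
                     gc = runif(200, 0.3, 0.6),
                     expr = rlnorm(200, 2, 1))
  # unbiased pick: no covariate should light up strongly
  unb <- biasDiagnostics(sample(meta$gene, 50), meta$gene, meta)
  expect_true(all(unb$p > 0.001))
  # force edited genes into the longest quintile: length must light up
  longest <- meta$gene[order(-meta$length)][1:40]
  bias <- biasDiagnostics(longest, meta$gene, meta)
  expect_lt(bias$p[bias$covariate == "length"], 1e-6)
  expect_gt(abs(bias$rankBiserial[bias$covariate == "length"]), 0.9)
  expect_gt(bias$p[bias$covariate == "gc"], 0.001)
  # identical value distributions give p = 1
  meta2 <- data.frame(gene = c("a", "b", "c", "d"),
                      cov = c(1, 2, 1, 2))
  expect_equal(biasDiagnostics(c("a", "b"), c("a", "b", "c", "d"),
                               meta2)$p, 1)
})

test_that("motif profiles are strand-aware neighbor frequencies", {
  ref <- readReference(writeTestRef(c(chr1 = "GGTAGGGCTTGG")))
  # plus-strand site at 4: neighbors T (5') and G (3')
  plus <- GRanges("chr1", IRanges(4, 4), strand = "+")
  prof <- motifProfile(plus, ref)
  expect_equal(prof$five[["U"]], 1)
  expect_equal(prof$three[["G"]], 1)
  # minus-strand T->C site: reference-forward triplet C-T-T at 8-10, the
  # edited base is the T at 9; reverse-complementing gives the
  # transcribed-strand context 5' A, 3' G around the edited A
  minus <- GRanges("chr1", IRanges(9, 9), strand = "-")
  profM <- motifProfile(minus, ref)
  expect_equal(profM$five[["A"]], 1)
  expect_equal(profM$three[["G"]], 1)
  expect_equal(sum(prof$five), 1)
  expect_equal(sum(prof$three), 1)
  # a site at the contig edge contributes N, which is excluded
  edge <- GRanges("chr1", IRanges(c(1, 4), c(1, 4)), strand = "+")
  profE <- motifProfile(edge, ref)
  expect_equal(profE$five[["U"]], 1)   # only the interior site counts 5'
})

test_that("plus-strand motif equals naive string slicing", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  ref <- readReference(writeTestRef(c(chr1 = s)))
  pos <- sort(sample(2:499, 60))
  gr <- GRanges("chr1", IRanges(pos, pos), strand = "+")
  prof <- motifProfile(gr, ref)
  five <- substring(s, pos - 1, pos - 1)
  three <- substring(s, pos + 1, pos + 1)
  toU <- function(x) { x[x == "T"] <- "U"
    as.numeric(table(factor(x, c("A", "C", "G", "U")))) / length(x) }
  expect_equal(unname(prof$five[1:4]), toU(five))
  expect_equal(unname(prof$three[1:4]), toU(three))
})

test_that("GMT files round-trip and the bundled placeholders load", {
  sets <- list(one = c("g1", "g2", "g3"), two = c("g9", "g8"))
  path <- file.path(withr::local_tempdir(), "sets.gmt")
  writeGmt(sets, path)
  expect_equal(readGmt(path), sets)
  shipped <- readGmt(system.file("extdata", "signatures_synthetic.gmt",
                                 package = "editscape"))
  expect_true(all(c("ISG_synthetic", "NFKB_synthetic",
                    "TEXH_synthetic") %in% names(shipped)))
  expect_length(shipped$TEXH_synthetic, 6)
})
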