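test_that("recurrence catalog applies the >10%/absent-in-controls rules", {
  # 25 tumors, 5 controls; four site archetypes
  profiles <- list(); groups <- character(0)
  siteOf <- list(
    tumor = list(A = 1:4, B = 1:2, C = 1:10, D = 1, E = 1:6),
    control = list(B = 1))
  posOf <- c(A = 100L, B = 200L, C = 300L, D = 400L, E = 500L)
  for (i in 1:25) {
    pos <- posOf[vapply(names(siteOf$tumor), function(s)
      i %in% siteOf$tumor[[s]], logical(1))]
    p <- mkProfile(sprintf("t%02d", i), unname(pos),
                   gene = ifelse(pos == 300L, NA_character_, "gX"),
                   region = ifelse(pos == 300L, "intergenic", "utr3"),
                   isA2I = pos != 500L)
    profiles <- c(profiles, p); groups <- c(groups, "tumor")
  }
  for (i in 1:5) {
    pos <- if (i %in% siteOf$control$B) 200L else integer(0)
    profiles <- c(profiles, mkProfile(sprintf("c%02d", i), pos,
                                      gene = rep("gX", length(pos))))
    groups <- c(groups, "control")
  }
  cat <- buildRecurrenceCatalog(profiles, groups)
  kept <- start(editingSites(cat))
  # A: 4/25 = 16% of tumors, absent in controls, genic, >=2 samples
  expect_equal(kept, 100L)
  expect_equal(mcols(editingSites(cat))$tumorCount, 4)
  # B seen in a control, C intergenic, D single-sample, E non-A2I: dropped
  expect_false(any(c(200L, 300L, 400L, 500L) %in% kept))
  # frequency matrix carries per-sample values where reported
  expect_equal(sum(!is.na(siteFrequencies(cat)[1, ])), 4)
  expect_true(all(siteFrequencies(cat)[1, 1:4] == 0.3))
  # edited-status matrix marks exactly the reporting tumors
  expect_equal(unname(geneEditedMatrix(cat)["gX", ]),
               c(rep(TRUE, 4), rep(FALSE, 26)))
  expect_error(buildRecurrenceCatalog(profiles[26:30],
                                      groups[26:30]), "tumor")
})

test_that("recurrence equals brute-force set algebra on random cohorts", {
  set.seed(11)
  nT <- 22; nC <- 8; nSites <- 40
  positions <- seq(100L, by = 10L, length.out = nSites)
  membership <- matrix(runif(nSites * (nT + nC)) < 0.2, nSites)
  profiles <- list(); groups <- c(rep("tumor", nT), rep("control", nC))
  for (j in seq_len(nT + nC)) {
    pos <- positions[membership[, j]]
    profiles[[j]] <- mkProfile(sprintf("s%02d", j), pos,
                               gene = rep("gY", length(pos)))
  }
  cat <- buildRecurrenceCatalog(profiles, groups, minFraction = 0.10)
  got <- sort(start(editingSites(cat)))
  # independent set-algebra evaluation
  tc <- rowSums(membership[, 1:nT, drop = FALSE])
  cc <- rowSums(membership[, nT + 1:nC, drop = FALSE])
  want <- sort(positions[tc / nT > 0.10 & cc == 0 & (tc + cc) >= 2])
  expect_identical(got, want)
})

test_that("landscape matrices restrict genes and report marginals", {
  # 50 samples: gene gM mutated in 15 (30%), edited in 1 (2%)
  n <- 50
  profiles <- lapply(seq_len(n), function(i)
    mkProfile(sprintf("s%02d", i), if (i == 1) c(100L, 100L)[1] else
      integer(0), gene = if (i == 1) "gM" else character(0)))
  # the single edited sample plus one more make the >=2-sample rule pass
  profiles[[2]] <- mkProfile("s02", 100L, gene = "gM")
  groups <- rep("tumor", n)
  gm <- simpleGeneModels("chr1", 50, 500, geneId = "gM")
  vt <- lapply(seq_len(n), function(i)
    if (i <= 15) data.frame(chrom = "chr1", pos = 60L, ref = "C",
                            alt = "T", source = "somatic")
    else data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    source = character(0)))
  names(vt) <- sprintf("s%02d", seq_len(n))
  cat <- buildRecurrenceCatalog(profiles, groups, minFraction = 0.01,
                                dnaVariantTables = vt, geneModels = gm)
  ls <- landscapeMatrices(cat, list(path1 = c("gM", "gAbsent")))
  expect_equal(ls$path1$marginals$fracMutated, 0.30)
  expect_equal(ls$path1$marginals$fracEdited, 0.04)  # 2 of 50 samples
  expect_equal(rownames(ls$path1$edited), "gM")
  # permuting the sample order permutes both matrices identically
  perm <- sample(n)
  cat2 <- buildRecurrenceCatalog(profiles[perm], groups[perm],
                                 minFraction = 0.01,
                                 dnaVariantTables = vt, geneModels = gm)
  expect_equal(geneEditedMatrix(cat2),
               geneEditedMatrix(cat)[, colnames(geneEditedMatrix(cat2)),
                                     drop = FALSE])
  expect_equal(geneMutatedMatrix(cat2),
               geneMutatedMatrix(cat)[, colnames(geneMutatedMatrix(cat2)),
                                      drop = FALSE])
  # an empty pathway yields an empty table with a warning
  expect_warning(ls2 <- landscapeMatrices(cat, list(none = "gNope")),
                 "no genes")
  expect_equal(nrow(ls2$none$edited), 0)
})

test_that("exclusivity test matches the hypergeometric oracle", {
  edited <- c(rep(TRUE, 10), rep(FALSE, 10))
  res <- exclusivityTest(edited, edited)   # perfect co-occurrence
  expect_equal(res$oddsRatio, Inf)
  expect_equal(res$p, fisherOracle(10, 0, 0, 10), tolerance = 1e-10)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-10)
  # a scattering of random tables against the enumeration oracle
  set.seed(21)
  for (i in 1:20) {
    e <- runif(16) < 0.5; m <- runif(16) < 0.5
    if (all(e) || !any(e) || all(m) || !any(m)) next
    res <- exclusivityTest(e, m)
    expect_equal(res$p, fisherOracle(sum(e & m), sum(e & !m),
                                     sum(!e & m), sum(!e & !m)),
                 tolerance = 1e-9)
  }
  # degenerate margins are flagged, not tested
  res <- exclusivityTest(rep(TRUE, 8), c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_true(res$degenerate)
  expect_true(is.na(res$oddsRatio))
  expect_equal(res$p, 1)
})

test_that("exclusivity p-values are calibrated under independence", {
  set.seed(31)
  ps <- replicate(400, {
    e <- runif(20) < 0.5; m <- runif(20) < 0.5
    if (all(e) || !any(e) || all(m) || !any(m)) return(NA_real_)
    exclusivityTest(e, m)$p
  })
  ps <- ps[!is.na(ps)]
  # discrete exact p-values are super-uniform: P(p <= a) <= a (+MC error)
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / length(ps)))
})

test_that("pooled differential editing gates coverage and edited reads", {
  a <- deTally(c(2, 0, 5), c(9, 20, 50), "a")    # pos1 under-covered
  b <- deTally(c(0, 0, 1), c(30, 20, 50), "b")   # pos2 has no edited read
  res <- differentialEditing(a, b, mode = "pooled")
  expect_equal(nrow(res), 1)                     # only position 3 survives
  expect_equal(res$pos, 60L)
  expect_equal(res$editedA, 5); expect_equal(res$editedB, 1)
  att <- attr(res, "gateAttrition")
  # the read stacks cover 10 adenosines each; two stacks clear the
  # coverage gate, and only the planted position carries an edited read
  expect_equal(unname(att["afterCoverage"]), 20)
  expect_equal(unname(att["afterEditedRead"]), 1)
})

test_that("replicate mode enforces per-replicate depth and WT frequency", {
  # two WT replicates, two KO replicates at one position
  wt1 <- deTally(8, 60, "w1"); wt2 <- deTally(7, 55, "w2")
  ko1 <- deTally(0, 60, "k1"); ko2 <- deTally(1, 70, "k2")
  # WT pooled frequency 15/115 = 0.13 < 0.2: gated out
  res <- differentialEditing(list(wt1, wt2), list(ko1, ko2),
                             mode = "replicate")
  expect_equal(nrow(res), 0)
  # raising WT editing above the frequency gate lets the site through
  wt1b <- deTally(20, 60, "w1"); wt2b <- deTally(15, 55, "w2")
  res2 <- differentialEditing(list(wt1b, wt2b), list(ko1, ko2),
                              mode = "replicate")
  expect_equal(nrow(res2), 1)
  expect_true(res2$pass)
  # a shallow replicate (49 < 50 reads) blocks the position
  res3 <- differentialEditing(list(wt1b, deTally(15, 49, "w2")),
                              list(ko1, ko2), mode = "replicate")
  expect_equal(nrow(res3), 0)
})

test_that("differential p-values match the exact oracle and BH is monotone", {
  set.seed(41)
  nNull <- 60
  covA <- rep(100L, nNull + 1); covB <- rep(100L, nNull + 1)
  gA <- c(20L, rbinom(nNull, 100, 0.05))
  gB <- c(2L, rbinom(nNull, 100, 0.05))
  a <- deTally(gA, covA, "a"); b <- deTally(gB, covB, "b")
  res <- differentialEditing(a, b, mode = "pooled")
  planted <- res[res$pos == 20L, ]
  expect_equal(planted$p, fisherOracle(20, 80, 2, 98), tolerance = 1e-9)
  expect_true(planted$pass)
  # step-up adjustment is non-decreasing along sorted raw p
  ord <- order(res$p)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj >= res$p - 1e-12))
})

test_that("hyper-editing clusters follow single-linkage gap merging", {
  cl <- clusterSites(c(100L, 110L, 120L, 500L, 505L), maxGap = 50L)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(100L, 500L))
  expect_equal(cl$end, c(120L, 505L))
  expect_equal(cl$n, c(3L, 2L))
  expect_equal(nrow(clusterSites(42L)), 1)
  expect_equal(clusterSites(42L)$n, 1L)
  # zero gap isolates every distinct position
  expect_equal(nrow(clusterSites(c(10L, 11L, 20L), maxGap = 0L)), 3)
  expect_equal(nrow(clusterSites(integer(0))), 0)
})
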