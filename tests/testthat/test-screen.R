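test_that("window extraction slices the edited strand with the site at center", {
  set.seed(21)
  seq <- randSeq(100)
  substr(seq, 41, 41) <- "A"
  g <- genomeAssembly(c(c1 = seq))
  w <- extractWindow(g, oneSite("c1", 41L), flank = 40L)
  expect_equal(nchar(w$seq), 81L)
  expect_equal(w$seq, fetchSeq(g, "c1", 0, 81))
  expect_equal(substr(w$seq, 41, 41), "A")

  # minus strand: plus-strand T becomes the centered A
  seq2 <- randSeq(100)
  substr(seq2, 50, 50) <- "T"
  g2 <- genomeAssembly(c(c1 = seq2))
  w2 <- extractWindow(g2, oneSite("c1", 50L, "-"), flank = 40L)
  expect_equal(substr(w2$seq, 41, 41), "A")
  expect_equal(w2$seq, revComp(fetchSeq(g2, "c1", 9, 90)))

  expect_error(extractWindow(g, oneSite("c1", 10L)), "contig end")
  substr(seq, 45, 45) <- "C"
  g3 <- genomeAssembly(c(c1 = seq))
  expect_error(extractWindow(g3, oneSite("c1", 45L)), "not 'A'")
  expect_silent(extractWindow(g3, oneSite("c1", 45L), requireCenterA = FALSE))
})

test_that("batch extraction skips edge and non-A sites with a warning", {
  set.seed(22)
  seq <- randSeq(200)
  substr(seq, 100, 100) <- "A"
  substr(seq, 120, 120) <- "C"
  g <- genomeAssembly(c(c1 = seq))
  sites <- siteTable("c1", c(100L, 120L, 5L), "+")
  expect_warning(res <- extractWindows(g, sites), "skipped")
  expect_equal(nrow(res$windows), 1L)
  expect_equal(res$windows$pos1, 100L)
  expect_setequal(res$skipped$reason, c("center_not_A", "edge"))
})

test_that("the screen recovers planted conserved sites among decoys", {
  pair <- simulateOrthologPair(simulationConfig(seed = 31))
  truth <- pair$truth
  qs <- rbind(truth$conservedQuery, truth$queryOnly[names(truth$conservedQuery)])
  ss <- rbind(truth$conservedSubject,
              truth$subjectOnly[names(truth$conservedSubject)])
  scr <- runScreen(qs, ss, pair$query, pair$subject)
  expect_setequal(siteKey(conservedSites(scr)), siteKey(truth$conservedQuery))
  expect_true(all(screenPairs(scr)$identical >= 70))
  # best hits first
  expect_equal(screenPairs(scr)$identical,
               sort(screenPairs(scr)$identical, decreasing = TRUE))
})

test_that("unrelated windows never reach the conservation threshold", {
  set.seed(32)
  qseq <- randSeq(8000); sseq <- randSeq(8000)
  pos <- seq(100L, 7900L, by = 130L)[1:60]
  for (p in pos) { substr(qseq, p, p) <- "A"; substr(sseq, p, p) <- "A" }
  gq <- genomeAssembly(c(c1 = qseq), "q")
  gs <- genomeAssembly(c(c1 = sseq), "s")
  sites <- siteTable("c1", pos, "+")
  scr <- runScreen(sites, sites, gq, gs)
  expect_equal(nrow(conservedSites(scr)), 0L)
})

test_that("a self-screen matches every site to itself", {
  pair <- simulateOrthologPair(simulationConfig(seed = 33, nQueryOnly = 20L,
                                                nSubjectOnly = 0L))
  qs <- rbind(pair$truth$conservedQuery,
              pair$truth$queryOnly[names(pair$truth$conservedQuery)])
  scr <- runScreen(qs, qs, pair$query, pair$query)
  expect_setequal(siteKey(conservedSites(scr)), siteKey(qs))
  self <- screenPairs(scr)[screenPairs(scr)$qKey == screenPairs(scr)$sKey, ]
  expect_equal(nrow(self), nrow(qs))
  expect_true(all(self$identical == 81L))
})

test_that("raising the identity threshold never adds conserved sites", {
  pair <- simulateOrthologPair(simulationConfig(seed = 34, nQueryOnly = 30L,
                                                nSubjectOnly = 30L,
                                                conservedDivergence = 0.05))
  truth <- pair$truth
  qs <- rbind(truth$conservedQuery, truth$queryOnly[names(truth$conservedQuery)])
  ss <- rbind(truth$conservedSubject,
              truth$subjectOnly[names(truth$conservedSubject)])
  prev <- Inf
  for (thr in c(60L, 70L, 75L, 78L, 81L)) {
    n <- nrow(conservedSites(runScreen(qs, ss, pair$query, pair$subject,
                                       minIdentical = thr)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("signal-to-noise normalization follows the size-scaling formula", {
  r <- signalNoiseReport(16L, 4L, 50000, 25000, 100000, 100000)
  expect_equal(r@controlNormalized, 0.5)
  expect_equal(signalToNoiseRatio(r), 32)
  expect_equal(signalToNoiseRatio(signalNoiseReport(5L, 0L, 10, 10, 10, 10)),
               Inf)
  expect_equal(signalToNoiseRatio(signalNoiseReport(0L, 0L, 10, 10, 10, 10)),
               0)
  expect_error(signalNoiseReport(1L, 1L, 0, 10, 10, 10), "positive")
})

test_that("the SNP control screen finds shared SNP positions without an A constraint", {
  pair <- simulateOrthologPair(simulationConfig(seed = 35, nQueryOnly = 10L,
                                                nSubjectOnly = 10L,
                                                nSnpsPerSpecies = 40L,
                                                sharedSnpFraction = 0.25))
  truth <- pair$truth
  qs <- rbind(truth$conservedQuery, truth$queryOnly[names(truth$conservedQuery)])
  ss <- rbind(truth$conservedSubject,
              truth$subjectOnly[names(truth$conservedSubject)])
  scr <- runScreen(qs, ss, pair$query, pair$subject)
  sn <- controlSignalToNoise(scr, truth$snpsQuery, truth$snpsSubject,
                             pair$query, pair$subject)
  ctrl <- attr(sn, "controlScreen")
  # shared SNP positions are near-identical windows at matching coordinates
  expect_setequal(siteKey(conservedSites(ctrl)), truth$sharedSnpKeys)
  expect_equal(sn@controlRawHits, 10L)
  expect_equal(sn@controlNormalized,
               10 * (scr@nQueryWindows / 40) * (scr@nSubjectWindows / 40))
})
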