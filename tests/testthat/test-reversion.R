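test_that("counterpart bases are read from the paired alignment column", {
  set.seed(81)
  qseq <- randSeq(300)
  substr(qseq, 150, 150) <- "A"
  sseq <- qseq
  substr(sseq, 150, 150) <- "G" # hardwired G at the orthologous position
  g1 <- genomeAssembly(c(c1 = qseq), "q")
  g2 <- genomeAssembly(c(c1 = sseq), "s")
  cp <- reversionCounterparts(oneSite("c1", 150L), g1, g2)
  expect_true(cp$matched)
  expect_equal(cp$counterpart, "G")

  # a diverged counterpart window below the identity threshold is unmatched
  g3 <- genomeAssembly(c(c1 = randSeq(300)), "s2")
  cp2 <- reversionCounterparts(oneSite("c1", 150L), g1, g3)
  expect_false(cp2$matched)
})

test_that("the adjacent-A control picks the nearest non-edited A, upstream first", {
  base <- strsplit(strrep("C", 101), "")[[1]]
  base[51] <- "A"   # the edited site
  base[48] <- "A"   # distance 3 upstream
  base[54] <- "A"   # distance 3 downstream
  g <- genomeAssembly(c(c1 = paste(base, collapse = "")))
  adj <- adjacentNonEditedA(oneSite("c1", 51L), g, maxOffset = 20L)
  expect_equal(adj$pos1, 48L) # tie at distance 3 resolves upstream

  # listed editing sites are excluded
  sites <- siteTable("c1", c(51L, 48L), "+")
  adj2 <- adjacentNonEditedA(sites[1, ], g, maxOffset = 20L)
  expect_equal(adj2$pos1, 48L)
  adjBoth <- adjacentNonEditedA(sites, g, maxOffset = 20L)
  expect_equal(adjBoth$pos1[1], 54L) # 48 is itself an editing site

  # minus strand: upstream means higher coordinate
  basem <- strsplit(strrep("G", 101), "")[[1]]
  basem[51] <- "T"; basem[47] <- "T"; basem[55] <- "T"
  gm <- genomeAssembly(c(c1 = paste(basem, collapse = "")))
  adjm <- adjacentNonEditedA(oneSite("c1", 51L, "-"), gm, maxOffset = 20L)
  expect_equal(adjm$pos1, 55L)
})

test_that("fraction-G arithmetic and the 2x2 odds ratio follow their definitions", {
  set.seed(82)
  cp <- data.frame(key = sprintf("k%03d", 1:100), matched = TRUE,
                   counterpart = sample(rep(c("G", "A", "C", "T"),
                                            c(26, 54, 10, 10))),
                   stringsAsFactors = FALSE)
  rep <- EditScreen:::directionReport("d", cp)
  expect_equal(rep$matchedSites, 100L)
  expect_equal(rep$fractionG, 0.26)
  expect_equal(rep$fractionGofAG, 26 / 80)

  tab <- matrix(c(26, 74, 18, 82), 2, byrow = TRUE)
  or <- (26 * 82) / (74 * 18)
  expect_equal(round(or, 3), 1.601)
  expect_equal(fisher.test(tab)$p.value, fisherOracle(tab), tolerance = 1e-12)
})

test_that("Fisher p matches the enumeration oracle on assorted tables", {
  set.seed(83)
  for (i in 1:30) {
    tab <- matrix(sample(0:60, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value, fisherOracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("planted reversion asymmetry is recovered end to end", {
  cfg <- simulationConfig(seed = 84, nConserved = 0L, nQueryOnly = 150L,
                          nSubjectOnly = 150L, nSnpsPerSpecies = 0L,
                          reversionFraction = c(0.4, 0.1),
                          chromLength = 40000L)
  pair <- simulateOrthologPair(cfg)
  truth <- pair$truth
  rev <- reversionAnalysis(truth$queryOnly, truth$subjectOnly,
                           pair$query, pair$subject, computeControl = FALSE)
  # planted counterpart bases are read back exactly for the matched sites
  cp1 <- reversionCounterparts(truth$queryOnly, pair$query, pair$subject)
  expect_equal(cp1$counterpart[cp1$matched],
               truth$queryOnly$counterpartBase[
                 match(cp1$key[cp1$matched], siteKey(truth$queryOnly))])
  expect_equal(rev$dir1$fractionG,
               mean(cp1$counterpart[cp1$matched] == "G"))
  cp2 <- reversionCounterparts(truth$subjectOnly, pair$subject, pair$query)
  expect_equal(rev$dir2$fractionG,
               mean(cp2$counterpart[cp2$matched] == "G"))
  expect_gt(rev$oddsRatio, 1)
  expect_lt(rev$fisherP, 0.01)
})
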