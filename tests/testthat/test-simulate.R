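test_that("identical configurations produce byte-identical artifacts", {
  cfg <- simulationConfig(seed = 101, nStrains = 3L, nQueryOnly = 15L,
                          nSubjectOnly = 15L, nSnpsPerSpecies = 10L,
                          chromLength = 20000L)
  p1 <- simulateOrthologPair(cfg)
  p2 <- simulateOrthologPair(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeGenome(p1$query, f1); writeGenome(p2$query, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(p1$truth$levels, p2$truth$levels)
  expect_identical(p1$truth$queryOnly, p2$truth$queryOnly)

  d1 <- tempfile(); d2 <- tempfile()
  simulatePileups(p1, d1); simulatePileups(p2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("planted conserved pairs always pass the criterion (self-check)", {
  for (s in 1:3) {
    pair <- simulateOrthologPair(simulationConfig(seed = 110 + s,
                                                  nQueryOnly = 5L,
                                                  nSubjectOnly = 5L,
                                                  nSnpsPerSpecies = 0L))
    qw <- extractWindows(pair$query, pair$truth$conservedQuery, 40L)$windows
    sw <- extractWindows(pair$subject, pair$truth$conservedSubject,
                         40L)$windows
    for (i in seq_len(nrow(qw))) {
      aln <- alignWindows(list(seq = qw$seq[i], centerIndex = 41L),
                          list(seq = sw$seq[i], centerIndex = 41L))
      expect_true(evaluateHit(aln))
    }
  }
})

test_that("zero conserved divergence gives perfect window identity", {
  pair <- simulateOrthologPair(simulationConfig(seed = 115,
                                                conservedDivergence = 0,
                                                nQueryOnly = 5L,
                                                nSubjectOnly = 5L,
                                                nSnpsPerSpecies = 0L))
  qw <- extractWindows(pair$query, pair$truth$conservedQuery, 40L)$windows
  sw <- extractWindows(pair$subject, pair$truth$conservedSubject,
                       40L)$windows
  for (i in seq_len(nrow(qw))) {
    aln <- alignWindows(list(seq = qw$seq[i], centerIndex = 41L),
                        list(seq = sw$seq[i], centerIndex = 41L))
    expect_equal(aln$identical, 81L)
  }
})

test_that("config validation rejects unsafe divergence and bad distributions", {
  expect_error(simulationConfig(conservedDivergence = 0.2), "margin")
  expect_error(simulationConfig(backgroundDivergence = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(conservedLevel = c(0.5, 0.6)), "sd\\^2")
  expect_error(simulateOrthologPair(
    simulationConfig(chromLength = 2000L)), "genome too small")
})

test_that("pileup simulation respects the true levels at the extremes", {
  cfg <- simulationConfig(seed = 120, nConserved = 5L, nQueryOnly = 5L,
                          nSubjectOnly = 0L, nSnpsPerSpecies = 0L,
                          nStrains = 2L, sequencingError = 0,
                          lowQualFraction = 0, coverageLambda = 40,
                          chromLength = 20000L)
  pair <- simulateOrthologPair(cfg)
  pair$truth$levels[] <- rep(c(1, 0), c(5, 5)) # conserved rows first
  d <- tempfile()
  paths <- simulatePileups(pair, d)
  sites <- rbind(pair$truth$conservedQuery,
                 pair$truth$queryOnly[seq_along(pair$truth$conservedQuery)])
  meas <- quantifySites(sites, readMpileup(paths[1]), "s1")
  lev <- setNames(meas$level, meas$key)
  consKeys <- siteKey(pair$truth$conservedQuery)
  expect_true(all(lev[consKeys] == 1))
  expect_true(all(lev[setdiff(names(lev), consKeys)] == 0))
})

test_that("strain panels saturate conserved sites and spread the rest", {
  cfg <- simulationConfig(seed = 130, nConserved = 40L, nQueryOnly = 400L)
  panel <- simulateStrainPanel(cfg)
  expect_length(panel$sets, 15L)
  presence <- sapply(panel$conservedKeys, function(k)
    mean(vapply(panel$sets, function(s) k %in% s, TRUE)))
  expect_true(all(presence >= 14 / 15)) # at most one absent strain each

  two <- simulateStrainPanel(simulationConfig(seed = 131, nStrains = 2L))
  expect_length(two$sets, 2L)
  curve <- accumulationCurve(two$sets)
  expect_length(curve$cumulativeCounts, 2L)

  # with certain presence, two strains cover every conserved site
  sure <- simulateStrainPanel(simulationConfig(seed = 132,
                                               conservedPresence = 1))
  consCurve <- accumulationCurve(lapply(sure$sets, intersect,
                                        sure$conservedKeys))
  expect_equal(consCurve$fractionAtK[2], 1)
})
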