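col <- function(chrom = "c1", pos1 = 100L, A = 0L, C = 0L, G = 0L, T = 0L)
  list(chrom = chrom, pos1 = pos1, A = A, C = C, G = G, T = T, N = 0L)

test_that("editing level is G/(A+G) on the edited strand", {
  m <- measureSite(col(A = 3L, G = 7L), oneSite("c1", 100L))
  expect_equal(m$level, 0.7)
  expect_equal(m$aReads, 3L)
  expect_equal(m$state, "edited")

  # minus strand reads the complement: T is A, C is G
  m2 <- measureSite(col(T = 6L, C = 2L), oneSite("c1", 100L, "-"))
  expect_equal(m2$aReads, 6L)
  expect_equal(m2$gReads, 2L)
  expect_equal(m2$level, 0.25)

  m3 <- measureSite(col(A = 2L), oneSite("c1", 100L))
  expect_equal(m3$state, "no_data") # fewer than three reads

  expect_error(measureSite(col(pos1 = 5L), oneSite("c1", 100L)),
               "does not match")
})

test_that("level complement symmetry: swapped A/G counts mirror the level", {
  set.seed(51)
  for (i in 1:25) {
    a <- sample(0:30, 1); g <- sample(0:30, 1)
    if (a + g == 0) next
    m1 <- measureSite(col(A = a, G = g), oneSite("c1", 100L))
    m2 <- measureSite(col(A = g, G = a), oneSite("c1", 100L))
    expect_equal(m1$level + m2$level, 1)
  }
})

test_that("coverage states partition measurements", {
  expect_equal(classifyState(list(total = 10L, gReads = 3L, level = 0.3)),
               "edited")
  expect_equal(classifyState(list(total = 10L, gReads = 0L, level = 0)),
               "covered_unedited")
  expect_equal(classifyState(list(total = 2L, gReads = 2L, level = 1)),
               "no_data")
  expect_equal(classifyState(list(total = 10L, gReads = 1L, level = 0.1)),
               "covered_unedited") # single G read is not evidence
  set.seed(52)
  for (i in 1:50) {
    a <- sample(0:10, 1); g <- sample(0:10, 1)
    m <- measureSite(col(A = a, G = g), oneSite("c1", 100L))
    expect_true(m$state %in% c("no_data", "edited", "covered_unedited"))
  }
})

test_that("candidate calling applies strict > thresholds", {
  lines <- c(
    paste("c1", 10, "A", 500, paste0(strrep(".", 494), strrep("G", 6)),
          strrep("I", 500), sep = "\t"),
    paste("c1", 20, "A", 100, paste0(strrep(".", 95), strrep("G", 5)),
          strrep("I", 100), sep = "\t"),
    paste("c1", 30, "A", 1000, paste0(strrep(".", 990), strrep("G", 10)),
          strrep("I", 1000), sep = "\t"))
  f <- tempfile(); writeLines(lines, f)
  called <- callCandidates(readMpileup(f))
  expect_equal(called$pos1, 10L)       # 6 > 5 and 6/500 = 0.012 > 0.01
  expect_equal(attr(called, "levels"), 6 / 500)
  # pos 20: 5 edited reads is not > 5; pos 30: 10/1000 = 0.01 is not > 0.01
})

test_that("matrix assembly fills missing cells and rejects duplicates", {
  sites <- siteTable("c1", c(10L, 20L, 30L), "+")
  pu <- data.frame(chrom = "c1", pos1 = c(10L, 20L, 30L), ref = "A",
                   depth = 10L, A = 5L, C = 0L, G = 5L, T = 0L, N = 0L)
  m1 <- quantifySites(sites, pu, "s1")
  m2 <- quantifySites(sites[1:2, ], pu, "s2")
  mat <- buildMatrix(rbind(m1, m2))
  expect_equal(dim(mat), c(3L, 2L))
  expect_equal(sum(editingStates(mat) == "no_data"), 1L)
  expect_equal(editingStates(mat)["c1:30:+", "s2"], "no_data")
  expect_true(all(editingLevels(mat)[editingStates(mat) == "edited"] == 0.5))
  expect_error(buildMatrix(rbind(m1, m1)), "duplicate")
})

test_that("level summaries recover per-site and group statistics", {
  sites <- siteTable("c1", c(10L, 20L, 30L), "+")
  meas <- do.call(rbind, lapply(1:3, function(k) {
    pu <- data.frame(chrom = "c1", pos1 = c(10L, 20L, 30L), ref = "A",
                     depth = 20L, A = c(10L, 18L, 4L), C = 0L,
                     G = c(10L, 2L, 16L), T = 0L, N = 0L)
    quantifySites(sites, pu, paste0("s", k))
  }))
  mat <- buildMatrix(meas)
  s <- summarizeLevels(mat)
  expect_equal(s$perSite$meanLevel, c(0.5, 0.1, 0.8))
  expect_equal(s$perSite$sdLevel, c(0, 0, 0))
  expect_equal(levelCorrelation(mat, mat)$r, 1)
})

test_that("independent panels are uncorrelated and planted groups are recovered", {
  set.seed(53)
  nSites <- 200L; nSamp <- 15L
  sites <- siteTable("c1", seq(10L, by = 10L, length.out = nSites), "+")
  simPanel <- function(levels) {
    do.call(rbind, lapply(seq_len(nSamp), function(k) {
      depth <- 60L
      g <- rbinom(nSites, depth, levels)
      pu <- data.frame(chrom = "c1", pos1 = sites$pos1, ref = "A",
                       depth = depth, A = depth - g, C = 0L, G = g, T = 0L,
                       N = 0L)
      quantifySites(sites, pu, sprintf("s%02d", k))
    }))
  }
  conserved <- seq_len(50L)
  lv <- rep(NA_real_, nSites)
  m1 <- buildMatrix(simPanel(runif(nSites)))
  m2 <- buildMatrix(simPanel(runif(nSites)))
  expect_lt(abs(levelCorrelation(m1, m2)$r), 0.2)

  # Beta-planted groups: conserved around 0.5 (sd 0.1), others around 0.1
  # (sd 0.2); 50 sites x 15 samples recovers group means within 0.03
  betaDraw <- function(n, mean, sd) {
    nu <- mean * (1 - mean) / sd^2 - 1
    rbeta(n, mean * nu, (1 - mean) * nu)
  }
  sites50 <- siteTable("c1", seq(10L, by = 10L, length.out = 100L), "+")
  meas <- do.call(rbind, lapply(seq_len(nSamp), function(k) {
    lev <- c(betaDraw(50, 0.5, 0.1), betaDraw(50, 0.1, 0.2))
    depth <- 60L
    g <- rbinom(100L, depth, lev)
    pu <- data.frame(chrom = "c1", pos1 = sites50$pos1, ref = "A",
                     depth = depth, A = depth - g, C = 0L, G = g, T = 0L,
                     N = 0L)
    quantifySites(sites50, pu, sprintf("s%02d", k))
  }))
  mat <- buildMatrix(meas)
  grp <- setNames(rep(c("conserved", "other"), each = 50L),
                  siteKey(sites50))
  gs <- summarizeLevels(mat, grp)$groupSummary
  expect_lt(abs(gs$meanLevel[gs$group == "conserved"] - 0.5), 0.03)
  expect_lt(abs(gs$meanLevel[gs$group == "other"] - 0.1), 0.03)
})
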