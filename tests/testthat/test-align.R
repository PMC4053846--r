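test_that("self-alignment of a window is perfect with paired centers", {
  set.seed(1)
  w <- asWindow(randSeq(81))
  a <- alignWindows(w, w)
  expect_equal(a$alignedLength, 81L)
  expect_equal(a$identical, 81L)
  expect_equal(a$gaps, 0L)
  expect_true(a$centersPaired)
  expect_true(a$centerMatch)
})

test_that("scattered substitutions reduce the identical count exactly", {
  set.seed(2)
  q <- randSeq(81)
  s <- mutateSeq(q, 11, allowed = setdiff(1:81, 41))
  a <- alignWindows(asWindow(q), asWindow(s))
  expect_equal(a$identical, 70L)
  expect_true(a$centersPaired)
  expect_true(a$centerMatch)
})

test_that("a center mismatch is recorded even at high identity", {
  set.seed(3)
  q <- randSeq(81)
  substr(q, 41, 41) <- "A"
  s <- q
  substr(s, 41, 41) <- "C"
  a <- alignWindows(asWindow(q), asWindow(s))
  expect_equal(a$identical, 80L)
  expect_true(a$centersPaired)
  expect_false(a$centerMatch)
})

test_that("aligner agrees with the naive DP oracle on random short pairs", {
  set.seed(4)
  for (i in 1:220) {
    n <- sample(5:30, 1); m <- sample(5:30, 1)
    q <- randSeq(n); s <- randSeq(m)
    qc <- sample(n, 1); sc <- sample(m, 1)
    got <- alignWindows(asWindow(q, qc), asWindow(s, sc))
    want <- naiveLocalAlign(q, s, qCenter = qc, sCenter = sc)
    expect_equal(got$score, want$score)
    expect_equal(got$identical, want$identical)
    expect_equal(got$alignedLength, want$alignedLength)
    expect_equal(got$gaps, want$gaps)
    expect_equal(got$centersPaired, want$centersPaired)
    expect_equal(got$centerMatch, want$centerMatch)
  }
})

test_that("aligner score matches Biostrings pairwiseAlignment on random pairs", {
  set.seed(5)
  for (i in 1:40) {
    q <- randSeq(60); s <- randSeq(60)
    got <- alignWindows(asWindow(q, 30), asWindow(s, 30))$score
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE)
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(got, as.integer(ref))
  }
})

test_that("optimal local score is symmetric under the symmetric scheme", {
  set.seed(6)
  for (i in 1:30) {
    q <- randSeq(50); s <- randSeq(50)
    expect_equal(alignWindows(asWindow(q, 25), asWindow(s, 25))$score,
                 alignWindows(asWindow(s, 25), asWindow(q, 25))$score)
  }
})

test_that("N columns never count as identical", {
  a <- alignWindows(asWindow("ACGNNACG", 4), asWindow("ACGNNACG", 4))
  expect_true(a$identical <= 6)
})

test_that("the conservation criterion enforces identity, pairing and center base", {
  set.seed(7)
  q <- randSeq(81); substr(q, 41, 41) <- "A"
  pass <- alignWindows(asWindow(q), asWindow(q))
  expect_true(evaluateHit(pass))
  low <- pass; low$identical <- 69L
  expect_false(evaluateHit(low))
  at70 <- pass; at70$identical <- 70L
  expect_true(evaluateHit(at70))
  # SNP mode relaxes the center base but not the pairing: a G-G center
  # passes, and even a mismatched center column passes when paired
  g <- q; substr(g, 41, 41) <- "G"
  snp <- alignWindows(asWindow(g), asWindow(g))
  expect_false(evaluateHit(snp))
  expect_true(evaluateHit(snp, requireCenterBase = NULL))
  g2 <- g; substr(g2, 41, 41) <- "T"
  snp2 <- alignWindows(asWindow(g), asWindow(g2))
  expect_true(snp2$centersPaired && !snp2$centerMatch)
  expect_false(evaluateHit(snp2))
  expect_true(evaluateHit(snp2, requireCenterBase = NULL))
})
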