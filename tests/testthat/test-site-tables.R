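test_that("tsv dialect parses 1-based records", {
  f <- tempfile()
  writeLines(c("species\tchrom\tpos\tstrand\tgene\tregion\tsubstitution\tsource",
               "human\tchr4\t158257875\t+\tGRIA2\tCDS\tNA\ttest"), f)
  s <- readSiteTable(f, "tsv")
  expect_equal(s$chrom, "chr4")
  expect_equal(s$pos1, 158257875L)
  expect_equal(s$strand, "+")
  expect_equal(s$gene, "GRIA2")
  expect_equal(s$region, "CDS")
})

test_that("BED6 converts 0-based starts and rejects malformed intervals", {
  f <- tempfile()
  writeLines("chr1\t99\t100\tx\t0\t+", f)
  s <- readSiteTable(f, "bed6")
  expect_equal(s$pos1, 100L)
  writeLines("chr1\t-1\t0\tx\t0\t+", f)
  expect_error(readSiteTable(f, "bed6"), "negative")
  writeLines("chr1\t10\t14\tx\t0\t+", f)
  expect_error(readSiteTable(f, "bed6"), "width 1")
})

test_that("site tables round-trip losslessly through both dialects", {
  s <- siteTable(chrom = c("chr1", "chr2"), pos1 = c(100L, 7L),
                 strand = c("+", "-"), species = "human",
                 gene = c("G1", NA), region = c("CDS", NA),
                 substitution = c("NM_1:c.A1G:p.K1R", NA), source = "t")
  f1 <- tempfile(); f2 <- tempfile()
  writeSiteTable(s, f1, "tsv")
  expect_identical(readSiteTable(f1, "tsv"), s)
  writeSiteTable(readSiteTable(f1, "tsv"), f2, "tsv")
  expect_identical(readLines(f1), readLines(f2)) # byte-identical
  fb <- tempfile()
  writeSiteTable(s, fb, "bed6")
  b <- readSiteTable(fb, "bed6", species = "human")
  expect_equal(b$pos1, s$pos1)
  expect_equal(b$strand, s$strand)
})

test_that("strand and position validation reject malformed records", {
  expect_error(siteTable("chr1", 0L, "+"), "1-based")
  expect_error(siteTable("chr1", 10L, "*"), "strand")
  expect_error(siteTable("chr1", c(1L, 2L), "+",
                         species = c("human", "mouse")), "one species")
})

test_that("merging deduplicates by (chrom, pos1, strand) and concatenates sources", {
  t1 <- siteTable(c("chr1", "chr1", "chr2"), c(10L, 20L, 5L), "+",
                  source = "a")
  t2 <- siteTable(c("chr1", "chr3"), c(10L, 9L), "+", source = "b")
  m <- mergeSiteDatasets(list(t1, t2))
  expect_equal(nrow(m), 4L) # 3 + 2 sharing one site
  expect_equal(m$source[m$chrom == "chr1" & m$pos1 == 10L], "a;b")
  expect_equal(order(m$chrom, m$pos1), seq_len(nrow(m)))

  expect_identical(mergeSiteDatasets(list(t1)), t1)

  # strand is part of the identity
  p <- siteTable("chr1", 10L, "+"); q <- siteTable("chr1", 10L, "-")
  expect_equal(nrow(mergeSiteDatasets(list(p, q))), 2L)

  hum <- siteTable("chr1", 1L, "+", species = "human")
  mou <- siteTable("chr1", 1L, "+", species = "mouse")
  expect_error(mergeSiteDatasets(list(hum, mou)), "different species")
})
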