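# Independent oracles and small fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute k positions of `seq` (1-based indices drawn from `allowed`)
# with a different base
mutateSeq <- function(seq, k, allowed = seq_len(nchar(seq))) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(allowed, k)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

complementBase_test <- function(b) chartr("ACGT", "TGCA", b)

revComp <- function(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")

asWindow <- function(seq, center = (nchar(seq) + 1L) %/% 2L)
  list(seq = seq, centerIndex = as.integer(center))

# Naive affine-gap local-alignment oracle, written independently of the
# package aligner but following the same documented conventions: gap of
# length k costs open + k*extend; traceback prefers diagonal, then up, then
# left; best cell is the first maximum in row-major order; N never matches.
naiveLocalAlign <- function(q, s, match = 2, mismatch = -3, open = -5,
                            extend = -2, qCenter = 0, sCenter = 0) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  sub <- function(a, b) if (a == "N" || b == "N") mismatch
                        else if (a == b) match else mismatch
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i, j + 1] + open + extend, E[i, j + 1] + extend)
    F[i + 1, j + 1] <- max(H[i + 1, j] + open + extend, F[i + 1, j] + extend)
    d <- H[i, j] + sub(qc[i], sc[j])
    H[i + 1, j + 1] <- max(0, d, E[i + 1, j + 1], F[i + 1, j + 1])
    if (H[i + 1, j + 1] > best) { best <- H[i + 1, j + 1]; bi <- i; bj <- j }
  }
  out <- list(score = best, identical = 0L, alignedLength = 0L, gaps = 0L,
              centersPaired = FALSE, centerMatch = FALSE)
  if (best == 0) return(out)
  i <- bi; j <- bj; state <- "H"
  repeat {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      d <- H[i, j] + sub(qc[i], sc[j])
      if (h == d) {
        out$alignedLength <- out$alignedLength + 1L
        idcol <- qc[i] != "N" && qc[i] == sc[j]
        if (idcol) out$identical <- out$identical + 1L
        if (i == qCenter && j == sCenter) {
          out$centersPaired <- TRUE
          out$centerMatch <- idcol
        }
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E" else state <- "F"
    } else if (state == "E") {
      out$alignedLength <- out$alignedLength + 1L
      out$gaps <- out$gaps + 1L
      fromH <- E[i + 1, j + 1] == H[i, j + 1] + open + extend
      i <- i - 1
      if (fromH) state <- "H"
    } else {
      out$alignedLength <- out$alignedLength + 1L
      out$gaps <- out$gaps + 1L
      fromH <- F[i + 1, j + 1] == H[i + 1, j] + open + extend
      j <- j - 1
      if (fromH) state <- "H"
    }
  }
  out
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (same <=, with the conventional relative
# tolerance, as the exact test's definition).
fisherOracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Exhaustive minimal-addition ordering: independently re-derives, step by
# step over all remaining samples, which one adds the fewest uncovered
# sites (lexicographic tie-break).
exhaustiveAccumulation <- function(siteSets) {
  remaining <- sort(names(siteSets))
  covered <- character(0)
  ord <- character(0)
  cum <- integer(0)
  while (length(remaining) > 0) {
    nNew <- sapply(remaining, function(nm)
      sum(!(unique(siteSets[[nm]]) %in% covered)))
    cand <- remaining[nNew == min(nNew)]
    pick <- sort(cand)[1]
    covered <- unique(c(covered, siteSets[[pick]]))
    ord <- c(ord, pick)
    cum <- c(cum, length(covered))
    remaining <- setdiff(remaining, pick)
  }
  list(order = ord, cumulative = cum)
}

# a window plus a search sequence with a planted (optionally degraded)
# reverse-complement ECS after a random spacer
makeEcsCase <- function(nSubs = 0, spacer = 500, seed = 91) {
  set.seed(seed)
  w <- randSeq(81)
  substr(w, 41, 41) <- "A"
  ecs <- revComp(w)
  if (nSubs > 0) ecs <- mutateSeq(ecs, nSubs, allowed = 5:77)
  searchSeq <- paste0(w, randSeq(spacer), ecs)
  list(window = list(seq = w, centerIndex = 41L,
                     site = oneSite("c1", 41L)),
       searchSeq = searchSeq, ecsStart = 81 + spacer + 1)
}

# one-row site helper
oneSite <- function(chrom, pos1, strand = "+", species = "query", ...)
  siteTable(chrom = chrom, pos1 = pos1, strand = strand, species = species,
            ...)

# write a toy FASTA and load it
toyGenome <- function(seqs, species = "toy") {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), fa)
  loadGenome(fa, species = species)
}
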