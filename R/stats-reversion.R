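#' Genomic counterpart bases of editing sites in another species
#'
#' For each editing site, aligns its edited-strand window against the
#' window at the same coordinates in the other genome and reads off the
#' base paired with the edited position. The identity requirement
#' (`identical >= minIdentical`) still applies, but — unlike the
#' conservation screen — the paired base may be anything: requiring A-A
#' would exclude exactly the hardwired-G (reversion) cases being counted.
#' Sites whose window cannot be extracted, whose alignment stays below the
#' identity threshold, or whose center falls in a gap are excluded from the
#' matched set and counted separately.
#'
#' @param sites site data.frame in `genomeFrom` coordinates.
#' @param genomeFrom,genomeTo [GenomeAssembly-class] objects sharing
#'   coordinates (e.g. a simulated ortholog pair).
#' @param flank,minIdentical,params as in [runScreen()].
#' @param requireCenterA validate the edited base as A in `genomeFrom`
#'   (TRUE for editing sites, FALSE for arbitrary positions).
#' @return data.frame with one row per extractable site: key, matched,
#'   counterpart (base or NA).
#' @export
reversionCounterparts <- function(sites, genomeFrom, genomeTo, flank = 40L,
                                  minIdentical = 70L,
                                  params = alignmentParams(),
                                  requireCenterA = TRUE) {
  fx <- extractWindows(genomeFrom, sites, flank, requireCenterA = requireCenterA)
  fw <- fx$windows
  if (!nrow(fw)) stop("no extractable windows")
  tx <- extractWindows(genomeTo, fw[SITE_COLUMNS], flank,
                       requireCenterA = FALSE)
  tw <- tx$windows
  idx <- match(siteKey(tw), siteKey(fw))
  aln <- .sw_align_pairs(fw$seq[idx], tw$seq, params$match, params$mismatch,
                         params$gapOpen, params$gapExtend,
                         fw$centerIndex[idx], tw$centerIndex)
  matched <- aln$identical >= minIdentical & aln$qCenterPairedPos > 0L &
    aln$qCenterPairedChar != ""
  data.frame(key = siteKey(tw), matched = matched,
             counterpart = ifelse(matched, aln$qCenterPairedChar,
                                  NA_character_),
             identical = aln$identical, stringsAsFactors = FALSE)
}

directionReport <- function(label, counterparts, controlCounterparts = NULL) {
  cp <- counterparts$counterpart[counterparts$matched]
  cp <- cp[cp %in% c("A", "C", "G", "T")]
  counts <- table(factor(cp, levels = c("A", "C", "G", "T")))
  matched <- sum(counts)
  rep <- list(direction = label, matchedSites = matched,
              counterpartCounts = counts,
              fractionG = if (matched) unname(counts["G"]) / matched
                          else NA_real_,
              fractionGofAG = if (sum(counts[c("A", "G")]) > 0)
                unname(counts["G"]) / sum(counts[c("A", "G")]) else NA_real_,
              unmatched = nrow(counterparts) - matched,
              controlMatched = NA_integer_, controlFractionG = NA_real_)
  if (!is.null(controlCounterparts)) {
    ccp <- controlCounterparts$counterpart[controlCounterparts$matched]
    ccp <- ccp[ccp %in% c("A", "C", "G", "T")]
    rep$controlMatched <- length(ccp)
    rep$controlFractionG <- if (length(ccp)) mean(ccp == "G") else NA_real_
  }
  rep
}

#' Nearest adjacent non-edited adenosines
#'
#' For each editing site, picks the closest 'A' on the edited strand within
#' `+/- maxOffset` nt that is not itself a listed editing site; distance
#' ties resolve upstream (5') first. Used as the control of the reversion
#' analysis: adjacent non-edited As should show no cross-species G
#' asymmetry.
#'
#' @param sites site data.frame.
#' @param genome their [GenomeAssembly-class].
#' @param maxOffset search radius in nt (default 20).
#' @return site data.frame of control positions (sites with no eligible A
#'   are dropped).
#' @export
adjacentNonEditedA <- function(sites, genome, maxOffset = 20L) {
  editedKeys <- siteKey(sites)
  cand <- seq(-maxOffset, maxOffset)
  offs <- setdiff(cand[order(abs(cand), cand)], 0L)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, , drop = FALSE]
    for (off in offs) {
      pos <- if (s$strand == "+") s$pos1 + off else s$pos1 - off
      len <- chromLengths(genome)[s$chrom]
      if (pos < 1L || pos > len) next
      base <- fetchSeq(genome, s$chrom, pos - 1L, pos, s$strand)
      if (base != "A") next
      key <- paste(s$chrom, pos, s$strand, sep = ":")
      if (key %in% editedKeys) next
      out <- s
      out$pos1 <- as.integer(pos)
      out$source <- "adjacent_A_control"
      return(out)
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- sites[integer(0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' G-reversion asymmetry between two species' editing sets
#'
#' Editing restores an ancestral G at the RNA level when the orthologous
#' genomic position in the other species carries a hardwired G. This
#' analysis measures, in both directions, the fraction of matched editing
#' sites whose counterpart base is G, a matched control built from adjacent
#' non-edited adenosines, and tests the direction asymmetry with a 2x2
#' Fisher exact test (G vs non-G, direction 1 vs direction 2). The sample
#' odds ratio `(g1 * n2) / (n1 * g2)` and its Woolf 95% confidence interval
#' are reported alongside the two fractions and their ratio.
#'
#' @param sitesDir1 editing sites of species 1 (coordinates of `genome1`).
#' @param sitesDir2 editing sites of species 2 (coordinates of `genome2`).
#' @param genome1,genome2 [GenomeAssembly-class] objects sharing a
#'   coordinate system (simulated ortholog pair).
#' @param flank,minIdentical,params as in [runScreen()].
#' @param controlOffsetMax radius for the adjacent-A control (default 20).
#' @param computeControl run the adjacent-A control (default TRUE).
#' @return list of class `reversionAnalysis`: `dir1`, `dir2` (direction
#'   reports), `contingency`, `oddsRatio`, `orCI`, `fisherP`,
#'   `fractionRatio`.
#' @export
reversionAnalysis <- function(sitesDir1, sitesDir2, genome1, genome2,
                              flank = 40L, minIdentical = 70L,
                              params = alignmentParams(),
                              controlOffsetMax = 20L,
                              computeControl = TRUE) {
  cp1 <- reversionCounterparts(sitesDir1, genome1, genome2, flank,
                               minIdentical, params)
  cp2 <- reversionCounterparts(sitesDir2, genome2, genome1, flank,
                               minIdentical, params)
  ctl1 <- ctl2 <- NULL
  if (computeControl) {
    adj1 <- adjacentNonEditedA(sitesDir1, genome1, controlOffsetMax)
    adj2 <- adjacentNonEditedA(sitesDir2, genome2, controlOffsetMax)
    if (nrow(adj1))
      ctl1 <- reversionCounterparts(adj1, genome1, genome2, flank,
                                    minIdentical, params)
    if (nrow(adj2))
      ctl2 <- reversionCounterparts(adj2, genome2, genome1, flank,
                                    minIdentical, params)
  }
  r1 <- directionReport("dir1_to_dir2", cp1, ctl1)
  r2 <- directionReport("dir2_to_dir1", cp2, ctl2)
  g1 <- unname(r1$counterpartCounts["G"]); n1 <- r1$matchedSites - g1
  g2 <- unname(r2$counterpartCounts["G"]); n2 <- r2$matchedSites - g2
  tab <- matrix(c(g1, n1, g2, n2), nrow = 2, byrow = TRUE,
                dimnames = list(c("dir1", "dir2"), c("G", "nonG")))
  orEst <- (g1 * n2) / (n1 * g2)
  se <- sqrt(1 / g1 + 1 / n1 + 1 / g2 + 1 / n2)
  orCI <- exp(log(orEst) + c(-1, 1) * 1.96 * se)
  fisherP <- fisher.test(tab)$p.value
  structure(list(dir1 = r1, dir2 = r2, contingency = tab, oddsRatio = orEst,
                 orCI = orCI, fisherP = fisherP,
                 fractionRatio = r1$fractionG / r2$fractionG),
            class = "reversionAnalysis")
}

#' @export
print.reversionAnalysis <- function(x, ...) {
  cat("reversionAnalysis\n")
  cat(sprintf("  %s: %d matched, fraction G = %.3f (control %.3f)\n",
              x$dir1$direction, x$dir1$matchedSites, x$dir1$fractionG,
              x$dir1$controlFractionG))
  cat(sprintf("  %s: %d matched, fraction G = %.3f (control %.3f)\n",
              x$dir2$direction, x$dir2$matchedSites, x$dir2$fractionG,
              x$dir2$controlFractionG))
  cat(sprintf("  odds ratio %.3f [%.3f, %.3f], Fisher p = %.3g\n",
              x$oddsRatio, x$orCI[1], x$orCI[2], x$fisherP))
  invisible(x)
}
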