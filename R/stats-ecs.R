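#' Scan for candidate exon complementary sequences (ECS)
#'
#' The dsRNA structure ADAR requires pairs the edited region with a nearby
#' complementary stretch (the ECS, typically intronic). This scan detects
#' candidate ECS at the sequence level: the site's 81-nt window is locally
#' aligned against the reverse complement of a surrounding locus sequence,
#' and every non-self hit with at least `minIdentical` identical columns is
#' reported, best first. Hits are candidate complements — no structure or
#' free energy is computed. After each hit the matched stretch is masked
#' with N and the scan repeats, so several ECS candidates per site can be
#' returned.
#'
#' @param window window list from [extractWindow()] (fields `seq`,
#'   `centerIndex`, `site`).
#' @param searchSeq plus-strand locus sequence containing the window.
#' @param minIdentical identity threshold (default 70).
#' @param params [alignmentParams()] scoring.
#' @param windowStart1 1-based start of the window's plus-strand slice
#'   within `searchSeq`; located by exact match when NULL.
#' @param maxHits scan stops after this many hits (default 10).
#' @return data.frame of hits: start1/end1 (plus-strand interval of the
#'   complementary stretch within `searchSeq`), identical, alignedLength,
#'   score, selfOverlap.
#' @export
findEcs <- function(window, searchSeq, minIdentical = 70L,
                    params = alignmentParams(), windowStart1 = NULL,
                    maxHits = 10L) {
  L <- nchar(searchSeq)
  w <- nchar(window$seq)
  if (L < w) stop("search sequence shorter than the window")
  plusWindow <- if (window$site$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(window$seq)))
  else window$seq
  if (is.null(windowStart1)) {
    windowStart1 <- as.integer(regexpr(plusWindow, searchSeq, fixed = TRUE))
    if (windowStart1 < 0L)
      stop("window not found in search sequence; give windowStart1")
  }
  selfIv <- c(windowStart1, windowStart1 + w - 1L)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(searchSeq)))
  hits <- NULL
  for (k in seq_len(maxHits)) {
    aln <- .sw_align(window$seq, rc, params$match, params$mismatch,
                     params$gapOpen, params$gapExtend, window$centerIndex, 0L)
    if (aln$identical < minIdentical) break
    # subject interval in RC coordinates -> plus-strand interval
    start1 <- L - aln$send + 1L
    end1 <- L - aln$sstart + 1L
    selfOverlap <- start1 <= selfIv[2] && end1 >= selfIv[1]
    hits <- rbind(hits, data.frame(
      start1 = start1, end1 = end1, identical = aln$identical,
      alignedLength = aln$alignedLength, score = aln$score,
      selfOverlap = selfOverlap, stringsAsFactors = FALSE))
    # mask the hit and rescan
    substr(rc, aln$sstart, aln$send) <- strrep("N", aln$send - aln$sstart + 1L)
  }
  if (is.null(hits))
    hits <- data.frame(start1 = integer(), end1 = integer(),
                       identical = integer(), alignedLength = integer(),
                       score = integer(), selfOverlap = logical(),
                       stringsAsFactors = FALSE)
  out <- hits[!hits$selfOverlap, , drop = FALSE]
  out <- out[order(-out$identical, out$start1), , drop = FALSE]
  rownames(out) <- NULL
  out
}
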