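#' Alignment scoring parameters
#'
#' Scoring for the exact local (Smith–Waterman, affine-gap) aligner used
#' throughout the screen. Defaults reward like discontiguous-megablast:
#' match +2, mismatch -3, gap of length k costs `gapOpen + k * gapExtend`
#' (-5 - 2k). N never matches, including against N.
#'
#' @param match,mismatch,gapOpen,gapExtend integer scores; gap penalties are
#'   negative.
#' @return a list of class `alignmentParams`.
#' @export
alignmentParams <- function(match = 2L, mismatch = -3L, gapOpen = -5L,
                            gapExtend = -2L) {
  stopifnot(match > 0, mismatch < 0, gapOpen <= 0, gapExtend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpen = as.integer(gapOpen),
                 gapExtend = as.integer(gapExtend)),
            class = "alignmentParams")
}

#' Extract the flanking window around a site
#'
#' Returns the `2*flank + 1` nt sequence centered on the site, read on the
#' edited strand: the plus-strand slice `[pos1-1-flank, pos1+flank)` for
#' plus-strand sites, its reverse complement for minus-strand sites. The
#' edited base sits at `centerIndex = flank + 1` (1-based) and is validated
#' to be 'A' for editing sites (`requireCenterA = TRUE`); SNP windows relax
#' that check. Sites closer than `flank` to a contig end cannot yield a full
#' window and are an error here (batch extraction skips them with a warning).
#'
#' @param genome a [GenomeAssembly-class].
#' @param site one-row site data.frame.
#' @param flank flanking bases on each side (default 40, so 81-nt windows).
#' @param requireCenterA must the center base be 'A'?
#' @return list with `seq`, `centerIndex`, and the site row.
#' @export
extractWindow <- function(genome, site, flank = 40L, requireCenterA = TRUE) {
  flank <- as.integer(flank)
  len <- chromLengths(genome)[site$chrom]
  if (is.na(len)) stop("unknown chromosome: ", site$chrom)
  start0 <- site$pos1 - 1L - flank
  end0 <- site$pos1 + flank
  if (start0 < 0L || end0 > len)
    stop("site ", siteKey(site), " is within ", flank, " nt of a contig end")
  seq <- fetchSeq(genome, site$chrom, start0, end0, site$strand)
  center <- flank + 1L
  if (requireCenterA && substr(seq, center, center) != "A")
    stop("center base of editing site ", siteKey(site), " is '",
         substr(seq, center, center), "', not 'A'")
  list(seq = seq, centerIndex = center, site = site)
}

#' Extract windows for a whole site table
#'
#' Batch version of [extractWindow()]: out-of-range sites and (for editing
#' sites) sites whose center base is not 'A' are skipped with one summary
#' warning, and returned in the `skipped` element.
#'
#' @inheritParams extractWindow
#' @param sites a site data.frame.
#' @return list with `windows` (site table plus `seq`, `centerIndex`
#'   columns) and `skipped` (site table plus `reason`).
#' @export
extractWindows <- function(genome, sites, flank = 40L, requireCenterA = TRUE) {
  flank <- as.integer(flank)
  lens <- chromLengths(genome)
  len <- lens[sites$chrom]
  inRange <- !is.na(len) & sites$pos1 - 1L - flank >= 0L &
    sites$pos1 + flank <= len
  seqs <- rep(NA_character_, nrow(sites))
  for (i in which(inRange)) {
    seqs[i] <- fetchSeq(genome, sites$chrom[i], sites$pos1[i] - 1L - flank,
                        sites$pos1[i] + flank, sites$strand[i])
  }
  center <- flank + 1L
  centerOk <- !requireCenterA | (!is.na(seqs) &
    substr(seqs, center, center) == "A")
  keep <- inRange & centerOk
  reason <- ifelse(!inRange, "edge",
                   ifelse(!centerOk, "center_not_A", NA_character_))
  if (any(!keep))
    warning(sum(!keep), " site(s) skipped (",
            paste(table(reason[!keep]), names(table(reason[!keep])),
                  collapse = ", "), ")")
  windows <- sites[keep, , drop = FALSE]
  windows$seq <- seqs[keep]
  windows$centerIndex <- center
  skipped <- sites[!keep, , drop = FALSE]
  if (nrow(skipped)) skipped$reason <- reason[!keep]
  rownames(windows) <- NULL
  list(windows = windows, skipped = skipped)
}

#' Align two flanking windows
#'
#' Optimal local alignment under the affine-gap scheme of
#' [alignmentParams()], with deterministic traceback (ties prefer diagonal,
#' then up, then left; the best cell is the first maximum in row-major
#' order; gap runs close as early as possible). Besides the usual statistics
#' the traceback records whether the two center (edited) positions occupy
#' the same alignment column (`centersPaired`), whether that column is an
#' identical match (`centerMatch`), and which subject position/base is
#' paired with the query center (used by the reversion analysis).
#'
#' @param q,s window lists from [extractWindow()], or plain lists with
#'   `seq` and `centerIndex`.
#' @param params an [alignmentParams()] list.
#' @return list of class `windowAlignment` with score, alignedLength,
#'   identical, gaps, qstart/qend/sstart/send, centersPaired, centerMatch,
#'   qCenterPairedPos, qCenterPairedChar, qCenterChar, sCenterChar.
#' @export
alignWindows <- function(q, s, params = alignmentParams()) {
  if (!nzchar(q$seq) || !nzchar(s$seq)) stop("empty window sequence")
  r <- .sw_align(q$seq, s$seq, params$match, params$mismatch, params$gapOpen,
                 params$gapExtend, q$centerIndex, s$centerIndex)
  r$qCenterChar <- substr(q$seq, q$centerIndex, q$centerIndex)
  r$sCenterChar <- substr(s$seq, s$centerIndex, s$centerIndex)
  class(r) <- "windowAlignment"
  r
}

#' @export
print.windowAlignment <- function(x, ...) {
  cat("windowAlignment: score ", x$score, ", ", x$identical, "/",
      x$alignedLength, " identical, ", x$gaps, " gap column(s), centers ",
      if (x$centersPaired) "paired" else "not paired",
      if (x$centersPaired) paste0(" (", if (x$centerMatch) "match" else
        "mismatch", ")"), "\n", sep = "")
  invisible(x)
}

#' Conservation criterion for one window alignment
#'
#' A hit passes when (i) at least `minIdentical` aligned columns are
#' identical (default 70 of the 81 window positions), (ii) the two edited
#' positions fall in the same alignment column, and (iii) that column is an
#' identical match — for editing sites an A aligned to an A
#' (`requireCenterBase = "A"`). SNP control screens pass
#' `requireCenterBase = NULL`, which keeps the positional-correspondence
#' rule (the two variant positions must occupy one alignment column) but
#' drops the identical-match requirement on that column.
#'
#' @param aln a `windowAlignment` from [alignWindows()].
#' @param minIdentical minimum identical columns (default 70).
#' @param requireCenterBase required center base, or `NULL` for none.
#' @return `TRUE` or `FALSE`.
#' @export
evaluateHit <- function(aln, minIdentical = 70L, requireCenterBase = "A") {
  if (aln$identical < minIdentical) return(FALSE)
  if (!isTRUE(aln$centersPaired)) return(FALSE)
  if (!is.null(requireCenterBase) &&
      (!isTRUE(aln$centerMatch) || aln$qCenterChar != requireCenterBase))
    return(FALSE)
  TRUE
}
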