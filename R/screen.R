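#' Run the cross-species conservation screen
#'
#' All-vs-all alignment of query-site windows against subject-site windows,
#' keeping every pair that passes the conservation criterion of
#' [evaluateHit()]: at least `minIdentical` identical columns (default 70 of
#' 81) and the two edited adenosines aligned to each other in one identical
#' column. A query site with any passing subject hit is conserved; multiple
#' hits are all reported but the site is counted once (no reciprocal-best
#' requirement). Windows that cannot be extracted (contig edge, non-A
#' center) are skipped with a warning and reported in the result.
#'
#' @param querySites,subjectSites site data.frames (one species each).
#' @param queryGenome,subjectGenome [GenomeAssembly-class] objects.
#' @param flank window flank (default 40).
#' @param minIdentical conservation threshold on identical columns
#'   (default 70).
#' @param params [alignmentParams()] scoring.
#' @param requireCenterBase center base constraint, `"A"` for editing
#'   screens, `NULL` for SNP controls.
#' @return a [ScreenResult-class].
#' @export
runScreen <- function(querySites, subjectSites, queryGenome, subjectGenome,
                      flank = 40L, minIdentical = 70L,
                      params = alignmentParams(),
                      requireCenterBase = "A") {
  requireA <- identical(requireCenterBase, "A")
  qx <- extractWindows(queryGenome, querySites, flank, requireCenterA = requireA)
  sx <- extractWindows(subjectGenome, subjectSites, flank,
                       requireCenterA = requireA)
  qw <- qx$windows; sw <- sx$windows
  if (!nrow(qw) || !nrow(sw))
    stop("no alignable windows on the ",
         if (!nrow(qw)) "query" else "subject", " side after filtering")
  hits <- .sw_screen_all(qw$seq, sw$seq, params$match, params$mismatch,
                         params$gapOpen, params$gapExtend, qw$centerIndex,
                         sw$centerIndex, as.integer(minIdentical),
                         !is.null(requireCenterBase),
                         if (is.null(requireCenterBase)) "" else
                           requireCenterBase)
  if (nrow(hits)) {
    pairs <- data.frame(
      qKey = siteKey(qw)[hits$qIndex], sKey = siteKey(sw)[hits$sIndex],
      qChrom = qw$chrom[hits$qIndex], qPos1 = qw$pos1[hits$qIndex],
      qStrand = qw$strand[hits$qIndex], sChrom = sw$chrom[hits$sIndex],
      sPos1 = sw$pos1[hits$sIndex], sStrand = sw$strand[hits$sIndex],
      score = hits$score, alignedLength = hits$alignedLength,
      identical = hits$identical, gaps = hits$gaps,
      stringsAsFactors = FALSE)
    pairs <- pairs[order(-pairs$identical, pairs$qKey, pairs$sKey,
                         method = "radix"), , drop = FALSE]
    rownames(pairs) <- NULL
    conserved <- qw[match(unique(pairs$qKey), siteKey(qw)),
                    SITE_COLUMNS, drop = FALSE]
    rownames(conserved) <- NULL
  } else {
    pairs <- data.frame(qKey = character(), sKey = character(),
                        qChrom = character(), qPos1 = integer(),
                        qStrand = character(), sChrom = character(),
                        sPos1 = integer(), sStrand = character(),
                        score = integer(), alignedLength = integer(),
                        identical = integer(), gaps = integer(),
                        stringsAsFactors = FALSE)
    conserved <- qw[integer(0), SITE_COLUMNS, drop = FALSE]
  }
  new("ScreenResult", pairs = pairs, conservedQuery = conserved,
      nQueryWindows = nrow(qw), nSubjectWindows = nrow(sw),
      parameters = list(flank = as.integer(flank),
                        minIdentical = as.integer(minIdentical),
                        scoring = unclass(params),
                        requireCenterBase = requireCenterBase),
      skipped = list(query = qx$skipped, subject = sx$skipped))
}

#' @describeIn ScreenResult-accessors unique conserved query sites.
#' @param x a `ScreenResult`.
#' @name ScreenResult-accessors
#' @aliases conservedSites screenPairs
#' @export
setMethod("conservedSites", "ScreenResult", function(x) x@conservedQuery)

#' @describeIn ScreenResult-accessors all passing pairs with alignment
#'   statistics, best first.
#' @export
setMethod("screenPairs", "ScreenResult", function(x) x@pairs)

setMethod("show", "ScreenResult", function(object) {
  p <- object@parameters
  cat("ScreenResult: ", nrow(object@conservedQuery), " conserved query",
      " site(s), ", nrow(object@pairs), " passing pair(s)\n", sep = "")
  cat("  windows aligned: ", object@nQueryWindows, " query x ",
      object@nSubjectWindows, " subject (flank ", p$flank,
      ", min identical ", p$minIdentical, ")\n", sep = "")
  nskip <- vapply(object@skipped, nrow, 1L)
  if (any(nskip > 0))
    cat("  skipped: ", nskip[["query"]], " query, ", nskip[["subject"]],
        " subject site(s)\n", sep = "")
})

#' Signal-to-noise arithmetic
#'
#' Chance-level conserved hits are estimated from a SNP control screen and
#' scaled to the editing dataset sizes:
#' `controlNormalized = controlRawHits * (nEditQuery / nControlQuery) *
#' (nEditSubject / nControlSubject)`; the signal-to-noise ratio is
#' `editingHits / controlNormalized` (`Inf` when the control yields no hit,
#' 0 when the editing screen yields none).
#'
#' @param editingHits conserved editing query sites.
#' @param controlRawHits conserved control (SNP) query sites.
#' @param nEditQuery,nEditSubject,nControlQuery,nControlSubject dataset
#'   sizes used for normalization.
#' @return a [SignalNoiseReport-class].
#' @export
signalNoiseReport <- function(editingHits, controlRawHits, nEditQuery,
                              nEditSubject, nControlQuery, nControlSubject) {
  if (min(nEditQuery, nEditSubject, nControlQuery, nControlSubject) <= 0)
    stop("dataset sizes must be positive")
  norm <- controlRawHits * (nEditQuery / nControlQuery) *
    (nEditSubject / nControlSubject)
  ratio <- if (norm == 0) {
    if (editingHits == 0) 0 else Inf
  } else editingHits / norm
  new("SignalNoiseReport", editingHits = as.integer(editingHits),
      controlRawHits = as.integer(controlRawHits),
      sizes = list(nEditQuery = nEditQuery, nEditSubject = nEditSubject,
                   nControlQuery = nControlQuery,
                   nControlSubject = nControlSubject),
      controlNormalized = norm, ratio = ratio)
}

#' Calibrate the screen against a SNP control
#'
#' Runs the identical window-extraction and alignment procedure on SNP
#' tables from both species — same flank, same scoring, same positional
#' center-correspondence rule, but without constraining the center base to
#' 'A' — and scales the control hit count to the editing dataset sizes.
#'
#' @param screen the editing [ScreenResult-class].
#' @param controlQuerySnps,controlSubjectSnps SNP site data.frames.
#' @param queryGenome,subjectGenome [GenomeAssembly-class] objects.
#' @param sizes optional list overriding the normalization sizes
#'   (`nEditQuery`, `nEditSubject`, `nControlQuery`, `nControlSubject`);
#'   defaults to the window counts of the two screens. Overriding lets the
#'   normalization refer to full dataset sizes rather than the aligned
#'   subsets.
#' @return a [SignalNoiseReport-class]; the control `ScreenResult` is
#'   attached as attribute `"controlScreen"`.
#' @export
controlSignalToNoise <- function(screen, controlQuerySnps,
                                 controlSubjectSnps, queryGenome,
                                 subjectGenome, sizes = list()) {
  p <- screen@parameters
  ctrl <- runScreen(controlQuerySnps, controlSubjectSnps, queryGenome,
                    subjectGenome, flank = p$flank,
                    minIdentical = p$minIdentical,
                    params = do.call(alignmentParams, p$scoring),
                    requireCenterBase = NULL)
  sz <- list(nEditQuery = screen@nQueryWindows,
             nEditSubject = screen@nSubjectWindows,
             nControlQuery = ctrl@nQueryWindows,
             nControlSubject = ctrl@nSubjectWindows)
  sz[names(sizes)] <- sizes
  rep <- signalNoiseReport(nrow(screen@conservedQuery),
                           nrow(ctrl@conservedQuery), sz$nEditQuery,
                           sz$nEditSubject, sz$nControlQuery,
                           sz$nControlSubject)
  attr(rep, "controlScreen") <- ctrl
  rep
}

#' @describeIn SignalNoiseReport-accessors the signal-to-noise ratio.
#' @param x a `SignalNoiseReport`.
#' @param ... unused.
#' @name SignalNoiseReport-accessors
#' @aliases signalToNoiseRatio
#' @export
setMethod("signalToNoiseRatio", "SignalNoiseReport", function(x, ...) x@ratio)

setMethod("show", "SignalNoiseReport", function(object) {
  cat("SignalNoiseReport: ", object@editingHits, " editing hit(s) vs ",
      object@controlRawHits, " raw control hit(s)\n", sep = "")
  cat("  normalized control hits: ",
      format(object@controlNormalized, digits = 4),
      "; signal-to-noise ratio: ", format(object@ratio, digits = 4),
      "\n", sep = "")
})
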