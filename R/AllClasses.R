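#' GenomeAssembly: a named set of chromosome sequences
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] holding the uppercase
#' chromosome sequences of one species. Sequences contain only A, C, G, T, N
#' (other IUPAC codes are mapped to N on load). Subsequence access goes
#' through [fetchSeq()], which uses 0-based half-open coordinates internally
#' and returns the reverse complement for minus-strand requests.
#'
#' @slot species single character label for the assembly.
#' @slot sequences a `DNAStringSet`, one element per chromosome, unique names.
#'
#' @seealso [loadGenome()], [fetchSeq()]
#' @export
setClass("GenomeAssembly",
  representation(species = "character", sequences = "DNAStringSet"))

setValidity("GenomeAssembly", function(object) {
  msg <- character()
  if (length(object@species) != 1L || is.na(object@species))
    msg <- c(msg, "'species' must be a single non-NA string")
  nm <- names(object@sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "all chromosomes must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, "duplicate chromosome names")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "empty chromosome sequence")
  if (length(msg)) msg else TRUE
})

#' ScreenResult: outcome of a cross-species conservation screen
#'
#' Produced by [runScreen()]. `pairs` holds every query/subject window pair
#' passing the conservation criterion (>= `minIdentical` identical columns,
#' edited positions aligned to each other in one identical column), sorted by
#' decreasing identical count. `conservedQuery` deduplicates the query sites
#' with at least one passing hit.
#'
#' @slot pairs data.frame of passing pairs with alignment statistics.
#' @slot conservedQuery data.frame of unique conserved query sites.
#' @slot nQueryWindows,nSubjectWindows number of windows actually aligned.
#' @slot parameters list: flank, minIdentical, scoring, requireCenterBase.
#' @slot skipped list of data.frames of skipped query/subject sites.
#'
#' @seealso [runScreen()], [conservedSites()], [screenPairs()]
#' @export
setClass("ScreenResult",
  representation(pairs = "data.frame", conservedQuery = "data.frame",
                 nQueryWindows = "integer", nSubjectWindows = "integer",
                 parameters = "list", skipped = "list"))

setValidity("ScreenResult", function(object) {
  ids <- unique(object@pairs$qKey)
  if (nrow(object@conservedQuery) != length(ids))
    return("conservedQuery must hold exactly the unique query sites in pairs")
  TRUE
})

#' SignalNoiseReport: SNP-calibrated signal-to-noise of the screen
#'
#' The control screen runs SNP windows through the same alignment machinery
#' as the editing screen (without the center-base-A requirement). Raw control
#' hits are scaled to the editing dataset sizes:
#' `controlNormalized = controlRawHits * (nEditQuery/nControlQuery) *
#' (nEditSubject/nControlSubject)`, and
#' `ratio = editingHits / controlNormalized` (`Inf` when no control hit).
#'
#' @slot editingHits,controlRawHits integer hit counts.
#' @slot sizes list with nEditQuery, nEditSubject, nControlQuery,
#'   nControlSubject.
#' @slot controlNormalized,ratio derived statistics.
#'
#' @seealso [controlSignalToNoise()], [signalToNoiseRatio()]
#' @export
setClass("SignalNoiseReport",
  representation(editingHits = "integer", controlRawHits = "integer",
                 sizes = "list", controlNormalized = "numeric",
                 ratio = "numeric"))

#' EditingMatrix: site-by-sample editing measurements
#'
#' A [SummarizedExperiment::SummarizedExperiment] with sites as rows (rowData
#' carries the site table) and samples as columns. Assays: `a`, `g`, `other`
#' (edited-strand read counts), `total`, `level` (G/(A+G), NA when A+G = 0)
#' and `state` (character: "no_data", "edited", "covered_unedited").
#'
#' @seealso [buildMatrix()], [editingLevels()], [editingStates()]
#' @export
setClass("EditingMatrix", contains = "SummarizedExperiment")

setValidity("EditingMatrix", function(object) {
  need <- c("a", "g", "other", "total", "level", "state")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    return(paste0("missing assays: ", paste(setdiff(need, have), collapse = ", ")))
  st <- SummarizedExperiment::assay(object, "state")
  if (!all(st %in% c("no_data", "edited", "covered_unedited")))
    return("invalid state value")
  TRUE
})
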