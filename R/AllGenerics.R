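#' @rdname fetchSeq
#' @export
setGeneric("fetchSeq", function(x, chrom, start0, end0, strand = "+")
  standardGeneric("fetchSeq"))

#' @rdname ScreenResult-accessors
#' @export
setGeneric("conservedSites", function(x) standardGeneric("conservedSites"))

#' @rdname ScreenResult-accessors
#' @export
setGeneric("screenPairs", function(x) standardGeneric("screenPairs"))

#' @rdname SignalNoiseReport-accessors
#' @export
setGeneric("signalToNoiseRatio", function(x, ...)
  standardGeneric("signalToNoiseRatio"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("editingLevels", function(x) standardGeneric("editingLevels"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("editingStates", function(x) standardGeneric("editingStates"))

#' @rdname EditingMatrix-accessors
#' @export
setGeneric("readTotals", function(x) standardGeneric("readTotals"))
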