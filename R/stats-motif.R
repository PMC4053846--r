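#' Neighbor-preference motif matrix
#'
#' Empirical base frequencies at offsets -halfwidth..+halfwidth around the
#' edited base, computed from edited-strand windows. ADAR targets show a
#' depleted G immediately upstream (-1) and an enriched G immediately
#' downstream (+1) of the edited adenosine; the matrix makes both visible
#' and exports cleanly to logo-rendering tools. For editing-site input the
#' offset-0 row is degenerate at A.
#'
#' @param windows window table from [extractWindows()] (needs `seq` and
#'   `centerIndex` columns), or a character vector of equal-length windows
#'   with odd width (center = middle base).
#' @param halfwidth offsets covered on each side (default 10).
#' @return matrix of class `motifMatrix` (rows: offsets, columns A/C/G/T;
#'   rows sum to 1). Attribute `"ic"` carries the per-offset information
#'   content `2 + sum(p * log2(p))` used for sequence logos; `"n"` the
#'   window count.
#' @export
motifMatrix <- function(windows, halfwidth = 10L) {
  if (is.character(windows)) {
    w <- unique(nchar(windows))
    if (length(w) != 1L || w %% 2L == 0L)
      stop("character windows must share one odd width")
    windows <- data.frame(seq = windows, centerIndex = (w + 1L) %/% 2L,
                          stringsAsFactors = FALSE)
  }
  if (!nrow(windows)) stop("no windows")
  center <- windows$centerIndex
  if (any(center - halfwidth < 1L) ||
      any(center + halfwidth > nchar(windows$seq)))
    stop("windows too short for halfwidth ", halfwidth)
  offsets <- seq(-halfwidth, halfwidth)
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, nrow = length(offsets), ncol = 4L,
                 dimnames = list(as.character(offsets), bases))
  for (k in seq_along(offsets)) {
    ch <- substr(windows$seq, center + offsets[k], center + offsets[k])
    tab <- table(factor(ch, levels = bases))
    n <- sum(tab)
    if (n == 0) stop("only N bases at offset ", offsets[k])
    freq[k, ] <- as.numeric(tab) / n
  }
  ic <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(freq, class = c("motifMatrix", "matrix"), ic = ic,
            n = nrow(windows))
}

#' Write a motif matrix as TSV
#'
#' Offsets as rows; columns A, C, G, T and the information content.
#'
#' @param m a [motifMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifMatrix <- function(m, path) {
  df <- data.frame(offset = rownames(m), round(unclass(m)[, , drop = FALSE], 6),
                   ic = round(attr(m, "ic"), 6), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
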