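#' Read samtools-mpileup text with base-quality filtering
#'
#' Parses 6-column samtools mpileup text (chrom, pos, ref, depth, bases,
#' quals; Phred+33 qualities) into per-position, reference-strand base
#' counts. `.`/`,` count as the reference base; letters as alternative bases
#' with lowercase (reverse-strand reads) folded to uppercase, so counts are
#' always reference-strand base counts — site strand is applied later by
#' [measureSite()]. Read-start markers `^` (plus their mapping-quality
#' character), read-end `$`, and inline indel blocks `+n…`/`-n…` are
#' consumed without contributing counts; reference skips `>`/`<` are
#' ignored; deletion placeholders `*` are counted as N (excluded from A/G
#' arithmetic). Base calls with Phred quality below `minPhred` are dropped.
#'
#' @param path mpileup text file.
#' @param minPhred minimum Phred score for a base call to count (default 30).
#' @return data.frame with columns chrom, pos1, ref, depth, A, C, G, T, N.
#' @export
readMpileup <- function(path, minPhred = 30) {
  if (!file.exists(path)) stop("mpileup file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), pos1 = integer(),
                      ref = character(), depth = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      N = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 6L)
  if (length(bad))
    stop("malformed mpileup line ", bad[1], ": fewer than 6 columns")
  counts <- matrix(0L, nrow = length(fields), ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    counts[i, ] <- .parse_pileup_bases(f[5], f[6], f[3], minPhred)
  }
  data.frame(chrom = vapply(fields, `[`, "", 1L),
             pos1 = as.integer(vapply(fields, `[`, "", 2L)),
             ref = toupper(vapply(fields, `[`, "", 3L)),
             depth = as.integer(vapply(fields, `[`, "", 4L)),
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], N = counts[, "N"], stringsAsFactors = FALSE)
}
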