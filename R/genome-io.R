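#' Load a genome assembly from FASTA
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file into a
#' [GenomeAssembly-class]. Sequences are uppercased and any IUPAC code
#' outside A/C/G/T is mapped to N. Record names are truncated at the first
#' whitespace, as is conventional for chromosome FASTA headers.
#'
#' @param path path to a FASTA file.
#' @param species label for the assembly (default: file name without
#'   extension).
#' @return a [GenomeAssembly-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "AACCGGTT"), fa)
#' g <- loadGenome(fa, species = "toy")
#' fetchSeq(g, "c1", 2, 6, "-")  # reverse complement of "CCGG"
#' @export
loadGenome <- function(path, species = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(species))
    species <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence in FASTA: ", path)
  chr <- toupper(as.character(seqs))
  chr <- chartr("RYSWKMBDHV", "NNNNNNNNNN", chr)
  x <- new("GenomeAssembly", species = species,
           sequences = Biostrings::DNAStringSet(chr))
  validObject(x)
  x
}

#' Build a genome assembly from in-memory sequences
#'
#' @param sequences named character vector or `DNAStringSet` of chromosome
#'   sequences (A/C/G/T/N).
#' @param species assembly label.
#' @return a [GenomeAssembly-class].
#' @export
genomeAssembly <- function(sequences, species = "genome") {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  x <- new("GenomeAssembly", species = species, sequences = sequences)
  validObject(x)
  x
}

#' Fetch a genomic subsequence
#'
#' Coordinates are 0-based half-open (`[start0, end0)`), the package's
#' internal convention; user-facing site tables are 1-based. For
#' `strand = "-"` the plus-strand slice is reverse complemented, so the
#' returned string always reads 5' to 3' on the requested strand.
#'
#' @param x a [GenomeAssembly-class].
#' @param chrom chromosome name.
#' @param start0,end0 0-based half-open range, `0 <= start0 < end0 <= length`.
#' @param strand `"+"` or `"-"`.
#' @return a character string of length `end0 - start0`.
#' @rdname fetchSeq
#' @export
setMethod("fetchSeq", "GenomeAssembly",
  function(x, chrom, start0, end0, strand = "+") {
    if (!chrom %in% names(x@sequences))
      stop("unknown chromosome: ", chrom)
    len <- Biostrings::width(x@sequences)[match(chrom, names(x@sequences))]
    if (start0 < 0 || end0 > len || start0 >= end0)
      stop("range [", start0, ",", end0, ") out of bounds for ", chrom,
           " (length ", len, ")")
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
    s <- Biostrings::subseq(x@sequences[[chrom]], start0 + 1L, end0)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })

#' @describeIn GenomeAssembly-class chromosome names.
#' @param x a `GenomeAssembly`.
#' @export
chromNames <- function(x) names(x@sequences)

#' @describeIn GenomeAssembly-class chromosome lengths, named.
#' @export
chromLengths <- function(x)
  setNames(Biostrings::width(x@sequences), names(x@sequences))

#' Write a genome assembly to FASTA
#'
#' Records are written in assembly order, unwrapped (one line per
#' chromosome), which keeps outputs byte-reproducible.
#'
#' @param x a [GenomeAssembly-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x@sequences)) {
    writeLines(paste0(">", nm), con)
    writeLines(as.character(x@sequences[[nm]]), con)
  }
  invisible(path)
}

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly '", object@species, "': ",
      length(object@sequences), " sequence(s), ",
      sum(Biostrings::width(object@sequences)), " bp total\n", sep = "")
  n <- min(5L, length(object@sequences))
  for (i in seq_len(n))
    cat("  ", names(object@sequences)[i], ": ",
        Biostrings::width(object@sequences)[i], " bp\n", sep = "")
  if (length(object@sequences) > n) cat("  ...\n")
})
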