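#' The packaged conserved-site table
#'
#' The 59 human evolutionarily selected editing sites (ESS) shipped with
#' the package as a plain-text fixture: hg19 coordinates, strand, gene,
#' region class and, for annotated coding sites, the
#' transcript/nucleotide/amino-acid substitution string. This is the
#' worked-example input for [classifyRegions()] and the region stage of
#' [runPipeline()].
#'
#' @return a site data.frame with 59 rows.
#' @examples
#' ess <- essSites()
#' classifyRegions(ess)
#' @export
essSites <- function() {
  path <- system.file("extdata", "ess_sites.tsv", package = "EditScreen",
                      mustWork = TRUE)
  readSiteTable(path, dialect = "tsv")
}

#' Dataset-size metadata accompanying the conserved-site table
#'
#' Published sizes of the merged candidate datasets the conserved set was
#' screened from: the merged human set (reported as both 1,432,743 and
#' 1,432,744 in different places of the source; both are recorded, and the
#' Methods figure 1,432,744 is used for derived shares), the merged mouse
#' set, the human non-Alu subset, and the chromosome-X SNP control sizes.
#'
#' @return a named list.
#' @export
essMetadata <- function() {
  path <- system.file("extdata", "ess_metadata.json", package = "EditScreen",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
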