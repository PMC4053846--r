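#' Classify sites by genomic region and recoding consequence
#'
#' Counts sites per region class (CDS, intron, 3UTR, 5UTR, microRNA,
#' intergenic, unannotated). A coding site is non-synonymous iff the
#' reference and alternate amino-acid symbols of its substitution
#' annotation differ (`p.Q607R` — non-synonymous; `p.L594L` — synonymous;
#' stop gains like `p.Q2180stop` count as non-synonymous). Coding sites
#' without a substitution annotation are counted separately
#' (`codingUnannotated`) and excluded from the synonymy denominator. An
#' intronic site is "in a recoding gene" when its gene also carries at
#' least one coding site in the same table.
#'
#' @param sites a site data.frame with `region` annotations (substitution
#'   optional).
#' @return list of class `regionReport`: `total`, `regionCounts`,
#'   `codingRows`, `codingAnnotated`, `codingUnannotated`,
#'   `nonSynonymous`, `synonymous`, `fracNonSynonymous`, `intronic`,
#'   `intronicInRecodingGenes`, `fracIntronicInRecoding`, `recodingGenes`,
#'   `perGene`.
#' @export
classifyRegions <- function(sites) {
  region <- ifelse(is.na(sites$region), "unannotated", sites$region)
  regionCounts <- table(region)
  coding <- region == "CDS"
  aa <- parseSubstitution(sites$substitution)
  annotated <- coding & !is.na(aa$ref)
  nonSyn <- annotated & aa$ref != aa$alt
  syn <- annotated & aa$ref == aa$alt
  recodingGenes <- unique(sites$gene[coding & !is.na(sites$gene)])
  intronic <- region == "intron"
  intronicInRec <- intronic & sites$gene %in% recodingGenes
  if (any(coding & is.na(aa$ref)))
    message(sum(coding & is.na(aa$ref)),
            " coding site(s) without substitution annotation")
  perGene <- table(sites$gene[!is.na(sites$gene)])
  structure(list(
    total = nrow(sites),
    regionCounts = regionCounts,
    codingRows = sum(coding),
    codingAnnotated = sum(annotated),
    codingUnannotated = sum(coding) - sum(annotated),
    nonSynonymous = sum(nonSyn),
    synonymous = sum(syn),
    fracNonSynonymous = if (sum(annotated)) sum(nonSyn) / sum(annotated)
                        else NA_real_,
    intronic = sum(intronic),
    intronicInRecodingGenes = sum(intronicInRec),
    fracIntronicInRecoding = if (sum(intronic))
      sum(intronicInRec) / sum(intronic) else NA_real_,
    recodingGenes = sort(recodingGenes),
    perGene = perGene), class = "regionReport")
}

#' Parse an amino-acid substitution annotation
#'
#' Extracts reference and alternate amino-acid symbols from annotations of
#' the form `NM_000826:c.A1820G:p.Q607R` or a bare `p.Q607R`. `stop`/`*`
#' alternates are kept verbatim (and therefore never equal the reference).
#'
#' @param x character vector of annotation strings.
#' @return data.frame with `ref`, `pos`, `alt` (NA when unparseable).
#' @export
parseSubstitution <- function(x) {
  m <- regmatches(x, regexec("p\\.([A-Za-z])(\\d+)([A-Za-z*]+)\\s*$",
                             ifelse(is.na(x), "", x)))
  ref <- vapply(m, function(g) if (length(g) == 4L) g[2] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g) == 4L) g[3] else NA_character_, "")
  alt <- vapply(m, function(g) if (length(g) == 4L) g[4] else NA_character_, "")
  data.frame(ref = ref, pos = suppressWarnings(as.integer(pos)), alt = alt,
             stringsAsFactors = FALSE)
}

#' @export
print.regionReport <- function(x, ...) {
  cat("regionReport:", x$total, "site(s)\n")
  print(x$regionCounts)
  cat("coding:", x$codingRows, "(", x$codingAnnotated, "annotated;",
      x$nonSynonymous, "non-synonymous,", x$synonymous, "synonymous )\n")
  cat("intronic:", x$intronic, "-", x$intronicInRecodingGenes,
      "in recoding genes\n")
  invisible(x)
}
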