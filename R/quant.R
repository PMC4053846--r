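#' Measure editing at a site from one pileup column
#'
#' Converts reference-strand base counts into edited-strand A/G counts: for
#' plus-strand sites A and G are read directly; for minus-strand sites the
#' edited-strand A reads appear as T and the edited G reads as C on the
#' reference strand. The editing level is `g / (a + g)` (NA when a + g = 0);
#' the coverage state follows [classifyState()].
#'
#' @param col one-row data.frame from [readMpileup()] (or a list with
#'   chrom, pos1 and A/C/G/T counts).
#' @param site one-row site data.frame at the same coordinate.
#' @param sample sample label attached to the measurement.
#' @param ... thresholds passed to [classifyState()].
#' @return one-row data.frame: site key columns, sample, aReads, gReads,
#'   otherReads, total, level, state.
#' @export
measureSite <- function(col, site, sample = "sample", ...) {
  if (col$chrom != site$chrom || col$pos1 != site$pos1)
    stop("pileup column (", col$chrom, ":", col$pos1,
         ") does not match site ", siteKey(site))
  if (site$strand == "+") {
    a <- col$A; g <- col$G; other <- col$C + col$T
  } else {
    a <- col$T; g <- col$C; other <- col$A + col$G
  }
  m <- data.frame(chrom = site$chrom, pos1 = site$pos1, strand = site$strand,
                  key = siteKey(site), sample = sample, aReads = a,
                  gReads = g, otherReads = other, total = a + g + other,
                  level = if (a + g > 0) g / (a + g) else NA_real_,
                  stringsAsFactors = FALSE)
  m$state <- classifyState(m, ...)
  m
}

#' Coverage/evidence state of a measurement
#'
#' Three mutually exclusive states: `"no_data"` when fewer than `minTotal`
#' (default 3) quality-passing edited-strand reads cover the site;
#' `"edited"` when at least `minEditedReads` G reads (default 2) and a level
#' of at least `minLevel` (default 0.01) are seen; `"covered_unedited"`
#' otherwise. The evidence thresholds are deliberately configurable: a
#' single edited read at Phred 30 is indistinguishable from sequencing
#' error.
#'
#' @param m one-row measurement (needs total, gReads, level).
#' @param minTotal,minEditedReads,minLevel thresholds.
#' @return character state.
#' @export
classifyState <- function(m, minTotal = 3L, minEditedReads = 2L,
                          minLevel = 0.01) {
  if (m$total < minTotal) return("no_data")
  if (m$gReads >= minEditedReads && !is.na(m$level) && m$level >= minLevel)
    return("edited")
  "covered_unedited"
}

#' Quantify editing at known sites across a pileup
#'
#' Looks up each site's coordinate in a parsed pileup and measures it;
#' sites absent from the pileup get a zero-count `"no_data"` measurement,
#' so the output always has one row per site.
#'
#' @param sites site data.frame.
#' @param pileup data.frame from [readMpileup()].
#' @param sample sample label.
#' @param ... thresholds passed to [classifyState()].
#' @return measurement data.frame, one row per site.
#' @export
quantifySites <- function(sites, pileup, sample = "sample", ...) {
  idx <- match(paste(sites$chrom, sites$pos1), paste(pileup$chrom, pileup$pos1))
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    if (is.na(idx[i])) {
      col <- list(chrom = sites$chrom[i], pos1 = sites$pos1[i],
                  A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
    } else {
      col <- pileup[idx[i], , drop = FALSE]
    }
    measureSite(col, sites[i, , drop = FALSE], sample, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' De-novo candidate calling from a pileup
#'
#' Scans reference-'A' pileup columns for A-to-G mismatches and calls a
#' candidate when strictly more than `minEditedReads - 1` G reads support
#' it at a level strictly above `minLevel` — i.e. with the defaults, more
#' than five edited reads and a level higher than 0.01 (both strict
#' inequalities). Unstranded pileups cannot assign a strand, so only
#' plus-strand reference-A columns are scanned unless
#' `scanMinusStrand = TRUE`, which additionally calls T-reference columns
#' with C mismatches as minus-strand candidates.
#'
#' @param pileup data.frame from [readMpileup()].
#' @param minEditedReads G reads must exceed `minEditedReads - 1`
#'   (default 6, i.e. "more than five edited reads").
#' @param minLevel level must exceed this (default 0.01).
#' @param species label for emitted sites.
#' @param scanMinusStrand also scan T-reference columns (minus-strand
#'   interpretation).
#' @return a site data.frame of candidates with per-candidate `level`
#'   attached as attribute `"levels"`.
#' @export
callCandidates <- function(pileup, minEditedReads = 6L, minLevel = 0.01,
                           species = "query", scanMinusStrand = FALSE) {
  callOne <- function(ref, aCol, gCol, strand) {
    sel <- pileup$ref == ref
    a <- pileup[[aCol]][sel]; g <- pileup[[gCol]][sel]
    lev <- ifelse(a + g > 0, g / (a + g), NA_real_)
    keep <- g > (minEditedReads - 1L) & !is.na(lev) & lev > minLevel
    if (!any(keep)) return(NULL)
    df <- siteTable(chrom = pileup$chrom[sel][keep],
                    pos1 = pileup$pos1[sel][keep], strand = strand,
                    species = species, source = "mpileup_scan")
    df$level <- lev[keep]
    df
  }
  out <- callOne("A", "A", "G", "+")
  if (scanMinusStrand)
    out <- rbind(out, callOne("T", "T", "C", "-"))
  if (is.null(out))
    out <- cbind(siteTable(character(), integer(), character(),
                           species = character()),
                 data.frame(level = numeric()))
  ord <- order(out$chrom, out$pos1, method = "radix")
  lev <- out$level[ord]
  out$level <- NULL
  out <- out[ord, , drop = FALSE]
  attr(out, "levels") <- lev
  rownames(out) <- NULL
  out
}

#' Assemble measurements into a site-by-sample editing matrix
#'
#' Builds an [EditingMatrix-class] (a `SummarizedExperiment`) from stacked
#' per-sample measurement tables. Rows are sites in genomic order (chrom,
#' pos1, strand), columns are samples in first-appearance order. Missing
#' (site, sample) cells become zero-count `"no_data"` measurements;
#' duplicated cells are an error.
#'
#' @param measurements data.frame as produced by [quantifySites()] (rows
#'   from several samples stacked).
#' @return an [EditingMatrix-class].
#' @export
buildMatrix <- function(measurements) {
  m <- measurements
  if (anyDuplicated(paste(m$key, m$sample)))
    stop("duplicate (site, sample) measurement")
  siteOrd <- unique(m[order(m$chrom, m$pos1, m$strand, method = "radix"),
                      c("chrom", "pos1", "strand", "key")])
  samples <- unique(m$sample)
  ri <- match(m$key, siteOrd$key)
  ci <- match(m$sample, samples)
  mk <- function(col, fill) {
    x <- matrix(fill, nrow = nrow(siteOrd), ncol = length(samples),
                dimnames = list(siteOrd$key, samples))
    x[cbind(ri, ci)] <- m[[col]]
    x
  }
  a <- mk("aReads", 0L); g <- mk("gReads", 0L); other <- mk("otherReads", 0L)
  total <- mk("total", 0L)
  level <- mk("level", NA_real_)
  state <- matrix("no_data", nrow = nrow(siteOrd), ncol = length(samples),
                  dimnames = list(siteOrd$key, samples))
  state[cbind(ri, ci)] <- m$state
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(a = a, g = g, other = other, total = total, level = level,
                  state = state),
    rowData = S4Vectors::DataFrame(siteOrd),
    colData = S4Vectors::DataFrame(sample = samples, row.names = samples))
  new("EditingMatrix", se)
}

#' @describeIn EditingMatrix-accessors editing-level matrix (NA when
#'   undefined).
#' @param x an `EditingMatrix`.
#' @name EditingMatrix-accessors
#' @aliases editingLevels editingStates readTotals
#' @export
setMethod("editingLevels", "EditingMatrix",
  function(x) SummarizedExperiment::assay(x, "level"))

#' @describeIn EditingMatrix-accessors state matrix
#'   (edited / covered_unedited / no_data).
#' @export
setMethod("editingStates", "EditingMatrix",
  function(x) SummarizedExperiment::assay(x, "state"))

#' @describeIn EditingMatrix-accessors total filtered read counts.
#' @export
setMethod("readTotals", "EditingMatrix",
  function(x) SummarizedExperiment::assay(x, "total"))

#' Summarize editing levels per site and per group
#'
#' Per site: mean and standard deviation of the editing level over samples
#' with a defined level (sites with none are excluded and listed), and an
#' expression proxy — the total read count at the site in the designated
#' expression sample (by default the sample with the largest summed
#' coverage). With `groups`, per-group means of the per-site statistics are
#' added together with the raw per-site vectors, ready for off-the-shelf
#' two-group tests.
#'
#' @param mat an [EditingMatrix-class].
#' @param groups optional named assignment of each site key to a group
#'   label.
#' @param expressionSample sample used for the expression proxy; default
#'   the deepest sample.
#' @return list with `perSite` (data.frame), `groupSummary` (data.frame or
#'   NULL), `expressionSample`, `excluded` (site keys with no defined
#'   level).
#' @export
summarizeLevels <- function(mat, groups = NULL, expressionSample = NULL) {
  lev <- editingLevels(mat)
  tot <- readTotals(mat)
  if (is.null(expressionSample))
    expressionSample <- colnames(tot)[which.max(colSums(tot))]
  nDef <- rowSums(!is.na(lev))
  excluded <- rownames(lev)[nDef == 0]
  keep <- nDef > 0
  perSite <- data.frame(
    key = rownames(lev)[keep],
    meanLevel = rowMeans(lev[keep, , drop = FALSE], na.rm = TRUE),
    sdLevel = apply(lev[keep, , drop = FALSE], 1, sd, na.rm = TRUE),
    nDefined = nDef[keep],
    expression = tot[keep, expressionSample],
    stringsAsFactors = FALSE)
  rownames(perSite) <- NULL
  groupSummary <- NULL
  if (!is.null(groups)) {
    perSite$group <- unname(groups[perSite$key])
    sp <- split(perSite, perSite$group)
    groupSummary <- do.call(rbind, lapply(names(sp), function(gname) {
      g <- sp[[gname]]
      data.frame(group = gname, nSites = nrow(g),
                 meanLevel = mean(g$meanLevel),
                 meanSD = mean(g$sdLevel, na.rm = TRUE),
                 meanExpression = mean(g$expression),
                 stringsAsFactors = FALSE)
    }))
  }
  if (length(excluded))
    message(length(excluded), " site(s) without any defined level excluded")
  list(perSite = perSite, groupSummary = groupSummary,
       expressionSample = expressionSample, excluded = excluded)
}

#' Correlate editing levels between two matrices
#'
#' Pearson correlation of per-site mean editing levels, restricted to sites
#' with a defined level in both matrices.
#'
#' @param m1,m2 [EditingMatrix-class] objects sharing site keys.
#' @return list with `r`, `n` (shared defined sites).
#' @export
levelCorrelation <- function(m1, m2) {
  s1 <- rowMeans(editingLevels(m1), na.rm = TRUE)
  s2 <- rowMeans(editingLevels(m2), na.rm = TRUE)
  shared <- intersect(names(s1)[!is.na(s1)], names(s2)[!is.na(s2)])
  if (length(shared) < 3L) stop("fewer than 3 shared sites with defined levels")
  list(r = cor(s1[shared], s2[shared]), n = length(shared))
}
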