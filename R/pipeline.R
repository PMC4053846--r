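#' Pipeline configuration
#'
#' Validated configuration for [runPipeline()]: a simulation config for the
#' synthetic two-species study, screen geometry and scoring,
#' quantification thresholds, and the site table used by the region stage
#' (defaulting to the packaged conserved-site table).
#'
#' @param outdir output directory; created if absent.
#' @param sim a [simulationConfig()].
#' @param flank,minIdentical,scoring screen parameters.
#' @param minTotal,minEditedReads,minLevel thresholds for
#'   [classifyState()].
#' @param regionSites site table for the region stage (NULL: packaged
#'   table).
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outdir, sim = simulationConfig(seed = 7L),
                           flank = 40L, minIdentical = 70L,
                           scoring = alignmentParams(), minTotal = 3L,
                           minEditedReads = 2L, minLevel = 0.01,
                           regionSites = NULL) {
  stopifnot(inherits(sim, "simulationConfig"),
            inherits(scoring, "alignmentParams"))
  structure(list(outdir = outdir, sim = sim, flank = as.integer(flank),
                 minIdentical = as.integer(minIdentical), scoring = scoring,
                 minTotal = minTotal, minEditedReads = minEditedReads,
                 minLevel = minLevel, regionSites = regionSites),
            class = "pipelineConfig")
}

writeTsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], round, digits = 6L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

writeJson <- function(x, path) {
  rounder <- function(v) {
    if (is.list(v)) lapply(v, rounder)
    else if (is.double(v)) round(v, 6L)
    else v
  }
  jsonlite::write_json(rounder(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-study pipeline
#'
#' Executes, in order: simulate (ortholog genome pair, site panels, SNP
#' controls, strain pileups), screen (cross-species conservation screen),
#' control (SNP signal-to-noise), quantify (per-strain editing levels and
#' the site-by-sample matrix with level summaries by truth group),
#' accumulate (strain accumulation curves), motif (neighbor-preference
#' matrix of the conserved windows), regions (classification of the
#' packaged conserved-site table, or `regionSites`), and reversion
#' (G-counterpart asymmetry on the planted lineage-specific sites). Every
#' stage writes its outputs before the next starts, so each is
#' independently re-runnable; numeric outputs are serialized at fixed
#' 6-decimal precision and reruns with one config are byte-identical.
#'
#' @param cfg a [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return the JSON-ready summary list, invisibly; files under
#'   `cfg$outdir`.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)

  say("simulate")
  pair <- stageTry("simulate", simulateOrthologPair(cfg$sim))
  truth <- pair$truth
  writeGenome(pair$query, file.path(out, "query.fa"))
  writeGenome(pair$subject, file.path(out, "subject.fa"))
  querySites <- rbind(truth$conservedQuery,
                      truth$queryOnly[SITE_COLUMNS])
  subjectSites <- rbind(truth$conservedSubject,
                        truth$subjectOnly[SITE_COLUMNS])
  writeSiteTable(querySites, file.path(out, "sites_query.tsv"))
  writeSiteTable(subjectSites, file.path(out, "sites_subject.tsv"))
  writeSiteTable(truth$snpsQuery, file.path(out, "snps_query.tsv"))
  writeSiteTable(truth$snpsSubject, file.path(out, "snps_subject.tsv"))
  writeJson(list(conserved = siteKey(truth$conservedQuery),
                 queryOnly = siteKey(truth$queryOnly),
                 subjectOnly = siteKey(truth$subjectOnly),
                 sharedSnps = truth$sharedSnpKeys),
            file.path(out, "truth.json"))
  pileups <- stageTry("simulate",
                      simulatePileups(pair, file.path(out, "pileups")))

  say("screen")
  screen <- stageTry("screen", {
    if (!nrow(querySites)) stop("empty query site table")
    runScreen(querySites, subjectSites, pair$query, pair$subject,
              flank = cfg$flank, minIdentical = cfg$minIdentical,
              params = cfg$scoring)
  })
  writeTsv(screenPairs(screen), file.path(out, "screen_pairs.tsv"))
  writeSiteTable(conservedSites(screen), file.path(out, "conserved_sites.tsv"))

  say("control")
  sn <- stageTry("control",
    controlSignalToNoise(screen, truth$snpsQuery, truth$snpsSubject,
                         pair$query, pair$subject))
  writeJson(list(editingHits = sn@editingHits,
                 controlRawHits = sn@controlRawHits, sizes = sn@sizes,
                 controlNormalized = sn@controlNormalized,
                 ratio = if (is.finite(sn@ratio)) sn@ratio else "Inf"),
            file.path(out, "control.json"))

  say("quantify")
  mat <- stageTry("quantify", {
    meas <- do.call(rbind, lapply(names(pileups), function(st)
      quantifySites(querySites, readMpileup(pileups[[st]]), sample = st,
                    minTotal = cfg$minTotal,
                    minEditedReads = cfg$minEditedReads,
                    minLevel = cfg$minLevel)))
    writeTsv(meas, file.path(out, "measurements.tsv"))
    buildMatrix(meas)
  })
  lev <- editingLevels(mat)
  writeTsv(data.frame(key = rownames(lev), round(lev, 6L),
                      check.names = FALSE),
           file.path(out, "matrix_levels.tsv"))
  st <- editingStates(mat)
  writeTsv(data.frame(key = rownames(st), st, check.names = FALSE),
           file.path(out, "matrix_states.tsv"))
  groups <- setNames(ifelse(rownames(lev) %in% siteKey(truth$conservedQuery),
                            "conserved", "other"), rownames(lev))
  levSummary <- stageTry("quantify",
                         suppressMessages(summarizeLevels(mat, groups)))
  writeTsv(levSummary$perSite, file.path(out, "levels_per_site.tsv"))
  writeTsv(levSummary$groupSummary, file.path(out, "levels_by_group.tsv"))

  say("accumulate")
  panel <- stageTry("accumulate", simulateStrainPanel(cfg$sim))
  curve <- accumulationCurve(panel$sets)
  consCurve <- accumulationCurve(lapply(panel$sets, intersect,
                                        panel$conservedKeys))
  writeTsv(data.frame(k = seq_along(curve$orderedSamples),
                      sample = curve$orderedSamples,
                      cumulative = curve$cumulativeCounts,
                      fraction = curve$fractionAtK,
                      conservedFraction =
                        consCurve$fractionAtK[match(curve$orderedSamples,
                                                    consCurve$orderedSamples)]),
           file.path(out, "accumulation.tsv"))

  say("motif")
  motif <- stageTry("motif", {
    w <- extractWindows(pair$query, truth$conservedQuery,
                        cfg$flank)$windows
    motifMatrix(w, halfwidth = 10L)
  })
  writeMotifMatrix(motif, file.path(out, "motif_matrix.tsv"))

  say("regions")
  regionSites <- if (is.null(cfg$regionSites)) essSites() else cfg$regionSites
  regions <- stageTry("regions",
                      suppressMessages(classifyRegions(regionSites)))
  writeJson(list(total = regions$total,
                 regionCounts = as.list(regions$regionCounts),
                 codingRows = regions$codingRows,
                 codingAnnotated = regions$codingAnnotated,
                 nonSynonymous = regions$nonSynonymous,
                 synonymous = regions$synonymous,
                 fracNonSynonymous = regions$fracNonSynonymous,
                 intronic = regions$intronic,
                 intronicInRecodingGenes = regions$intronicInRecodingGenes,
                 fracIntronicInRecoding = regions$fracIntronicInRecoding),
            file.path(out, "regions.json"))

  say("reversion")
  rev <- stageTry("reversion",
    reversionAnalysis(truth$queryOnly[SITE_COLUMNS],
                      truth$subjectOnly[SITE_COLUMNS], pair$query,
                      pair$subject, flank = cfg$flank,
                      minIdentical = cfg$minIdentical,
                      params = cfg$scoring))
  writeJson(list(
    dir1 = rev$dir1[c("matchedSites", "fractionG", "fractionGofAG",
                      "controlMatched", "controlFractionG")],
    dir2 = rev$dir2[c("matchedSites", "fractionG", "fractionGofAG",
                      "controlMatched", "controlFractionG")],
    contingency = as.vector(rev$contingency), oddsRatio = rev$oddsRatio,
    orCI = rev$orCI, fisherP = rev$fisherP,
    fractionRatio = rev$fractionRatio), file.path(out, "reversion.json"))

  summary <- list(
    parameters = list(seed = cfg$sim$seed, flank = cfg$flank,
                      minIdentical = cfg$minIdentical,
                      scoring = unclass(cfg$scoring)),
    conservedCount = nrow(conservedSites(screen)),
    plantedConserved = nrow(truth$conservedQuery),
    signalToNoise = if (is.finite(sn@ratio)) sn@ratio else "Inf",
    controlRawHits = sn@controlRawHits,
    groupLevels = levSummary$groupSummary,
    accumulationFractionAt2 = curve$fractionAtK[2],
    conservedAccumulationFractionAt2 = consCurve$fractionAtK[2],
    motifUpstreamG = unname(unclass(motif)["-1", "G"]),
    motifDownstreamG = unname(unclass(motif)["1", "G"]),
    regions = list(intronic = regions$intronic,
                   microRNA = sum(regionSites$region == "microRNA",
                                  na.rm = TRUE),
                   nonSynonymous = regions$nonSynonymous,
                   intronicInRecodingGenes = regions$intronicInRecodingGenes),
    reversion = list(fractionG1 = rev$dir1$fractionG,
                     fractionG2 = rev$dir2$fractionG,
                     oddsRatio = rev$oddsRatio, fisherP = rev$fisherP))
  writeJson(summary, file.path(out, "summary.json"))
  say("done")
  invisible(summary)
}
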