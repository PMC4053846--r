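# Seeded generators for a two-species study: diverged ortholog genomes with
# planted conserved / lineage-specific edited adenosines, SNP controls,
# reversion counterparts, strain panels and multi-strain pileups.

#' Simulation configuration
#'
#' Collects every knob of the synthetic two-species study in one validated
#' list. Defaults are the package's reference study conditions: 5%
#' background divergence between the species, 2% divergence inside
#' conserved-site windows (expected identity 81 x 0.98 = 79.4 of 81, a safe
#' margin above the 70 threshold), 10 planted conserved sites against 100
#' query-only decoys, editing levels Beta-distributed with mean 0.515
#' (SD 0.1) at conserved sites and mean 0.1 (SD 0.2) elsewhere, counterpart
#' G fractions 0.26/0.18 for the two reversion directions, and an ADAR-like
#' neighbor bias (upstream G 0.05, downstream G 0.45) at conserved sites.
#'
#' @param seed integer seed; identical configs give byte-identical outputs.
#' @param nChrom,chromLength genome shape.
#' @param backgroundDivergence,conservedDivergence per-base substitution
#'   probabilities between the species (outside / inside conserved
#'   windows). `conservedDivergence` must satisfy
#'   `(2*flank+1) * (1 - conservedDivergence) >= minIdentical + 2`.
#' @param nConserved,nQueryOnly,nSubjectOnly site panel sizes.
#' @param nSnpsPerSpecies SNP control size per species;
#'   `sharedSnpFraction` of them sit at positions shared by both species
#'   (the chance-conservation the control measures).
#' @param reversionFraction length-2: probability that the counterpart
#'   (other-species) base of a query-only / subject-only site is a
#'   hardwired G; the complement keeps A.
#' @param nStrains,coverageLambda strain panel size and Poisson mean read
#'   depth.
#' @param conservedLevel,nonconservedLevel `c(mean, sd)` of the Beta true
#'   editing-level distributions (drawn independently per site and strain).
#' @param sequencingError per-read substitution probability.
#' @param lowQualFraction fraction of read bases emitted below Phred 30
#'   (exercises the quality filter; independent of the base call).
#' @param motifBias `c(upstreamG, downstreamG)` neighbor-G probabilities at
#'   conserved sites.
#' @param conservedPresence,otherPresence per-strain presence probabilities
#'   for the strain panel; conserved sites are additionally capped at one
#'   absent strain each.
#' @param flank,minIdentical screen geometry the margins are validated
#'   against.
#' @return list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 1L, nChrom = 1L, chromLength = 60000L,
                             backgroundDivergence = 0.05,
                             conservedDivergence = 0.02,
                             nConserved = 10L, nQueryOnly = 100L,
                             nSubjectOnly = 100L, nSnpsPerSpecies = 100L,
                             sharedSnpFraction = 0.1,
                             reversionFraction = c(0.26, 0.18),
                             nStrains = 15L, coverageLambda = 30,
                             conservedLevel = c(mean = 0.515, sd = 0.1),
                             nonconservedLevel = c(mean = 0.1, sd = 0.2),
                             sequencingError = 0.001,
                             lowQualFraction = 0.1,
                             motifBias = c(upstreamG = 0.05,
                                           downstreamG = 0.45),
                             conservedPresence = 0.97, otherPresence = 0.5,
                             flank = 40L, minIdentical = 70L) {
  cfg <- list(seed = as.integer(seed), nChrom = as.integer(nChrom),
              chromLength = as.integer(chromLength),
              backgroundDivergence = backgroundDivergence,
              conservedDivergence = conservedDivergence,
              nConserved = as.integer(nConserved),
              nQueryOnly = as.integer(nQueryOnly),
              nSubjectOnly = as.integer(nSubjectOnly),
              nSnpsPerSpecies = as.integer(nSnpsPerSpecies),
              sharedSnpFraction = sharedSnpFraction,
              reversionFraction = rep_len(reversionFraction, 2L),
              nStrains = as.integer(nStrains),
              coverageLambda = coverageLambda,
              conservedLevel = conservedLevel,
              nonconservedLevel = nonconservedLevel,
              sequencingError = sequencingError,
              lowQualFraction = lowQualFraction,
              motifBias = setNames(rep_len(motifBias, 2L),
                                   c("upstreamG", "downstreamG")),
              conservedPresence = conservedPresence,
              otherPresence = otherPresence,
              flank = as.integer(flank),
              minIdentical = as.integer(minIdentical))
  probs <- c(cfg$backgroundDivergence, cfg$conservedDivergence,
             cfg$sharedSnpFraction, cfg$reversionFraction,
             cfg$sequencingError, cfg$lowQualFraction, cfg$motifBias,
             cfg$conservedPresence, cfg$otherPresence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  winLen <- 2L * cfg$flank + 1L
  if (winLen * (1 - cfg$conservedDivergence) < cfg$minIdentical + 2)
    stop("conservedDivergence too high: expected window identity ",
         round(winLen * (1 - cfg$conservedDivergence), 1),
         " leaves no margin over the threshold ", cfg$minIdentical)
  for (nm in c("conservedLevel", "nonconservedLevel")) {
    p <- cfg[[nm]]
    if (p[1] <= 0 || p[1] >= 1 || p[2] <= 0 ||
        p[1] * (1 - p[1]) <= p[2]^2)
      stop(nm, ": need 0 < mean < 1 and sd^2 < mean*(1-mean)")
  }
  structure(cfg, class = "simulationConfig")
}

betaFromMeanSD <- function(p) {
  nu <- p[1] * (1 - p[1]) / p[2]^2 - 1
  unname(c(p[1] * nu, (1 - p[1]) * nu))
}

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

randomBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

complementBase <- function(b) chartr("ACGT", "TGCA", b)

# vectorized: set edited-strand bases at 1-based plus-strand positions of a
# per-chromosome character-vector genome
setEditedBases <- function(chrs, sites, bases) {
  bases <- rep_len(bases, nrow(sites))
  plus <- ifelse(sites$strand == "+", bases, complementBase(bases))
  for (cn in unique(sites$chrom)) {
    sel <- sites$chrom == cn
    chrs[[cn]][sites$pos1[sel]] <- plus[sel]
  }
  chrs
}

#' Simulate a diverged ortholog genome pair with planted sites
#'
#' Builds a random query genome, plants edited adenosines and SNP controls
#' on a collision-free position grid, and derives the subject genome by
#' i.i.d. Jukes–Cantor-style substitution: rate `backgroundDivergence`
#' everywhere except inside conserved-site windows
#' (`conservedDivergence`, edited base preserved in both species). The
#' genomes share coordinates (no indels), so a site's counterpart is the
#' same position in the other species. Query-only sites receive a forced
#' counterpart base (G with probability `reversionFraction[1]`, otherwise
#' A) in the subject genome; symmetrically for subject-only sites in the
#' query genome. A post-generation self-check re-aligns every planted
#' conserved pair and aborts if any fails the conservation criterion.
#'
#' @param cfg a [simulationConfig()].
#' @return list: `query`, `subject` ([GenomeAssembly-class]), `truth` (list
#'   with site tables `conservedQuery`, `conservedSubject`, `queryOnly`,
#'   `subjectOnly`, `snpsQuery`, `snpsSubject`, counterpart bases, shared
#'   SNP keys, and per-site-per-strain true editing `levels` for the query
#'   species).
#' @export
simulateOrthologPair <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  withSeed(cfg$seed, {
    flank <- cfg$flank
    spacing <- max(2L * flank + 10L, 110L)
    chromNames <- sprintf("chr%d", seq_len(cfg$nChrom))
    grid <- do.call(rbind, lapply(chromNames, function(cn) {
      pos <- seq(flank + spacing, cfg$chromLength - flank - spacing,
                 by = spacing)
      data.frame(chrom = cn, pos1 = pos, stringsAsFactors = FALSE)
    }))
    nShared <- round(cfg$sharedSnpFraction * cfg$nSnpsPerSpecies)
    nOwn <- cfg$nSnpsPerSpecies - nShared
    need <- cfg$nConserved + cfg$nQueryOnly + cfg$nSubjectOnly +
      nShared + 2L * nOwn
    if (nrow(grid) < need)
      stop("genome too small: ", need, " site slots needed, ",
           nrow(grid), " available; increase chromLength or nChrom")
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    take <- function(n) {
      out <- grid[seq_len(n), , drop = FALSE]
      if (n > 0L) grid <<- grid[-seq_len(n), , drop = FALSE]
      out$strand <- sample(c("+", "-"), n, replace = TRUE)
      out
    }
    cons <- take(cfg$nConserved)
    qOnly <- take(cfg$nQueryOnly)
    sOnly <- take(cfg$nSubjectOnly)
    snpShared <- take(nShared)
    snpQ <- rbind(take(nOwn), snpShared)
    snpS <- rbind(take(nOwn), snpShared)

    # query genome as per-chromosome character vectors
    qChrV <- setNames(lapply(chromNames, function(cn)
      randomBases(cfg$chromLength)), chromNames)

    qChrV <- setEditedBases(qChrV, cons, "A")
    qChrV <- setEditedBases(qChrV, qOnly, "A")
    # counterparts of subject-only sites in the query genome (direction 2)
    sOnlyCounterpart <- ifelse(
      runif(nrow(sOnly)) < cfg$reversionFraction[2], "G", "A")
    qChrV <- setEditedBases(qChrV, sOnly, sOnlyCounterpart)
    # ADAR-like neighbor bias at conserved sites (edited strand)
    biasDraw <- function(p, n) ifelse(runif(n) < p, "G",
                                      sample(c("A", "C", "T"), n,
                                             replace = TRUE))
    up <- cons; up$pos1 <- ifelse(cons$strand == "+", cons$pos1 - 1L,
                                  cons$pos1 + 1L)
    dn <- cons; dn$pos1 <- ifelse(cons$strand == "+", cons$pos1 + 1L,
                                  cons$pos1 - 1L)
    qChrV <- setEditedBases(qChrV, up,
                            biasDraw(cfg$motifBias["upstreamG"], nrow(cons)))
    qChrV <- setEditedBases(qChrV, dn,
                            biasDraw(cfg$motifBias["downstreamG"], nrow(cons)))

    # subject genome: per-position substitution rates
    sChrV <- qChrV
    bases <- c("A", "C", "G", "T")
    for (cn in chromNames) {
      rate <- rep(cfg$backgroundDivergence, cfg$chromLength)
      inCons <- cons$chrom == cn
      for (i in which(inCons)) {
        w <- (cons$pos1[i] - flank):(cons$pos1[i] + flank)
        rate[w] <- cfg$conservedDivergence
      }
      frozen <- c(cons$pos1[cons$chrom == cn],
                  qOnly$pos1[qOnly$chrom == cn],
                  sOnly$pos1[sOnly$chrom == cn])
      rate[frozen] <- 0
      mut <- which(runif(cfg$chromLength) < rate)
      if (length(mut)) {
        # uniform substitution to one of the three other bases
        old <- match(sChrV[[cn]][mut], bases)
        shift <- sample.int(3L, length(mut), replace = TRUE)
        sChrV[[cn]][mut] <- bases[(old - 1L + shift) %% 4L + 1L]
      }
    }
    # planted subject-side centers
    sChrV <- setEditedBases(sChrV, sOnly, "A")
    qOnlyCounterpart <- ifelse(
      runif(nrow(qOnly)) < cfg$reversionFraction[1], "G", "A")
    sChrV <- setEditedBases(sChrV, qOnly, qOnlyCounterpart)

    query <- genomeAssembly(vapply(qChrV, paste, "", collapse = ""),
                            species = "query")
    subject <- genomeAssembly(vapply(sChrV, paste, "", collapse = ""),
                              species = "subject")

    mkSites <- function(df, species, source) {
      ord <- order(df$chrom, df$pos1, method = "radix")
      df <- df[ord, , drop = FALSE]
      out <- siteTable(df$chrom, df$pos1, df$strand, species = species,
                       source = source)
      attr(out, "order") <- ord
      out
    }
    consQ <- mkSites(cons, "query", "planted_conserved")
    consS <- mkSites(cons, "subject", "planted_conserved")
    qOnlySites <- mkSites(qOnly, "query", "planted_query_only")
    qOnlySites$counterpartBase <- qOnlyCounterpart[attr(qOnlySites, "order")]
    sOnlySites <- mkSites(sOnly, "subject", "planted_subject_only")
    sOnlySites$counterpartBase <- sOnlyCounterpart[attr(sOnlySites, "order")]
    snpsQ <- mkSites(snpQ, "query", "snp_control")
    snpsS <- mkSites(snpS, "subject", "snp_control")

    # true editing levels per query-species site and strain
    querySites <- rbind(consQ, qOnlySites[names(consQ)])
    conservedFlag <- c(rep(TRUE, nrow(consQ)), rep(FALSE, nrow(qOnlySites)))
    ab1 <- betaFromMeanSD(cfg$conservedLevel)
    ab2 <- betaFromMeanSD(cfg$nonconservedLevel)
    strains <- sprintf("strain%02d", seq_len(cfg$nStrains))
    levels <- matrix(NA_real_, nrow(querySites), cfg$nStrains,
                     dimnames = list(siteKey(querySites), strains))
    for (j in seq_len(cfg$nStrains)) {
      levels[conservedFlag, j] <- rbeta(sum(conservedFlag), ab1[1], ab1[2])
      levels[!conservedFlag, j] <- rbeta(sum(!conservedFlag), ab2[1], ab2[2])
    }

    truth <- list(conservedQuery = consQ, conservedSubject = consS,
                  queryOnly = qOnlySites, subjectOnly = sOnlySites,
                  snpsQuery = snpsQ, snpsSubject = snpsS,
                  sharedSnpKeys = paste(snpShared$chrom, snpShared$pos1,
                                        snpShared$strand, sep = ":"),
                  conservedFlag = conservedFlag, levels = levels,
                  config = cfg)

    # self-check: every planted conserved pair must pass the criterion
    if (nrow(consQ)) {
      qwin <- extractWindows(query, consQ, flank)$windows
      swin <- extractWindows(subject, consS, flank)$windows
      idx <- match(siteKey(qwin), siteKey(swin))
      aln <- .sw_align_pairs(qwin$seq, swin$seq[idx], 2L, -3L, -5L, -2L,
                             qwin$centerIndex, swin$centerIndex[idx])
      ok <- aln$identical >= cfg$minIdentical & aln$centersPaired &
        aln$centerMatch
      if (!all(ok))
        stop("self-check failed: ", sum(!ok), " planted conserved pair(s) ",
             "below the conservation criterion; lower conservedDivergence")
    }
    list(query = query, subject = subject, truth = truth)
  })
}

#' Simulate per-strain mpileup files
#'
#' For every query-species editing site and strain: read depth is
#' Poisson(`coverageLambda`), edited (G) reads are Binomial(depth, true
#' level) with the site's per-strain level from the truth table,
#' sequencing errors substitute a uniform other base at rate
#' `sequencingError`, read strands are random (lowercase/uppercase mpileup
#' case), and a `lowQualFraction` of base calls get Phred 2 qualities
#' (below the Phred-30 filter) independently of the call. Zero-depth sites
#' are omitted, as samtools does. Files are valid 6-column mpileup text.
#'
#' @param pair result of [simulateOrthologPair()].
#' @param dir output directory (created).
#' @return character vector of file paths, named by strain.
#' @export
simulatePileups <- function(pair, dir) {
  truth <- pair$truth
  cfg <- truth$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- rbind(truth$conservedQuery,
                 truth$queryOnly[names(truth$conservedQuery)])
  ord <- order(sites$chrom, sites$pos1, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  keys <- siteKey(sites)
  strains <- colnames(truth$levels)
  refBase <- vapply(seq_len(nrow(sites)), function(i)
    fetchSeq(pair$query, sites$chrom[i], sites$pos1[i] - 1L, sites$pos1[i],
             "+"), "")
  withSeed(cfg$seed + 1L, {
    paths <- setNames(file.path(dir, paste0(strains, ".pileup")), strains)
    for (st in strains) {
      lines <- character(0)
      for (i in seq_len(nrow(sites))) {
        depth <- rpois(1, cfg$coverageLambda)
        if (depth == 0) next
        p <- truth$levels[keys[i], st]
        nG <- rbinom(1, depth, p)
        edited <- rep(c(TRUE, FALSE), c(nG, depth - nG))
        baseEdited <- ifelse(edited, "G", "A")     # edited-strand call
        err <- runif(depth) < cfg$sequencingError
        for (k in which(err))
          baseEdited[k] <- sample(setdiff(c("A", "C", "G", "T"),
                                          baseEdited[k]), 1)
        basePlus <- if (sites$strand[i] == "+") baseEdited
                    else complementBase(baseEdited)
        revRead <- runif(depth) < 0.5
        chars <- ifelse(basePlus == refBase[i],
                        ifelse(revRead, ",", "."),
                        ifelse(revRead, tolower(basePlus), basePlus))
        quals <- ifelse(runif(depth) < cfg$lowQualFraction, "#", "I")
        lines <- c(lines, paste(sites$chrom[i], sites$pos1[i], refBase[i],
                                depth, paste(chars, collapse = ""),
                                paste(quals, collapse = ""), sep = "\t"))
      }
      writeLines(lines, paths[st])
    }
    paths
  })
}

#' Simulate a strain site panel
#'
#' Standalone generator of per-strain site sets (the input shape of the
#' accumulation curve): conserved sites appear in each strain with
#' probability `conservedPresence` and are additionally capped at one
#' absent strain each, so any two strains jointly cover nearly all of
#' them; other sites appear independently with probability
#' `otherPresence`.
#'
#' @param cfg a [simulationConfig()] (uses nConserved, nQueryOnly,
#'   nStrains, presence probabilities, seed).
#' @return list: `sets` (named list strain -> site keys), `conservedKeys`,
#'   `otherKeys`.
#' @export
simulateStrainPanel <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  if (cfg$nStrains < 2L) stop("need at least 2 strains")
  withSeed(cfg$seed + 2L, {
    consKeys <- sprintf("cons%03d", seq_len(cfg$nConserved))
    otherKeys <- sprintf("site%04d", seq_len(cfg$nQueryOnly))
    strains <- sprintf("strain%02d", seq_len(cfg$nStrains))
    consPresent <- matrix(runif(cfg$nConserved * cfg$nStrains) <
                            cfg$conservedPresence,
                          nrow = cfg$nConserved)
    for (i in seq_len(cfg$nConserved)) {
      absent <- which(!consPresent[i, ])
      if (length(absent) > 1L) {
        keep <- sample(absent, 1L)
        consPresent[i, setdiff(absent, keep)] <- TRUE
      }
    }
    otherPresent <- matrix(runif(cfg$nQueryOnly * cfg$nStrains) <
                             cfg$otherPresence,
                           nrow = cfg$nQueryOnly)
    sets <- setNames(lapply(seq_len(cfg$nStrains), function(j)
      c(consKeys[consPresent[, j]], otherKeys[otherPresent[, j]])), strains)
    list(sets = sets, conservedKeys = consKeys, otherKeys = otherKeys)
  })
}
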