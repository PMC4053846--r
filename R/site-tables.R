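SITE_COLUMNS <- c("species", "chrom", "pos1", "strand", "gene", "region",
                  "substitution", "source")

#' Construct and validate a site table
#'
#' A site table is a plain data.frame with one row per candidate editing site
#' or SNP and columns `species`, `chrom`, `pos1` (1-based), `strand`
#' (`"+"`/`"-"`), `gene`, `region`, `substitution`, `source`. The identity of
#' a site is the triple (chrom, pos1, strand); `species` is a label, and site
#' lists never mix species. Missing annotation fields are `NA`.
#'
#' @param chrom,pos1,strand per-site coordinates; `pos1` is 1-based.
#' @param species single species label, recycled.
#' @param gene,region,substitution,source optional annotations, recycled.
#' @return a validated site data.frame.
#' @export
siteTable <- function(chrom, pos1, strand, species = "query", gene = NA,
                      region = NA, substitution = NA, source = NA) {
  n <- max(length(chrom), length(pos1))
  rl <- function(x) rep_len(as.character(x), n)
  df <- data.frame(species = rl(species), chrom = rl(chrom),
                   pos1 = rep_len(as.integer(pos1), n), strand = rl(strand),
                   gene = rl(gene), region = rl(region),
                   substitution = rl(substitution),
                   source = rl(source), stringsAsFactors = FALSE)
  validateSites(df)
}

validateSites <- function(df) {
  miss <- setdiff(SITE_COLUMNS, names(df))
  if (length(miss))
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[SITE_COLUMNS]
  if (any(is.na(df$pos1)) || any(df$pos1 < 1L))
    stop("site positions must be 1-based positive integers")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (length(unique(df$species)) > 1L)
    stop("a site table holds one species; got: ",
         paste(unique(df$species), collapse = ", "))
  df
}

#' Site identity key
#'
#' @param sites a site table.
#' @return character vector `chrom:pos1:strand`, the site identity triple.
#' @export
siteKey <- function(sites) paste(sites$chrom, sites$pos1, sites$strand, sep = ":")

#' Read a site table
#'
#' Two dialects are supported. `"tsv"` is a TSV with header
#' `species chrom pos strand gene region substitution source` carrying
#' 1-based positions (the layout of the packaged conserved-site table);
#' missing trailing annotation columns are tolerated. `"bed6"` is headerless
#' BED6 (`chrom start end name score strand`) with 0-based half-open starts;
#' `pos1 = start + 1`, and the interval must have width 1.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"bed6"`.
#' @param species species label; for `"tsv"` defaults to the file's
#'   `species` column.
#' @return a site data.frame (see [siteTable()]).
#' @export
readSiteTable <- function(path, dialect = c("tsv", "bed6"), species = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("site table not found: ", path)
  if (dialect == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
    if (!all(c("chrom", "pos", "strand") %in% names(df)))
      stop("tsv dialect requires columns chrom, pos, strand")
    out <- data.frame(
      species = if (!is.null(species)) species
                else if ("species" %in% names(df)) df$species else "query",
      chrom = df$chrom, pos1 = as.integer(df$pos), strand = df$strand,
      gene = if ("gene" %in% names(df)) df$gene else NA_character_,
      region = if ("region" %in% names(df)) df$region else NA_character_,
      substitution = if ("substitution" %in% names(df)) df$substitution
                     else NA_character_,
      source = if ("source" %in% names(df)) df$source else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("BED6 requires 6 columns")
    names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
    if (any(df$start < 0L)) stop("negative BED start")
    if (any(df$end - df$start != 1L))
      stop("site BED intervals must have width 1")
    out <- data.frame(
      species = if (is.null(species)) "query" else species,
      chrom = df$chrom, pos1 = as.integer(df$start) + 1L, strand = df$strand,
      gene = ifelse(df$name %in% c(".", ""), NA_character_, df$name),
      region = NA_character_, substitution = NA_character_,
      source = NA_character_, stringsAsFactors = FALSE)
  }
  validateSites(out)
}

#' Write a site table
#'
#' @param sites a site data.frame.
#' @param path output file.
#' @param dialect `"tsv"` (TSV, 1-based, full annotation) or `"bed6"`
#'   (0-based half-open width-1 intervals; gene in the name column).
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(sites, path, dialect = c("tsv", "bed6")) {
  dialect <- match.arg(dialect)
  sites <- validateSites(sites)
  if (dialect == "tsv") {
    out <- sites
    names(out)[names(out) == "pos1"] <- "pos"
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  } else {
    bed <- data.frame(chrom = sites$chrom, start = sites$pos1 - 1L,
                      end = sites$pos1,
                      name = ifelse(is.na(sites$gene), ".", sites$gene),
                      score = 0L, strand = sites$strand)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Merge site datasets into unique sites
#'
#' Merges several site tables from the same species into one deduplicated
#' table, keyed by (chrom, pos1, strand) — the same site on opposite strands
#' stays distinct. Source labels of duplicate records are concatenated with
#' `";"` (first occurrence order, duplicates dropped); the first non-missing
#' value is kept for the other annotation columns. Rows are stably sorted by
#' (chrom, pos1, strand).
#'
#' @param tables list of site data.frames from a single species.
#' @return one merged site data.frame.
#' @export
mergeSiteDatasets <- function(tables) {
  if (!length(tables)) stop("no site tables to merge")
  tables <- lapply(tables, validateSites)
  sp <- unique(unlist(lapply(tables, function(t) unique(t$species))))
  if (length(sp) > 1L)
    stop("cannot merge site tables from different species: ",
         paste(sp, collapse = ", "))
  all <- do.call(rbind, tables)
  key <- siteKey(all)
  firstNonNA <- function(x) { x <- x[!is.na(x)]; if (length(x)) x[1] else NA_character_ }
  parts <- split(seq_len(nrow(all)), factor(key, levels = unique(key)))
  merged <- do.call(rbind, lapply(parts, function(ix) {
    r <- all[ix[1], , drop = FALSE]
    src <- unique(all$source[ix][!is.na(all$source[ix])])
    r$source <- if (length(src)) paste(src, collapse = ";") else NA_character_
    r$gene <- firstNonNA(all$gene[ix])
    r$region <- firstNonNA(all$region[ix])
    r$substitution <- firstNonNA(all$substitution[ix])
    r
  }))
  merged <- merged[order(merged$chrom, merged$pos1, merged$strand,
                         method = "radix"), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}
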