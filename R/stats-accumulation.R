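#' Greedy site accumulation curve
#'
#' Orders samples (e.g. mouse strains) by greedy minimal addition: first the
#' sample with the fewest sites, then at each step the sample adding the
#' fewest sites not yet covered; ties break lexicographically by sample
#' name. Reports cumulative union sizes and the covered fraction of the
#' overall union after each addition. A flat tail means extra samples stop
#' contributing new sites — the behaviour expected of a saturated,
#' conserved site set.
#'
#' @param siteSets named list, one character vector of site keys per sample.
#' @return list of class `accumulationCurve`: `orderedSamples`,
#'   `cumulativeCounts`, `fractionAtK`, `total`.
#' @export
accumulationCurve <- function(siteSets) {
  if (!length(siteSets)) stop("empty sample map")
  if (is.null(names(siteSets)) || any(names(siteSets) == ""))
    stop("siteSets must be a named list")
  sets <- lapply(siteSets, unique)
  total <- length(unique(unlist(sets, use.names = FALSE)))
  remaining <- names(sets)
  covered <- character(0)
  orderedSamples <- character(0)
  cumulative <- integer(0)
  while (length(remaining)) {
    adds <- vapply(remaining,
                   function(s) length(setdiff(sets[[s]], covered)), 1L)
    pick <- remaining[order(adds, remaining, method = "radix")][1]
    covered <- union(covered, sets[[pick]])
    orderedSamples <- c(orderedSamples, pick)
    cumulative <- c(cumulative, length(covered))
    remaining <- setdiff(remaining, pick)
  }
  structure(list(orderedSamples = orderedSamples,
                 cumulativeCounts = cumulative,
                 fractionAtK = cumulative / total, total = total),
            class = "accumulationCurve")
}

#' @export
print.accumulationCurve <- function(x, ...) {
  cat("accumulationCurve over", length(x$orderedSamples), "sample(s),",
      x$total, "site(s) total\n")
  print(data.frame(k = seq_along(x$orderedSamples),
                   sample = x$orderedSamples,
                   cumulative = x$cumulativeCounts,
                   fraction = round(x$fractionAtK, 4)))
  invisible(x)
}
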