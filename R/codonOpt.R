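#' Recode a coding sequence toward a reference codon-usage table
#'
#' Produces a synonymous recoding of \code{cds} whose translation is
#' identical to the input, under one of three strategies:
#' \describe{
#'   \item{\code{max}}{every codon is replaced by its family-optimal
#'     triplet (the stop codon becomes the optimal stop).}
#'   \item{\code{match}}{each codon is drawn from its family's
#'     reference frequency distribution; requires \code{seed} and is
#'     reproducible (Mersenne-Twister, rejection sampling).}
#'   \item{\code{threshold}}{codons with reference frequency at or
#'     below \code{rareCeiling} are replaced by the family optimum,
#'     others (including a non-rare stop) are kept.}
#' }
#' Codons of single-member families (Met, Trp under code 11) are never
#' changed.  When \code{forbiddenMotifs} is non-empty, motif occurrences
#' in the recoded sequence are removed where possible by switching
#' overlapping codons to their next-most-frequent synonym; unavoidable
#' occurrences are reported in the result, not silently dropped.
#'
#' @param cds a single coding sequence; an internal stop codon is an
#'   error (a terminal stop is allowed and recoded within the stop
#'   family).
#' @param table reference \code{\link{CodonUsageTable}}.
#' @param strategy one of \code{"max"}, \code{"match"},
#'   \code{"threshold"}.
#' @param rareCeiling replacement ceiling for the threshold strategy.
#' @param seed integer RNG seed (required for \code{match}).
#' @param forbiddenMotifs character vector of nucleotide motifs to
#'   avoid in the output.
#' @param variant mean-frequency-difference variant used in the
#'   before/after diagnostics.
#' @return a list of class \code{optimizationResult}: \code{cds} (named
#'   character), \code{changes} (\code{\link{ChangeSummary}}),
#'   \code{before}, \code{after} (\code{\link{DiagnosticsReport}}),
#'   \code{strategy}, \code{seed}, \code{unresolvedMotifs}.
#' @examples
#' tab <- buildUsageTable(c("ATGAAAAAATTATTAAAATAA"))
#' res <- optimizeCds("ATGAAGCTGTAA", tab, strategy = "max")
#' res$cds
#' @export
optimizeCds <- function(cds, table,
    strategy = c("max", "match", "threshold"),
    rareCeiling = 0.10, seed = NULL, forbiddenMotifs = character(),
    variant = "global") {
  strategy <- match.arg(strategy)
  stopifnot(methods::is(table, "CodonUsageTable"))
  s <- asCdsStrings(cds)
  if (length(s) != 1L) stop("optimizeCds expects a single CDS", call. = FALSE)
  codons <- splitCodons(s)
  code <- table@geneticCode
  aas <- code[codons]
  n <- length(codons)
  if (any(aas[-n] == "*"))
    stop("internal stop codon at position(s): ",
      paste(which(aas[-n] == "*"), collapse = ", "), call. = FALSE)
  if (strategy == "match" && is.null(seed))
    stop("match strategy requires a seed", call. = FALSE)

  fam <- split(ALL_CODONS, code[ALL_CODONS])
  opt <- optimalCodons(table)
  names(opt) <- code[opt]

  out <- codons
  if (strategy == "max") {
    has <- aas %in% names(opt)
    out[has] <- opt[aas[has]]
  } else if (strategy == "threshold") {
    rare <- table@freq[codons] <= rareCeiling
    has <- aas %in% names(opt)
    repl <- rare & has
    out[repl] <- opt[aas[repl]]
  } else {
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
      sample.kind = "Rejection")
    for (i in seq_len(n)) {
      cc <- fam[[aas[i]]]
      f <- table@freq[cc]
      if (sum(f) > 0)
        out[i] <- sample(cc, 1L, prob = f)
    }
  }

  unresolved <- character(0)
  if (length(forbiddenMotifs)) {
    fixed <- avoidMotifs(out, aas, table, toupper(forbiddenMotifs))
    out <- fixed$codons
    unresolved <- fixed$unresolved
    if (length(unresolved))
      warning("forbidden motif(s) could not be removed: ",
        paste(unresolved, collapse = ", "))
  }

  newSeq <- paste0(out, collapse = "")
  names(newSeq) <- names(s)
  if (!identical(unname(code[splitCodons(newSeq)]), unname(aas)))
    stop("internal error: translation changed during recoding")
  res <- list(
    cds = newSeq,
    changes = compareSynonymous(s, newSeq, codeId = table@codeId),
    before = diagnoseCds(s, table, variant = variant),
    after = diagnoseCds(newSeq, table, variant = variant),
    strategy = strategy,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    unresolvedMotifs = unresolved)
  class(res) <- "optimizationResult"
  res
}

# Greedy motif removal: for each motif hit, try the next-most-frequent
# synonyms at each overlapping codon until the hit disappears.
avoidMotifs <- function(codons, aas, table, motifs) {
  fam <- split(ALL_CODONS, table@geneticCode[ALL_CODONS])
  unresolved <- character(0)
  for (motif in motifs) {
    for (pass in 1:3) {
      seq <- paste0(codons, collapse = "")
      hit <- regexpr(motif, seq, fixed = TRUE)
      if (hit < 0) break
      from <- (as.integer(hit) - 1L) %/% 3L + 1L
      to <- (as.integer(hit) + nchar(motif) - 2L) %/% 3L + 1L
      fixedIt <- FALSE
      for (i in from:to) {
        alts <- fam[[aas[i]]]
        alts <- alts[order(-table@freq[alts])]
        alts <- setdiff(alts, codons[i])
        for (alt in alts) {
          trial <- codons
          trial[i] <- alt
          if (regexpr(motif, paste0(trial, collapse = ""),
              fixed = TRUE) != hit) {
            codons <- trial
            fixedIt <- TRUE
            break
          }
        }
        if (fixedIt) break
      }
      if (!fixedIt) { unresolved <- c(unresolved, motif); break }
    }
    if (regexpr(motif, paste0(codons, collapse = ""), fixed = TRUE) > 0 &&
        !motif %in% unresolved)
      unresolved <- c(unresolved, motif)
  }
  list(codons = codons, unresolved = unique(unresolved))
}

#' @export
print.optimizationResult <- function(x, ...) {
  cat("optimizationResult (strategy = ", x$strategy,
    if (!is.na(x$seed)) paste0(", seed = ", x$seed), ")\n", sep = "")
  show(x$changes)
  cat("before: "); show(x$before)
  cat("after:  "); show(x$after)
  if (length(x$unresolvedMotifs))
    cat("unresolved motifs:", paste(x$unresolvedMotifs, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an optimization result as JSON
#'
#' @param res result of \code{\link{optimizeCds}}.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
optimizationAsJson <- function(res, path = NULL) {
  js <- jsonlite::toJSON(list(
    strategy = res$strategy,
    seed = res$seed,
    sequence = unname(res$cds),
    changes = reportToList(res$changes),
    before = reportToList(res$before),
    after = reportToList(res$after),
    unresolved_motifs = res$unresolvedMotifs),
    auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
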