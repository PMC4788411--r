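#' Write / read a codon usage table as TSV
#'
#' Columns: \code{codon}, \code{amino_acid}, \code{count},
#' \code{freq_among_synonyms} (4 decimal places), \code{is_optimal},
#' \code{is_rare}.  On read, frequencies are recomputed from the exact
#' integer counts when any are present, so a write/read round trip is
#' lossless; tables with all-zero counts fall back to the 4-decimal
#' frequencies.
#'
#' @param table a \code{\link{CodonUsageTable}}.
#' @param path file path.
#' @param rareThreshold rare cutoff used for the \code{is_rare} column.
#' @return \code{writeUsageTable}: the path, invisibly.
#' @export
writeUsageTable <- function(table, path, rareThreshold = 0.10) {
  stopifnot(methods::is(table, "CodonUsageTable"))
  cls <- classifyCodon(ALL_CODONS, table, rareThreshold)
  df <- data.frame(
    codon = ALL_CODONS,
    amino_acid = unname(table@geneticCode[ALL_CODONS]),
    count = unname(table@counts[ALL_CODONS]),
    freq_among_synonyms = sprintf("%.4f", table@freq[ALL_CODONS]),
    is_optimal = cls == "optimal",
    is_rare = cls == "rare")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeUsageTable
#' @param codeId translation table used to interpret the codons.
#' @param includeStops whether the stop family counts are meaningful.
#' @param nCds source-CDS count to record (not stored in the TSV).
#' @return \code{readUsageTable}: a \code{\link{CodonUsageTable}}.
#' @export
readUsageTable <- function(path, codeId = "11", includeStops = TRUE,
    nCds = 0L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "count", "freq_among_synonyms")
  if (!all(need %in% names(df)))
    stop("usage table TSV must have columns ",
      paste(need, collapse = ", "), call. = FALSE)
  if (!setequal(df$codon, ALL_CODONS))
    stop("usage table TSV must list the 64 triplets exactly once",
      call. = FALSE)
  counts <- setNames(as.integer(df$count), df$codon)[ALL_CODONS]
  if (sum(counts) == 0L) {
    # frequency-only table: materialize pseudo-counts at the stated
    # 4-decimal precision so the object stays internally consistent
    freq <- setNames(as.numeric(df$freq_among_synonyms), df$codon)[ALL_CODONS]
    counts <- setNames(as.integer(round(freq * 10000)), ALL_CODONS)
  }
  newUsageTable(counts, codeId, nCds, includeStops)
}

reportToList <- function(x) {
  if (methods::is(x, "DiagnosticsReport"))
    list(gc3 = x@gc3, n_codons = x@nCodons,
      n_optimal = x@nOptimal, n_rare = x@nRare,
      frac_optimal = x@fracOptimal, frac_rare = x@fracRare,
      mean_freq_diff_pct = x@meanFreqDiff, variant = x@variant,
      per_codon_classes = as.character(x@perCodonClass))
  else if (methods::is(x, "ChangeSummary"))
    list(n_changed = x@nChanged, n_total = x@nTotal,
      per_segment = x@perSegment, segment_size = x@segmentSize,
      changed_positions = x@changedPositions)
  else stop("no JSON form for this object", call. = FALSE)
}

#' Serialize a diagnostics or change report as JSON
#'
#' @param x a \code{DiagnosticsReport} or \code{ChangeSummary}.
#' @param path optional file; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
reportAsJson <- function(x, path = NULL) {
  js <- jsonlite::toJSON(reportToList(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
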