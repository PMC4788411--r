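#' @importFrom Biostrings DNAStringSet getGeneticCode oligonucleotideFrequency
NULL

ALL_CODONS <- sort(as.character(outer(outer(c("A", "C", "G", "T"),
  c("A", "C", "G", "T"), paste0), c("A", "C", "G", "T"), paste0)))

geneticCodeMap <- function(codeId = "11") {
  gc <- Biostrings::getGeneticCode(as.character(codeId))
  names(gc) <- toupper(chartr("U", "T", names(gc)))
  gc[ALL_CODONS]
}

# Coerce CDS input (character vector, DNAString, DNAStringSet) to a named
# uppercase character vector and enforce the frame/alphabet contract.
asCdsStrings <- function(x, what = "CDS") {
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x))
    stop(what, " must be a character vector or DNAString(Set)", call. = FALSE)
  if (!length(x)) stop("empty ", what, " set", call. = FALSE)
  x <- toupper(x)
  if (is.null(names(x))) names(x) <- paste0("cds", seq_along(x))
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("non-ACGT character in ", what, ": ",
      paste(names(x)[bad], collapse = ", "), call. = FALSE)
  off <- nchar(x) %% 3L != 0L | nchar(x) == 0L
  if (any(off))
    stop("frame error: length not a positive multiple of 3 in ", what, ": ",
      paste(names(x)[off], collapse = ", "), call. = FALSE)
  x
}

splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translateCodons <- function(codons, code) unname(code[codons])

#' GC3: G+C fraction at third codon positions
#'
#' The average frequency of guanine or cytosine at the third position of
#' the codons of a coding sequence; the stop codon, when present, is one
#' of those codons.  AT-rich plastomes have low GC3, so a gene recoded
#' for chloroplast expression should see its GC3 drop toward the
#' genome-wide value.
#'
#' @param x a coding sequence (character, \code{DNAString}) or a set
#'   (character vector, \code{DNAStringSet}); or a
#'   \code{\link{CodonUsageTable}}, for which the count-weighted GC3 of
#'   the source CDS set is returned.
#' @return numeric vector of per-sequence GC3 fractions (single number
#'   for a table).
#' @examples
#' gc3(c(lowGC = "AAAAAT", highGC = "GGGGGC"))
#' @export
setGeneric("gc3", function(x) standardGeneric("gc3"))

#' @rdname gc3
#' @export
setMethod("gc3", "character", function(x) {
  s <- asCdsStrings(x)
  vapply(s, function(seq) {
    third <- substring(seq, seq(3L, nchar(seq), by = 3L),
      seq(3L, nchar(seq), by = 3L))
    mean(third %in% c("G", "C"))
  }, numeric(1))
})

#' @rdname gc3
#' @export
setMethod("gc3", "DNAString", function(x) gc3(as.character(x)))

#' @rdname gc3
#' @export
setMethod("gc3", "DNAStringSet", function(x) {
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- paste0("cds", seq_along(s))
  gc3(s)
})

#' @rdname gc3
#' @export
setMethod("gc3", "CodonUsageTable", function(x) {
  gcEnding <- substring(ALL_CODONS, 3L, 3L) %in% c("G", "C")
  tot <- sum(x@counts)
  if (tot == 0L) return(NA_real_)
  sum(x@counts[ALL_CODONS][gcEnding]) / tot
})

countCodons <- function(cdsStrings) {
  dss <- Biostrings::DNAStringSet(cdsStrings)
  m <- Biostrings::oligonucleotideFrequency(dss, width = 3L, step = 3L)
  cnt <- colSums(m)
  out <- setNames(integer(64L), ALL_CODONS)
  out[names(cnt)] <- as.integer(cnt)
  out
}

# counts -> synonymous-relative frequencies (0 across unobserved families)
freqFromCounts <- function(counts, code) {
  fam <- split(ALL_CODONS, code[ALL_CODONS])
  freq <- setNames(numeric(64L), ALL_CODONS)
  for (aa in names(fam)) {
    tot <- sum(counts[fam[[aa]]])
    if (tot > 0L) freq[fam[[aa]]] <- counts[fam[[aa]]] / tot
  }
  freq
}

newUsageTable <- function(counts, codeId, nCds, includeStops) {
  code <- geneticCodeMap(codeId)
  if (!includeStops) counts[names(code)[code == "*"]] <- 0L
  freq <- freqFromCounts(counts, code)
  fam <- split(ALL_CODONS, code[ALL_CODONS])
  famTot <- vapply(fam, function(cc) sum(counts[cc]), numeric(1))
  empty <- names(famTot)[famTot == 0]
  if (!includeStops) empty <- setdiff(empty, "*")
  ties <- vapply(fam, function(cc) {
    f <- freq[cc]
    sum(f == max(f)) > 1L && max(f) > 0
  }, logical(1))
  methods::new("CodonUsageTable",
    codeId = as.character(codeId), geneticCode = code,
    counts = counts[ALL_CODONS], freq = freq[ALL_CODONS],
    nCds = as.integer(nCds), includeStops = includeStops,
    emptyFamilies = empty, tieFamilies = names(ties)[ties])
}

#' Build a codon usage table from a set of coding sequences
#'
#' Aggregates codon counts over all codons of all CDS and derives, for
#' every amino-acid family, the relative frequency of each synonymous
#' triplet.  Families never observed get frequency 0 for all members and
#' are flagged in \code{emptyFamilies}.
#'
#' @param cds CDS set (character vector or \code{DNAStringSet}); every
#'   sequence must be a positive multiple of 3 over A/C/G/T.
#' @param codeId NCBI translation table (default \code{"11"},
#'   plastid/bacterial).
#' @param includeStops count stop codons as a synonymous family
#'   (default \code{TRUE}).
#' @return a \code{\link{CodonUsageTable}}.
#' @examples
#' tab <- buildUsageTable("ATGAAATAA")
#' codonFreq(tab)[c("ATG", "AAA", "AAG", "TAA")]
#' @export
buildUsageTable <- function(cds, codeId = "11", includeStops = TRUE) {
  s <- asCdsStrings(cds)
  newUsageTable(countCodons(s), codeId, length(s), isTRUE(includeStops))
}

#' Build a usage table directly from synonymous frequency vectors
#'
#' Used by the synthetic generators: takes a per-family frequency
#' profile (list of named numeric vectors, each summing to 1) and
#' synthesizes a consistent table with \code{countsPerFamily}
#' pseudo-observations per family.
#'
#' @param profile named list; names are one-letter amino-acid codes
#'   (stop = \code{"*"}), elements are named frequency vectors over the
#'   family's codons.
#' @param codeId NCBI translation table identifier.
#' @param countsPerFamily pseudo-observations per family used to
#'   materialize integer counts.
#' @param nCds value recorded as the source-CDS count (0 = synthetic).
#' @return a \code{\link{CodonUsageTable}}.
#' @export
usageTableFromFrequencies <- function(profile, codeId = "11",
    countsPerFamily = 1000L, nCds = 0L) {
  code <- geneticCodeMap(codeId)
  counts <- setNames(integer(64L), ALL_CODONS)
  for (aa in names(profile)) {
    p <- profile[[aa]]
    if (abs(sum(p) - 1) > 1e-9)
      stop("profile for family ", aa, " does not sum to 1", call. = FALSE)
    if (!all(names(p) %in% ALL_CODONS) ||
        !all(code[names(p)] == aa))
      stop("profile codons inconsistent with family ", aa, call. = FALSE)
    cnt <- round(p * countsPerFamily)
    counts[names(p)] <- as.integer(cnt)
  }
  newUsageTable(counts, codeId, nCds,
    includeStops = "*" %in% names(profile))
}

#' @describeIn codonAccessors per-triplet observation counts
#' @export
codonCounts <- function(table) table@counts

#' Accessors for CodonUsageTable
#'
#' @param table a \code{\link{CodonUsageTable}}.
#' @name codonAccessors
#' @return named vectors over the 64 triplets.
NULL

#' @describeIn codonAccessors synonymous-relative frequencies
#' @export
codonFreq <- function(table) table@freq

#' @describeIn codonAccessors number of source CDS
#' @export
nCds <- function(table) table@nCds

# For each family pick the single optimal codon: maximum frequency,
# ties broken by lexicographic triplet order (tie families are flagged
# on the table).  Unobserved families have no optimal codon.
optimalCodons <- function(table) {
  fam <- split(ALL_CODONS, table@geneticCode[ALL_CODONS])
  out <- character(0)
  for (aa in names(fam)) {
    cc <- sort(fam[[aa]])
    f <- table@freq[cc]
    if (max(f) > 0) out <- c(out, cc[which.max(f)])
  }
  out
}

#' Classify codons as optimal, rare or intermediate
#'
#' A triplet is \emph{optimal} when it is the most frequently used among
#' its synonyms in the reference table (ties broken lexicographically,
#' flagged on the table), and \emph{rare} when its synonymous-relative
#' frequency is at most \code{rareThreshold} (boundary inclusive).
#' Optimal takes precedence over rare in the degenerate case where a
#' family maximum falls at or below the threshold (flagged via a
#' warning).  Members of unobserved families are rare (frequency 0).
#'
#' @param triplet character vector of DNA triplets.
#' @param table a \code{\link{CodonUsageTable}}.
#' @param rareThreshold rare cutoff on synonymous-relative frequency
#'   (default 0.10, inclusive).
#' @return factor with levels \code{optimal}, \code{intermediate},
#'   \code{rare}.
#' @examples
#' tab <- buildUsageTable(c("ATGAAAAAAAAGTAA"))
#' classifyCodon(c("ATG", "AAA", "AAG"), tab)
#' @export
classifyCodon <- function(triplet, table, rareThreshold = 0.10) {
  stopifnot(methods::is(table, "CodonUsageTable"))
  triplet <- toupper(triplet)
  bad <- !triplet %in% ALL_CODONS
  if (any(bad))
    stop("invalid triplet(s): ", paste(unique(triplet[bad]), collapse = ", "),
      call. = FALSE)
  opt <- optimalCodons(table)
  cls <- rep("intermediate", length(triplet))
  cls[table@freq[triplet] <= rareThreshold] <- "rare"
  isOpt <- triplet %in% opt
  if (any(isOpt & cls == "rare"))
    warning("optimal codon(s) at or below the rare threshold; ",
      "optimal takes precedence: ",
      paste(unique(triplet[isOpt & cls == "rare"]), collapse = ", "))
  cls[isOpt] <- "optimal"
  factor(cls, levels = c("optimal", "intermediate", "rare"))
}

#' Mean codon frequency difference between a gene and a reference table
#'
#' Compares the gene's own synonymous-relative codon frequencies
#' (computed over the gene's codons, stop family included when the table
#' includes stops) with the reference table's, as a mean absolute
#' difference in percent.  Three definitions are provided:
#' \describe{
#'   \item{\code{global}}{(default) unweighted mean over all 64 triplets
#'     of |f_gene - f_ref|; triplets of families absent from the gene
#'     contribute their reference frequency.}
#'   \item{\code{position}}{mean over codon positions of the difference
#'     at the codon occupying each position (occurrence-weighted).}
#'   \item{\code{present}}{unweighted mean over the distinct triplets
#'     present in the gene.}
#' }
#'
#' @param cds a single coding sequence.
#' @param table a \code{\link{CodonUsageTable}}.
#' @param variant which definition to use.
#' @return mean absolute frequency difference, in percent.
#' @examples
#' tab <- buildUsageTable("ATGAAATAA")
#' meanFreqDiff("ATGAAATAA", tab)  # gene identical to reference: 0
#' @export
meanFreqDiff <- function(cds, table,
    variant = c("global", "position", "present")) {
  variant <- match.arg(variant)
  stopifnot(methods::is(table, "CodonUsageTable"))
  s <- asCdsStrings(cds)
  if (length(s) != 1L) stop("meanFreqDiff expects a single CDS", call. = FALSE)
  codons <- splitCodons(s)
  code <- table@geneticCode
  if (!table@includeStops) codons <- codons[code[codons] != "*"]
  gcnt <- setNames(integer(64L), ALL_CODONS)
  tb <- base::table(codons)
  gcnt[names(tb)] <- as.integer(tb)
  gfreq <- freqFromCounts(gcnt, code)
  d <- abs(gfreq - table@freq)
  keep <- rep(TRUE, 64L)
  if (!table@includeStops) keep <- code[ALL_CODONS] != "*"
  val <- switch(variant,
    global = mean(d[keep]),
    position = mean(d[codons]),
    present = mean(d[unique(codons)]))
  100 * val
}

#' Full codon-usage diagnostics for a gene against a reference table
#'
#' Aggregates \code{\link{gc3}}, optimal/rare composition under
#' \code{\link{classifyCodon}}, and \code{\link{meanFreqDiff}} into a
#' \code{\link{DiagnosticsReport}}.
#'
#' @inheritParams meanFreqDiff
#' @param rareThreshold rare cutoff (inclusive), default 0.10.
#' @return a \code{\link{DiagnosticsReport}}.
#' @export
diagnoseCds <- function(cds, table,
    variant = c("global", "position", "present"), rareThreshold = 0.10) {
  variant <- match.arg(variant)
  s <- asCdsStrings(cds)
  if (length(s) != 1L) stop("diagnoseCds expects a single CDS", call. = FALSE)
  codons <- splitCodons(s)
  cls <- classifyCodon(codons, table, rareThreshold)
  n <- length(codons)
  nOpt <- sum(cls == "optimal")
  nRare <- sum(cls == "rare")
  methods::new("DiagnosticsReport",
    gc3 = unname(gc3(s)), nCodons = n,
    nOptimal = nOpt, nRare = nRare,
    fracOptimal = nOpt / n, fracRare = nRare / n,
    meanFreqDiff = meanFreqDiff(s, table, variant),
    variant = variant, perCodonClass = cls)
}

#' Synonymous-change accounting between two same-protein CDS
#'
#' Counts codon positions at which two equal-length coding sequences
#' with identical translations differ, overall and within consecutive
#' windows of \code{segmentSize} codons (1-based; the last window may be
#' short).  Any position whose difference is non-synonymous is an error
#' (the comparison is defined for synonymous recodings only).
#'
#' @param a,b coding sequences of equal length and identical translation.
#' @param segmentSize window width in codons (default 80).
#' @param codeId NCBI translation table for the synonymy check.
#' @return a \code{\link{ChangeSummary}}.
#' @examples
#' s <- compareSynonymous("ATGAAAAAGTAA", "ATGAAAAAATAA", segmentSize = 2)
#' nChanged(s)
#' @export
compareSynonymous <- function(a, b, segmentSize = 80L, codeId = "11") {
  sa <- asCdsStrings(a, "CDS a")
  sb <- asCdsStrings(b, "CDS b")
  if (length(sa) != 1L || length(sb) != 1L)
    stop("compareSynonymous expects single sequences", call. = FALSE)
  if (nchar(sa) != nchar(sb))
    stop("sequences have unequal lengths (", nchar(sa), " vs ", nchar(sb), ")",
      call. = FALSE)
  ca <- splitCodons(sa); cb <- splitCodons(sb)
  code <- geneticCodeMap(codeId)
  nonsyn <- which(code[ca] != code[cb])
  if (length(nonsyn))
    stop("non-synonymous difference at codon position(s): ",
      paste(nonsyn, collapse = ", "), call. = FALSE)
  changed <- which(ca != cb)
  n <- length(ca)
  segmentSize <- as.integer(segmentSize)
  if (segmentSize < 1L) stop("segmentSize must be >= 1", call. = FALSE)
  segIdx <- (seq_len(n) - 1L) %/% segmentSize + 1L
  nSeg <- max(segIdx)
  perSeg <- vapply(seq_len(nSeg),
    function(k) sum(segIdx[changed] == k), integer(1))
  methods::new("ChangeSummary",
    nChanged = length(changed), nTotal = n, perSegment = perSeg,
    segmentSize = segmentSize, changedPositions = as.integer(changed))
}

#' @describeIn compareSynonymous number of changed codon positions
#' @param x a \code{ChangeSummary}.
#' @export
nChanged <- function(x) x@nChanged

#' @describeIn compareSynonymous per-window changed-codon counts
#' @export
perSegment <- function(x) x@perSegment
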