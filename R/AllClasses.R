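#' @import methods
#' @importFrom stats coef fitted lm vcov sd qt rnorm rpois runif setNames var
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
NULL

#' CodonUsageTable: reference codon usage for a genetic code
#'
#' Per-triplet counts observed over a set of coding sequences, together
#' with synonymous-relative frequencies: for every amino-acid family (and
#' the stop family when \code{includeStops} is \code{TRUE}) the frequency
#' of each member triplet among all observations of that family.  The
#' table is the reference against which genes are scored
#' (\code{\link{diagnoseCds}}) and recoded (\code{\link{optimizeCds}}).
#'
#' @slot codeId NCBI translation-table identifier (e.g. \code{"11"} for
#'   the plastid/bacterial code).
#' @slot geneticCode named character vector of length 64 mapping each
#'   DNA triplet to its one-letter amino acid (stop = \code{"*"}).
#' @slot counts named integer vector of length 64; observation counts
#'   per triplet.
#' @slot freq named numeric vector of length 64; synonymous-relative
#'   frequency of each triplet within its family (0 for all members of
#'   an unobserved family).
#' @slot nCds number of source coding sequences.
#' @slot includeStops whether stop codons were counted.
#' @slot emptyFamilies one-letter codes of families with zero
#'   observations (flagged, frequencies reported as 0).
#' @slot tieFamilies one-letter codes of families whose maximum
#'   frequency is shared by more than one triplet (ties broken
#'   lexicographically for optimal-codon calls).
#' @export
setClass("CodonUsageTable",
  representation(
    codeId = "character",
    geneticCode = "character",
    counts = "integer",
    freq = "numeric",
    nCds = "integer",
    includeStops = "logical",
    emptyFamilies = "character",
    tieFamilies = "character"
  )
)

setValidity("CodonUsageTable", function(object) {
  msgs <- character()
  cods <- names(object@geneticCode)
  if (length(cods) != 64L || anyDuplicated(cods))
    msgs <- c(msgs, "genetic code must cover the 64 triplets exactly once")
  if (!identical(sort(names(object@counts)), sort(cods)))
    msgs <- c(msgs, "counts must be named by the 64 triplets")
  if (!identical(sort(names(object@freq)), sort(cods)))
    msgs <- c(msgs, "freq must be named by the 64 triplets")
  if (any(object@counts < 0L))
    msgs <- c(msgs, "counts must be non-negative")
  if (any(object@freq < 0 | object@freq > 1))
    msgs <- c(msgs, "frequencies must lie in [0, 1]")
  fam <- split(names(object@geneticCode), object@geneticCode)
  for (aa in names(fam)) {
    s <- sum(object@freq[fam[[aa]]])
    tot <- sum(object@counts[fam[[aa]]])
    if (tot > 0L && abs(s - 1) > 1e-9)
      msgs <- c(msgs, sprintf("family %s frequencies sum to %g, not 1", aa, s))
    if (tot == 0L && s != 0)
      msgs <- c(msgs, sprintf("unobserved family %s must have zero frequencies", aa))
  }
  if (length(msgs)) msgs else TRUE
})

#' DiagnosticsReport: per-gene codon-usage diagnostics
#'
#' @slot gc3 fraction of codons whose third base is G or C.
#' @slot nCodons number of codons scored (stop included when present).
#' @slot nOptimal,nRare counts of codons classified optimal / rare
#'   against the reference table.
#' @slot fracOptimal,fracRare the same as fractions of \code{nCodons}.
#' @slot meanFreqDiff mean codon frequency difference versus the
#'   reference table, in percent, under \code{variant}.
#' @slot variant which mean-frequency-difference definition was used.
#' @slot perCodonClass factor (\code{optimal}/\code{intermediate}/
#'   \code{rare}) of length \code{nCodons}.
#' @export
setClass("DiagnosticsReport",
  representation(
    gc3 = "numeric",
    nCodons = "integer",
    nOptimal = "integer",
    nRare = "integer",
    fracOptimal = "numeric",
    fracRare = "numeric",
    meanFreqDiff = "numeric",
    variant = "character",
    perCodonClass = "factor"
  )
)

setValidity("DiagnosticsReport", function(object) {
  msgs <- character()
  if (object@gc3 < 0 || object@gc3 > 1) msgs <- c(msgs, "gc3 must lie in [0, 1]")
  if (object@nOptimal + object@nRare > object@nCodons)
    msgs <- c(msgs, "nOptimal + nRare exceeds nCodons")
  if (length(object@perCodonClass) != object@nCodons)
    msgs <- c(msgs, "perCodonClass length must equal nCodons")
  if (abs(object@fracOptimal - object@nOptimal / object@nCodons) > 1e-12)
    msgs <- c(msgs, "fracOptimal inconsistent with counts")
  if (length(msgs)) msgs else TRUE
})

#' ChangeSummary: synonymous-change accounting between two CDS
#'
#' @slot nChanged number of codon positions whose triplets differ.
#' @slot nTotal total codon positions compared.
#' @slot perSegment changed-codon counts over consecutive windows of
#'   \code{segmentSize} codons (1-based; last window may be short).
#' @slot segmentSize window width in codons.
#' @slot changedPositions 1-based codon indices that differ.
#' @export
setClass("ChangeSummary",
  representation(
    nChanged = "integer",
    nTotal = "integer",
    perSegment = "integer",
    segmentSize = "integer",
    changedPositions = "integer"
  )
)

setValidity("ChangeSummary", function(object) {
  msgs <- character()
  if (sum(object@perSegment) != object@nChanged)
    msgs <- c(msgs, "per-segment counts must sum to nChanged")
  if (object@nChanged > object@nTotal)
    msgs <- c(msgs, "nChanged cannot exceed nTotal")
  if (length(msgs)) msgs else TRUE
})

#' TwoChannelImage: reporter + autofluorescence channel pair
#'
#' Two equally shaped non-negative 2-D intensity arrays: the reporter
#' (CFP) emission channel and the chlorophyll autofluorescence channel
#' used for masking and depth normalization.
#'
#' @slot cfp reporter-channel intensity matrix.
#' @slot auto autofluorescence-channel intensity matrix.
#' @slot bitDepth nominal pixel depth in bits (informational).
#' @export
setClass("TwoChannelImage",
  representation(cfp = "matrix", auto = "matrix", bitDepth = "numeric")
)

setValidity("TwoChannelImage", function(object) {
  msgs <- character()
  if (!identical(dim(object@cfp), dim(object@auto)))
    msgs <- c(msgs, "cfp and auto channels must have identical shapes")
  if (any(object@cfp < 0) || any(object@auto < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ParticleTable: per-particle intensity summaries for one section
#'
#' @slot particles data.frame with columns \code{label}, \code{area_px},
#'   \code{mean_cfp}, \code{mean_auto}, \code{ratio}.
#' @slot meanRatio mean of per-particle ratios in the section.
#' @slot sdRatio standard deviation of per-particle ratios.
#' @slot nParticles number of retained particles.
#' @slot nExcluded particles dropped because their mean autofluorescence
#'   was zero.
#' @export
setClass("ParticleTable",
  representation(
    particles = "data.frame",
    meanRatio = "numeric",
    sdRatio = "numeric",
    nParticles = "integer",
    nExcluded = "integer"
  )
)

setValidity("ParticleTable", function(object) {
  p <- object@particles
  need <- c("label", "area_px", "mean_cfp", "mean_auto", "ratio")
  if (!all(need %in% names(p)))
    return(paste("particles must have columns", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (anyDuplicated(p$label) || any(p$label <= 0))
      return("labels must be positive and unique")
    ok <- abs(p$ratio - p$mean_cfp / p$mean_auto) <= 1e-9 * pmax(1, abs(p$ratio))
    if (!all(ok)) return("ratio must equal mean_cfp/mean_auto for every row")
  }
  TRUE
})

#' StandardCurve: fitted density-versus-amount line for densitometry
#'
#' @slot slope density units per ng.
#' @slot intercept density units at 0 ng (0 when forced through origin).
#' @slot rSquared coefficient of determination of the fit.
#' @slot nPoints number of standard points (distinct amounts).
#' @slot replicateSd per-point standard deviation across replicates.
#' @slot forceOrigin whether the intercept was fixed at 0.
#' @slot fit the underlying \code{lm} fit (for covariance propagation).
#' @export
setClass("StandardCurve",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    nPoints = "integer",
    replicateSd = "numeric",
    forceOrigin = "logical",
    fit = "ANY"
  )
)

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (object@nPoints < 2L) msgs <- c(msgs, "need at least 2 standard points")
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    msgs <- c(msgs, "rSquared must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
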