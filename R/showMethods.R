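setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable (translation table ", object@codeId, ")\n", sep = "")
  cat("  source CDS: ", object@nCds, "; codons counted: ",
    sum(object@counts), "; stops ",
    if (object@includeStops) "included" else "excluded", "\n", sep = "")
  cat("  count-weighted GC3: ",
    if (sum(object@counts)) sprintf("%.4f", gc3(object)) else "NA", "\n",
    sep = "")
  if (length(object@emptyFamilies))
    cat("  unobserved families: ",
      paste(object@emptyFamilies, collapse = " "), "\n", sep = "")
  if (length(object@tieFamilies))
    cat("  tied-maximum families: ",
      paste(object@tieFamilies, collapse = " "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "DiagnosticsReport", function(object) {
  cat("DiagnosticsReport over ", object@nCodons, " codons\n", sep = "")
  cat(sprintf("  GC3: %.4f (%.2f%%)\n", object@gc3, 100 * object@gc3))
  cat(sprintf("  optimal: %d (%.2f%%)   rare: %d (%.2f%%)\n",
    object@nOptimal, 100 * object@fracOptimal,
    object@nRare, 100 * object@fracRare))
  cat(sprintf("  mean codon frequency difference (%s): %.2f%%\n",
    object@variant, object@meanFreqDiff))
  invisible(NULL)
})

setMethod("show", "ChangeSummary", function(object) {
  cat("ChangeSummary: ", object@nChanged, " of ", object@nTotal,
    " codons changed\n", sep = "")
  cat("  per ", object@segmentSize, "-codon segment: ",
    paste(object@perSegment, collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "TwoChannelImage", function(object) {
  d <- dim(object@cfp)
  cat("TwoChannelImage ", d[1], "x", d[2], " (", object@bitDepth,
    "-bit)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ParticleTable", function(object) {
  cat("ParticleTable: ", object@nParticles, " particles (",
    object@nExcluded, " excluded)\n", sep = "")
  cat(sprintf("  mean ratio: %.4f   sd: %.4f\n",
    object@meanRatio, object@sdRatio))
  invisible(NULL)
})

setMethod("show", "StandardCurve", function(object) {
  cat("StandardCurve: density = ",
    sprintf("%.4g", object@slope), " * ng + ",
    sprintf("%.4g", object@intercept),
    if (object@forceOrigin) " (through origin)", "\n", sep = "")
  cat(sprintf("  r^2 = %.4f over %d points\n",
    object@rSquared, object@nPoints))
  invisible(NULL)
})
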