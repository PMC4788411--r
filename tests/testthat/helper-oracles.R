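# Independent brute-force oracles and tiny fixture builders used across
# the suite.  These deliberately avoid the package's own vectorized
# implementations.

# third-base G/C fraction by an explicit per-codon loop
bruteGc3 <- function(seq) {
  n <- nchar(seq) / 3
  hits <- 0
  for (i in seq_len(n)) {
    third <- substr(seq, 3 * i, 3 * i)
    if (third == "G" || third == "C") hits <- hits + 1
  }
  hits / n
}

# random in-frame CDS over ACGT (may contain internal stops; fine for
# counting statistics)
randomCodonString <- function(nCodons) {
  paste0(sample(c("A", "C", "G", "T"), 3 * nCodons, replace = TRUE),
    collapse = "")
}

# random valid protein-coding CDS: ATG start, no internal stop, one
# terminal stop
randomValidCds <- function(nCodons) {
  code <- Biostrings::getGeneticCode("11")
  names(code) <- chartr("U", "T", names(code))
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  paste0(c("ATG", sample(sense, nCodons - 2, replace = TRUE),
    sample(stops, 1)), collapse = "")
}

# grayscale opening with a ball element by explicit per-pixel loops
bruteBallOpening <- function(img, radius) {
  r <- ceiling(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dx^2 - offs$dy^2)
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- Inf
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs$dx[k]; jj <- j + offs$dy[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        best <- min(best, img[ii, jj] - offs$h[k])
    }
    ero[i, j] <- best
  }
  dil <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- -Inf
    for (k in seq_len(nrow(offs))) {
      ii <- i - offs$dx[k]; jj <- j - offs$dy[k]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        best <- max(best, ero[ii, jj] + offs$h[k])
    }
    dil[i, j] <- best
  }
  dil
}

# exhaustive between-class-variance threshold search over observed values
bruteMaxVarThreshold <- function(v) {
  cands <- sort(unique(v))
  cands <- cands[-length(cands)]
  best <- cands[1]; bestVar <- -Inf
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > bestVar) { bestVar <- bc; best <- t }
  }
  best
}

# binary disc mask helper
discMask <- function(size, cx, cy, r) {
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}
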