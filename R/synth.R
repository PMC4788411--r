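#' AT-rich chloroplast-style synonymous frequency profile
#'
#' A fixed synthetic per-family codon frequency profile emulating the
#' strong A/T bias at third positions typical of liverwort plastome
#' coding sequences: in almost every family the A- or T-ending codon
#' dominates while G/C-ending codons are rare or intermediate (Cys is
#' deliberately C-optimal so that GC-ending optimal codons exist).  All
#' family vectors sum to 1.  This profile is \emph{synthetic}: it is a
#' stand-in with the right statistical character, not codon counts from
#' any sequenced genome.
#'
#' @return named list of per-family frequency vectors (stop family
#'   \code{"*"} included).
#' @export
chloroplastStyleProfile <- function() {
  list(
    "F" = c(TTT = 0.93, TTC = 0.07),
    "L" = c(TTA = 0.50, TTG = 0.20, CTT = 0.14, CTA = 0.08, CTC = 0.04,
            CTG = 0.04),
    "I" = c(ATT = 0.70, ATA = 0.25, ATC = 0.05),
    "M" = c(ATG = 1),
    "V" = c(GTT = 0.55, GTA = 0.35, GTG = 0.05, GTC = 0.05),
    "S" = c(TCT = 0.60, AGT = 0.22, TCA = 0.08, TCC = 0.04, TCG = 0.03,
            AGC = 0.03),
    "P" = c(CCT = 0.60, CCA = 0.22, CCG = 0.13, CCC = 0.05),
    "T" = c(ACT = 0.55, ACA = 0.27, ACC = 0.13, ACG = 0.05),
    "A" = c(GCT = 0.55, GCA = 0.27, GCC = 0.13, GCG = 0.05),
    "Y" = c(TAT = 0.92, TAC = 0.08),
    "H" = c(CAT = 0.92, CAC = 0.08),
    "Q" = c(CAA = 0.92, CAG = 0.08),
    "N" = c(AAT = 0.92, AAC = 0.08),
    "K" = c(AAA = 0.92, AAG = 0.08),
    "D" = c(GAT = 0.92, GAC = 0.08),
    "E" = c(GAA = 0.92, GAG = 0.08),
    "C" = c(TGC = 0.55, TGT = 0.45),
    "W" = c(TGG = 1),
    "R" = c(CGT = 0.45, AGA = 0.30, CGA = 0.13, AGG = 0.05, CGC = 0.04,
            CGG = 0.03),
    "G" = c(GGT = 0.55, GGA = 0.25, GGG = 0.15, GGC = 0.05),
    "*" = c(TAA = 0.85, TAG = 0.10, TGA = 0.05)
  )
}

setSeed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
    sample.kind = "Rejection")
}

#' Generate a CDS set drawn from a synonymous frequency profile
#'
#' Each CDS starts with ATG, ends with exactly one stop codon drawn
#' from the stop family, and has its internal codons drawn per amino
#' acid from the profile's family frequencies.  When \code{targetGc3}
#' is given, third bases are adjusted by deterministic synonymous swaps
#' (toward each family's most frequent alternative of the opposite
#' GC class) until the set-wide GC3 matches the target to within one
#' codon.
#'
#' @param nCds number of sequences.
#' @param meanLengthCodons mean length in codons (lengths are drawn
#'   Poisson around this mean, minimum 10).
#' @param profile per-family frequency profile
#'   (default \code{\link{chloroplastStyleProfile}}).
#' @param targetGc3 optional set-wide GC3 to hit.
#' @param seed RNG seed (required; generation is reproducible).
#' @return list: \code{cds} (named character), \code{profile} (the true
#'   generating frequencies), \code{realizedGc3}.
#' @export
genCdsSet <- function(nCds, meanLengthCodons = 250,
    profile = chloroplastStyleProfile(), targetGc3 = NULL, seed) {
  if (missing(seed)) stop("genCdsSet requires an explicit seed", call. = FALSE)
  if (nCds < 1L) stop("nCds must be positive", call. = FALSE)
  setSeed(seed)
  aaPool <- setdiff(names(profile), "*")
  cds <- character(nCds)
  for (i in seq_len(nCds)) {
    len <- max(10L, rpois(1L, meanLengthCodons))
    aas <- c("M", sample(aaPool, len - 2L, replace = TRUE), "*")
    codons <- vapply(aas, function(aa) {
      p <- profile[[aa]]
      sample(names(p), 1L, prob = p)
    }, character(1))
    cds[i] <- paste0(codons, collapse = "")
  }
  names(cds) <- sprintf("synthgene%03d", seq_len(nCds))
  if (!is.null(targetGc3)) cds <- adjustGc3(cds, targetGc3, profile)
  list(cds = cds, profile = profile,
    realizedGc3 = sum(vapply(cds, function(s) {
      third <- substring(s, seq(3, nchar(s), 3), seq(3, nchar(s), 3))
      sum(third %in% c("G", "C"))
    }, numeric(1))) / (sum(nchar(cds)) / 3))
}

# Deterministic synonymous third-base adjustment toward a target GC3.
adjustGc3 <- function(cds, targetGc3, profile) {
  code <- geneticCodeMap("11")
  swapTo <- function(codon, wantGC) {
    aa <- code[[codon]]
    p <- profile[[aa]]
    alt <- names(p)[substring(names(p), 3, 3) %in%
      (if (wantGC) c("G", "C") else c("A", "T"))]
    alt <- setdiff(alt, codon)
    if (!length(alt)) return(NA_character_)
    alt[which.max(p[alt])]
  }
  allCodons <- lapply(cds, splitCodons)
  total <- sum(lengths(allCodons))
  isGC <- function(cod) substring(cod, 3, 3) %in% c("G", "C")
  cur <- sum(vapply(allCodons, function(cc) sum(isGC(cc)), numeric(1)))
  want <- round(targetGc3 * total)
  dirGC <- want > cur
  need <- abs(want - cur)
  if (need > 0) {
    for (g in seq_along(allCodons)) {
      cc <- allCodons[[g]]
      for (i in seq_along(cc)) {
        if (need == 0) break
        if (isGC(cc[i]) != dirGC) {
          alt <- swapTo(cc[i], dirGC)
          if (!is.na(alt)) {
            cc[i] <- alt
            need <- need - 1
          }
        }
      }
      allCodons[[g]] <- cc
      if (need == 0) break
    }
  }
  out <- vapply(allCodons, paste0, character(1), collapse = "")
  names(out) <- names(cds)
  out
}

# --- designed reporter pair ----------------------------------------------

# Per-position recoding patterns: native codon, optimized codon, with
# known class (optimal/intermediate/rare) and third-base GC under the
# chloroplast-style profile.  Used by syntheticReporterPair().
reporterPatterns <- function() {
  list(
    # native rare & GC-ending -> optimized optimal & AT-ending
    p1 = list(c("TTC", "TTT"), c("TAC", "TAT"), c("CAC", "CAT"),
              c("CAG", "CAA"), c("AAC", "AAT"), c("GAC", "GAT"),
              c("GAG", "GAA"), c("ATC", "ATT"), c("GTC", "GTT"),
              c("AAG", "AAA")),
    # native intermediate & GC-ending -> optimized optimal & AT-ending
    p2 = list(c("GGG", "GGT"), c("CCG", "CCT"), c("ACC", "ACT"),
              c("GCC", "GCT")),
    # native rare & GC-ending -> optimized intermediate & AT-ending
    p3 = list(c("GTG", "GTA"), c("ATC", "ATA"), c("ACG", "ACA"),
              c("GCG", "GCA"), c("CCC", "CCA"), c("GGC", "GGA")),
    # native intermediate & GC-ending -> optimized intermediate & AT-ending
    p4 = list(c("TTG", "CTT"), c("GGG", "GGA"), c("ACC", "ACA"),
              c("GCC", "GCA"), c("CCG", "CCA")),
    # native rare & GC-ending -> optimized intermediate & GC-ending
    p7 = list(c("CTC", "TTG")),
    # native optimal & GC-ending -> optimized intermediate & AT-ending
    p8 = list(c("TGC", "TGT")),
    # native intermediate & AT-ending -> optimized rare & AT-ending
    p9 = list(c("AGT", "TCA"))
  )
}

#' Synthetic stand-in reporter gene pair with designed diagnostics
#'
#' Constructs, deterministically, a 240-codon "native" coding sequence
#' and its synonymous recoding, engineered so that every headline
#' diagnostic of a chloroplast codon-optimization exercise is known by
#' construction against the accompanying
#' \code{\link{chloroplastStyleProfile}} table:
#' \itemize{
#'   \item native GC3 = 231/240 (96.25\%), optimized GC3 = 30/240
#'     (12.50\%);
#'   \item 212 of 240 codons changed, distributed 72/71/69 over the
#'     three 80-codon segments;
#'   \item native composition 16 optimal / 160 rare codons; optimized
#'     composition 174 optimal / 15 rare.
#' }
#' Both sequences translate identically, start with ATG and end with a
#' stop codon.  These are \emph{synthetic} sequences: they reproduce
#' the arithmetic of a published optimization design, not any deposited
#' nucleotide sequence.
#'
#' @return list: \code{native}, \code{optimized} (named character
#'   sequences), \code{table} (the matching
#'   \code{\link{CodonUsageTable}}), and \code{design} (the designed
#'   truth: gc3Native, gc3Optimized, nChanged, perSegment,
#'   nativeOptimal, nativeRare, optimizedOptimal, optimizedRare).
#' @export
syntheticReporterPair <- function() {
  pat <- reporterPatterns()
  cyc <- function(set, n) {
    m <- length(set)
    lapply(seq_len(n), function(i) set[[(i - 1L) %% m + 1L]])
  }
  # changed-position pattern instances (stop change appended last)
  changed <- c(cyc(pat$p1, 124L), cyc(pat$p2, 35L), cyc(pat$p3, 19L),
    cyc(pat$p4, 20L), cyc(pat$p7, 6L), cyc(pat$p8, 2L), cyc(pat$p9, 5L))
  # deterministic interleave so families spread along the gene
  changed <- changed[order(seq_along(changed) %% 7L, seq_along(changed))]
  changed <- c(changed, list(c("TAG", "TAA")))   # stop: rare/GC -> optimal/AT
  stopifnot(length(changed) == 212L)

  # unchanged positions: 14 single-family optimal (Met/Trp, GC-ending),
  # 10 rare (AAG), 4 intermediate (CTT); distributed 8/9/11 per segment
  unchangedCodons <- c("ATG", rep(c("TGG", "ATG"), length.out = 13L),
    rep("AAG", 10L), rep("CTT", 4L))
  unchangedIdx <- c(1L, 12L, 23L, 34L, 45L, 56L, 67L, 78L,       # seg 1: 8
    81L, 91L, 101L, 111L, 121L, 131L, 141L, 151L, 160L,          # seg 2: 9
    161L, 169L, 177L, 185L, 193L, 201L, 209L, 217L, 225L, 233L, 239L) # seg 3: 11
  stopifnot(length(unchangedIdx) == 28L, !anyDuplicated(unchangedIdx))

  native <- optimized <- character(240L)
  native[unchangedIdx] <- unchangedCodons
  optimized[unchangedIdx] <- unchangedCodons
  slots <- setdiff(seq_len(240L), unchangedIdx)
  # keep the stop change at position 240
  slots <- c(setdiff(slots, 240L), 240L)
  for (i in seq_along(slots)) {
    native[slots[i]] <- changed[[i]][1]
    optimized[slots[i]] <- changed[[i]][2]
  }
  tab <- usageTableFromFrequencies(chloroplastStyleProfile())
  list(
    native = c(reporter_native_synthetic = paste0(native, collapse = "")),
    optimized = c(reporter_optimized_synthetic =
      paste0(optimized, collapse = "")),
    table = tab,
    design = list(gc3Native = 231 / 240, gc3Optimized = 30 / 240,
      nChanged = 212L, perSegment = c(72L, 71L, 69L),
      nativeOptimal = 16L, nativeRare = 160L,
      optimizedOptimal = 174L, optimizedRare = 15L))
}

# --- synthetic plastome --------------------------------------------------

#' Write a minimal single-record GenBank flat file
#'
#' @param sequence genome sequence (uppercase ACGT string).
#' @param features data.frame with columns \code{key}, \code{location}
#'   and optionally \code{gene}, \code{pseudo}.
#' @param path output file.
#' @param name LOCUS name.
#' @return the path, invisibly.
#' @export
writeGenBankRecord <- function(sequence, features, path,
    name = "SYNTHETIC") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-2000",
    name, nchar(sequence)), con)
  writeLines(sprintf("DEFINITION  synthetic record %s.", name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(sequence)), con)
  for (i in seq_len(nrow(features))) {
    writeLines(sprintf("     %-16s%s", features$key[i],
      features$location[i]), con)
    if (!is.null(features$gene) && !is.na(features$gene[i]))
      writeLines(sprintf("                     /gene=\"%s\"",
        features$gene[i]), con)
    if (!is.null(features$pseudo) && isTRUE(features$pseudo[i]))
      writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, nchar(sequence), by = 60L)
  for (p in pos) {
    chunk <- substr(sequence, p, min(p + 59L, nchar(sequence)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

randomSpacer <- function(n) {
  paste0(sample(c("A", "T", "A", "T", "G", "C"), n, replace = TRUE),
    collapse = "")
}

#' Synthetic AT-rich plastome with a ground-truthed CDS census
#'
#' Generates \code{nGenes} coding sequences from the chloroplast-style
#' profile with the set-wide GC3 adjusted to \code{targetGc3}, then
#' assembles them into a synthetic genome with AT-rich spacers.  Some
#' genes are placed on the minus strand (\code{complement()}), some are
#' split into two exons (\code{join()}), a configurable number are
#' duplicated verbatim as inverted-repeat copies, and one pseudo gene
#' plus one frame-violating CDS are included so extraction policies
#' have something to reject.  The \emph{designed} truth (the CDS set
#' and its GC3) is returned alongside.
#'
#' @param nGenes number of unique CDS (default 94).
#' @param meanLengthCodons mean CDS length in codons.
#' @param targetGc3 set-wide GC3 of the unique CDS set (default 0.1210).
#' @param nIrDuplicates how many genes to duplicate verbatim.
#' @param seed RNG seed.
#' @return list: \code{path}-ready \code{sequence} + \code{features}
#'   (pass to \code{\link{writeGenBankRecord}}), \code{cds} (the true
#'   unique CDS set), \code{gc3} (its aggregate GC3).
#' @export
syntheticPlastome <- function(nGenes = 94L, meanLengthCodons = 230,
    targetGc3 = 0.1210, nIrDuplicates = 8L, seed = 1L) {
  gen <- genCdsSet(nGenes, meanLengthCodons, targetGc3 = targetGc3,
    seed = seed)
  cds <- gen$cds
  segs <- character(0)
  feats <- list()
  posn <- 0L
  addSeg <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    start <- posn + 1L
    posn <<- posn + nchar(s)
    c(start, posn)
  }
  addSeg(randomSpacer(120L))
  strand <- rep_len(c("+", "+", "-"), nGenes)
  split2 <- seq_len(nGenes) %% 17L == 0L            # a few join() genes
  for (i in seq_len(nGenes)) {
    s <- cds[[i]]
    gene <- names(cds)[i]
    if (split2[i]) {
      cut <- 3L * (nchar(s) %/% 6L)
      ex1 <- substr(s, 1L, cut); ex2 <- substr(s, cut + 1L, nchar(s))
      if (strand[i] == "-") {
        rc <- function(x) as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(x)))
        r2 <- addSeg(rc(ex2)); addSeg(randomSpacer(40L)); r1 <- addSeg(rc(ex1))
        loc <- sprintf("complement(join(%d..%d,%d..%d))",
          r2[1], r2[2], r1[1], r1[2])
      } else {
        r1 <- addSeg(ex1); addSeg(randomSpacer(40L)); r2 <- addSeg(ex2)
        loc <- sprintf("join(%d..%d,%d..%d)", r1[1], r1[2], r2[1], r2[2])
      }
    } else if (strand[i] == "-") {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
      r <- addSeg(rc)
      loc <- sprintf("complement(%d..%d)", r[1], r[2])
    } else {
      r <- addSeg(s)
      loc <- sprintf("%d..%d", r[1], r[2])
    }
    feats[[length(feats) + 1L]] <- data.frame(key = "CDS", location = loc,
      gene = gene, pseudo = FALSE)
    addSeg(randomSpacer(60L + (i %% 5L) * 20L))
  }
  # inverted-repeat verbatim duplicates of the first nIrDuplicates genes
  for (i in seq_len(nIrDuplicates)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds[[i]])))
    r <- addSeg(rc)
    feats[[length(feats) + 1L]] <- data.frame(key = "CDS",
      location = sprintf("complement(%d..%d)", r[1], r[2]),
      gene = names(cds)[i], pseudo = FALSE)
    addSeg(randomSpacer(50L))
  }
  # a pseudo gene and a frame-violating CDS for the policy to reject
  r <- addSeg(cds[[1L]])
  feats[[length(feats) + 1L]] <- data.frame(key = "CDS",
    location = sprintf("%d..%d", r[1], r[2]),
    gene = "pseudo_copy", pseudo = TRUE)
  addSeg(randomSpacer(30L))
  r <- addSeg(substr(cds[[2L]], 1L, nchar(cds[[2L]]) - 1L))
  feats[[length(feats) + 1L]] <- data.frame(key = "CDS",
    location = sprintf("%d..%d", r[1], r[2]),
    gene = "frameshift_orf", pseudo = FALSE)
  addSeg(randomSpacer(80L))
  list(sequence = paste0(unlist(segs), collapse = ""),
    features = do.call(rbind, feats),
    cds = cds, gc3 = gen$realizedGc3)
}

# --- image scenes --------------------------------------------------------

#' Synthetic two-channel plastid scene with ground truth
#'
#' Renders soft-edged discs ("plastids") into an autofluorescence
#' channel and a reporter channel whose per-particle signal is exactly
#' \code{cfpAutoRatio} times the autofluorescence signal before noise;
#' Gaussian read noise and constant channel offsets are then added and
#' intensities clipped at zero.  When \code{overlapFraction > 0}, the
#' corresponding fraction of particles is placed as touching pairs
#' (centers 1.5 radii apart) to exercise watershed splitting.
#'
#' @param nParticles number of particles.
#' @param radiusRange min/max disc radius in px; the default stays
#'   below the usual rolling-ball radius of 5 px so particles survive
#'   opening-based background subtraction.
#' @param cfpAutoRatio true per-particle CFP/autofluorescence ratio
#'   (scalar or length-\code{nParticles}).
#' @param amplitude peak autofluorescence signal above background.
#' @param background per-channel constant offsets,
#'   \code{c(cfp = ..., auto = ...)}.
#' @param noiseSd Gaussian noise standard deviation (same on both
#'   channels); \code{amplitude / noiseSd} is the scene's SNR.
#' @param overlapFraction fraction of particles placed as touching
#'   pairs.
#' @param imageSize image side length in px.
#' @param edgeSd Gaussian edge falloff scale in px.
#' @param seed RNG seed.
#' @return list: \code{image} (a \code{\link{TwoChannelImage}}),
#'   \code{truthLabels} (integer matrix, 0 = background; a particle's
#'   footprint is everything above half its peak intensity),
#'   \code{truthRatios} (per-particle true ratios), \code{centers},
#'   \code{radii}.
#' @export
genPlastidScene <- function(nParticles = 12L, radiusRange = c(2.5, 4),
    cfpAutoRatio = 1.0, amplitude = 100, background = c(cfp = 0, auto = 0),
    noiseSd = 0, overlapFraction = 0, imageSize = 160L, edgeSd = 1.5,
    seed) {
  if (missing(seed)) stop("genPlastidScene requires an explicit seed",
    call. = FALSE)
  setSeed(seed)
  ratios <- rep_len(cfpAutoRatio, nParticles)
  radii <- runif(nParticles, radiusRange[1], radiusRange[2])
  nPair <- floor(nParticles * overlapFraction / 2)
  centers <- matrix(NA_real_, nParticles, 2L)
  margin <- max(radiusRange) + 6
  placed <- 0L
  tries <- 0L
  minSep <- 2.6 * max(radiusRange)
  while (placed < nParticles && tries < 20000L) {
    tries <- tries + 1L
    p <- runif(2L, margin, imageSize - margin)
    if (placed > 0L) {
      d <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
        matrix(p, placed, 2L, byrow = TRUE))^2))
      if (min(d) < minSep) next
    }
    placed <- placed + 1L
    centers[placed, ] <- p
    # touching partner at 1.5 radii for the first nPair placements
    if (placed <= 2L * nPair && placed %% 2L == 1L &&
        placed + 1L <= nParticles) {
      ang <- runif(1L, 0, 2 * pi)
      off <- 1.5 * radii[placed] * c(cos(ang), sin(ang))
      q <- pmin(pmax(p + off, margin), imageSize - margin)
      placed <- placed + 1L
      centers[placed, ] <- q
    }
  }
  if (placed < nParticles)
    stop("could not place all particles; reduce nParticles or radii",
      call. = FALSE)
  xg <- matrix(seq_len(imageSize), imageSize, imageSize)
  yg <- t(xg)
  auto <- matrix(0, imageSize, imageSize)
  cfp <- matrix(0, imageSize, imageSize)
  labels <- matrix(0L, imageSize, imageSize)
  bestD <- matrix(Inf, imageSize, imageSize)
  halfMax <- edgeSd * sqrt(2 * log(2))   # half-maximum footprint margin
  for (i in seq_len(nParticles)) {
    d <- sqrt((xg - centers[i, 1])^2 + (yg - centers[i, 2])^2)
    fall <- ifelse(d <= radii[i], 1,
      exp(-((d - radii[i])^2) / (2 * edgeSd^2)))
    sig <- amplitude * fall
    auto <- auto + sig
    cfp <- cfp + ratios[i] * sig
    # truth label = half-maximum footprint, nearest particle wins
    core <- d <= radii[i] + halfMax & d < bestD
    labels[core] <- i
    bestD[core] <- d[core]
  }
  auto <- auto + background[["auto"]]
  cfp <- cfp + background[["cfp"]]
  if (noiseSd > 0) {
    auto <- auto + matrix(rnorm(imageSize^2, 0, noiseSd), imageSize)
    cfp <- cfp + matrix(rnorm(imageSize^2, 0, noiseSd), imageSize)
  }
  img <- methods::new("TwoChannelImage", cfp = pmax(cfp, 0),
    auto = pmax(auto, 0), bitDepth = 16)
  list(image = img, truthLabels = labels, truthRatios = ratios,
    centers = centers, radii = radii)
}

# --- gel series ----------------------------------------------------------

#' Synthetic densitometry standard series
#'
#' Densities follow \code{slope * ng + intercept} with additive
#' Gaussian noise, replicated \code{nReplicates} times per amount;
#' reproducible under seed.  The default amounts are ten 2-fold serial
#' dilutions from 1000 ng, the design of a typical in-gel fluorescence
#' standard curve.
#'
#' @param slope,intercept true line parameters (density units per ng /
#'   density units).
#' @param amounts ng loaded per lane.
#' @param noiseSd additive Gaussian noise SD in density units (applied
#'   per replicate).
#' @param nReplicates replicates per amount.
#' @param seed RNG seed.
#' @return list: \code{table} (data.frame \code{amount_ng},
#'   \code{replicate}, \code{density}), \code{truth} (slope,
#'   intercept).
#' @export
genGelSeries <- function(slope, intercept = 0,
    amounts = 1000 / 2^(0:9), noiseSd = 0, nReplicates = 3L, seed) {
  if (missing(seed)) stop("genGelSeries requires an explicit seed",
    call. = FALSE)
  setSeed(seed)
  df <- expand.grid(replicate = seq_len(nReplicates), amount_ng = amounts)
  df <- df[, c("amount_ng", "replicate")]
  df$density <- slope * df$amount_ng + intercept +
    rnorm(nrow(df), 0, noiseSd)
  list(table = df[order(-df$amount_ng, df$replicate), ],
    truth = list(slope = slope, intercept = intercept))
}
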