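#' @importFrom EBImage distmap watershed
NULL

#' Construct a TwoChannelImage
#'
#' @param cfp reporter-channel matrix.
#' @param auto autofluorescence-channel matrix (same shape).
#' @param bitDepth nominal pixel depth in bits.
#' @return a \code{\link{TwoChannelImage}}.
#' @export
twoChannelImage <- function(cfp, auto, bitDepth = 16) {
  methods::new("TwoChannelImage", cfp = as.matrix(cfp),
    auto = as.matrix(auto), bitDepth = bitDepth)
}

#' Read a two-channel TIFF pair into a TwoChannelImage
#'
#' Accepts either two single-channel grayscale TIFFs or one multi-page
#' TIFF with the channel pages given by index.  8- and 16-bit files are
#' read as stored integer intensities.
#'
#' @param cfpPath,autoPath single-channel TIFF files; or
#' @param path a multi-page TIFF with both channels.
#' @param cfpPage,autoPage page indices within \code{path}.
#' @return a \code{\link{TwoChannelImage}}.
#' @export
readTwoChannelTiff <- function(cfpPath = NULL, autoPath = NULL,
    path = NULL, cfpPage = 1L, autoPage = 2L) {
  asIntensity <- function(x) {
    bps <- attr(x, "bits.per.sample")
    if (is.null(bps)) bps <- 16L
    round(x * (2^bps - 1))
  }
  if (!is.null(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(pages) < max(cfpPage, autoPage))
      stop("TIFF has fewer pages than requested", call. = FALSE)
    cfp <- asIntensity(pages[[cfpPage]])
    auto <- asIntensity(pages[[autoPage]])
    bits <- attr(pages[[cfpPage]], "bits.per.sample")
  } else {
    stopifnot(!is.null(cfpPath), !is.null(autoPath))
    c1 <- tiff::readTIFF(cfpPath, info = TRUE)
    c2 <- tiff::readTIFF(autoPath, info = TRUE)
    cfp <- asIntensity(c1); auto <- asIntensity(c2)
    bits <- attr(c1, "bits.per.sample")
  }
  if (is.null(bits)) bits <- 16L
  twoChannelImage(cfp, auto, bitDepth = bits)
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels integer label matrix (0 = background).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLabelTiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

ballElement <- function(radius) {
  r <- ceiling(radius)
  dx <- matrix(-r:r, 2L * r + 1L, 2L * r + 1L)
  dy <- t(dx)
  d2 <- dx^2 + dy^2
  keep <- d2 <= radius^2
  list(dx = dx[keep], dy = dy[keep],
    h = sqrt(pmax(radius^2 - d2[keep], 0)))
}

# Non-flat grayscale erosion/dilation with a ball structuring element,
# vectorized as shift-and-min / shift-and-max over the ball's offsets.
# Borders use only the offsets that fall inside the image.
ballMorph <- function(img, elem, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  for (k in seq_along(elem$dx)) {
    dx <- elem$dx[k]; dy <- elem$dy[k]; h <- elem$h[k]
    sr <- max(1L, 1L - dx):min(nr, nr - dx)   # destination rows
    sc <- max(1L, 1L - dy):min(nc, nc - dy)
    src <- img[sr + dx, sc + dy, drop = FALSE]
    if (op == "erode")
      out[sr, sc] <- pmin(out[sr, sc], src - h)
    else
      out[sr, sc] <- pmax(out[sr, sc], src + h)
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a grayscale image as the grayscale
#' opening by a ball structuring element of the given radius (the
#' surface traced by a ball of radius \eqn{r} rolling under the
#' intensity landscape) and returns \code{image - background}, clipped
#' at zero.  A constant image has background equal to itself, so the
#' result is all zeros; features narrower than the ball are preserved.
#'
#' @param image numeric intensity matrix.
#' @param radius ball radius in pixels (default 5).
#' @return background-subtracted matrix, same shape.
#' @export
rollingBallSubtract <- function(image, radius = 5) {
  image <- as.matrix(image)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (2 * radius > min(dim(image)))
    stop("radius exceeds half the image size", call. = FALSE)
  elem <- ballElement(radius)
  bg <- ballMorph(ballMorph(image, elem, "erode"), elem, "dilate")
  pmax(image - bg, 0)
}

# IsoData / iterative-intermeans threshold: t <- mean of the two class
# means, iterated to a fixed point.
isodataThreshold <- function(v) {
  t0 <- mean(range(v))
  for (i in 1:100) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-7 * max(1, abs(t0))) { t0 <- t1; break }
    t0 <- t1
  }
  t0
}

# Otsu: threshold maximizing between-class variance over candidate
# cutpoints (exhaustive over 256 histogram bins).
otsuThreshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(v, brk, all.inside = TRUE), nbins = 256L)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-257]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[256L]
  bcv <- (muT * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Binary mask of plastid candidates from the autofluorescence channel
#'
#' Thresholds an (ideally background-subtracted) autofluorescence image
#' into a foreground mask.  The default method is IsoData-style
#' iterative intermeans; \code{"otsu"} (between-class variance
#' maximization) is the alternative.  A constant image yields an empty
#' mask with a warning rather than an error.
#'
#' @param image numeric intensity matrix.
#' @param method \code{"isodata"} or \code{"otsu"}.
#' @return logical matrix (TRUE = foreground).
#' @export
makeMask <- function(image, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  image <- as.matrix(image)
  v <- as.numeric(image)
  if (diff(range(v)) == 0) {
    warning("constant image: returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- switch(method, isodata = isodataThreshold(v), otsu = otsuThreshold(v))
  image > thr
}

#' Split touching particles by distance-transform watershed
#'
#' Labels connected foreground of a binary mask, splitting touching
#' particles along ridges of the Euclidean distance transform
#' (EBImage's watershed on the distance map, 8-connected in spirit of
#' the classical binary watershed).  Labels are relabelled consecutive
#' from 1 in raster order; an empty mask yields zero labels.
#'
#' @param mask logical matrix.
#' @param tolerance minimum object-depth separation between two
#'   distance-map maxima for them to seed distinct particles.
#' @param ext neighborhood radius (px) used for the local-maxima
#'   search (minimum seed separation is about \code{2 * ext}).
#' @return integer label matrix, 0 = background.
#' @export
watershedSplit <- function(mask, tolerance = 1, ext = 1) {
  mask <- as.matrix(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask))
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  relab <- setNames(seq_along(ids), ids)
  out <- matrix(0L, nrow(mask), ncol(mask))
  nz <- lab > 0L
  out[nz] <- relab[as.character(lab[nz])]
  out
}

#' Per-particle channel summaries and normalized ratios for one section
#'
#' Given a two-channel image and a particle label matrix, computes for
#' every particle its area and mean intensity in each channel, and the
#' normalized fluorescence ratio mean_cfp / mean_auto (the
#' autofluorescence denominator corrects for tissue depth).  Particles
#' with zero mean autofluorescence are excluded and counted.
#'
#' @param image a \code{\link{TwoChannelImage}}.
#' @param labels integer label matrix (e.g. from
#'   \code{\link{watershedSplit}}).
#' @param minArea drop particles smaller than this many pixels.
#' @return a \code{\link{ParticleTable}}.
#' @export
particleTable <- function(image, labels, minArea = 5L) {
  stopifnot(methods::is(image, "TwoChannelImage"))
  labels <- as.matrix(labels)
  stopifnot(identical(dim(labels), dim(image@cfp)))
  keep <- labels > 0L
  nExcluded <- 0L
  if (!any(keep)) {
    df <- data.frame(label = integer(0), area_px = integer(0),
      mean_cfp = numeric(0), mean_auto = numeric(0), ratio = numeric(0))
    return(methods::new("ParticleTable", particles = df,
      meanRatio = NA_real_, sdRatio = NA_real_, nParticles = 0L,
      nExcluded = 0L))
  }
  lab <- labels[keep]
  area <- tabulate(lab)
  sumC <- rowsum(as.numeric(image@cfp[keep]), lab)
  sumA <- rowsum(as.numeric(image@auto[keep]), lab)
  ids <- as.integer(rownames(sumC))
  df <- data.frame(label = ids, area_px = area[ids],
    mean_cfp = sumC[, 1] / area[ids], mean_auto = sumA[, 1] / area[ids])
  df <- df[df$area_px >= minArea, , drop = FALSE]
  zero <- df$mean_auto == 0
  if (any(zero)) {
    nExcluded <- sum(zero)
    message(nExcluded, " particle(s) excluded: zero mean autofluorescence")
    df <- df[!zero, , drop = FALSE]
  }
  df$ratio <- df$mean_cfp / df$mean_auto
  rownames(df) <- NULL
  methods::new("ParticleTable", particles = df,
    meanRatio = if (nrow(df)) mean(df$ratio) else NA_real_,
    sdRatio = if (nrow(df) > 1L) sd(df$ratio) else NA_real_,
    nParticles = nrow(df), nExcluded = nExcluded)
}

#' Normalized chloroplast fluorescence over thallus sections
#'
#' Runs the full quantification pipeline on one or more two-channel
#' sections: rolling-ball background subtraction of the
#' autofluorescence channel, binary masking, watershed particle
#' splitting, and per-particle CFP/autofluorescence ratios.  Section
#' means are then aggregated as mean +/- SD \emph{across sections}
#' (matching error bars taken between thallus sections; the
#' per-particle SD within each section is reported separately).  With a
#' single section the cross-section SD is \code{NA}.
#'
#' @param sections a \code{\link{TwoChannelImage}} or list of them.
#' @param ballRadius rolling-ball radius for background subtraction.
#' @param method threshold method for \code{\link{makeMask}}.
#' @param measure \code{"raw"} (default) measures particle intensities
#'   on the original channels; \code{"subtracted"} measures on
#'   rolling-ball-subtracted channels (use when both channels carry a
#'   constant offset).
#' @param minArea minimum particle area in px.
#' @param tolerance,ext watershed parameters, see
#'   \code{\link{watershedSplit}}.
#' @return list: \code{sections} (list of \code{ParticleTable}),
#'   \code{sectionMeans}, \code{meanRatio}, \code{sdRatio},
#'   \code{nSections}.
#' @export
normalizedFluorescence <- function(sections, ballRadius = 5,
    method = "isodata", measure = c("raw", "subtracted"), minArea = 5L,
    tolerance = 1, ext = 1) {
  measure <- match.arg(measure)
  if (methods::is(sections, "TwoChannelImage")) sections <- list(sections)
  if (!length(sections)) stop("need at least one section", call. = FALSE)
  tables <- lapply(sections, function(img) {
    stopifnot(methods::is(img, "TwoChannelImage"))
    sub <- rollingBallSubtract(img@auto, ballRadius)
    mask <- makeMask(sub, method)
    labels <- watershedSplit(mask, tolerance = tolerance, ext = ext)
    meas <- if (measure == "raw") img else
      twoChannelImage(rollingBallSubtract(img@cfp, ballRadius), sub,
        img@bitDepth)
    particleTable(meas, labels, minArea = minArea)
  })
  sm <- vapply(tables, function(t) t@meanRatio, numeric(1))
  list(sections = tables, sectionMeans = sm,
    meanRatio = mean(sm, na.rm = TRUE),
    sdRatio = if (length(sm) > 1L) sd(sm) else NA_real_,
    nSections = length(sm))
}

#' Fold change of normalized fluorescence over a reference line
#'
#' @param sample,reference results of
#'   \code{\link{normalizedFluorescence}} (or numbers: mean ratios).
#' @return sample mean ratio divided by reference mean ratio.
#' @export
foldChange <- function(sample, reference) {
  val <- function(x) if (is.numeric(x)) x else x$meanRatio
  val(sample) / val(reference)
}

#' Write a ParticleTable as CSV
#'
#' @param pt a \code{\link{ParticleTable}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeParticleCsv <- function(pt, path) {
  write.csv(pt@particles, path, row.names = FALSE)
  invisible(path)
}
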