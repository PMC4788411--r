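#' Fit a densitometric standard curve
#'
#' Ordinary least squares of mean band density on loaded amount over a
#' dilution series; per-point replicate standard deviations are
#' retained for downstream uncertainty propagation.  The regression is
#' unweighted on replicate means by default (\code{weighted = TRUE}
#' weights each mean by its inverse replicate variance), and the
#' intercept is free unless \code{forceOrigin}.
#'
#' @param amounts ng loaded per standard point (>= 2 distinct values).
#' @param densities replicate densities: a list of numeric vectors
#'   (one per amount), a matrix with one row per amount, or a numeric
#'   vector of single measurements.
#' @param forceOrigin fix the intercept at 0.
#' @param weighted inverse-variance weights from replicate SDs.
#' @return a \code{\link{StandardCurve}}.
#' @examples
#' sc <- fitStandardCurve(c(10, 50, 100), 3 * c(10, 50, 100) + 7)
#' c(slope(sc), intercept(sc))
#' @export
fitStandardCurve <- function(amounts, densities, forceOrigin = FALSE,
    weighted = FALSE) {
  amounts <- as.numeric(amounts)
  if (length(unique(amounts)) < 2L)
    stop("need at least 2 distinct amounts", call. = FALSE)
  if (var(amounts) == 0) stop("zero variance in amounts", call. = FALSE)
  if (is.matrix(densities)) densities <- asplit(densities, 1)
  if (is.numeric(densities)) densities <- as.list(densities)
  if (length(densities) != length(amounts))
    stop("densities must provide one (set of) replicate(s) per amount",
      call. = FALSE)
  mu <- vapply(densities, function(v) mean(as.numeric(v)), numeric(1))
  repSd <- vapply(densities, function(v)
    if (length(v) > 1L) sd(as.numeric(v)) else NA_real_, numeric(1))
  w <- NULL
  if (weighted) {
    if (anyNA(repSd) || any(repSd == 0))
      stop("weighted fit needs >= 2 replicates with spread at every point",
        call. = FALSE)
    w <- 1 / repSd^2
  }
  df <- data.frame(amount = amounts, density = mu)
  fit <- if (forceOrigin)
    lm(density ~ 0 + amount, data = df, weights = w)
  else
    lm(density ~ amount, data = df, weights = w)
  pred <- fitted(fit)
  ssRes <- sum((mu - pred)^2)
  ssTot <- sum((mu - mean(mu))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  cf <- coef(fit)
  methods::new("StandardCurve",
    slope = unname(cf[["amount"]]),
    intercept = if (forceOrigin) 0 else unname(cf[["(Intercept)"]]),
    rSquared = max(0, min(1, r2)),
    nPoints = length(amounts),
    replicateSd = repSd,
    forceOrigin = forceOrigin,
    fit = fit)
}

#' @describeIn fitStandardCurve fitted slope (density units per ng)
#' @param curve a \code{StandardCurve}.
#' @export
slope <- function(curve) curve@slope

#' @describeIn fitStandardCurve fitted intercept (density units)
#' @export
intercept <- function(curve) curve@intercept

#' @describeIn fitStandardCurve coefficient of determination
#' @export
rSquared <- function(curve) curve@rSquared

#' Estimate protein amount from a band density (inverse prediction)
#'
#' Inverts the standard curve: \code{ng = (density - intercept) /
#' slope}.  The standard error combines the slope/intercept covariance
#' of the fit with the measurement uncertainty of the band itself
#' (replicate SD of the unknown, scaled by its replicate count) by the
#' delta method; the confidence interval uses the t distribution on the
#' fit's residual degrees of freedom.  A negative estimate is reported
#' as below detection with the raw value retained.
#'
#' @param bandDensity measured density of the unknown band (mean over
#'   replicates).
#' @param curve a fitted \code{\link{StandardCurve}}.
#' @param bandSd replicate SD of the unknown band (0 = none).
#' @param nBand number of replicates behind \code{bandDensity}.
#' @param level confidence level for the interval.
#' @return list: \code{ng}, \code{se}, \code{ci} (length 2),
#'   \code{belowDetection}, \code{raw}.
#' @export
estimateAmount <- function(bandDensity, curve, bandSd = 0, nBand = 1L,
    level = 0.95) {
  stopifnot(methods::is(curve, "StandardCurve"))
  if (abs(curve@slope) <= 1e-12 * (1 + abs(curve@intercept)))
    stop("curve slope is zero: densities carry no amount information",
      call. = FALSE)
  b1 <- curve@slope; b0 <- curve@intercept
  x0 <- (bandDensity - b0) / b1
  V <- suppressWarnings(vcov(curve@fit))  # quiet on perfect fits
  varD <- bandSd^2 / max(1L, nBand)
  if (curve@forceOrigin) {
    v11 <- V["amount", "amount"]
    varX <- varD / b1^2 + x0^2 * v11 / b1^2
  } else {
    v00 <- V["(Intercept)", "(Intercept)"]
    v11 <- V["amount", "amount"]
    v01 <- V["(Intercept)", "amount"]
    # g = (d - b0)/b1; dg/db0 = -1/b1; dg/db1 = -x0/b1
    varX <- varD / b1^2 + (v00 + 2 * x0 * v01 + x0^2 * v11) / b1^2
  }
  se <- sqrt(max(varX, 0))
  dfree <- stats::df.residual(curve@fit)
  tq <- if (dfree > 0) qt(1 - (1 - level) / 2, dfree) else Inf
  list(ng = max(x0, 0), se = se, ci = c(x0 - tq * se, x0 + tq * se),
    belowDetection = x0 < 0, raw = x0)
}

#' Convert an on-gel amount to ng per mg fresh weight
#'
#' Scales an estimated on-gel amount back through the extraction:
#' \deqn{ng/mg = ng \cdot (V_{buffer}/V_{loaded}) \cdot dilution /
#'   m_{fresh}}
#' so a lane loaded with a fraction of a diluted extract reports the
#' concentration in the original tissue.
#'
#' @param amountNg amount estimated on the gel (ng).
#' @param freshWeightMg tissue fresh weight extracted (mg).
#' @param bufferVolumeUl extraction buffer volume (microlitre).
#' @param loadedVolumeUl volume loaded on the gel (microlitre).
#' @param dilutionFactor fold dilution applied before loading.
#' @return ng protein per mg fresh weight.
#' @examples
#' concentrationFw(250, freshWeightMg = 50, bufferVolumeUl = 200,
#'   loadedVolumeUl = 10, dilutionFactor = 2)  # 200 ng/mg
#' @export
concentrationFw <- function(amountNg, freshWeightMg, bufferVolumeUl,
    loadedVolumeUl, dilutionFactor = 1) {
  ctx <- c(freshWeightMg, bufferVolumeUl, loadedVolumeUl, dilutionFactor)
  if (any(!is.finite(ctx)) || any(ctx <= 0))
    stop("extraction context values must all be positive", call. = FALSE)
  amountNg * (bufferVolumeUl / loadedVolumeUl) * dilutionFactor /
    freshWeightMg
}

#' Read / write gel density tables
#'
#' CSV with columns \code{amount_ng} (NA or empty for unknown lanes),
#' \code{replicate}, \code{density}.
#'
#' @param path CSV file.
#' @return \code{readGelCsv}: data.frame.
#' @export
readGelCsv <- function(path) {
  df <- read.csv(path)
  need <- c("amount_ng", "density")
  if (!all(need %in% names(df)))
    stop("gel CSV must have columns ", paste(need, collapse = ", "),
      call. = FALSE)
  df
}

#' @rdname readGelCsv
#' @param df data.frame as produced by \code{\link{genGelSeries}}.
#' @export
writeGelCsv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit a standard curve from a long-format gel table
#'
#' @param df data.frame with \code{amount_ng}, \code{density} (and
#'   optionally \code{replicate}); rows with missing \code{amount_ng}
#'   are treated as unknown lanes and ignored by the fit.
#' @param ... passed to \code{\link{fitStandardCurve}}.
#' @return a \code{\link{StandardCurve}}.
#' @export
fitGelTable <- function(df, ...) {
  std <- df[!is.na(df$amount_ng), , drop = FALSE]
  amounts <- sort(unique(std$amount_ng), decreasing = TRUE)
  reps <- lapply(amounts, function(a) std$density[std$amount_ng == a])
  fitStandardCurve(amounts, reps, ...)
}
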