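test_that("rolling-ball subtraction zeroes constant images and validates radius", {
  expect_true(all(rollingBallSubtract(matrix(13.5, 30, 40)) == 0))
  expect_error(rollingBallSubtract(matrix(0, 20, 20), radius = 0.5), "radius")
  expect_error(rollingBallSubtract(matrix(0, 8, 8), radius = 5),
    "exceeds half")
})

test_that("ball opening matches the brute-force min-then-max filter", {
  set.seed(31)
  for (i in 1:4) {
    img <- matrix(runif(24 * 24, 0, 100), 24, 24)
    r <- sample(c(2, 3), 1)
    expected <- pmax(img - bruteBallOpening(img, r), 0)
    expect_equal(rollingBallSubtract(img, r), expected, tolerance = 1e-10)
  }
})

test_that("a narrow bright disc on flat background survives subtraction", {
  bg <- 40
  img <- matrix(bg, 60, 60) + 90 * discMask(60, 30, 30, 3)
  out <- rollingBallSubtract(img, radius = 5)
  # background fully removed away from the disc
  expect_equal(out[1:10, 1:10], matrix(0, 10, 10))
  # disc interior preserved close to its true height
  expect_gt(out[30, 30], 80)
})

test_that("residual on a linear ramp is bounded by the ball chord height", {
  # ramp slope s over ball width 2r: the ball of radius r rolling under a
  # plane leaves at most r*(1 - sqrt(1 - s^2/(1+s^2))) ~ chord sag; use
  # the loose closed-form bound s*r for the residual
  s <- 0.5; r <- 4
  img <- matrix(rep(s * (1:50), each = 50), 50, 50)
  out <- rollingBallSubtract(img, r)
  bound <- r * (sqrt(1 + s^2) - 1) + 1e-9
  inner <- out[(r + 1):(50 - r), (r + 1):(50 - r)]
  expect_lte(max(inner), bound)
})

test_that("thresholding separates a balanced two-Gaussian histogram between the modes", {
  set.seed(8)
  v <- c(rnorm(1250, 20, 3), rnorm(1250, 80, 5))
  img <- matrix(sample(v), 50, 50)
  for (m in c("isodata", "otsu")) {
    mask <- makeMask(img, method = m)
    thr <- min(img[mask])
    expect_gt(thr, 35)
    expect_lt(thr, 65)
  }
  # otsu agrees with the exhaustive between-class-variance search, also
  # on a strongly imbalanced mixture
  for (w in c(1250, 400)) {
    set.seed(w)
    vv <- c(rnorm(2500 - w, 20, 3), rnorm(w, 80, 5))
    thrPkg <- plastidReporter:::otsuThreshold(vv)
    thrBrute <- bruteMaxVarThreshold(vv)
    expect_lt(abs(thrPkg - thrBrute), diff(range(vv)) / 128)
  }
})

test_that("constant and empty images give an empty mask with a warning", {
  expect_warning(m <- makeMask(matrix(0, 10, 10)), "constant")
  expect_false(any(m))
  expect_warning(m2 <- makeMask(matrix(5, 10, 10)), "constant")
  expect_false(any(m2))
})

test_that("masking ground-truth blobs reaches Jaccard >= 0.9", {
  # sharp-edged blobs on a flat background: the half-maximum footprint
  # is well defined and the mask must recover it closely
  for (s in c(17, 3, 99)) {
    sc <- genPlastidScene(nParticles = 8, radiusRange = c(5, 8),
      edgeSd = 0.8, noiseSd = 5, imageSize = 200, seed = s)
    mask <- makeMask(sc$image@auto)
    truth <- sc$truthLabels > 0
    jac <- sum(mask & truth) / sum(mask | truth)
    expect_gte(jac, 0.9)
  }
})

test_that("watershed splits touching discs and labels consecutively", {
  m <- discMask(80, 30, 40, 12) | discMask(80, 48, 40, 12)  # centers 1.5 r
  lab <- watershedSplit(m)
  expect_equal(sort(unique(as.integer(lab))), 0:2)
  # a single convex disc is never split
  expect_equal(max(watershedSplit(discMask(60, 30, 30, 10))), 1L)
  # empty mask: zero labels
  expect_equal(max(watershedSplit(matrix(FALSE, 20, 20))), 0L)
  # label count never below connected-component count
  cc <- max(EBImage::bwlabel(EBImage::Image(m * 1)))
  expect_gte(max(lab), cc)
})

test_that("per-particle ratios follow the two-channel contract", {
  sc <- genPlastidScene(nParticles = 8, cfpAutoRatio = 0.6, noiseSd = 0,
    seed = 2)
  pt <- particleTable(sc$image, sc$truthLabels)
  expect_s4_class(pt, "ParticleTable")
  expect_equal(pt@particles$ratio,
    pt@particles$mean_cfp / pt@particles$mean_auto)
  expect_equal(pt@particles$ratio, rep(0.6, pt@nParticles), tolerance = 1e-12)
  # scalar invariance: scaling both channels leaves ratios unchanged
  img2 <- twoChannelImage(3.7 * sc$image@cfp, 3.7 * sc$image@auto)
  pt2 <- particleTable(img2, sc$truthLabels)
  expect_equal(pt2@particles$ratio, pt@particles$ratio, tolerance = 1e-12)
  # linearity: scaling only CFP scales ratios
  img3 <- twoChannelImage(2 * sc$image@cfp, sc$image@auto)
  pt3 <- particleTable(img3, sc$truthLabels)
  expect_equal(pt3@particles$ratio, 2 * pt@particles$ratio, tolerance = 1e-12)
})

test_that("particles with zero autofluorescence are excluded and counted", {
  cfp <- matrix(0, 20, 20); auto <- matrix(0, 20, 20)
  lab <- matrix(0L, 20, 20)
  lab[3:6, 3:6] <- 1L; cfp[3:6, 3:6] <- 5; auto[3:6, 3:6] <- 10
  lab[12:15, 12:15] <- 2L; cfp[12:15, 12:15] <- 5  # auto stays 0
  expect_message(
    pt <- particleTable(twoChannelImage(cfp, auto), lab),
    "zero mean autofluorescence")
  expect_equal(pt@nParticles, 1L)
  expect_equal(pt@nExcluded, 1L)
  expect_equal(pt@particles$ratio, 0.5)
})

test_that("identical channels give unit ratios and zero spread across sections", {
  sc <- genPlastidScene(nParticles = 6, cfpAutoRatio = 1, noiseSd = 0,
    seed = 13)
  res <- normalizedFluorescence(list(sc$image, sc$image, sc$image))
  expect_equal(res$meanRatio, 1, tolerance = 1e-12)
  expect_equal(res$sdRatio, 0, tolerance = 1e-12)
  expect_equal(res$nSections, 3L)
  # one section: mean computed, cross-section SD not available
  one <- normalizedFluorescence(sc$image)
  expect_equal(one$meanRatio, 1, tolerance = 1e-12)
  expect_true(is.na(one$sdRatio))
})

test_that("the pipeline recovers configured ratios within 5% at SNR 10", {
  errs <- vapply(1:6, function(seed) {
    sc <- genPlastidScene(nParticles = 10, cfpAutoRatio = 0.8,
      amplitude = 100, noiseSd = 10, seed = seed)
    res <- normalizedFluorescence(sc$image)
    abs(res$meanRatio - 0.8) / 0.8
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("TIFF I/O round-trips both channels and label images", {
  sc <- genPlastidScene(nParticles = 5, noiseSd = 0, seed = 23)
  mx <- max(sc$image@auto)
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(sc$image@cfp / mx, f1, bits.per.sample = 16L)
  tiff::writeTIFF(sc$image@auto / mx, f2, bits.per.sample = 16L)
  img <- readTwoChannelTiff(f1, f2)
  expect_s4_class(img, "TwoChannelImage")
  expect_equal(dim(img@cfp), dim(sc$image@cfp))
  # ratio preserved to 16-bit quantization
  pt <- particleTable(img, sc$truthLabels)
  expect_equal(pt@particles$ratio, rep(1, pt@nParticles), tolerance = 1e-3)
  f3 <- tempfile(fileext = ".tif")
  writeLabelTiff(sc$truthLabels, f3)
  back <- round(tiff::readTIFF(f3) * 65535)
  expect_equal(back, sc$truthLabels, ignore_attr = TRUE)
})
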