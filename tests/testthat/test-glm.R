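test_that("motion confound expansion follows the {p, dp, p^2, dp^2} scheme", {
  m <- simulateMotion(60, seed = 2)
  ext <- extendMotionRegressors(m)
  expect_identical(dim(ext), c(60L, 24L))
  expect_identical(anyDuplicated(colnames(ext)), 0L)
  # zero input stays zero
  expect_true(all(extendMotionRegressors(matrix(0, 10, 6)) == 0))
  # constant input: derivatives vanish, squares constant
  const <- extendMotionRegressors(matrix(2, 10, 6))
  expect_true(all(const[, 7:12] == 0))
  expect_true(all(const[, 13:18] == 4))
  # derivative columns are backward differences with leading zero
  expect_equal(ext[, 7], c(0, diff(m[, 1])), ignore_attr = TRUE)
  expect_error(extendMotionRegressors(matrix(0, 10, 5)), "6 columns")
})

test_that("DCT drift basis has the cutoff-determined order and filters as claimed", {
  b <- highpassBasis(155, 2, 100)
  expect_identical(ncol(b), 7L)  # intercept + floor(2 * 310 / 100)
  expect_identical(colnames(b)[1], "intercept")
  # constant series is fully captured
  resid <- boldretest:::residualizeDrift(rep(5, 155), b)
  expect_lt(max(abs(resid)), 1e-10)
  # a 20 s sinusoid (well above cutoff frequency) passes through
  t <- (0:154) * 2
  y <- sin(2 * pi * t / 20)
  resid <- boldretest:::residualizeDrift(y, b)
  expect_gt(sqrt(sum(resid^2)) / sqrt(sum(y^2)), 0.99)
  # a very slow fluctuation (period 620 s) is removed
  slow <- sin(2 * pi * t / 620)
  resid <- boldretest:::residualizeDrift(slow, b)
  expect_lt(sqrt(sum(resid^2)) / sqrt(sum(slow^2)), 0.1)
  expect_error(highpassBasis(155, 2, 3), "cutoff")
})

test_that("Gaussian smoothing preserves totals and realizes the requested FWHM", {
  x <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  expect_identical(smoothGaussian(x, fwhm = 0), x)
  # delta in the interior: mass conserved, FWHM close to 6 mm
  delta <- array(0, c(21, 21, 21))
  delta[11, 11, 11] <- 1
  sm <- smoothGaussian(delta, fwhm = 6, voxelSize = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  widthMm <- (diff(above)) * 3
  expect_gte(widthMm, 3); expect_lte(widthMm, 9)  # 6 mm to grid resolution
  # interpolated width is closer
  xs <- (seq_len(21) - 11) * 3
  fine <- stats::approx(xs, prof, xout = seq(-9, 9, by = 0.01))
  expect_equal(diff(range(fine$x[fine$y >= half])), 6, tolerance = 0.15)
})

test_that("design matrix has 4 + 4 + 24 + drift named columns", {
  acq <- acquisitionSpec()
  sch <- generateSchedule()
  X <- buildDesignMatrix(sch, simulateMotion(acq$nVolumes, seed = 4), acq)
  expect_identical(ncol(X), 32L + 7L)
  expect_identical(anyDuplicated(colnames(X)), 0L)
  expect_false(any(apply(X, 2, function(col) all(col == 0))))
  expect_identical(attr(X, "conditions"), trialConditions(active = TRUE))
  # derivative columns are finite differences of the condition columns
  expect_equal(X[, "auditory_deriv"], c(0, diff(X[, "auditory"])),
               ignore_attr = TRUE)
  # null-only schedules cannot be modelled
  nullOnly <- data.frame(onset = c(0, 3), duration = 3, condition = "null")
  expect_error(buildDesignMatrix(nullOnly, simulateMotion(acq$nVolumes), acq),
               "no active trials")
})

test_that("first-level OLS recovers noiseless amplitudes exactly", {
  acq <- acquisitionSpec(nVolumes = 155L, gridShape = c(8L, 8L, 6L))
  top <- tinyTopology(acq, radius = 3)
  vm <- varianceModel(sigmaB = 0, sigmaW = 0, sigmaN = 0, driftAmp = 0)
  amp <- c(auditory = 0.8, visual = 1.6, motor = 0.5, cognitive = 1.1)
  run <- simulateRun(generateSchedule(), top, amp, acq, vm)
  X <- buildDesignMatrix(generateSchedule(), simulateMotion(155, seed = 8), acq)
  fit <- fitFirstLevel(run, X)
  masks <- attr(top, "masks")
  for (cond in names(amp)) {
    inRegion <- effectMap(fit, cond)[masks[[cond]]]
    expect_equal(unname(inRegion), rep(unname(amp[cond]), length(inRegion)),
                 tolerance = 1e-8)
  }
  expect_equal(fit@dof, 155 - ncol(X))
})

test_that("OLS residuals are orthogonal to the design and fits are volume-order invariant", {
  acq <- acquisitionSpec(nVolumes = 155L, gridShape = c(4L, 4L, 3L))
  set.seed(21)
  arr <- array(rnorm(4 * 4 * 3 * 155), c(4, 4, 3, 155))
  X <- buildDesignMatrix(generateSchedule(), simulateMotion(155, seed = 3), acq)
  fit <- fitFirstLevel(arr, X)
  # orthogonality at one voxel
  y <- arr[1, 1, 1, ]
  beta <- qr.coef(qr(unclass(X)), y)
  expect_lt(max(abs(crossprod(unclass(X), y - unclass(X) %*% beta))), 1e-8)
  # permuting volumes of both data and design leaves betas unchanged
  p <- sample(155)
  Xp <- structure(unclass(X)[p, ], conditions = attr(X, "conditions"))
  fitP <- fitFirstLevel(arr[, , , p], Xp)
  expect_equal(fit@effects, fitP@effects, tolerance = 1e-9)
  # z maps are invariant to positive rescaling of the data
  fitS <- fitFirstLevel(arr * 3.7, X)
  expect_equal(fit@z, fitS@z, tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the offending columns named", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, 1] + X[, 2])
  attr(X, "conditions") <- "a"
  arr <- array(rnorm(2 * 2 * 1 * 20), c(2, 2, 1, 20))
  expect_error(fitFirstLevel(arr, X), "rank deficient")
})

test_that("fixed-effects combination is inverse-variance weighting", {
  mk <- function(eff, var) {
    m <- array(TRUE, c(2, 2, 1))
    new("FirstLevelFit",
        effects = list(auditory = array(eff, c(2, 2, 1))),
        variances = list(auditory = array(var, c(2, 2, 1))),
        z = list(auditory = array(0, c(2, 2, 1))),
        dof = 10, mask = m, affine = diag(4),
        subject = 1L, session = 1L)
  }
  fe <- fixedEffectsCombine(mk(2, 1), mk(4, 1))
  expect_equal(unique(as.vector(fe$effects$auditory)), 3)
  expect_equal(unique(as.vector(fe$variances$auditory)), 0.5)
  # one session with enormous variance contributes nothing
  fe2 <- fixedEffectsCombine(mk(2, 1), mk(100, 1e12))
  expect_equal(unique(as.vector(fe2$effects$auditory)), 2, tolerance = 1e-6)
  # combined variance never exceeds either input
  fe3 <- fixedEffectsCombine(mk(1, 0.5), mk(5, 3))
  expect_lte(unique(as.vector(fe3$variances$auditory)), 0.5)
})

test_that("group one-sample statistics behave under degeneracy and sign flips", {
  d <- c(6L, 6L, 4L)
  blob <- array(0, d); blob[2:4, 2:4, 2] <- 1
  same <- lapply(1:5, function(i) blob + 0)
  g <- groupOneSample(same, zThresh = 3.1, method = "fixed_extent",
                      kExtent = 0)
  expect_true(all(zMap(g)[blob == 1] == 38))  # zero-variance cap
  expect_true(all(sigMask(g)[blob == 1]))
  set.seed(5)
  maps <- lapply(1:8, function(i) array(rnorm(prod(d)), d))
  g1 <- groupOneSample(maps, method = "fixed_extent", kExtent = 1e9)
  g2 <- groupOneSample(lapply(maps, function(m) -m),
                       method = "fixed_extent", kExtent = 1e9)
  expect_equal(zMap(g1), -zMap(g2), tolerance = 1e-9)
  expect_error(groupOneSample(maps[1:2]), "3 subjects")
})

test_that("t-to-z conversion matches the CDF mapping and is monotone", {
  t <- c(-30, -5, -1, 0, 1, 5, 30)
  z <- boldretest:::tToZ(t, 12)
  expect_equal(z[4], 0)
  expect_true(all(diff(z) > 0))
  expect_equal(z[3], qnorm(pt(-1, 12)), tolerance = 1e-12)
  expect_equal(z, -rev(z), tolerance = 1e-12)  # antisymmetric
  expect_equal(boldretest:::tToZ(Inf, 5), 38)  # overflow cap
})
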