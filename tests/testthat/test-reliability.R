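test_that("icc31 agrees with the ANOVA oracle on the frozen example", {
  x <- cbind(c(1, 3, 5, 7, 9), c(2, 3, 6, 6, 10))
  est <- icc31(x)
  expect_equal(as.numeric(est), 0.959595959595960, tolerance = 1e-12)
  expect_equal(as.numeric(est), bruteIcc31(x), tolerance = 1e-10)
  ms <- attr(est, "meanSquares")
  expect_equal(ms$bms, 19.4)
  expect_equal(ms$jms, 0.4)
  expect_equal(ms$ems, 0.4)
})

test_that("icc31 matches the ANOVA oracle on random matrices, including k > 2", {
  set.seed(100)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n <- sample(4:20, 1)
    x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n)  # subject effects
    expect_equal(as.numeric(icc31(x)), bruteIcc31(x), tolerance = 1e-10)
  }
})

test_that("icc31 has the consistency-ICC invariances", {
  set.seed(7)
  x <- matrix(rnorm(30), 15, 2) + rnorm(15)
  base <- as.numeric(icc31(x))
  # identical sessions
  expect_equal(as.numeric(icc31(cbind(x[, 1], x[, 1]))), 1)
  # additive session offsets are ignored
  shifted <- cbind(x[, 1], x[, 2] + 5)
  expect_equal(as.numeric(icc31(shifted)), base, tolerance = 1e-12)
  # positive affine rescaling of all entries
  expect_equal(as.numeric(icc31(3 * x + 10)), base, tolerance = 1e-12)
  # degenerate input signals distinctly
  expect_error(icc31(matrix(1, 5, 2)), class = "iccZeroVariance")
  expect_error(icc31(matrix(rnorm(2), 1, 2)))
})

test_that("voxel-wise ICC map matches the scalar implementation and handles masks", {
  d <- c(5L, 4L, 3L)
  V <- prod(d)
  set.seed(33)
  x1 <- matrix(rnorm(12 * V), 12) + rnorm(12)
  x2 <- x1 * 0.7 + matrix(rnorm(12 * V, sd = 0.5), 12)
  m <- iccMap(list(x1, x2), d)
  byVoxel <- vapply(seq_len(V), function(v)
    as.numeric(icc31(cbind(x1[, v], x2[, v]))), numeric(1))
  expect_equal(as.vector(iccValues(m)), byVoxel, tolerance = 1e-10)
  expect_identical(nSubjects(m), 12L)
  # duplicated sessions: ICC 1 everywhere in mask
  mask <- array(c(TRUE, FALSE), d)
  m2 <- iccMap(list(x1, x1), d, mask = mask)
  expect_true(all(iccValues(m2)[mask] == 1))
  expect_true(all(is.na(iccValues(m2)[!mask])))
  # more than two sessions unsupported
  expect_error(iccMap(array(rnorm(12 * 3 * V), c(12, 3, V)), d), "two sessions")
})

test_that("independent sessions give a near-zero mean ICC map", {
  d <- c(10L, 10L, 5L)
  set.seed(44)
  x1 <- matrix(rnorm(200 * prod(d)), 200)
  x2 <- matrix(rnorm(200 * prod(d)), 200)
  m <- iccMap(list(x1, x2), d)
  expect_lt(abs(mean(iccValues(m))), 0.05)
})

test_that("voxel ICC recovers a known population value at large n", {
  acq <- tinyAcq()
  top <- tinyTopology(acq)
  co <- simulateCohort(200L, topology = top, acq = acq, seed = 77,
                       keepData = FALSE)
  # amplitude-level stack with negligible measurement noise
  masks <- attr(top, "masks")
  d <- acq$gridShape
  set.seed(78)
  mkSession <- function(j) {
    out <- matrix(0, 200, prod(d))
    for (cond in dimnames(co$amplitudes)[[3]])
      out[, as.vector(masks[[cond]])] <- co$amplitudes[, j, cond]
    out + matrix(rnorm(length(out), sd = 1e-4), nrow(out))
  }
  m <- iccMap(list(mkSession(1), mkSession(2)), d)
  active <- as.vector(Reduce(`|`, masks))
  expect_equal(mean(iccValues(m)[active]), 0.7, tolerance = 0.05 / 0.7)
})

test_that("Fisher-z standardization is the scaled atanh with clipping", {
  expect_equal(iccStandardize(0, 15), 0)
  expect_equal(iccStandardize(0.77, 15), 3.534519035574, tolerance = 1e-10)
  expect_true(is.finite(iccStandardize(1, 15)))
  g <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(iccStandardize(g, 10)) > 0))
  expect_error(iccStandardize(0.5, 3), "4 subjects")
})

test_that("thresholding retains original ICC values on surviving clusters only", {
  d <- c(10L, 10L, 6L)
  n <- 16
  set.seed(55)
  blob <- array(FALSE, d); blob[3:6, 3:6, 2:4] <- TRUE
  subj <- rnorm(n, sd = 2)
  x1 <- matrix(rnorm(n * prod(d), sd = 0.3), n)
  x2 <- matrix(rnorm(n * prod(d), sd = 0.3), n)
  x1[, blob] <- x1[, blob] + subj
  x2[, blob] <- x2[, blob] + subj
  m <- iccMap(list(x1, x2), d)
  m <- thresholdIccMap(m, list(x1, x2), nPerm = 300, seed = 6)
  expect_true(any(sigMask(m)[blob]))
  expect_false(any(sigMask(m)[!blob]))
  masked <- maskedIcc(m)
  expect_equal(masked[sigMask(m)], iccValues(m)[sigMask(m)])
  expect_true(all(is.na(masked[!sigMask(m)])))
  # all-below-threshold maps yield an empty mask
  flat <- iccMap(list(matrix(rnorm(n * prod(d)), n),
                      matrix(rnorm(n * prod(d)), n)), d)
  flat <- thresholdIccMap(flat, list(x1 * 0 + rnorm(n * prod(d)),
                                     x1 * 0 + rnorm(n * prod(d))),
                          nPerm = 200, seed = 8)
  expect_lt(sum(sigMask(flat)), 5)
})

test_that("median ICC summarises retained voxels and flags empty masks", {
  arr <- array(NA_real_, c(3, 3, 1))
  arr[1, 1, 1] <- 0.7
  expect_equal(medianIcc(arr), 0.7)
  arr[2, 1, 1] <- 0.1; arr[3, 1, 1] <- 0.9
  expect_equal(medianIcc(arr), 0.7)
  set.seed(3)
  u <- array(runif(8000, 0.5, 0.9), c(20, 20, 20))
  expect_equal(medianIcc(u), 0.7, tolerance = 0.02)
  expect_error(medianIcc(array(NA_real_, c(2, 2, 2))), class = "emptyMask")
})

test_that("activation-threshold sweep has nested masks and reproduces dissociation", {
  d <- c(10L, 10L, 4L)
  icc <- array(0.4, d)
  zconst <- array(5, d)
  sw <- activationMaskedMedians(icc, zconst)
  expect_equal(sw$z_threshold, c(2.3, 3.1, 3.7, 4.3))
  expect_true(all(sw$median_icc == 0.4))
  set.seed(10)
  z <- array(rnorm(prod(d), mean = 2, sd = 1.5), d)
  sw2 <- activationMaskedMedians(array(runif(prod(d)), d), z)
  expect_true(all(diff(sw2$n_voxels) <= 0))
  # dissociation: activation blob disjoint from the high-ICC blob
  icc2 <- array(0.1, d); icc2[1:3, 1:3, 1] <- 0.9
  z2 <- array(0, d); z2[7:9, 7:9, 3] <- 6
  sw3 <- activationMaskedMedians(icc2, z2)
  expect_true(all(sw3$median_icc == 0.1))
  highIccMedian <- stats::median(icc2[icc2 > 0.5])
  expect_true(all(sw3$median_icc < highIccMedian))
  # an empty mask is flagged, not dropped
  sw4 <- activationMaskedMedians(icc2, array(0, d))
  expect_identical(nrow(sw4), 4L)
  expect_true(all(sw4$empty))
})

test_that("overlap percentage is the share of ICC voxels inside the activation mask", {
  d <- c(4L, 4L, 2L)
  a <- array(FALSE, d); a[1:2, , 1] <- TRUE
  expect_equal(overlapPercentage(a, a), 100)
  b <- array(FALSE, d); b[3:4, , 2] <- TRUE
  expect_equal(overlapPercentage(a, b), 0)
  icc <- array(FALSE, d); icc[seq_len(10)] <- TRUE
  act <- array(FALSE, d); act[seq_len(4)] <- TRUE
  expect_equal(overlapPercentage(icc, act), 40)
  expect_error(overlapPercentage(array(FALSE, d), a), class = "emptyMask")
  # subset property
  expect_equal(overlapPercentage(act, icc), 100)
})

test_that("qualitative ICC bands partition [-1, 1] with the published boundaries", {
  expect_identical(classifyIcc(c(0.76, 0.75, 0.17)),
                   c("excellent", "good", "poor"))
  expect_identical(classifyIcc(c(0.6, 0.59, 0.4, 0.399)),
                   c("good", "fair", "fair", "poor"))
  g <- seq(-1, 1, by = 0.001)
  lab <- classifyIcc(g)
  expect_false(anyNA(lab))
  expect_identical(sort(unique(lab)), c("excellent", "fair", "good", "poor"))
  # monotone: band index never decreases in the ICC
  idx <- match(lab, c("poor", "fair", "good", "excellent"))
  expect_true(all(diff(idx) >= 0))
  expect_error(classifyIcc(1.2), "\\[-1, 1\\]")
})
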