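test_that("volume count covers the run: 155 at TR 2, and degenerate TRs", {
  sch <- generateSchedule()
  expect_identical(nVolumesFor(sch, 2), 155L)
  expect_identical(nVolumesFor(sch, 310), 1L)
  expect_identical(nVolumesFor(sch, 4), 78L)  # ceiling(310 / 4)
  expect_error(nVolumesFor(sch, 0))
})

test_that("double-gamma HRF has canonical shape", {
  h <- doubleGammaHrf(0.1)
  tm <- attr(h, "times")
  expect_equal(h[1], 0)                      # gamma density at origin, shape > 1
  peak <- tm[which.max(h)]
  expect_gte(peak, 5); expect_lte(peak, 6)
  expect_equal(max(h), 1)                    # peak-normalized
  expect_gt(sum(h), 0)
  expect_gte(max(tm), 32)
  # convolving with a unit impulse reproduces the kernel
  imp <- c(1, rep(0, 400))
  conv <- stats::convolve(imp, rev(h), type = "open")[seq_along(h)]
  expect_equal(conv, as.numeric(h), tolerance = 1e-12)
  expect_error(doubleGammaHrf(0))
})

test_that("condition regressors have the expected support and peak latency", {
  sch <- generateSchedule()
  r <- conditionRegressor(sch, "visual", 2)
  expect_length(r, 155L)
  # positive responses with at most the HRF's bounded undershoot
  expect_gt(max(r), 0)
  expect_gte(min(r), -abs(min(doubleGammaHrf(0.1))) * max(r) * 1.01)
  expect_error(conditionRegressor(sch, "null", 2), "baseline")
  # a condition with no trials gives a flat zero regressor
  tbl <- singleTrial("motor")
  expect_equal(conditionRegressor(tbl, "auditory", 2, nVolumes = 20),
               rep(0, 20))
  # single 3 s trial at t = 0: response peaks 6-8 s after onset
  r1 <- conditionRegressor(singleTrial(), "auditory", 2, nVolumes = 20)
  expect_true(which.max(r1) %in% c(4L, 5L))  # volumes at 6 s or 8 s
})

test_that("canonical-schedule regressors are mutually near-orthogonal", {
  sch <- generateSchedule()
  X <- sapply(trialConditions(active = TRUE), function(cond)
    conditionRegressor(sch, cond, 2))
  cors <- cor(X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.5)
})

test_that("motion traces are seeded random walks", {
  expect_equal(simulateMotion(50, stepSd = 0, seed = 3),
               matrix(0, 50, 6), ignore_attr = TRUE)
  expect_identical(simulateMotion(155, seed = 11), simulateMotion(155, seed = 11))
  tr <- simulateMotion(500, stepSd = 0.1, seed = 7)
  expect_identical(dim(tr), c(500L, 6L))
  stepSds <- apply(apply(tr, 2, diff), 2, sd)
  expect_true(all(stepSds > 0.08 & stepSds < 0.12))
})

test_that("true ICC is the between/total variance ratio", {
  expect_equal(trueIcc(1, 0), 1)
  expect_equal(trueIcc(1, 1), 0.5)
  expect_equal(trueIcc(0.6, 0.8), 0.36)
  expect_error(trueIcc(0, 0), "undefined")
})

test_that("zero variance components give identical deterministic runs", {
  acq <- acquisitionSpec(nVolumes = 155L, gridShape = c(10L, 10L, 8L))
  top <- tinyTopology(acq)
  co <- simulateCohort(4L, list(generateSchedule()), top, acq,
                       varianceModel(sigmaB = 0, sigmaW = 0, sigmaN = 0,
                                     driftAmp = 0),
                       seed = 5)
  arr1 <- boldData(co$runs[[1]][[1]])
  for (s in 1:4) for (j in 1:2)
    expect_equal(boldData(co$runs[[s]][[j]]), arr1)
  expect_true(all(abs(co$amplitudes - 1) < 1e-12))
})

test_that("cohorts are reproducible under a fixed seed and sessions share traits", {
  acq <- acquisitionSpec(nVolumes = 155L, gridShape = c(10L, 10L, 8L))
  top <- tinyTopology(acq)
  a <- simulateCohort(2L, topology = top, acq = acq, seed = 42)
  b <- simulateCohort(2L, topology = top, acq = acq, seed = 42)
  expect_equal(boldData(a$runs[[2]][[1]]), boldData(b$runs[[2]][[1]]))
  expect_equal(a$amplitudes, b$amplitudes)
  c2 <- simulateCohort(2L, topology = top, acq = acq, seed = 43)
  expect_false(isTRUE(all.equal(a$amplitudes, c2$amplitudes)))
})

test_that("amplitude variance components match the generating model", {
  acq <- tinyAcq()
  top <- tinyTopology(acq)
  vm <- varianceModel()
  co <- simulateCohort(200L, topology = top, acq = acq, vm = vm, seed = 9,
                       keepData = FALSE)
  amp <- co$amplitudes
  for (cond in dimnames(amp)[[3]]) {
    m <- amp[, , cond]
    # session difference isolates 2 * sigmaW^2
    expect_equal(stats::var(m[, 1] - m[, 2]), 2 * vm$sigmaW^2,
                 tolerance = 0.3)
    # session mean variance is sigmaB^2 + sigmaW^2 / 2
    expect_equal(stats::var(rowMeans(m)), vm$sigmaB^2 + vm$sigmaW^2 / 2,
                 tolerance = 0.3)
  }
})

test_that("amplitude-level ICC converges to the population value", {
  acq <- tinyAcq()
  top <- tinyTopology(acq)
  co <- simulateCohort(200L, topology = top, acq = acq, seed = 31,
                       keepData = FALSE)
  est <- as.numeric(icc31(co$amplitudes[, , "auditory"]))
  expect_equal(est, co$trueIcc, tolerance = 0.03 / co$trueIcc)
  expect_equal(co$trueIcc, 0.7)
  expect_equal(unique(co$trueIccMap[attr(top, "masks")$auditory]), 0.7)
})

test_that("simulated signal appears only inside the condition's region", {
  acq <- acquisitionSpec(nVolumes = 155L, gridShape = c(10L, 10L, 8L))
  top <- tinyTopology(acq)
  vm <- varianceModel(sigmaB = 0, sigmaW = 0, sigmaN = 0, driftAmp = 0)
  amp <- c(auditory = 2, visual = 0, motor = 0, cognitive = 0)
  run <- simulateRun(generateSchedule(), top, amp, acq, vm, seed = 1)
  arr <- boldData(run)
  aud <- attr(top, "masks")$auditory
  ts1 <- arr[which(aud, arr.ind = TRUE)[1, 1],
             which(aud, arr.ind = TRUE)[1, 2],
             which(aud, arr.ind = TRUE)[1, 3], ]
  reg <- conditionRegressor(generateSchedule(), "auditory", acq$tr,
                            acq$nVolumes)
  expect_equal(ts1, 100 + 2 * reg, tolerance = 1e-12)
  out <- !Reduce(`|`, attr(top, "masks"))
  vox <- which(out)[1]
  ijk <- arrayInd(vox, dim(out))
  expect_true(all(arr[ijk[1], ijk[2], ijk[3], ] == 100))
})
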