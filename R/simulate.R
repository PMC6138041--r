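#' Acquisition geometry for simulated runs
#'
#' Describes the simulated EPI acquisition: repetition time, volume
#' count, grid shape and voxel size.  The default mirrors the control
#' task's acquisition (TR 2 s, 155 volumes, 3 mm isotropic voxels) on a
#' small synthetic grid.  The attached affine maps 0-based voxel indices
#' to mm with the grid centred on the origin, mimicking MNI-style mm
#' coordinates so that ROI spheres defined in mm work unchanged.
#'
#' @param tr Repetition time in seconds.
#' @param nVolumes Number of volumes; default covers the canonical 310 s
#'   run.
#' @param gridShape Integer vector of 3 grid dimensions.
#' @param voxelSize Isotropic voxel size in mm.
#' @return A list with elements `tr`, `nVolumes`, `gridShape`,
#'   `voxelSize` and `affine`.
#' @examples
#' acquisitionSpec()$nVolumes   # 155
#' @export
acquisitionSpec <- function(tr = 2, nVolumes = nVolumesFor(310, tr),
                            gridShape = c(20L, 24L, 20L), voxelSize = 3) {
  stopifnot(tr > 0, voxelSize > 0, length(gridShape) == 3L,
            all(gridShape >= 1))
  gridShape <- as.integer(gridShape)
  affine <- diag(c(rep(voxelSize, 3), 1))
  affine[1:3, 4] <- -voxelSize * (gridShape - 1) / 2
  list(tr = tr, nVolumes = as.integer(nVolumes), gridShape = gridShape,
       voxelSize = voxelSize, affine = affine)
}

#' Variance components of the simulated cohort
#'
#' The amplitude of each subject's regional response is decomposed into a
#' stable trait component (between-subject SD `sigmaB`, identical across
#' sessions) and a session-specific deviation (between-session SD
#' `sigmaW`); scan noise of SD `sigmaN` with AR(1) autocorrelation
#' `ar1Rho` and slow polynomial drift of amplitude `driftAmp` are added
#' per voxel.  The population consistency ICC of the amplitudes is
#' `sigmaB^2 / (sigmaB^2 + sigmaW^2)` (see [trueIcc()]); the defaults set
#' it to 0.7.
#'
#' @param sigmaB Between-subject amplitude SD (signal units).
#' @param sigmaW Between-session amplitude SD.
#' @param sigmaN Per-volume scan-noise SD.
#' @param ar1Rho Temporal autocorrelation of the noise, in \[0, 1).
#' @param driftAmp Slow-drift amplitude (signal units).
#' @return A named list of variance components.
#' @examples
#' vm <- varianceModel()
#' trueIcc(vm$sigmaB, vm$sigmaW)   # 0.7
#' @export
varianceModel <- function(sigmaB = 0.5, sigmaW = 0.5 * sqrt(3 / 7),
                          sigmaN = 1, ar1Rho = 0.3, driftAmp = 1) {
  stopifnot(sigmaB >= 0, sigmaW >= 0, sigmaN >= 0, driftAmp >= 0,
            ar1Rho >= 0, ar1Rho < 1)
  list(sigmaB = sigmaB, sigmaW = sigmaW, sigmaN = sigmaN,
       ar1Rho = ar1Rho, driftAmp = driftAmp)
}

#' Population consistency ICC implied by the variance components
#'
#' The variance-ratio target that ICC(3,1) estimates:
#' `sigmaB^2 / (sigmaB^2 + sigmaW^2)`.
#'
#' @param sigmaB Between-subject amplitude SD.
#' @param sigmaW Between-session amplitude SD.
#' @return Ratio in \[0, 1\].
#' @examples
#' trueIcc(1, 1)     # 0.5
#' trueIcc(0.6, 0.8) # 0.36
#' @export
trueIcc <- function(sigmaB, sigmaW) {
  stopifnot(sigmaB >= 0, sigmaW >= 0)
  if (sigmaB == 0 && sigmaW == 0)
    stop("true ICC is undefined when both variance components are zero")
  sigmaB^2 / (sigmaB^2 + sigmaW^2)
}

#' Default regional activation topology
#'
#' Places one activation region per active condition on the synthetic
#' grid, emulating the expected activation sites of the control task:
#' bilateral auditory cortex, bilateral visual cortex, left motor cortex,
#' and for the cognitive condition the frontal eye fields (eye-movement
#' variant) or dorsolateral prefrontal cortex (working-memory variant).
#' Centres are in mm through the acquisition affine; coordinates are
#' synthetic placeholders on the small grid, not MNI152 anatomy.
#'
#' @param acq An [acquisitionSpec()].
#' @param variant Task variant; selects which cognitive region is active.
#' @param amplitude Mean response amplitude `mu` per region (signal
#'   units, arbitrary).
#' @return A data.frame with one row per sphere: `region`, `condition`,
#'   `x`, `y`, `z` (mm), `radius` (mm), `mu`, plus attribute `"masks"`, a
#'   named list of 3D logical masks per condition.
#' @export
defaultTopology <- function(acq = acquisitionSpec(),
                            variant = c("eye-movement", "working-memory"),
                            amplitude = 1) {
  variant <- match.arg(variant)
  cog <- if (variant == "eye-movement") "FEF" else "DLPFC"
  cogY <- if (variant == "eye-movement") 6 else 15
  cogZ <- if (variant == "eye-movement") 15 else 6
  spheres <- rbind(
    data.frame(region = "auditory", condition = "auditory",
               x = c(-21, 21), y = -9, z = 3, radius = 6),
    data.frame(region = "visual", condition = "visual",
               x = c(-9, 9), y = -27, z = 0, radius = 6),
    data.frame(region = "motor", condition = "motor",
               x = -18, y = -12, z = 15, radius = 6),
    data.frame(region = cog, condition = "cognitive",
               x = c(-15, 15), y = cogY, z = cogZ, radius = 5))
  spheres$mu <- amplitude
  activationTopology(spheres, acq, variant)
}

#' Build an activation topology from a sphere table
#'
#' Lower-level constructor behind [defaultTopology()]: takes a table of
#' spheres (`region`, `condition`, `x`, `y`, `z` mm, `radius` mm, `mu`)
#' and computes the per-condition voxel masks on the acquisition grid.
#' Spheres sharing a condition are unioned.
#'
#' @param spheres Sphere table as described above.
#' @param acq An [acquisitionSpec()].
#' @param variant Optional variant tag stored on the result.
#' @return The sphere table with attribute `"masks"` (named list of 3D
#'   logical masks per active condition).
#' @export
activationTopology <- function(spheres, acq, variant = NULL) {
  stopifnot(all(c("condition", "x", "y", "z", "radius", "mu") %in%
                  names(spheres)))
  masks <- lapply(trialConditions(active = TRUE), function(cond) {
    rows <- which(spheres$condition == cond)
    m <- array(FALSE, acq$gridShape)
    for (i in rows)
      m <- m | sphereMask(c(spheres$x[i], spheres$y[i], spheres$z[i]),
                          spheres$radius[i], acq$affine, acq$gridShape)
    m
  })
  names(masks) <- trialConditions(active = TRUE)
  structure(spheres, masks = masks, variant = variant)
}

#' Simulate a head-motion trace
#'
#' Gaussian random walk in the six rigid-body parameters (3 translations
#' in mm, 3 rotations in rad), in FSL `.par` column order.  Motion enters
#' the analysis only as confound regressors; images are not resampled.
#'
#' @param nVolumes Number of volumes.
#' @param stepSd Per-step SD; scalar or length 6 (defaults: 0.02 mm
#'   translations, 2e-4 rad rotations).
#' @param seed RNG seed.
#' @return `nVolumes` x 6 matrix with named columns.
#' @export
simulateMotion <- function(nVolumes, stepSd = c(rep(0.02, 3), rep(2e-4, 3)),
                           seed = 1) {
  stopifnot(nVolumes >= 1)
  if (length(stepSd) == 1L) stepSd <- rep(stepSd, 6L)
  stopifnot(length(stepSd) == 6L)
  withSeed(seed, {
    steps <- matrix(stats::rnorm(nVolumes * 6L), nVolumes, 6L)
    steps <- sweep(steps, 2L, stepSd, `*`)
    out <- apply(steps, 2L, cumsum)
    out <- matrix(out, nVolumes, 6L)
    colnames(out) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
    out
  })
}

# Draw per-subject regional amplitudes: trait a_{s,r} ~ N(mu_r, sigmaB^2)
# once per subject, session value a + e with e ~ N(0, sigmaW^2).
# Returns array [subject, session, region sphere-group by condition].
drawAmplitudes <- function(nSubjects, topology, vm, seed, nSessions = 2L) {
  conds <- trialConditions(active = TRUE)
  mu <- vapply(conds, function(cond)
    topology$mu[match(cond, topology$condition)], numeric(1))
  withSeed(seed, {
    trait <- matrix(stats::rnorm(nSubjects * length(conds), mean = rep(mu, each = nSubjects),
                                 sd = vm$sigmaB), nSubjects, length(conds))
    amp <- array(NA_real_, c(nSubjects, nSessions, length(conds)),
                 dimnames = list(NULL, NULL, conds))
    for (j in seq_len(nSessions))
      amp[, j, ] <- trait + matrix(stats::rnorm(nSubjects * length(conds),
                                                sd = vm$sigmaW),
                                   nSubjects, length(conds))
    amp
  })
}

#' Simulate one subject-session BOLD run
#'
#' Voxel time-series are built as baseline 100 plus the sum over active
#' conditions of the subject-session amplitude times the HRF-convolved
#' condition regressor (within that condition's topology mask), plus
#' per-voxel random polynomial drift and AR(1) Gaussian scan noise.
#'
#' @param schedule An [EventSchedule-class].
#' @param topology A [defaultTopology()] (or same-shaped) object.
#' @param amplitudes Named numeric vector of amplitudes per active
#'   condition for this subject-session.
#' @param acq An [acquisitionSpec()].
#' @param vm A [varianceModel()].
#' @param seed RNG seed for noise and drift.
#' @param subject,session Integer labels stored on the run.
#' @return A [BOLDRun-class].
#' @export
simulateRun <- function(schedule, topology, amplitudes, acq = acquisitionSpec(),
                        vm = varianceModel(), seed = 1,
                        subject = 1L, session = 1L) {
  masks <- attr(topology, "masks")
  nv <- acq$nVolumes
  if (nv < nVolumesFor(schedule, acq$tr))
    stop("acquisition has too few volumes for this schedule")
  V <- prod(acq$gridShape)
  ts <- matrix(100, nv, V)  # flat baseline; null trials live here
  for (cond in trialConditions(active = TRUE)) {
    m <- masks[[cond]]
    if (!any(m)) next
    reg <- conditionRegressor(schedule, cond, acq$tr, nv)
    ts[, as.vector(m)] <- ts[, as.vector(m)] + amplitudes[[cond]] * reg
  }
  withSeed(seed, {
    if (vm$driftAmp > 0) {
      tnorm <- seq(-1, 1, length.out = nv)
      basis <- cbind(tnorm, tnorm^2 - mean(tnorm^2))
      coef <- matrix(stats::rnorm(2L * V, sd = vm$driftAmp), 2L, V)
      ts <- ts + basis %*% coef
    }
    if (vm$sigmaN > 0) {
      innovSd <- vm$sigmaN * sqrt(1 - vm$ar1Rho^2)
      noise <- matrix(stats::rnorm(nv * V, sd = innovSd), nv, V)
      if (vm$ar1Rho > 0)
        noise <- matrix(stats::filter(noise, vm$ar1Rho, method = "recursive"),
                        nv, V)
      ts <- ts + noise
    }
  })
  new("BOLDRun", data = array(t(ts), c(acq$gridShape, nv)) , affine = acq$affine,
      tr = acq$tr, subject = as.integer(subject), session = as.integer(session))
}

#' Simulate a two-session cohort with known reliability
#'
#' Draws per-subject regional trait amplitudes (between-subject SD
#' `sigmaB`, stable across sessions) and session deviations
#' (between-session SD `sigmaW`), then builds one [BOLDRun-class] per
#' subject and session.  The population amplitude ICC is known by
#' construction ([trueIcc()]), so downstream estimates can be checked
#' against ground truth.
#'
#' @param nSubjects Number of subjects.
#' @param schedules List of one [EventSchedule-class] per session (a
#'   single schedule is recycled to both sessions).
#' @param topology A [defaultTopology()] object.
#' @param acq An [acquisitionSpec()].
#' @param vm A [varianceModel()].
#' @param seed Base RNG seed; all runs derive sub-seeds from it.
#' @param keepData If `FALSE`, omit the BOLD arrays (amplitudes and
#'   ground truth only), useful for large cohorts.
#' @return A list with `runs` (list of subjects, each a list of 2
#'   [BOLDRun-class]s; `NULL` if `keepData = FALSE`), `amplitudes`
#'   (subject x session x condition array), `trueIcc` (scalar population
#'   amplitude ICC), `trueIccMap` (3D array: population ICC inside active
#'   regions, `NA` elsewhere) and the generating specs.
#' @export
simulateCohort <- function(nSubjects = 15L,
                           schedules = list(generateSchedule()),
                           topology = defaultTopology(),
                           acq = acquisitionSpec(), vm = varianceModel(),
                           seed = 1, keepData = TRUE) {
  if (length(schedules) == 1L) schedules <- rep(schedules, 2L)
  stopifnot(length(schedules) == 2L)
  amp <- drawAmplitudes(nSubjects, topology, vm, subSeed(seed, 1))
  masks <- attr(topology, "masks")
  anyActive <- Reduce(`|`, masks)
  truth <- if (vm$sigmaB == 0 && vm$sigmaW == 0) NA_real_
           else trueIcc(vm$sigmaB, vm$sigmaW)
  truthMap <- array(NA_real_, acq$gridShape)
  truthMap[anyActive] <- truth
  runs <- NULL
  if (keepData) {
    runs <- lapply(seq_len(nSubjects), function(s)
      lapply(1:2, function(j)
        simulateRun(schedules[[j]], topology, amp[s, j, ], acq, vm,
                    seed = subSeed(seed, c(2, s, j)),
                    subject = s, session = j)))
  }
  list(runs = runs, amplitudes = amp, trueIcc = truth, trueIccMap = truthMap,
       schedules = schedules, topology = topology, acq = acq, vm = vm,
       seed = seed)
}
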