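#' Extended 24-parameter motion confound set
#'
#' Expands the six rigid-body motion parameters into the field-standard
#' 24-column confound set: the 6 parameters, their 6 backward-difference
#' temporal derivatives (first row 0), and the squares of both sets.
#'
#' @param motion `nVolumes` x 6 matrix (3 translations mm, 3 rotations
#'   rad).
#' @return `nVolumes` x 24 named matrix, columns ordered
#'   `{p, dp, p^2, dp^2}`.
#' @examples
#' ncol(extendMotionRegressors(simulateMotion(155)))   # 24
#' @export
extendMotionRegressors <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion trace must have exactly 6 columns, got ", ncol(motion))
  if (is.null(colnames(motion)))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2, d^2)
  colnames(out) <- c(colnames(motion),
                     paste0(colnames(motion), "_deriv"),
                     paste0(colnames(motion), "_sq"),
                     paste0(colnames(motion), "_deriv_sq"))
  out
}

#' Discrete-cosine high-pass drift basis
#'
#' High-pass temporal filtering is implemented as a discrete-cosine
#' drift basis included in the design matrix: an intercept plus the
#' `floor(2 * nVolumes * tr / cutoff)` lowest-order DCT components, i.e.
#' all cosines of period longer than the cutoff.  Residualizing a series
#' against the basis removes fluctuations slower than `cutoff` seconds.
#'
#' @param nVolumes Number of volumes.
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff in seconds (> 2 * tr); default 100 s.
#' @return `nVolumes` x (1 + K) named matrix (intercept first).
#' @examples
#' ncol(highpassBasis(155, 2))   # intercept + 6 DCT columns
#' @export
highpassBasis <- function(nVolumes, tr, cutoff = 100) {
  if (cutoff <= 2 * tr)
    stop("high-pass cutoff must exceed twice the TR")
  K <- floor(2 * nVolumes * tr / cutoff)
  i <- seq_len(nVolumes) - 1L
  basis <- vapply(seq_len(K), function(k)
    cos(pi * k * (2 * i + 1) / (2 * nVolumes)), numeric(nVolumes))
  out <- cbind(1, matrix(basis, nVolumes, K))
  colnames(out) <- c("intercept", if (K > 0) paste0("drift_", seq_len(K)))
  out
}

# Residualize columns of y against the drift basis (least squares).
residualizeDrift <- function(y, basis) {
  y <- as.matrix(y)
  y - basis %*% qr.coef(qr(basis), y)
}

#' Spatial Gaussian smoothing
#'
#' Separable per-volume 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` converted to voxel units.  The
#' boundary is zero-padded (the kernel is normalized, so the image total
#' is conserved away from the edges); `fwhm = 0` is the identity.
#'
#' @param x 3D or 4D array (4th dimension = time).
#' @param fwhm Full width at half maximum in mm; default 6.
#' @param voxelSize Voxel size in mm (scalar isotropic or length 3).
#' @return Array of the same shape.
#' @export
smoothGaussian <- function(x, fwhm = 6, voxelSize = 3) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(x)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  d <- dim(x)
  stopifnot(length(d) %in% c(3L, 4L))
  sigmaVox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxelSize
  for (ax in 1:3) {
    r <- max(1L, ceiling(3.5 * sigmaVox[ax]))
    k <- stats::dnorm(-r:r, sd = sigmaVox[ax])
    k <- k / sum(k)
    x <- convolveAxis(x, k, ax)
  }
  x
}

# 1D zero-padded convolution along axis `ax` of a 3D/4D array, as a
# banded-matrix multiply on the (axis x rest) unfolding.
convolveAxis <- function(x, kernel, ax) {
  d <- dim(x)
  perm <- c(ax, setdiff(seq_along(d), ax))
  xp <- if (ax == 1L) x else aperm(x, perm)
  dp <- d[perm]
  n <- dp[1]
  r <- (length(kernel) - 1L) / 2L
  off <- outer(seq_len(n), seq_len(n), function(i, j) j - i) + r + 1L
  K <- matrix(0, n, n)
  inband <- off >= 1L & off <= length(kernel)
  K[inband] <- kernel[off[inband]]
  out <- K %*% matrix(xp, n, prod(dp[-1]))
  if (ax == 1L) array(out, d) else aperm(array(out, dp), order(perm))
}

#' Build the first-level design matrix
#'
#' Columns, in order: the 4 HRF-convolved active-condition regressors,
#' their 4 temporal derivatives (backward difference, first row 0), the
#' 24 extended motion confounds, and the discrete-cosine drift basis
#' (intercept included).  Null trials are the implicit baseline: no
#' regressor is added and the condition columns are not mean-centred.
#'
#' @param schedule An [EventSchedule-class] (or trial `data.frame`)
#'   containing active trials.
#' @param motion `nVolumes` x 6 motion-parameter matrix.
#' @param acq An [acquisitionSpec()].
#' @param highpass High-pass cutoff in seconds.
#' @return `nVolumes` x (32 + drift) named matrix with attribute
#'   `"conditions"` naming the condition columns.
#' @export
buildDesignMatrix <- function(schedule, motion, acq = acquisitionSpec(),
                              highpass = 100) {
  nv <- acq$nVolumes
  if (nrow(as.matrix(motion)) != nv)
    stop("motion trace rows must equal the acquisition volume count")
  conds <- intersect(trialConditions(active = TRUE),
                     unique(scheduleTrials(schedule)$condition))
  if (length(conds) == 0L)
    stop("schedule contains no active trials; nothing to model")
  X <- vapply(conds, function(cond)
    conditionRegressor(schedule, cond, acq$tr, nv), numeric(nv))
  D <- rbind(0, diff(X))
  colnames(D) <- paste0(conds, "_deriv")
  out <- cbind(X, D, extendMotionRegressors(motion),
               highpassBasis(nv, acq$tr, highpass))
  structure(out, conditions = conds)
}

#' Voxel-wise first-level GLM fit
#'
#' Ordinary-least-squares fit of every in-mask voxel time-series on the
#' design matrix.  The contrast for each active condition is its
#' canonical-regressor beta against the implicit null baseline; t
#' statistics are converted to z through the t CDF at the residual
#' degrees of freedom.
#'
#' @param bold A [BOLDRun-class] (or 4D array).
#' @param design Design matrix from [buildDesignMatrix()].
#' @param mask 3D logical analysis mask (default: all voxels).
#' @return A [FirstLevelFit-class].
#' @export
fitFirstLevel <- function(bold, design, mask = NULL) {
  arr <- if (is(bold, "BOLDRun")) bold@data else bold
  affine <- if (is(bold, "BOLDRun")) bold@affine else diag(4)
  subject <- if (is(bold, "BOLDRun")) bold@subject else NA_integer_
  session <- if (is(bold, "BOLDRun")) bold@session else NA_integer_
  d <- dim(arr)
  nv <- d[4]
  if (nrow(design) != nv)
    stop("design rows (", nrow(design), ") must equal volumes (", nv, ")")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(identical(dim(mask), d[1:3]))
  X <- unclass(design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- matrix(arr, prod(d[1:3]), nv)[as.vector(mask), , drop = FALSE]
  Y <- t(Y)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dof <- nv - qrX$rank
  sigma2 <- colSums(resid^2) / dof
  unpivot <- order(qrX$pivot)
  XtXinv <- chol2inv(qr.R(qrX))[unpivot, unpivot, drop = FALSE]
  conds <- attr(design, "conditions")
  if (is.null(conds)) conds <- colnames(X)[seq_len(min(4L, ncol(X)))]
  toMap <- function(v) {
    m <- array(NA_real_, d[1:3])
    m[mask] <- v
    m
  }
  effects <- variances <- zmaps <- stats::setNames(vector("list", length(conds)),
                                                   conds)
  for (cond in conds) {
    ci <- match(cond, colnames(X))
    eff <- beta[ci, ]
    v <- sigma2 * XtXinv[ci, ci]
    t <- eff / sqrt(v)
    t[v == 0] <- sign(eff[v == 0]) * Inf
    effects[[cond]] <- toMap(eff)
    variances[[cond]] <- toMap(v)
    zmaps[[cond]] <- toMap(tToZ(t, dof))
  }
  new("FirstLevelFit", effects = effects, variances = variances, z = zmaps,
      dof = dof, mask = mask, affine = affine,
      subject = subject, session = session)
}

#' Fixed-effects combination of two sessions
#'
#' Inverse-variance-weighted average of a subject's two session-level
#' contrast estimates, the standard mid-level fixed-effects model used to
#' average responses across scan sessions.  The combined variance is
#' `1 / (1/v1 + 1/v2)`, never larger than either input.
#'
#' @param fit1,fit2 [FirstLevelFit-class] objects on the same grid with
#'   the same contrasts.
#' @return A list with named lists `effects` and `variances` of combined
#'   3D maps, plus `conditions`.
#' @export
fixedEffectsCombine <- function(fit1, fit2) {
  stopifnot(is(fit1, "FirstLevelFit"), is(fit2, "FirstLevelFit"))
  conds <- conditionNames(fit1)
  if (!identical(conds, conditionNames(fit2)))
    stop("sessions have different contrasts")
  if (!identical(dim(fit1@mask), dim(fit2@mask)))
    stop("sessions are on different grids")
  effects <- variances <- stats::setNames(vector("list", length(conds)), conds)
  for (cond in conds) {
    w1 <- 1 / fit1@variances[[cond]]
    w2 <- 1 / fit2@variances[[cond]]
    variances[[cond]] <- 1 / (w1 + w2)
    effects[[cond]] <- (w1 * fit1@effects[[cond]] +
                          w2 * fit2@effects[[cond]]) / (w1 + w2)
  }
  list(effects = effects, variances = variances, conditions = conds)
}
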