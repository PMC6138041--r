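#' ICC(3,1): two-way mixed, single measure, consistency
#'
#' Shrout-Fleiss ICC(3,1) of an `n` subjects by `k` sessions (raters)
#' matrix: `(BMS - EMS) / (BMS + (k - 1) EMS)` where BMS and EMS are the
#' between-subject and residual mean squares of the two-way ANOVA
#' decomposition.  Session main effects are removed by the decomposition,
#' so a constant offset between sessions leaves the coefficient at 1
#' (consistency, not absolute agreement).  Negative estimates are
#' returned as computed.
#'
#' @param data Numeric `n x k` matrix, `n >= 2`, `k >= 2`, finite.
#' @return The coefficient, with the mean squares as attribute
#'   `"meanSquares"` (see [anovaMeanSquares()]).  A matrix with zero
#'   total variance raises an error of class `"iccZeroVariance"`.
#' @examples
#' x <- cbind(c(1, 3, 5, 7, 9), c(2, 3, 6, 6, 10))
#' icc31(x)
#' @export
icc31 <- function(data) {
  ms <- anovaMeanSquares(data)
  icc <- (ms$bms - ms$ems) / (ms$bms + (ms$k - 1) * ms$ems)
  structure(icc, meanSquares = ms)
}

#' Two-way ANOVA mean squares
#'
#' The mean-square decomposition underlying ICC(3,1): between-subjects
#' (BMS), between-sessions (JMS) and residual (EMS) mean squares of an
#' `n x k` matrix with subjects as rows and sessions/raters as columns.
#'
#' @param data Numeric `n x k` matrix.
#' @return List with `bms`, `jms`, `ems`, `n`, `k`.
#' @export
anovaMeanSquares <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 sessions")
  if (!all(is.finite(data))) stop("data must be finite")
  if (stats::var(as.vector(data)) == 0)
    stop(structure(class = c("iccZeroVariance", "error", "condition"),
                   list(message = "zero total variance: ICC undefined",
                        call = sys.call(-1))))
  g <- mean(data)
  rm <- rowMeans(data)
  cm <- colMeans(data)
  bms <- k * sum((rm - g)^2) / (n - 1)
  jms <- n * sum((cm - g)^2) / (k - 1)
  resid <- data - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + g
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  list(bms = bms, jms = jms, ems = ems, n = n, k = k)
}

# Vectorized two-session consistency ICC over voxels.  x1, x2 are
# n x V matrices (session 1 and 2).  For k = 2 the session-centred
# residuals of the two sessions are mirror images, giving the closed
# form below; voxels with zero total variance return NA.
iccPairsVec <- function(x1, x2) {
  n <- nrow(x1)
  m <- (x1 + x2) / 2
  gm <- colMeans(m)
  bms <- 2 * colSums(sweep(m, 2L, gm)^2) / (n - 1)
  half <- (x1 - x2) / 2
  dev <- sweep(half, 2L, colMeans(half))
  ems <- 2 * colSums(dev^2) / (n - 1)
  icc <- (bms - ems) / (bms + ems)
  icc[bms + ems == 0] <- NA_real_
  icc
}

#' Voxel-wise ICC(3,1) map
#'
#' Applies [icc31()] per voxel to the stack of per-subject, per-session
#' contrast effects for one condition, producing an [ICCMap-class] whose
#' standardized image is `atanh(icc) * sqrt(n - 3)` (see
#' [iccStandardize()]).  Exactly two sessions are supported.
#'
#' @param stack `n x 2 x V` array, or a list of two `n x V` session
#'   matrices, of contrast effects (V = voxels of the grid).
#' @param dims Grid dimensions.
#' @param mask Optional 3D logical mask; out-of-mask voxels are `NA`.
#' @param affine Voxel-to-mm affine.
#' @return An [ICCMap-class] (significance mask all-`FALSE` until
#'   [thresholdIccMap()] is applied).
#' @export
iccMap <- function(stack, dims, mask = NULL, affine = diag(4)) {
  if (is.list(stack)) {
    stopifnot(length(stack) == 2L)
    x1 <- as.matrix(stack[[1]]); x2 <- as.matrix(stack[[2]])
  } else {
    stopifnot(length(dim(stack)) == 3L)
    if (dim(stack)[2] != 2L)
      stop("only two sessions are supported")
    x1 <- stack[, 1, ]; x2 <- stack[, 2, ]
  }
  n <- nrow(x1)
  icc <- iccPairsVec(x1, x2)
  if (!is.null(mask)) icc[!as.vector(mask)] <- NA_real_
  iccArr <- array(icc, dims)
  new("ICCMap", icc = iccArr, z = array(iccStandardize(icc, n), dims),
      sigMask = array(FALSE, dims), nSubjects = as.integer(n),
      affine = affine)
}

#' Fisher-z standardization of ICC values
#'
#' Variance-stabilizing transform used to threshold ICC images on the
#' same z scale as the activation maps:
#' `z = atanh(icc) * sqrt(n - 3)`, approximately standard normal under
#' the null of zero ICC.  Values are clipped at `+/-(1 - 1e-7)` before
#' `atanh`; the transform is strictly increasing in the ICC.
#'
#' @param icc Numeric vector/array of ICC values.
#' @param n Number of subjects (>= 4).
#' @return Standardized values, same shape as `icc`.
#' @examples
#' iccStandardize(0.77, 15)   # atanh(0.77) * sqrt(12)
#' @export
iccStandardize <- function(icc, n) {
  if (n < 4) stop("standardization needs at least 4 subjects")
  atanh(pmin(pmax(icc, -1 + 1e-7), 1 - 1e-7)) * sqrt(n - 3)
}

#' Threshold an ICC map by cluster-corrected significance
#'
#' Cluster-extent correction ([clusterCorrect()]) is applied to the
#' standardized (z) image; the surviving mask is then used to mask the
#' original ICC image, producing a robustly thresholded map that retains
#' the original, more interpretable ICC values.  The permutation null
#' re-pairs session-2 subjects at random, which destroys the
#' within-subject correspondence and so samples the null ICC.
#'
#' @param map An [ICCMap-class].
#' @param stack The `n x 2 x V` effect stack (or list of two `n x V`
#'   matrices) the map was computed from; required for the permutation
#'   null.
#' @param zThresh,alpha Cluster-forming threshold and familywise alpha.
#' @param method `"permutation"` or `"fixed_extent"`.
#' @param kExtent Critical extent for `"fixed_extent"`.
#' @param nPerm,connectivity,seed Permutation-null settings.
#' @return The [ICCMap-class] with `sigMask` filled in; [maskedIcc()]
#'   returns the masked image.
#' @export
thresholdIccMap <- function(map, stack = NULL, zThresh = 3.1, alpha = 0.05,
                            method = c("permutation", "fixed_extent"),
                            kExtent = NULL, nPerm = 1000, connectivity = 26,
                            seed = 1) {
  method <- match.arg(method)
  stopifnot(is(map, "ICCMap"))
  nullSizes <- NULL
  if (method == "permutation") {
    if (is.null(stack))
      stop("permutation thresholding needs the effect stack")
    if (is.list(stack)) {
      x1 <- as.matrix(stack[[1]]); x2 <- as.matrix(stack[[2]])
    } else {
      x1 <- stack[, 1, ]; x2 <- stack[, 2, ]
    }
    nullSizes <- permNullIccPairing(x1, x2, zThresh, nPerm, seed,
                                    dim(map@icc), connectivity)
  }
  mask <- clusterCorrect(map@z, zThresh, alpha, method,
                         nullMaxSizes = nullSizes, kExtent = kExtent,
                         nPerm = nPerm, connectivity = connectivity,
                         seed = seed)
  map@sigMask <- array(as.logical(mask), dim(map@icc))
  map
}

#' Median ICC over retained voxels
#'
#' @param x An [ICCMap-class] (median over its significance mask) or a
#'   numeric array of masked ICC values (`NA` = not retained).
#' @return Scalar median; an empty mask raises an error of class
#'   `"emptyMask"`.
#' @export
medianIcc <- function(x) {
  v <- if (is(x, "ICCMap")) x@icc[x@sigMask] else x[!is.na(x)]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop(structure(class = c("emptyMask", "error", "condition"),
                   list(message = "no retained voxels: median undefined",
                        call = sys.call(-1))))
  stats::median(v)
}

#' Median ICC within progressively stricter activation masks
#'
#' For each threshold, masks the *unthresholded* ICC image by the voxels
#' whose activation z exceeds the threshold (plain voxel threshold, no
#' cluster step) and records the median ICC and mask size.  The default
#' thresholds 2.3, 3.1, 3.7, 4.3 correspond to one-tailed p of 0.01,
#' 0.001, 0.0001 and 0.00001.
#'
#' @param icc 3D array of unthresholded ICC values (or an
#'   [ICCMap-class]).
#' @param activationZ 3D array of activation z statistics, same grid.
#' @param thresholds Increasing z thresholds.
#' @return `data.frame` with columns `z_threshold`, `n_voxels`,
#'   `median_icc` (`NA` with `empty = TRUE` where a mask is empty).
#' @export
activationMaskedMedians <- function(icc, activationZ,
                                    thresholds = c(2.3, 3.1, 3.7, 4.3)) {
  if (is(icc, "ICCMap")) icc <- icc@icc
  stopifnot(identical(dim(icc), dim(activationZ)))
  rows <- lapply(thresholds, function(th) {
    sel <- !is.na(activationZ) & activationZ > th & !is.na(icc)
    data.frame(z_threshold = th, n_voxels = sum(sel),
               median_icc = if (any(sel)) stats::median(icc[sel]) else NA_real_,
               empty = !any(sel))
  })
  do.call(rbind, rows)
}

#' Overlap between reliability and activation masks
#'
#' Percentage of above-threshold voxels of the ICC significance mask that
#' are also above threshold in the activation mask:
#' `100 * |icc & activation| / |icc|`.
#'
#' @param iccMask 3D logical ICC significance mask.
#' @param activationMask 3D logical activation mask, same grid.
#' @return Percentage in \[0, 100\]; an empty ICC mask raises an error of
#'   class `"emptyMask"`.
#' @export
overlapPercentage <- function(iccMask, activationMask) {
  stopifnot(identical(dim(iccMask), dim(activationMask)))
  nIcc <- sum(iccMask)
  if (nIcc == 0L)
    stop(structure(class = c("emptyMask", "error", "condition"),
                   list(message = "empty ICC mask: overlap undefined",
                        call = sys.call(-1))))
  100 * sum(iccMask & activationMask) / nIcc
}

#' Qualitative interpretation of an ICC value
#'
#' Standard interpretation bands for intraclass correlations:
#' above 0.75 excellent, 0.6 to 0.75 good, 0.4 to below 0.6 fair, below
#' 0.4 poor.
#'
#' @param value Numeric vector of ICC values in \[-1, 1\].
#' @return Character vector of labels.
#' @examples
#' classifyIcc(c(0.76, 0.75, 0.17))
#' @export
classifyIcc <- function(value) {
  if (any(!is.na(value) & (value < -1 | value > 1)))
    stop("ICC values must lie in [-1, 1]")
  out <- rep(NA_character_, length(value))
  out[value < 0.4] <- "poor"
  out[value >= 0.4 & value < 0.6] <- "fair"
  out[value >= 0.6 & value <= 0.75] <- "good"
  out[value > 0.75] <- "excellent"
  out
}
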