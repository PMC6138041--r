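#' @import methods
NULL

#' Trial schedule for one run of the control task
#'
#' An `EventSchedule` holds the ordered trial list for one run of one of the
#' two task variants.  Each run consists of 100 back-to-back 3 s trials
#' (20 each of auditory, visual, motor, cognitive and null) followed by a
#' 10 s buffer, for a total duration of 310 s.  The cognitive condition is
#' an eye-movement trial in the `"eye-movement"` variant and a brief
#' working-memory trial in the `"working-memory"` variant; the schedule's
#' `variant` slot carries that semantics.
#'
#' @slot variant Character, `"eye-movement"` or `"working-memory"`.
#' @slot order Character, `"forward"` or `"reversed"`.  The reversed order
#'   is the exact reversal of the forward trial sequence.
#' @slot trials A `data.frame` with columns `onset` (s), `duration` (s) and
#'   `condition` (character).
#' @slot buffer Numeric, trailing buffer in seconds (10).
#'
#' @seealso [generateSchedule()], [writeEvents()]
#' @export
setClass("EventSchedule",
  representation(variant = "character", order = "character",
                 trials = "data.frame", buffer = "numeric"))

setValidity("EventSchedule", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("eye-movement", "working-memory"))
    msg <- c(msg, "variant must be 'eye-movement' or 'working-memory'")
  if (!object@order %in% c("forward", "reversed"))
    msg <- c(msg, "order must be 'forward' or 'reversed'")
  tr <- object@trials
  if (!all(c("onset", "duration", "condition") %in% names(tr)))
    msg <- c(msg, "trials must have columns onset, duration, condition")
  if (nrow(tr) != 100L) msg <- c(msg, "a run has exactly 100 trials")
  else {
    if (!all(tr$duration == 3)) msg <- c(msg, "every trial lasts 3 s")
    if (!isTRUE(all.equal(tr$onset, seq(0, 297, by = 3))))
      msg <- c(msg, "trials are back-to-back: onsets 0, 3, ..., 297 s")
    cnt <- table(factor(tr$condition, levels = trialConditions()))
    if (!all(cnt == 20L)) msg <- c(msg, "exactly 20 trials per condition")
  }
  if (!identical(object@buffer, 10)) msg <- c(msg, "buffer is 10 s")
  if (length(msg)) msg else TRUE
})

#' One subject-session 4D BOLD acquisition
#'
#' Container for a 4D BOLD array together with its voxel-to-mm affine and
#' repetition time, plus the subject/session labels it belongs to.
#'
#' @slot data 4D numeric array (x, y, z, t), arbitrary signal units.
#' @slot affine 4x4 voxel-to-mm matrix (0-based voxel indices).
#' @slot tr Repetition time in seconds.
#' @slot subject,session Integer labels.
#' @export
setClass("BOLDRun",
  representation(data = "array", affine = "matrix", tr = "numeric",
                 subject = "integer", session = "integer"))

setValidity("BOLDRun", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 4L) msg <- c(msg, "data must be 4D (x,y,z,t)")
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < .Machine$double.eps)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "tr must be > 0")
  if (length(msg)) msg else TRUE
})

#' First-level GLM results for one subject-session
#'
#' Per-condition contrast effect (beta versus implicit null baseline),
#' contrast variance and z maps from a voxel-wise ordinary-least-squares
#' fit, with the residual degrees of freedom and the analysis mask.
#'
#' @slot effects,variances,z Named lists of 3D arrays, one per active
#'   condition; `NA` outside the mask.
#' @slot dof Residual degrees of freedom (volumes minus design rank).
#' @slot mask 3D logical analysis mask.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @slot subject,session Integer labels.
#' @export
setClass("FirstLevelFit",
  representation(effects = "list", variances = "list", z = "list",
                 dof = "numeric", mask = "array", affine = "matrix",
                 subject = "integer", session = "integer"))

setValidity("FirstLevelFit", function(object) {
  msg <- character(0)
  nm <- names(object@effects)
  if (is.null(nm) || !identical(nm, names(object@variances)) ||
      !identical(nm, names(object@z)))
    msg <- c(msg, "effects, variances and z must share condition names")
  if (object@dof <= 0) msg <- c(msg, "dof must be positive")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(msg)) msg else TRUE
})

#' Group-level one-sample result
#'
#' Voxel-wise one-sample group statistics over subject contrast maps:
#' the group mean effect, its z map, and the cluster-extent corrected
#' significance mask with the thresholding metadata that produced it.
#'
#' @slot effect,zmap 3D arrays (group mean effect; one-sample z).
#' @slot mask 3D logical cluster-corrected mask.
#' @slot zThresh,alpha Cluster-forming z threshold and familywise alpha.
#' @slot method Cluster correction method used.
#' @slot nSubjects Number of subjects.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @export
setClass("GroupMap",
  representation(effect = "array", zmap = "array", mask = "array",
                 zThresh = "numeric", alpha = "numeric", method = "character",
                 nSubjects = "integer", affine = "matrix"))

setValidity("GroupMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@effect), dim(object@zmap)) ||
      !identical(dim(object@zmap), dim(object@mask)))
    msg <- c(msg, "effect, zmap and mask must share a grid")
  if (object@nSubjects < 3L) msg <- c(msg, "group statistics need >= 3 subjects")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise ICC(3,1) reliability map
#'
#' Voxel-wise two-way mixed-effects, single-measure, consistency intraclass
#' correlation across two sessions, with its Fisher-z standardized image
#' and (once thresholded) the cluster-corrected significance mask.  The
#' masked image retains the original ICC values inside the mask.
#'
#' @slot icc 3D array of ICC(3,1) values in \[-1, 1\] (NA outside the mask).
#' @slot z 3D array, `atanh(icc) * sqrt(n - 3)`.
#' @slot sigMask 3D logical significance mask (all-`FALSE` until thresholded).
#' @slot nSubjects Number of subjects entering each voxel's ICC.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @export
setClass("ICCMap",
  representation(icc = "array", z = "array", sigMask = "array",
                 nSubjects = "integer", affine = "matrix"))

setValidity("ICCMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@icc), dim(object@z)) ||
      !identical(dim(object@z), dim(object@sigMask)))
    msg <- c(msg, "icc, z and sigMask must share a grid")
  v <- object@icc[is.finite(object@icc)]
  if (length(v) && (min(v) < -1 - 1e-8 || max(v) > 1 + 1e-8))
    msg <- c(msg, "ICC values must lie in [-1, 1]")
  if (object@nSubjects < 2L) msg <- c(msg, "ICC needs >= 2 subjects")
  if (length(msg)) msg else TRUE
})
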