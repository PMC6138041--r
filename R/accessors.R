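#' @rdname accessors
#' @export
setMethod("trials", "EventSchedule", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("scheduleVariant", "EventSchedule", function(x) x@variant)
#' @rdname accessors
#' @export
setMethod("scheduleOrder", "EventSchedule", function(x) x@order)
#' @rdname accessors
#' @export
setMethod("runDuration", "EventSchedule", function(x)
  max(x@trials$onset + x@trials$duration) + x@buffer)

#' @rdname accessors
#' @export
setMethod("boldData", "BOLDRun", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "BOLDRun", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("repetitionTime", "BOLDRun", function(x) x@tr)

#' @rdname accessors
#' @export
setMethod("conditionNames", "FirstLevelFit", function(x) names(x@effects))
#' @rdname accessors
#' @export
setMethod("effectMap", "FirstLevelFit", function(x, condition)
  x@effects[[matchCondition(condition, names(x@effects))]])
#' @rdname accessors
#' @export
setMethod("varianceMap", "FirstLevelFit", function(x, condition)
  x@variances[[matchCondition(condition, names(x@variances))]])
#' @rdname accessors
#' @param condition Active condition label.
#' @param ... Unused.
#' @export
setMethod("zMap", "FirstLevelFit", function(x, condition)
  x@z[[matchCondition(condition, names(x@z))]])
#' @rdname accessors
#' @export
setMethod("zMap", "GroupMap", function(x) x@zmap)
#' @rdname accessors
#' @export
setMethod("zMap", "ICCMap", function(x) x@z)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "FirstLevelFit", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "GroupMap", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "ICCMap", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("iccValues", "ICCMap", function(x) x@icc)
#' @rdname accessors
#' @export
setMethod("sigMask", "ICCMap", function(x) x@sigMask)
#' @rdname accessors
#' @export
setMethod("sigMask", "GroupMap", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("nSubjects", "ICCMap", function(x) x@nSubjects)
#' @rdname accessors
#' @export
setMethod("nSubjects", "GroupMap", function(x) x@nSubjects)

#' @rdname accessors
#' @export
setMethod("maskedIcc", "ICCMap", function(x) {
  out <- x@icc
  out[!x@sigMask] <- NA_real_
  out
})

matchCondition <- function(condition, names) {
  i <- match(condition, names)
  if (is.na(i))
    stop("unknown condition '", condition, "'; available: ",
         paste(names, collapse = ", "), call. = FALSE)
  i
}

setMethod("show", "EventSchedule", function(object) {
  cat(sprintf("EventSchedule: %s variant, %s order\n",
              object@variant, object@order))
  cat(sprintf("  %d trials of %g s + %g s buffer (%.0f s total)\n",
              nrow(object@trials), object@trials$duration[1], object@buffer,
              runDuration(object)))
  cnt <- table(object@trials$condition)
  cat("  per condition:",
      paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "BOLDRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BOLDRun: subject %d, session %d\n", object@subject, object@session))
  cat(sprintf("  grid %dx%dx%d, %d volumes, TR %g s\n", d[1], d[2], d[3], d[4],
              object@tr))
})

setMethod("show", "FirstLevelFit", function(object) {
  cat(sprintf("FirstLevelFit: subject %d, session %d (dof %g)\n",
              object@subject, object@session, object@dof))
  cat("  contrasts:", paste(names(object@effects), collapse = ", "), "\n")
  cat(sprintf("  mask: %d of %d voxels\n", sum(object@mask), length(object@mask)))
})

setMethod("show", "GroupMap", function(object) {
  cat(sprintf("GroupMap: one-sample z over %d subjects\n", object@nSubjects))
  cat(sprintf("  cluster-corrected (%s) at z > %g, alpha %g: %d voxels survive\n",
              object@method, object@zThresh, object@alpha, sum(object@mask)))
})

setMethod("show", "ICCMap", function(object) {
  v <- object@icc[is.finite(object@icc)]
  cat(sprintf("ICCMap: voxel-wise ICC(3,1), n = %d subjects\n", object@nSubjects))
  if (length(v))
    cat(sprintf("  in-mask voxels: %d, median ICC %.3f\n", length(v),
                stats::median(v)))
  cat(sprintf("  significance mask: %d voxels\n", sum(object@sigMask)))
})
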