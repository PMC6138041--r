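#' Spherical ROI mask on a voxel grid
#'
#' Voxels are included when the Euclidean distance from their centre (mm,
#' through the affine) to the ROI centre is at most the radius
#' (inclusive boundary).  If no voxel centre falls inside the sphere, the
#' nearest voxel is included, so the mask is never empty.
#'
#' @param centre Numeric length-3 mm coordinates (x, y, z).
#' @param radius Sphere radius in mm (> 0).
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel indices).
#' @param dims Integer grid dimensions.
#' @return 3D logical mask.
#' @examples
#' acq <- acquisitionSpec()
#' sum(sphereMask(c(0, 0, 0), 5, acq$affine, acq$gridShape))
#' @export
sphereMask <- function(centre, radius, affine, dims) {
  stopifnot(length(centre) == 3L, radius > 0, length(dims) == 3L)
  vox <- solve(affine) %*% c(centre, 1)
  if (any(vox[1:3] < -0.5) || any(vox[1:3] > dims - 0.5))
    stop("ROI centre maps outside the grid")
  idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  mm <- idx %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(idx), 3L, byrow = TRUE)
  d2 <- rowSums(sweep(mm, 2L, centre)^2)
  inside <- d2 <= radius^2
  if (!any(inside)) inside[which.min(d2)] <- TRUE
  array(inside, dims)
}

#' Default ROI specifications
#'
#' Five 5 mm-radius spherical ROIs, one per expected activation site
#' (auditory, visual, motor cortex, frontal eye fields and dorsolateral
#' prefrontal cortex), centred on the synthetic topology's region
#' centres.  These are placeholder coordinates for the synthetic grid,
#' not meta-analytic MNI coordinates: users analysing real data should
#' supply their own table in the same format.
#'
#' @param radius Sphere radius in mm.
#' @return `data.frame` with columns `name`, `x`, `y`, `z`, `radius`,
#'   `condition`.
#' @export
defaultRois <- function(radius = 5) {
  data.frame(
    name = c("auditory", "visual", "motor", "FEF", "DLPFC"),
    x = c(-21, -9, -18, -15, -15),
    y = c(-9, -27, -12, 6, 15),
    z = c(3, 0, 15, 15, 6),
    radius = radius,
    condition = c("auditory", "visual", "motor", "cognitive", "cognitive"),
    stringsAsFactors = FALSE)
}

#' Mean effect within a mask
#'
#' Arithmetic mean of a 3D map over the `TRUE` voxels of a mask.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical mask with at least one `TRUE` voxel.
#' @return Scalar mean.
#' @export
extractMean <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  if (!any(mask)) stop("empty mask: mean undefined")
  mean(map[mask])
}

#' ROI-level reliability table
#'
#' For each ROI, extracts the per-subject, per-session mean contrast
#' effect of the ROI's condition, computes ICC(3,1) across the two
#' sessions with its qualitative classification, and runs a two-sided
#' paired t test of session 1 versus session 2 at a Bonferroni-corrected
#' alpha (`familyAlpha / nComparisons`).
#'
#' @param fits List of subjects, each a list of two
#'   [FirstLevelFit-class]s (sessions 1 and 2).
#' @param rois ROI table as from [defaultRois()]; the `condition` column
#'   selects which contrast each ROI indexes.
#' @param familyAlpha Familywise alpha; default 0.05.
#' @param nComparisons Number of comparisons in the family; default
#'   `nrow(rois)`.  The study design's full family is 8 (four conditions
#'   in each of two task variants).
#' @return `data.frame` with one row per ROI: `condition`, `roi`, `icc`,
#'   `classification`, `t`, `p`, `significant`, `corrected_alpha`, plus
#'   attribute `"amplitudes"` (named list of n x 2 matrices).
#' @export
roiIccTable <- function(fits, rois = defaultRois(), familyAlpha = 0.05,
                        nComparisons = nrow(rois)) {
  stopifnot(length(fits) >= 2L)
  affine <- fits[[1]][[1]]@affine
  dims <- dim(fits[[1]][[1]]@mask)
  alphaCorr <- familyAlpha / nComparisons
  amps <- list()
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    mask <- sphereMask(c(roi$x, roi$y, roi$z), roi$radius, affine, dims)
    m <- t(vapply(fits, function(subj)
      c(extractMean(subj[[1]]@effects[[roi$condition]], mask),
        extractMean(subj[[2]]@effects[[roi$condition]], mask)),
      numeric(2)))
    amps[[roi$name]] <<- m
    icc <- as.numeric(icc31(m))
    dif <- m[, 1] - m[, 2]
    if (stats::sd(dif) == 0) {
      # identical sessions: no paired difference to test
      tStat <- 0
      pVal <- 1
    } else {
      tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
      tStat <- unname(tt$statistic)
      pVal <- tt$p.value
    }
    data.frame(condition = roi$condition, roi = roi$name, icc = icc,
               classification = classifyIcc(icc),
               t = tStat, p = pVal,
               significant = pVal < alphaCorr,
               corrected_alpha = alphaCorr, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), amplitudes = amps)
}
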