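#' Pipeline configuration
#'
#' Declarative configuration for [runPipeline()]: cohort size and seed,
#' variance components, acquisition geometry, GLM options, reliability
#' thresholds and ROI table.  The defaults reproduce the study
#' conditions: 15 subjects scanned in two sessions, both task variants,
#' 155 volumes at TR 2 s, 6 mm smoothing, 100 s high-pass, cluster
#' correction at z > 3.1 with alpha 0.05, sweep thresholds 2.3/3.1/3.7/
#' 4.3 and five spherical ROIs.
#'
#' @param nSubjects Number of subjects.
#' @param variants Task variants to run.
#' @param seed Base seed; every random draw derives a sub-seed from it.
#' @param vm A [varianceModel()].
#' @param acq An [acquisitionSpec()].
#' @param amplitude Mean regional response amplitude (signal units).
#' @param fwhm Spatial smoothing FWHM in mm.
#' @param highpass High-pass cutoff in seconds.
#' @param zThresh Cluster-forming z threshold.
#' @param alpha Familywise alpha for cluster correction.
#' @param clusterMethod `"permutation"` or `"fixed_extent"`.
#' @param kExtent Critical extent when `clusterMethod = "fixed_extent"`.
#' @param nPerm Permutations per cluster-correction null.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param sweepThresholds Increasing activation z thresholds for the
#'   median-ICC sweep.
#' @param rois ROI table, see [defaultRois()].
#' @param familyAlpha Family alpha for the ROI paired tests.
#' @param nComparisons ROI-test family size (default: 4 conditions per
#'   variant).
#' @param counterbalanceOrder If `TRUE`, session 2 uses the reversed
#'   trial order.
#' @return A list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(nSubjects = 15L,
                           variants = c("eye-movement", "working-memory"),
                           seed = 1, vm = varianceModel(),
                           acq = acquisitionSpec(), amplitude = 1,
                           fwhm = 6, highpass = 100, zThresh = 3.1,
                           alpha = 0.05, clusterMethod = "permutation",
                           kExtent = NULL, nPerm = 1000, connectivity = 26,
                           sweepThresholds = c(2.3, 3.1, 3.7, 4.3),
                           rois = defaultRois(), familyAlpha = 0.05,
                           nComparisons = 4L * length(variants),
                           counterbalanceOrder = FALSE) {
  structure(list(nSubjects = as.integer(nSubjects), variants = variants,
                 seed = seed, vm = vm, acq = acq, amplitude = amplitude,
                 fwhm = fwhm, highpass = highpass, zThresh = zThresh,
                 alpha = alpha, clusterMethod = clusterMethod,
                 kExtent = kExtent, nPerm = nPerm,
                 connectivity = connectivity,
                 sweepThresholds = sweepThresholds, rois = rois,
                 familyAlpha = familyAlpha,
                 nComparisons = as.integer(nComparisons),
                 counterbalanceOrder = counterbalanceOrder),
            class = "pipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Checks ranges and internal consistency without mutating anything.
#'
#' @param config A [pipelineConfig()].
#' @return Character vector of violations; `character(0)` when valid.
#' @examples
#' validateConfig(pipelineConfig())          # character(0)
#' @export
validateConfig <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$nSubjects >= 3, "nSubjects: need at least 3 subjects")
  chk(all(config$variants %in% c("eye-movement", "working-memory")),
      "variants: unknown task variant")
  chk(config$acq$tr > 0, "acq$tr: TR must be positive")
  chk(config$acq$nVolumes >= nVolumesFor(310, config$acq$tr),
      "acq$nVolumes: too few volumes to cover the 310 s run")
  chk(config$fwhm >= 0, "fwhm: must be non-negative")
  chk(config$highpass > 2 * config$acq$tr,
      "highpass: cutoff must exceed twice the TR")
  chk(config$zThresh > 0, "zThresh: must be positive")
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must be in (0, 1)")
  chk(config$clusterMethod %in% c("permutation", "fixed_extent"),
      "clusterMethod: unknown method")
  chk(config$clusterMethod != "fixed_extent" || !is.null(config$kExtent),
      "kExtent: required for fixed_extent correction")
  chk(config$nPerm >= 100, "nPerm: need at least 100 permutations")
  chk(!is.unsorted(config$sweepThresholds, strictly = TRUE),
      "sweepThresholds: must be strictly increasing")
  chk(all(config$rois$radius > 0), "rois: radius must be positive")
  chk(all(c("name", "x", "y", "z", "radius", "condition") %in%
            names(config$rois)), "rois: missing columns")
  chk(config$vm$sigmaB > 0 || config$vm$sigmaW > 0,
      "vm: sigmaB and sigmaW cannot both be zero")
  v
}

# One-sample z map without cluster correction (per-session group maps).
groupZOnly <- function(maps, dims) {
  X <- t(vapply(maps, as.vector, numeric(prod(dims))))
  n <- nrow(X)
  mu <- colMeans(X)
  sd <- sqrt(apply(X, 2L, stats::var))
  t <- mu / (sd / sqrt(n))
  t[sd == 0] <- sign(mu[sd == 0]) * Inf
  array(tToZ(t, n - 1), dims)
}

variantStem <- function(variant) sub("-", "", variant)

#' Run the full simulate / GLM / reliability / ROI pipeline
#'
#' Executes, for each task variant: cohort simulation, per-run smoothing
#' and first-level GLM, per-session and fixed-effects group activation
#' maps with cluster correction, voxel-wise ICC(3,1) maps with Fisher-z
#' standardization and cluster-corrected thresholding, the
#' activation-threshold median-ICC sweep, ICC/activation overlap, and the
#' ROI reliability table.  All maps are written as NIfTI-1 and all tables
#' as TSV under `outDir`; the run is deterministic given the config seed.
#'
#' @param config A [pipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param verbose Print per-stage progress.
#' @return A list of class `"runReport"`: `summary` (one row per variant
#'   x condition), `roiTable`, `sweeps`, per-variant `groupMaps`
#'   ([GroupMap-class]) and `iccMaps` ([ICCMap-class]), and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  bad <- validateConfig(config)
  if (length(bad))
    stop("invalid config:\n  ", paste(bad, collapse = "\n  "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  acq <- config$acq
  dims <- acq$gridShape
  conds <- trialConditions(active = TRUE)
  summaries <- list()
  roiTables <- list()
  sweeps <- list()
  groupMaps <- list()
  iccMaps <- list()

  for (vi in seq_along(config$variants)) {
    variant <- config$variants[vi]
    vdir <- file.path(outDir, paste0("task-", variantStem(variant)))
    dir.create(vdir, showWarnings = FALSE)
    t0 <- Sys.time()
    schedules <- list(
      generateSchedule(variant, "forward"),
      generateSchedule(variant,
                       if (config$counterbalanceOrder) "reversed" else "forward"))
    topology <- defaultTopology(acq, variant, config$amplitude)
    amps <- drawAmplitudes(config$nSubjects, topology, config$vm,
                           subSeed(config$seed, c(100, vi)))
    say("[%s] simulating and fitting %d subjects x 2 sessions",
        variant, config$nSubjects)
    fits <- lapply(seq_len(config$nSubjects), function(s) {
      lapply(1:2, function(j) {
        run <- simulateRun(schedules[[j]], topology, amps[s, j, ], acq,
                           config$vm, seed = subSeed(config$seed, c(vi, s, j)),
                           subject = s, session = j)
        sm <- smoothGaussian(run@data, config$fwhm, acq$voxelSize)
        motion <- simulateMotion(acq$nVolumes,
                                 seed = subSeed(config$seed, c(500 + vi, s, j)))
        design <- buildDesignMatrix(schedules[[j]], motion, acq,
                                    config$highpass)
        fitFirstLevel(new("BOLDRun", data = sm, affine = acq$affine,
                          tr = acq$tr, subject = as.integer(s),
                          session = as.integer(j)), design)
      })
    })

    say("[%s] group activation maps", variant)
    vGroup <- list()
    vIcc <- list()
    sumRows <- list()
    sweepRows <- list()
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      for (j in 1:2) {
        zses <- groupZOnly(lapply(fits, function(f) f[[j]]@effects[[cond]]),
                           dims)
        writeVolume(zses, file.path(vdir,
          sprintf("group_ses-%d_cond-%s_zmap.nii.gz", j, cond)), acq$affine)
      }
      fe <- lapply(fits, function(f)
        fixedEffectsCombine(f[[1]], f[[2]])$effects[[cond]])
      gm <- groupOneSample(fe, zThresh = config$zThresh,
                           alpha = config$alpha,
                           method = config$clusterMethod,
                           kExtent = config$kExtent, nPerm = config$nPerm,
                           connectivity = config$connectivity,
                           seed = subSeed(config$seed, c(200, vi, ci)),
                           affine = acq$affine)
      vGroup[[cond]] <- gm
      writeVolume(gm@zmap, file.path(vdir,
        sprintf("group_fixed_cond-%s_zmap.nii.gz", cond)), acq$affine)
      writeVolume(gm@mask + 0, file.path(vdir,
        sprintf("group_fixed_cond-%s_mask.nii.gz", cond)), acq$affine)

      stack <- list(
        t(vapply(fits, function(f) as.vector(f[[1]]@effects[[cond]]),
                 numeric(prod(dims)))),
        t(vapply(fits, function(f) as.vector(f[[2]]@effects[[cond]]),
                 numeric(prod(dims)))))
      im <- iccMap(stack, dims, affine = acq$affine)
      im <- thresholdIccMap(im, stack, zThresh = config$zThresh,
                            alpha = config$alpha,
                            method = config$clusterMethod,
                            kExtent = config$kExtent, nPerm = config$nPerm,
                            connectivity = config$connectivity,
                            seed = subSeed(config$seed, c(300, vi, ci)))
      vIcc[[cond]] <- im
      writeVolume(im@icc, file.path(vdir,
        sprintf("icc_cond-%s_iccmap.nii.gz", cond)), acq$affine)
      writeVolume(im@z, file.path(vdir,
        sprintf("icc_cond-%s_zmap.nii.gz", cond)), acq$affine)
      writeVolume(im@sigMask + 0, file.path(vdir,
        sprintf("icc_cond-%s_sigmask.nii.gz", cond)), acq$affine)
      mi <- maskedIcc(im)
      mi[is.na(mi)] <- 0
      writeVolume(mi, file.path(vdir,
        sprintf("icc_cond-%s_masked.nii.gz", cond)), acq$affine)

      medThr <- tryCatch(medianIcc(im), emptyMask = function(e) NA_real_)
      sweep <- activationMaskedMedians(im@icc, gm@zmap,
                                       config$sweepThresholds)
      overlap <- tryCatch(overlapPercentage(im@sigMask, gm@mask),
                          emptyMask = function(e) NA_real_)
      sweepRows[[cond]] <- cbind(variant = variant, condition = cond, sweep)
      row <- data.frame(variant = variant, condition = cond,
                        median_thresholded_icc = medThr,
                        icc_sig_voxels = sum(im@sigMask),
                        stringsAsFactors = FALSE)
      for (k in seq_along(config$sweepThresholds))
        row[[sprintf("sweep_z%.1f", config$sweepThresholds[k])]] <-
          sweep$median_icc[k]
      row$overlap_pct <- overlap
      sumRows[[cond]] <- row
    }
    groupMaps[[variant]] <- vGroup
    iccMaps[[variant]] <- vIcc

    say("[%s] ROI reliability table", variant)
    rois <- config$rois
    dropCog <- if (variant == "eye-movement") "DLPFC" else "FEF"
    rois <- rois[rois$name != dropCog, , drop = FALSE]
    roiTab <- roiIccTable(fits, rois, config$familyAlpha,
                          config$nComparisons)
    roiTab <- cbind(variant = variant, roiTab)
    roiTables[[variant]] <- roiTab
    writeTsv(roiTab, file.path(vdir, "roi.tsv"))

    summary <- do.call(rbind, sumRows)
    roiIccByCond <- stats::setNames(roiTab$icc, roiTab$condition)
    summary$roi_icc <- unname(roiIccByCond[summary$condition])
    summary$roi_classification <- classifyIcc(summary$roi_icc)
    summaries[[variant]] <- summary
    sweeps[[variant]] <- do.call(rbind, sweepRows)
    writeTsv(summary, file.path(vdir, "summary.tsv"))
    writeTsv(sweeps[[variant]], file.path(vdir, "sweep.tsv"))
    say("[%s] done in %.1f s", variant,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  writeTsv(summary, file.path(outDir, "summary.tsv"))
  roiTable <- do.call(rbind, roiTables)
  rownames(roiTable) <- NULL
  writeTsv(roiTable, file.path(outDir, "roi.tsv"))

  manifest <- list(
    package = "boldretest",
    version = as.character(utils::packageVersion("boldretest")),
    seed = config$seed,
    nSubjects = config$nSubjects,
    variants = config$variants,
    varianceModel = config$vm,
    trueAmplitudeIcc = trueIcc(config$vm$sigmaB, config$vm$sigmaW),
    acquisition = config$acq[c("tr", "nVolumes", "gridShape", "voxelSize")],
    glm = list(fwhm = config$fwhm, highpass = config$highpass,
               zThresh = config$zThresh, alpha = config$alpha,
               clusterMethod = config$clusterMethod, nPerm = config$nPerm,
               connectivity = config$connectivity),
    sweepThresholds = config$sweepThresholds)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(summary = summary, roiTable = roiTable, sweeps = sweeps,
                 groupMaps = groupMaps, iccMaps = iccMaps,
                 manifest = manifest, outDir = outDir),
            class = "runReport")
}

#' @export
print.runReport <- function(x, ...) {
  cat("Control-task reliability run\n")
  cat(sprintf("  %d summary rows (%s)\n", nrow(x$summary),
              paste(unique(x$summary$variant), collapse = ", ")))
  cat(sprintf("  outputs under %s\n", x$outDir))
  print(x$summary[, c("variant", "condition", "median_thresholded_icc",
                      "roi_icc", "overlap_pct")], ...)
  invisible(x)
}
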