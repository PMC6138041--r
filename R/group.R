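#' Group-level one-sample statistics
#'
#' Voxel-wise one-sample t test across subjects' contrast maps, converted
#' to z, with cluster-extent correction of the z map (sign-flip
#' permutation null by default).  Zero-variance voxels are assigned the
#' capped z of +/- 38.
#'
#' @param maps List of 3D subject contrast arrays, or an n x V matrix.
#' @param mask Optional 3D logical analysis mask.
#' @param zThresh,alpha Cluster-forming z threshold and familywise alpha.
#' @param method Cluster correction method, see [clusterCorrect()].
#' @param kExtent Critical extent for `method = "fixed_extent"`.
#' @param nPerm Number of sign-flip permutations.
#' @param connectivity Cluster connectivity.
#' @param seed RNG seed for the permutation null.
#' @param affine Voxel-to-mm affine stored on the result.
#' @param dims Grid dimensions (required if `maps` is a matrix).
#' @return A [GroupMap-class].
#' @export
groupOneSample <- function(maps, mask = NULL, zThresh = 3.1, alpha = 0.05,
                           method = c("permutation", "fixed_extent"),
                           kExtent = NULL, nPerm = 1000, connectivity = 26,
                           seed = 1, affine = diag(4), dims = NULL) {
  method <- match.arg(method)
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    X <- t(vapply(maps, as.vector, numeric(prod(dims))))
  } else {
    X <- as.matrix(maps)
    if (is.null(dims)) stop("dims is required when maps is a matrix")
  }
  n <- nrow(X)
  if (n < 3L) stop("group statistics need at least 3 subjects")
  if (!is.null(mask)) X[, !as.vector(mask)] <- NA
  mu <- colMeans(X)
  sd <- sqrt(apply(X, 2L, stats::var))
  t <- mu / (sd / sqrt(n))
  t[sd == 0] <- sign(mu[sd == 0]) * Inf
  z <- tToZ(t, n - 1)
  zmap <- array(z, dims)
  Xperm <- X
  Xperm[is.na(Xperm)] <- 0
  cmask <- clusterCorrect(zmap, zThresh, alpha, method,
                          nullMaps = if (method == "permutation") Xperm,
                          kExtent = kExtent, nPerm = nPerm,
                          connectivity = connectivity, seed = seed,
                          mask = mask)
  new("GroupMap", effect = array(mu, dims), zmap = zmap,
      mask = array(as.logical(cmask), dims), zThresh = zThresh,
      alpha = alpha, method = method, nSubjects = n, affine = affine)
}
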