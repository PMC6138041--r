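# 26-connected component labelling and permutation cluster-extent
# correction for statistical maps.

neighbourOffsets <- function(connectivity = 26) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6, 18 or 26")
  offs
}

#' Label connected clusters in a binary mask
#'
#' Groups `TRUE` voxels of a 3D mask into connected components under
#' 26-neighbour (default), 18- or 6-neighbour connectivity.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer 3D array: 0 outside the mask, cluster id (1, 2, ...)
#'   inside, with attribute `"sizes"` giving voxels per cluster.
#' @export
clusterLabel <- function(mask, connectivity = 26) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  out <- array(0L, d)
  idx <- which(mask)
  m <- length(idx)
  if (m == 0L)
    return(structure(out, sizes = integer(0)))
  coords <- arrayInd(idx, d)
  labels <- clusterMembership(coords, d, connectivity)
  out[idx] <- labels
  structure(out, sizes = as.integer(tabulate(labels)))
}

# Union-find over the supra-threshold voxel set; returns component id per
# row of `coords` (1-based, compacted).  Neighbour lookups for all offsets
# are matched in one vectorized pass; only the (few) realized adjacency
# edges are walked.
clusterMembership <- function(coords, d, connectivity = 26) {
  m <- nrow(coords)
  if (m == 1L) return(1L)
  strides <- cumprod(c(1, d[-3]))
  lin <- as.vector((coords - 1) %*% strides)
  offs <- neighbourOffsets(connectivity)
  nOff <- nrow(offs)
  # all neighbour coordinates of all voxels, stacked
  nb1 <- rep(coords[, 1], each = nOff) + rep(offs[, 1], m)
  nb2 <- rep(coords[, 2], each = nOff) + rep(offs[, 2], m)
  nb3 <- rep(coords[, 3], each = nOff) + rep(offs[, 3], m)
  ok <- nb1 >= 1 & nb1 <= d[1] & nb2 >= 1 & nb2 <= d[2] &
    nb3 >= 1 & nb3 <= d[3]
  src <- rep(seq_len(m), each = nOff)[ok]
  hit <- match((nb1[ok] - 1) + (nb2[ok] - 1) * strides[2] +
                 (nb3[ok] - 1) * strides[3], lin)
  keep <- !is.na(hit) & hit > src  # each undirected edge once
  src <- src[keep]
  dst <- hit[keep]
  parent <- seq_len(m)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(src)) {
    a <- findRoot(src[e]); b <- findRoot(dst[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(m), findRoot, integer(1))
  match(roots, unique(roots))
}

# Maximum cluster size among supra-threshold entries of a statistic
# vector laid out on grid `d` (fast path for permutation nulls).
maxClusterSize <- function(stat, thresh, d, connectivity = 26) {
  maxClusterSizeIdx(which(stat > thresh), d, connectivity)
}

maxClusterSizeIdx <- function(idx, d, connectivity = 26) {
  m <- length(idx)
  if (m <= 1L) return(m)
  labels <- clusterMembership(arrayInd(idx, d), d, connectivity)
  max(tabulate(labels))
}

# Max cluster size for every permutation in one union-find pass: the
# permutations' supra-threshold voxels are stacked along a padded
# z-axis (2 empty slices between maps, unreachable by +/-1 offsets) and
# labelled together.  `vox` are linear voxel indices on grid `d`,
# `perm` the permutation id of each entry.
batchMaxClusterSizes <- function(vox, perm, nPerm, d, connectivity = 26) {
  out <- integer(nPerm)
  if (length(vox) == 0L) return(out)
  coords <- arrayInd(vox, d)
  coords[, 3] <- coords[, 3] + (perm - 1L) * (d[3] + 2L)
  dv <- c(d[1], d[2], (d[3] + 2L) * nPerm)
  labels <- clusterMembership(coords, dv, connectivity)
  sizes <- tabulate(labels)
  labPerm <- perm[match(seq_along(sizes), labels)]
  agg <- tapply(sizes, labPerm, max)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

# Sign-flip max-cluster-size null for a one-sample design.  `maps` is an
# n x V matrix of subject maps; statistics are computed as one-sample t
# and thresholded at the t value equivalent to z > zThresh.  The identity
# flip is included so the observed statistic is a member of its own null.
permNullOneSample <- function(maps, zThresh, nPerm = 1000, seed = 1,
                              d, connectivity = 26) {
  n <- nrow(maps)
  ssq <- colSums(maps^2)
  tThresh <- stats::qt(stats::pnorm(zThresh, lower.tail = FALSE), df = n - 1,
                       lower.tail = FALSE)
  withSeed(seed, {
    S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    S[1, ] <- 1
    M <- (S %*% maps) / n
    V <- sweep(-n * M^2, 2L, ssq, `+`) / (n - 1)
    Tm <- M / sqrt(V / n)
    supra <- which(Tm > tThresh)  # column-major: perm index = (i-1) %% nPerm
    permId <- (supra - 1L) %% nPerm + 1L
    vox <- (supra - 1L) %/% nPerm + 1L
    batchMaxClusterSizes(vox, permId, nPerm, d, connectivity)
  })
}

# Session re-pairing max-cluster-size null for voxel-wise ICC z maps.
# Each permutation pairs subject i's session-1 map with a random
# subject's session-2 map, destroying the within-subject correspondence
# that ICC measures; the ICC threshold equivalent to z > zThresh is
# icc > tanh(zThresh / sqrt(n - 3)).  For k = 2 sessions the ICC reduces
# to the cross-sum form below, in which only the cross term depends on
# the pairing (session-wise sums are pairing-invariant).
permNullIccPairing <- function(x1, x2, zThresh, nPerm = 1000, seed = 1,
                               d, connectivity = 26) {
  n <- nrow(x1)
  iccThresh <- tanh(zThresh / sqrt(n - 3))
  g1 <- colMeans(x1)
  g2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n * g1^2
  ss2 <- colSums(x2^2) - n * g2^2
  denom <- (ss1 + ss2) / 2
  withSeed(seed, {
    supra <- lapply(seq_len(nPerm), function(p) {
      perm <- if (p == 1L) seq_len(n) else sample.int(n)
      cross <- colSums(x1 * x2[perm, , drop = FALSE]) - n * g1 * g2
      icc <- cross / denom
      icc[denom == 0] <- 0
      which(icc > iccThresh)
    })
    batchMaxClusterSizes(unlist(supra),
                         rep(seq_len(nPerm), lengths(supra)),
                         nPerm, d, connectivity)
  })
}

#' Cluster-extent correction of a z map
#'
#' Thresholds a z map at the cluster-forming threshold, groups
#' supra-threshold voxels into 26-connected clusters, and retains the
#' clusters whose extent exceeds the alpha-level critical size.  With
#' `method = "permutation"` the critical size is the `1 - alpha` quantile
#' of a max-cluster-size null distribution, either supplied directly
#' (`nullMaxSizes`) or computed by sign-flipping the subject-level maps
#' (`nullMaps`); with `method = "fixed_extent"` a user-supplied extent
#' `kExtent` is used (clusters strictly larger survive).
#'
#' @param zmap 3D array of z statistics.
#' @param zThresh Cluster-forming threshold (> 0); default 3.1.
#' @param alpha Familywise alpha; default 0.05.
#' @param method `"permutation"` or `"fixed_extent"`.
#' @param nullMaps Optional n x V matrix of subject maps for the
#'   sign-flip null (V = number of voxels of `zmap`).
#' @param nullMaxSizes Optional precomputed vector of null max cluster
#'   sizes (overrides `nullMaps`).
#' @param kExtent Critical extent for `method = "fixed_extent"`.
#' @param nPerm Number of permutations.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param seed RNG seed for the permutation null.
#' @param mask Optional 3D logical analysis mask.
#' @return 3D logical mask of surviving voxels, with attributes
#'   `"criticalSize"` and `"clusterSizes"`.
#' @export
clusterCorrect <- function(zmap, zThresh = 3.1, alpha = 0.05,
                           method = c("permutation", "fixed_extent"),
                           nullMaps = NULL, nullMaxSizes = NULL,
                           kExtent = NULL, nPerm = 1000, connectivity = 26,
                           seed = 1, mask = NULL) {
  method <- match.arg(method)
  stopifnot(zThresh > 0)
  d <- dim(zmap)
  z <- zmap
  if (!is.null(mask)) z[!mask] <- -Inf
  z[is.na(z)] <- -Inf
  if (method == "permutation") {
    if (is.null(nullMaxSizes)) {
      if (is.null(nullMaps))
        stop("permutation correction needs nullMaps or nullMaxSizes")
      nullMaxSizes <- permNullOneSample(nullMaps, zThresh, nPerm, seed, d,
                                        connectivity)
    }
    crit <- stats::quantile(nullMaxSizes, 1 - alpha, type = 1, names = FALSE)
  } else {
    if (is.null(kExtent)) stop("fixed_extent correction needs kExtent")
    crit <- kExtent
  }
  lab <- clusterLabel(z > zThresh, connectivity)
  sizes <- attr(lab, "sizes")
  keep <- which(sizes > crit)
  out <- array(lab %in% keep, d)
  structure(out, criticalSize = crit, clusterSizes = sizes)
}
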