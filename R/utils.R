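# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Deterministic per-run sub-seed below 2^31.
subSeed <- function(seed, ...) {
  parts <- c(...)
  (as.numeric(seed) * 7919 + sum(parts * 131^seq_along(parts))) %% 2147483629
}

# Convert t statistics to standard-normal z equivalents through the t CDF,
# using log-tail evaluation for numerical stability and capping at +/- 38
# where the double-precision normal quantile saturates.
tToZ <- function(t, df) {
  z <- numeric(length(t))
  neg <- !is.na(t) & t < 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE), log.p = TRUE)
  z[is.na(t)] <- NA_real_
  pmin(pmax(z, -38), 38)
}

# Write a data.frame as a deterministic TSV (fixed column order, no quoting).
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# Write a 3D/4D array as NIfTI-1 with the given affine and TR.
writeVolume <- function(x, path, affine, tr = NULL) {
  img <- RNifti::asNifti(x)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  if (!is.null(tr) && length(dim(x)) == 4L)
    RNifti::pixdim(img)[4] <- tr
  RNifti::writeNifti(img, path)
  invisible(path)
}

readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = structure(as.matrix(RNifti::xform(img)), dimnames = NULL))
}
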