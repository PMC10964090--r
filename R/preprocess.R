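#' Axial Gaussian denoising
#'
#' Suppresses high-frequency detector (photomultiplier) noise by a 1-D
#' Gaussian convolution along Z only.  Because the Z step of a confocal
#' stack is typically smaller than the axial optical resolution, a small
#' axial kernel removes detector noise without degrading the axial
#' resolution of the neurites -- unlike a lateral median filter, which
#' would also erase fine, dim neurites.  Lateral values are untouched by
#' the kernel; boundaries are handled by edge replication so end slices
#' are not darkened; the kernel is truncated at +/- 4 sigma and normalized
#' to unit sum.
#'
#' @param stack an [ImageStack-class] (>= 2 slices when `sigmaZ > 0`).
#' @param sigmaZ Gaussian standard deviation along Z in voxels (default 2);
#'   `sigmaZ = 0` returns the input unchanged.
#' @return An [ImageStack-class] of the same shape and spacing.
#' @seealso [subtractBackground()]
#' @export
axialGaussianDenoise <- function(stack, sigmaZ = 2) {
  stopifnot(is(stack, "ImageStack"), sigmaZ >= 0)
  if (sigmaZ == 0) return(stack)
  v <- voxels(stack)
  nz <- dim(v)[1]
  if (nz < 2L)
    stop("axial filtering undefined for a single-slice stack with sigmaZ > 0")
  half <- max(1L, ceiling(4 * sigmaZ))
  off <- -half:half
  k <- exp(-off^2 / (2 * sigmaZ^2))
  k <- k / sum(k)
  # weight matrix W[i, j]: contribution of source slice j to output slice i,
  # with out-of-range source indices clamped (edge replication)
  W <- matrix(0, nz, nz)
  for (i in seq_len(nz)) {
    src <- pmin(pmax(i + off, 1L), nz)
    for (t in seq_along(off)) W[i, src[t]] <- W[i, src[t]] + k[t]
  }
  dv <- dim(v)
  out <- W %*% matrix(v, nrow = nz)
  imageStack(array(out, dv), spacing(stack))
}

#' Structured-background subtraction by lateral disk median
#'
#' Estimates the background of every Z slice independently with a 2-D
#' median filter over a discrete disk (pixels whose center distance is at
#' most `medianRadius`), then subtracts it.  Neurites are thin, sparse
#' structures, so the median excises them from the background estimate
#' while retaining mottled autofluorescence and vignetting; subtracting
#' the estimate therefore normalizes local neurite contrast.  Negative
#' differences are clamped at zero -- negative intensities are physically
#' meaningless and would perturb maxima detection downstream.
#'
#' @param stack an [ImageStack-class].
#' @param medianRadius integer disk radius in pixels (default 3, >= 1).
#' @return An [ImageStack-class] of the same shape and spacing with
#'   non-negative intensities.
#' @seealso [axialGaussianDenoise()], [skeletonizeStack()]
#' @export
subtractBackground <- function(stack, medianRadius = 3) {
  stopifnot(is(stack, "ImageStack"))
  medianRadius <- as.integer(medianRadius)
  if (medianRadius < 1L) stop("medianRadius must be an integer >= 1")
  v <- voxels(stack)
  out <- v
  for (z in seq_len(dim(v)[1])) {
    bg <- disk_median_cpp(v[z, , ], medianRadius)
    out[z, , ] <- pmax(v[z, , ] - bg, 0)
  }
  imageStack(out, spacing(stack))
}

#' Preprocess a stack for skeletonization
#'
#' Convenience composition of [axialGaussianDenoise()] followed by
#' [subtractBackground()] with the package defaults (sigma 2 voxels,
#' radius 3 pixels).
#'
#' @inheritParams axialGaussianDenoise
#' @inheritParams subtractBackground
#' @return A preprocessed [ImageStack-class].
#' @export
preprocessStack <- function(stack, sigmaZ = 2, medianRadius = 3) {
  subtractBackground(axialGaussianDenoise(stack, sigmaZ), medianRadius)
}
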