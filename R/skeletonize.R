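#' Reslice a stack into orthogonal Z projections
#'
#' Rotates the (Z, Y, X) stack 90 degrees about the X axis (`axis = "X"`),
#' so each output slice is an XZ plane stacked along Y, or about the Y
#' axis (`axis = "Y"`), so each output slice is a YZ plane stacked along
#' X.  Both reslices are pure axis transpositions: voxel values are
#' preserved, spacing is permuted accordingly, and applying the same
#' reslice again recovers the original stack exactly (the operation is an
#' involution).
#'
#' The index mapping is `(z, y, x) -> (y, z, x)` about X and
#' `(z, y, x) -> (x, y, z)` about Y.
#'
#' @param stack an [ImageStack-class].
#' @param axis `"X"` or `"Y"`.
#' @return The resliced [ImageStack-class].
#' @export
resliceOrthogonal <- function(stack, axis = c("X", "Y")) {
  stopifnot(is(stack, "ImageStack"))
  axis <- match.arg(axis)
  perm <- if (axis == "X") c(2L, 1L, 3L) else c(3L, 2L, 1L)
  imageStack(aperm(voxels(stack), perm), spacing(stack)[perm])
}

#' Prominence-filtered local maxima of a 2-D slice
#'
#' Marks the regional maxima of a slice whose topographic prominence
#' (height above the highest saddle connecting them to a higher maximum)
#' exceeds `prominence` times the slice maximum and whose intensity
#' exceeds `minIntensity`.  The relative prominence threshold makes the
#' detection intensity-scale-free: it thresholds on local contrast rather
#' than a global cutoff.  A flat plateau of tied maxima marks only the
#' pixel closest to the plateau centroid, keeping the skeleton about one
#' pixel wide.  An all-zero slice yields an empty result.
#'
#' @param slice finite numeric matrix.
#' @param prominence minimum prominence as a fraction of the slice maximum
#'   (default 0.10, in (0, 1]).
#' @param minIntensity absolute intensity floor (default 0); maxima at or
#'   below it are discarded.
#' @return Integer 0/1 matrix of the slice's shape.
#' @seealso [skeletonizeStack()]
#' @export
sliceLocalMaxima <- function(slice, prominence = 0.1, minIntensity = 0) {
  stopifnot(is.matrix(slice), all(is.finite(slice)),
            prominence > 0, prominence <= 1, minIntensity >= 0)
  mx <- max(slice)
  prominent_maxima_cpp(slice, prominence * mx, minIntensity)
}

#' Skeletonize a preprocessed stack to a 2-D neurite mask
#'
#' Converts a denoised, background-subtracted stack into a binary
#' one-pixel-wide neurite skeleton, normalizing neurite intensity and
#' thickness so bright bundles are not over-represented in the Fourier
#' spectrum.  The stack is resliced into both orthogonal Z projections
#' (XZ and YZ planes); [sliceLocalMaxima()] is applied to every slice of
#' each reslice; the two binary volumes are mapped back to (Z, Y, X)
#' orientation and combined by voxelwise union; finally the union is
#' flattened by a maximum projection along Z.  Both reslices are required:
#' a neurite running exactly along X appears as a translation-invariant
#' ridge in the XZ planes (where per-slice maxima degenerate to a single
#' plateau point), but as a clean spot maximum in every YZ plane, and vice
#' versa -- the union therefore segments neurites of every in-plane
#' orientation completely.
#'
#' @param stack a preprocessed [ImageStack-class] (see
#'   [preprocessStack()]).
#' @param prominence,minIntensity see [sliceLocalMaxima()].
#' @return A [NeuriteMask-class] with the stack's lateral shape and
#'   lateral spacing.
#' @export
skeletonizeStack <- function(stack, prominence = 0.1, minIntensity = 0) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(voxels(stack))
  union <- array(0L, d)
  for (axis in c("X", "Y")) {
    r <- resliceOrthogonal(stack, axis)
    rv <- voxels(r)
    marks <- array(0L, dim(rv))
    for (s in seq_len(dim(rv)[1])) {
      sl <- rv[s, , ]
      if (max(sl) <= 0) next
      marks[s, , ] <- sliceLocalMaxima(sl, prominence, minIntensity)
    }
    perm <- if (axis == "X") c(2L, 1L, 3L) else c(3L, 2L, 1L)
    union <- union | aperm(marks, perm)  # involution: same permutation back
  }
  mask2d <- apply(union, c(2L, 3L), max)
  neuriteMask(mask2d * 1, spacing(stack)[2:3])
}
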