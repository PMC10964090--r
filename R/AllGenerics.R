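#' Accessors for neurotort data classes
#'
#' Accessor generics: `voxels()` and `pixels()` return the raw image data,
#' `spacing()` the physical pixel/voxel size in micrometres,
#' `profileAngles()`/`profileRadii()` the polar-profile coordinates,
#' `gridSize()`, `cellTau()`, `cellRho()` and `tauNet()` the components of a
#' grid analysis.
#'
#' @param x an object of the documented class.
#' @return The slot value: an array/matrix, a numeric vector, or a single
#'   number, depending on the accessor.
#' @name accessors
#' @aliases voxels pixels spacing profileAngles profileRadii gridSize
#'   cellTau cellRho tauNet
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname accessors
#' @export
setGeneric("profileAngles", function(x) standardGeneric("profileAngles"))

#' @rdname accessors
#' @export
setGeneric("profileRadii", function(x) standardGeneric("profileRadii"))

#' @rdname accessors
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname accessors
#' @export
setGeneric("cellTau", function(x) standardGeneric("cellTau"))

#' @rdname accessors
#' @export
setGeneric("cellRho", function(x) standardGeneric("cellRho"))

#' @rdname accessors
#' @export
setGeneric("tauNet", function(x) standardGeneric("tauNet"))

setMethod("voxels", "ImageStack", function(x) x@voxels)
setMethod("spacing", "ImageStack", function(x) x@spacing)
setMethod("pixels", "NeuriteMask", function(x) x@pixels)
setMethod("spacing", "NeuriteMask", function(x) x@spacing)
setMethod("amplitude", "PowerSpectrum", function(x) x@amplitude)
setMethod("spacing", "PowerSpectrum", function(x) x@spacing)
setMethod("profileAngles", "PolarProfile", function(x) x@angles)
setMethod("profileRadii", "PolarProfile", function(x) x@radii)
setMethod("gridSize", "GridTortuosityResult", function(x) x@n)
setMethod("cellTau", "GridTortuosityResult", function(x) x@tau)
setMethod("cellRho", "GridTortuosityResult", function(x) x@rho)
setMethod("tauNet", "GridTortuosityResult", function(x) x@tauNet)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d x %d (Z x Y x X), spacing %s um\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "NeuriteMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("NeuriteMask: %d x %d (Y x X), spacing %s um\n", d[1], d[2],
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat(sprintf("  foreground pixels: %d (density %.4f)\n",
              sum(object@pixels), mean(object@pixels)))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d x %d centered DFT amplitude", object@side,
              object@side))
  if (is.na(object@spacing)) cat(" (pixel units)\n")
  else cat(sprintf(" (pixel size %.4g um)\n", object@spacing))
})

setMethod("show", "Passband", function(object) {
  cat(sprintf("Passband: %.3g to %.3g %s per cycle\n", object@periodMin,
              object@periodMax, if (object@units == "um") "um" else "pixels"))
})

setMethod("show", "PolarProfile", function(object) {
  cat(sprintf(
    "PolarProfile: %d directions, sector halfwidth %.3g deg\n",
    length(object@angles), object@sectorHalfwidth))
  cat(sprintf("  radii range [%.4g, %.4g]\n", min(object@radii),
              max(object@radii)))
})

setMethod("show", "GridTortuosityResult", function(object) {
  cat(sprintf("GridTortuosityResult: %d x %d grid, tau_net = %.4f\n",
              object@n, object@n, object@tauNet))
  nd <- sum(is.na(object@tau))
  if (nd > 0) cat(sprintf("  %d of %d cells without measurable signal\n",
                          nd, object@n^2))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %s model, side %d px, %d lines, alpha = %.3g, seed %d\n",
    object@variant, object@side, object@nLines, object@alphaScale,
    object@seed))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison (n = %d vs %d):\n  delta median = %.4g (%.3g%% vs reference)\n  KS D = %.4g, p = %.4g\n",
    object@nA, object@nB, object@deltaMedian, object@percentDifference,
    object@ksStatistic, object@pValue))
})
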