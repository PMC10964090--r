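#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib neurotort, .registration = TRUE
NULL

#' ImageStack: a 3-D fluorescence image volume
#'
#' Container for a grayscale confocal z-stack with its physical voxel
#' spacing.  The voxel array is ordered (Z, Y, X): slices along the first
#' dimension are lateral (Y, X) planes.  Intensities are non-negative finite
#' doubles; the package processes in floating point regardless of the bit
#' depth on disk so that faint neurites are not quantized away.
#'
#' @slot voxels 3-D numeric array (Z x Y x X) of non-negative intensities.
#' @slot spacing numeric(3), voxel size (dz, dy, dx) in micrometres; all
#'   strictly positive.
#'
#' @seealso [imageStack()], [readStack()], [makePhantomStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  slots = c(voxels = "array", spacing = "numeric"))

setValidity("ImageStack", function(object) {
  v <- object@voxels
  s <- object@spacing
  if (length(dim(v)) != 3L)
    return("voxels must be a 3-D array ordered (Z, Y, X)")
  if (!all(is.finite(v)))
    return("voxels must be finite (no NA/NaN/Inf)")
  if (any(v < 0))
    return("voxel intensities must be non-negative")
  if (length(s) != 3L || !all(is.finite(s)) || any(s <= 0))
    return("spacing must be 3 strictly positive values (dz, dy, dx) in um")
  TRUE
})

#' NeuriteMask: a 2-D binary neurite skeleton mask
#'
#' The normalized input to all tortuosity measurement: a binary (0/1) image
#' in which every visible neurite segment is reduced to a roughly
#' one-pixel-wide trace.  The mask need not be connected -- the spectral
#' method is designed for discontinuously segmented neurites.
#'
#' @slot pixels numeric or integer matrix (Y x X) with values exactly 0 or 1.
#' @slot spacing numeric(2), pixel size (dy, dx) in micrometres.
#'
#' @seealso [neuriteMask()], [skeletonizeStack()], [simulateMask()]
#' @exportClass NeuriteMask
setClass("NeuriteMask",
  slots = c(pixels = "matrix", spacing = "numeric"))

setValidity("NeuriteMask", function(object) {
  p <- object@pixels
  s <- object@spacing
  if (!all(p %in% c(0, 1)))
    return("mask pixels must be exactly 0 or 1")
  if (length(s) != 2L || !all(is.finite(s)) || any(s <= 0))
    return("spacing must be 2 strictly positive values (dy, dx) in um")
  TRUE
})

#' PowerSpectrum: centered 2-D DFT amplitude of a mask
#'
#' Magnitude of the 2-D discrete Fourier transform of a (square-embedded)
#' neurite mask, with the zero-frequency component relocated to the
#' geometric center.  Real input makes the amplitude point-symmetric about
#' the center.
#'
#' @slot amplitude square numeric matrix of non-negative DFT magnitudes.
#' @slot side integer, edge length of the transformed (square) image.
#' @slot spacing numeric, lateral pixel size in micrometres, or `NA_real_`
#'   for pixel-unit analysis.
#'
#' @seealso [powerSpectrum()], [polarProfile()]
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  slots = c(amplitude = "matrix", side = "integer", spacing = "numeric"))

setValidity("PowerSpectrum", function(object) {
  a <- object@amplitude
  if (nrow(a) != ncol(a)) return("amplitude must be square")
  if (nrow(a) != object@side) return("side must equal the amplitude edge length")
  if (any(a < 0)) return("amplitude must be non-negative")
  if (length(object@spacing) != 1L)
    return("spacing must be a single value (possibly NA for pixel units)")
  TRUE
})

#' Passband: the range of spatial periods analyzed
#'
#' The annular bandpass targets the analysis to a range of tortuosity
#' feature sizes and suppresses pixel-harmonic artefacts at the highest
#' spatial frequencies.  Periods are expressed per cycle, either in
#' micrometres (`units = "um"`, requires a mask with physical spacing) or in
#' pixels (`units = "px"`).
#'
#' @slot periodMin,periodMax numeric spatial periods, 0 < periodMin <
#'   periodMax.
#' @slot units `"um"` or `"px"`.
#'
#' @seealso [passband()], [bandToRadii()]
#' @exportClass Passband
setClass("Passband",
  slots = c(periodMin = "numeric", periodMax = "numeric", units = "character"))

setValidity("Passband", function(object) {
  if (!(object@units %in% c("um", "px")))
    return("units must be 'um' or 'px'")
  if (length(object@periodMin) != 1L || length(object@periodMax) != 1L ||
      !is.finite(object@periodMin) || !is.finite(object@periodMax) ||
      object@periodMin <= 0 || object@periodMin >= object@periodMax)
    return("need 0 < periodMin < periodMax")
  TRUE
})

#' PolarProfile: median spectrum amplitude versus direction
#'
#' For each of K equally spaced directions, the median DFT amplitude over
#' the annular sector of the centered power spectrum lying within the
#' passband and within a small angular window of the direction.  Real-valued
#' input makes the profile point-symmetric: `radii[k] == radii[k + K/2]`.
#'
#' @slot angles numeric(K), directions in degrees on [0, 360).
#' @slot radii numeric(K), median amplitude per direction (>= 0).
#' @slot sectorHalfwidth numeric, angular half-width of each sector in
#'   degrees.
#' @slot band the [Passband-class] used.
#'
#' @seealso [polarProfile()], [fitEllipseAspect()]
#' @exportClass PolarProfile
setClass("PolarProfile",
  slots = c(angles = "numeric", radii = "numeric",
            sectorHalfwidth = "numeric", band = "Passband"))

setValidity("PolarProfile", function(object) {
  K <- length(object@angles)
  if (K < 8L) return("a polar profile needs at least 8 directions")
  if (length(object@radii) != K) return("angles and radii lengths differ")
  if (any(object@radii < 0)) return("radii must be non-negative")
  if (K %% 2L == 0L) {
    half <- K %/% 2L
    a <- object@radii
    b <- a[((seq_len(K) - 1L + half) %% K) + 1L]
    tol <- 1e-6 * (max(a) + 1e-300)
    if (any(abs(a - b) > tol))
      return("profile is not point-symmetric (radii[k] != radii[k + K/2])")
  }
  TRUE
})

#' GridTortuosityResult: per-cell tortuosity, density and their aggregate
#'
#' Result of grid-wise tortuosity analysis: the mask is divided into an
#' n x n grid; each cell gets a tortuosity score tau (minor:major aspect
#' ratio of the fitted spectral ellipse, in (0, 1]) and a neurite density
#' rho (fractional mask area in the cell, in [0, 1]).  Cells without neurite
#' signal have tau = NA and are excluded from the aggregate.  The
#' density-weighted aggregate is
#' \deqn{\tau_{net} = \frac{\sum_{i,j} \tau_{i,j}\,\rho_{i,j}}
#'                         {\sum_{i,j} \rho_{i,j}}}
#' over the cells with defined tau, so tau_net always lies between the
#' smallest and largest defined per-cell tau.
#'
#' @slot n integer, grid divisions per side.
#' @slot tau n x n numeric matrix of per-cell tortuosity (NA where
#'   undefined).
#' @slot rho n x n numeric matrix of per-cell neurite density.
#' @slot tauNet numeric, the density-weighted aggregate.
#'
#' @seealso [gridTortuosity()], [aggregateTauNet()]
#' @exportClass GridTortuosityResult
setClass("GridTortuosityResult",
  slots = c(n = "integer", tau = "matrix", rho = "matrix", tauNet = "numeric"))

setValidity("GridTortuosityResult", function(object) {
  n <- object@n
  if (length(n) != 1L || n < 1L) return("n must be a single integer >= 1")
  if (!all(dim(object@tau) == c(n, n)) || !all(dim(object@rho) == c(n, n)))
    return("tau and rho must be n x n matrices")
  if (any(object@rho < 0 | object@rho > 1))
    return("rho must lie in [0, 1]")
  tdef <- object@tau[!is.na(object@tau)]
  if (length(tdef) && (any(tdef < 0) || any(tdef > 1)))
    return("defined tau must lie in [0, 1]")
  if (length(tdef)) {
    tol <- 1e-8
    if (object@tauNet < min(tdef) - tol || object@tauNet > max(tdef) + tol)
      return("tauNet must lie between the min and max defined per-cell tau")
  }
  TRUE
})

#' SimulationConfig: parameters of the tortuous-line simulator
#'
#' Describes one simulated field of discontinuous, 1-pixel-wide neurite
#' traces.  The `"invariant"` model draws lines starting evenly spaced along
#' the left edge with a common initial heading (parallel lines); the
#' `"scale_variant"` model starts lines on concentric circles about the
#' image center with tangential headings and a deterministic per-segment
#' base turn of segmentLength / radius, emulating curvature about a central
#' origin.  In both models each successive segment heading is
#' \deqn{\theta_{final} = \theta_{initial} + \alpha_{scale}\,\varphi_{random}}
#' with phi ~ Uniform(-pi, pi).  Discontinuity comes from the per-line
#' segment count, drawn uniformly from [segmentsMin, segmentsMax].  All
#' randomness flows from the single seed in a fixed line-major order, so an
#' identical seed gives identical draws across the two variants -- only the
#' geometry differs.
#'
#' @slot side integer image size in pixels (>= 64).
#' @slot nLines integer number of simulated neurites.
#' @slot segmentLength numeric, pixels per line segment.
#' @slot segmentsMin,segmentsMax integer bounds of the per-line segment
#'   count.
#' @slot alphaScale numeric tortuosity scaling factor in [0, 1].
#' @slot variant `"invariant"` or `"scale_variant"`.
#' @slot baseRadius numeric starting radius of curvature in pixels
#'   (scale-variant model).
#' @slot radiusStep numeric per-line radius increment in pixels, keeping
#'   concentric lines from overlapping.
#' @slot seed integer random-number-generator seed.
#'
#' @seealso [simulationConfig()], [simulateMask()], [sweepAlpha()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(side = "integer", nLines = "integer", segmentLength = "numeric",
            segmentsMin = "integer", segmentsMax = "integer",
            alphaScale = "numeric", variant = "character",
            baseRadius = "numeric", radiusStep = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@side < 64L) return("side must be >= 64 pixels")
  if (object@nLines < 1L) return("nLines must be >= 1")
  if (object@segmentLength <= 0) return("segmentLength must be positive")
  if (object@segmentsMin < 1L || object@segmentsMin > object@segmentsMax)
    return("need 1 <= segmentsMin <= segmentsMax")
  if (object@alphaScale < 0 || object@alphaScale > 1)
    return("alphaScale must lie in [0, 1]")
  if (!(object@variant %in% c("invariant", "scale_variant")))
    return("variant must be 'invariant' or 'scale_variant'")
  if (object@variant == "scale_variant" && object@baseRadius <= 0)
    return("baseRadius must be positive for the scale-variant model")
  TRUE
})

#' GroupComparison: two-group tortuosity comparison
#'
#' Summary of a two-sample comparison of tau_net values: difference of
#' group medians, percent difference relative to the reference (second)
#' group, and the two-sample Kolmogorov-Smirnov statistic with its
#' two-sided p-value.
#'
#' @slot deltaMedian numeric, median(a) - median(b).
#' @slot percentDifference numeric, 100 * deltaMedian / median(b).
#' @slot ksStatistic numeric D in [0, 1].
#' @slot pValue numeric in [0, 1].
#' @slot nA,nB integer group sizes.
#'
#' @seealso [compareGroups()]
#' @exportClass GroupComparison
setClass("GroupComparison",
  slots = c(deltaMedian = "numeric", percentDifference = "numeric",
            ksStatistic = "numeric", pValue = "numeric",
            nA = "integer", nB = "integer"))

setValidity("GroupComparison", function(object) {
  if (object@ksStatistic < 0 || object@ksStatistic > 1)
    return("ksStatistic must lie in [0, 1]")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})
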