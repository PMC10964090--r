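#' Construct an ImageStack
#'
#' @param voxels 3-D numeric array ordered (Z, Y, X).
#' @param spacing numeric(3) voxel size (dz, dy, dx) in micrometres.
#' @return A validated [ImageStack-class].
#' @examples
#' s <- imageStack(array(0, c(3, 8, 8)), spacing = c(1.24, 1.24, 1.24))
#' @export
imageStack <- function(voxels, spacing = c(1, 1, 1)) {
  new("ImageStack", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a NeuriteMask
#'
#' @param pixels binary (0/1) matrix ordered (Y, X).
#' @param spacing numeric(2) pixel size (dy, dx) in micrometres; use
#'   `c(1, 1)` for pixel-unit analysis.
#' @return A validated [NeuriteMask-class].
#' @examples
#' m <- neuriteMask(diag(32), spacing = c(1.24, 1.24))
#' @export
neuriteMask <- function(pixels, spacing = c(1, 1)) {
  storage.mode(pixels) <- "double"
  new("NeuriteMask", pixels = pixels, spacing = as.numeric(spacing))
}

#' Construct a Passband
#'
#' @param periodMin,periodMax spatial periods per cycle, 0 < periodMin <
#'   periodMax.
#' @param units `"um"` (physical, requires mask spacing) or `"px"`.
#' @return A [Passband-class].
#' @examples
#' passband(5, 40, "um")   # corneal image analysis
#' passband(4, 32, "px")   # simulated-mask analysis
#' @export
passband <- function(periodMin, periodMax, units = c("um", "px")) {
  units <- match.arg(units)
  new("Passband", periodMin = as.numeric(periodMin),
      periodMax = as.numeric(periodMax), units = units)
}

#' Construct a SimulationConfig
#'
#' Defaults define the package's validation simulations: a 1024 px canvas
#' holding 128 discontinuous lines of 40 px segments, 4-24 segments per
#' line (line lengths 160-960 px); the scale-variant model starts on
#' concentric circles from radius 300 px with a 1.5 px per-line increment
#' (the outermost start circle, radius 490 px, stays inside the canvas).
#'
#' Two considerations fix the geometry.  Segment length: each segment adds
#' a heading perturbation of standard deviation `alpha * pi / sqrt(3)`
#' (uniform on +/- alpha * pi), so over a feature of size s the heading
#' spreads by about `alpha * (pi / sqrt(3)) * sqrt(s / segmentLength)`
#' radians; 40 px segments put that spread at ~1 radian for the largest
#' analyzed feature (32 px period) only at the top of the standard sweep
#' (alpha = 0.6), keeping the tortuosity score responsive over the whole
#' sweep instead of saturating early.  Line count: a region containing n
#' independently oriented segments shows a spurious spectral anisotropy
#' (sample quadrupole) of roughly sqrt(pi / (4 n)), so the 256 px cells of
#' the local analysis need on the order of a hundred segments or more;
#' 128 lines put about 7% ink on the canvas and ~100-150 segments per
#' cell.
#'
#' @param side image size in pixels (>= 64).
#' @param nLines number of simulated neurites.
#' @param segmentLength pixels per line segment.
#' @param segmentsMin,segmentsMax bounds of the uniformly drawn per-line
#'   segment count.
#' @param alphaScale tortuosity scaling factor in [0, 1].
#' @param variant `"invariant"` (parallel lines) or `"scale_variant"`
#'   (lines curving about the image center).
#' @param baseRadius starting radius of curvature in pixels (scale-variant
#'   model only).
#' @param radiusStep per-line radius increment in pixels.
#' @param seed RNG seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(alphaScale = 0.3, variant = "invariant", seed = 7)
#' @export
simulationConfig <- function(side = 1024, nLines = 128, segmentLength = 40,
                             segmentsMin = 4, segmentsMax = 24,
                             alphaScale = 0,
                             variant = c("invariant", "scale_variant"),
                             baseRadius = 300, radiusStep = 1.5, seed = 1) {
  variant <- match.arg(variant)
  new("SimulationConfig", side = as.integer(side), nLines = as.integer(nLines),
      segmentLength = as.numeric(segmentLength),
      segmentsMin = as.integer(segmentsMin),
      segmentsMax = as.integer(segmentsMax),
      alphaScale = as.numeric(alphaScale), variant = variant,
      baseRadius = as.numeric(baseRadius), radiusStep = as.numeric(radiusStep),
      seed = as.integer(seed))
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
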