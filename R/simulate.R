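# Rasterize a segment between float endpoints onto a binary canvas,
# clipping to the canvas.  Integer line stepping vertex-to-vertex; sub-pixel
# position accumulates in floating point between vertices so headings are
# not quantized.
.rasterSegment <- function(img, x0, y0, x1, y1) {
  side <- nrow(img)
  xr <- round(c(x0, x1))
  yr <- round(c(y0, y1))
  nstep <- max(abs(diff(xr)), abs(diff(yr))) + 1L
  xs <- round(seq(xr[1], xr[2], length.out = nstep))
  ys <- round(seq(yr[1], yr[2], length.out = nstep))
  keep <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
  if (any(keep)) img[cbind(ys[keep], xs[keep])] <- 1
  img
}

#' Simulate a field of discontinuous tortuous lines
#'
#' Draws `nLines` one-pixel-wide polylines on a square canvas, emulating a
#' discontinuously segmented neurite field with controllable tortuosity.
#' Each successive segment heading follows
#' `theta_final = theta_initial + alphaScale * phi` with
#' `phi ~ Uniform(-pi, pi)`; `alphaScale = 0` gives perfectly smooth
#' paths, 1 gives a random walk.  The `"invariant"` model starts lines
#' evenly spaced along the left edge heading right (parallel lines: no
#' tortuosity at any scale when alpha = 0); the `"scale_variant"` model
#' starts lines on concentric circles about the canvas center with
#' tangential headings and adds a deterministic base turn of
#' `segmentLength / radius` per segment, so alpha = 0 traces circles --
#' tortuous at the global scale, directionally coherent locally.
#' Discontinuity comes solely from the uniformly drawn per-line segment
#' count (lines end early); a line whose path escapes the canvas is
#' clipped at the boundary and ends there.
#'
#' Randomness is consumed in a fixed line-major, segment-minor order from
#' the config's seed, so identical seeds give identical draws across the
#' two variants: only the geometry differs, exactly as the paired
#' simulations require.
#'
#' @param config a [SimulationConfig-class].
#' @return A [NeuriteMask-class] (spacing 1 x 1: simulated masks are
#'   analyzed in pixel units).
#' @seealso [sweepAlpha()], [simulateIsotropicField()]
#' @export
simulateMask <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  side <- config@side
  img <- matrix(0, side, side)
  for (path in .simulatePaths(config)) {
    for (s in seq_len(nrow(path) - 1L)) {
      img <- .rasterSegment(img, path$x[s], path$y[s],
                            path$x[s + 1L], path$y[s + 1L])
      # a path escaping the canvas is clipped at the boundary and ends
      if (path$x[s + 1L] < 1 || path$x[s + 1L] > side ||
          path$y[s + 1L] < 1 || path$y[s + 1L] > side) break
    }
  }
  neuriteMask(img)
}

# Polyline vertices of every simulated line, before rasterization/clipping.
# Randomness (per-line segment count, then per-segment phi) is consumed in a
# fixed line-major order, identically for both variants.
.simulatePaths <- function(config) {
  side <- config@side
  segLen <- config@segmentLength
  ctr <- (side + 1) / 2
  withLocalSeed(config@seed, {
    lapply(seq_len(config@nLines), function(i) {
      nseg <- sample(config@segmentsMin:config@segmentsMax, 1L)
      phi <- stats::runif(nseg, -pi, pi)
      if (config@variant == "invariant") {
        x <- 1
        y <- (i - 0.5) * side / config@nLines
        heading <- 0
        baseTurn <- 0
      } else {
        radius <- config@baseRadius + (i - 1) * config@radiusStep
        psi <- 2 * pi * (i - 1) / config@nLines
        x <- ctr + radius * cos(psi)
        y <- ctr + radius * sin(psi)
        baseTurn <- segLen / radius
        # half-turn back-rotation makes the chords of the alpha = 0 path
        # exactly inscribe the circle of this radius about the center
        heading <- psi + pi / 2 - baseTurn / 2
      }
      xs <- numeric(nseg + 1L)
      ys <- numeric(nseg + 1L)
      xs[1L] <- x
      ys[1L] <- y
      for (s in seq_len(nseg)) {
        heading <- heading + baseTurn + config@alphaScale * phi[s]
        xs[s + 1L] <- xs[s] + segLen * cos(heading)
        ys[s + 1L] <- ys[s] + segLen * sin(heading)
      }
      data.frame(x = xs, y = ys)
    })
  })
}

#' Simulate an isotropic field of short random segments
#'
#' Control condition for the tortuosity scale: straight segments at
#' uniformly random positions and orientations carry no shared heading,
#' so the power spectrum is near-isotropic and the measured tortuosity
#' approaches its ceiling of 1.
#'
#' @param side canvas size in pixels.
#' @param nSegments number of segments.
#' @param segmentLength segment length in pixels.
#' @param seed RNG seed.
#' @return A [NeuriteMask-class].
#' @export
simulateIsotropicField <- function(side = 512, nSegments = 600,
                                   segmentLength = 24, seed = 1) {
  img <- matrix(0, side, side)
  withLocalSeed(seed, {
    for (i in seq_len(nSegments)) {
      x <- stats::runif(1, 1, side)
      y <- stats::runif(1, 1, side)
      a <- stats::runif(1, 0, 2 * pi)
      img <- .rasterSegment(img, x, y, x + segmentLength * cos(a),
                            y + segmentLength * sin(a))
    }
  })
  neuriteMask(img)
}

#' Sweep the tortuosity scaling factor and measure tau_net
#'
#' For every `alpha` and grid size, simulates `replicates` masks from
#' `baseConfig` with that `alphaScale` (seeds varied deterministically:
#' `seed + (alpha index - 1) * replicates + replicate - 1`) and records
#' the mean density-weighted tortuosity, measured with the pixel-unit
#' passband.  Reproduces the validation design: sweeping alpha from 0 (no
#' tortuosity) to 0.6 (high tortuosity), measured globally (1 x 1 grid)
#' and locally (4 x 4 grid), for either line model.  Replicate averaging
#' reduces the Monte Carlo error of each point (a single mask's tau_net
#' carries sampling noise from the finite number of drawn segments).
#'
#' @param baseConfig a [SimulationConfig-class]; its `alphaScale` is
#'   overridden by each swept value.
#' @param alphas numeric vector of tortuosity scaling factors in [0, 1].
#' @param grids integer vector of grid divisions (default `c(1, 4)`).
#' @param band [Passband-class] for the measurement; default 4-32
#'   pixels/cycle, the simulated-data band.
#' @param K,sectorHalfwidth see [polarProfile()].
#' @param replicates simulated masks per alpha whose tau_net is averaged
#'   (default 1).
#' @return A data.frame with columns `alpha`, `grid`, `tau_net`, one row
#'   per (alpha, grid) pair.
#' @export
sweepAlpha <- function(baseConfig, alphas = seq(0, 0.6, by = 0.1),
                       grids = c(1, 4), band = passband(4, 32, "px"),
                       K = 360, sectorHalfwidth = 1, replicates = 1) {
  stopifnot(is(baseConfig, "SimulationConfig"),
            all(alphas >= 0 & alphas <= 1), all(grids >= 1),
            replicates >= 1)
  replicates <- as.integer(replicates)
  taus <- array(NA_real_, c(length(alphas), length(grids), replicates))
  for (a in seq_along(alphas)) {
    for (r in seq_len(replicates)) {
      cfg <- baseConfig
      cfg@alphaScale <- alphas[a]
      cfg@seed <- baseConfig@seed + (a - 1L) * replicates + (r - 1L)
      mask <- simulateMask(cfg)
      for (g in seq_along(grids)) {
        res <- gridTortuosity(mask, grids[g], band = band, K = K,
                              sectorHalfwidth = sectorHalfwidth)
        taus[a, g, r] <- tauNet(res)
      }
    }
  }
  out <- expand.grid(grid = grids, alpha = alphas)[, c("alpha", "grid")]
  out$tau_net <- as.vector(t(apply(taus, c(1, 2), mean)))
  rownames(out) <- NULL
  out
}
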