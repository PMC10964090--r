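#' Centered DFT power spectrum of a neurite mask
#'
#' The mask is embedded centered in a zero-valued square array of side
#' `max(nrow, ncol)` (a square support makes the frequency radius
#' isotropic, so the bandpass annulus is circular), the 2-D DFT is
#' computed, and the magnitude is returned with the zero-frequency
#' component relocated to the geometric center.  Because the input is
#' real, the amplitude is point-symmetric about the center; the returned
#' amplitude is explicitly symmetrized (averaging each bin with its point
#' reflection) so the symmetry holds exactly in floating point.
#'
#' Spatial structures oriented at angle theta contribute energy along the
#' frequency direction orthogonal to theta, so a directionally coherent
#' mask produces an anisotropic spectrum.
#'
#' @param mask a [NeuriteMask-class] with both dimensions >= 8.
#' @param apodize apply a Hann window to the embedded image before the
#'   DFT.  Off by default: the binary mask is transformed directly;
#'   edge-discontinuity energy concentrates on the frequency axes and is
#'   suppressed by the bandpass and the median sector statistic.
#' @return A [PowerSpectrum-class].
#' @export
powerSpectrum <- function(mask, apodize = FALSE) {
  stopifnot(is(mask, "NeuriteMask"))
  p <- pixels(mask)
  if (min(dim(p)) < 8L)
    stop("mask too small for spectral analysis: both dimensions must be >= 8")
  side <- max(dim(p))
  sq <- matrix(0, side, side)
  r0 <- (side - nrow(p)) %/% 2L
  c0 <- (side - ncol(p)) %/% 2L
  sq[r0 + seq_len(nrow(p)), c0 + seq_len(ncol(p))] <- p
  if (apodize) {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(side) - 1) / (side - 1))
    sq <- sq * outer(w, w)
  }
  amp <- Mod(stats::fft(sq))
  h <- ceiling(side / 2)
  ord <- c((h + 1L):side, 1L:h)  # DC lands at floor(side/2) + 1
  amp <- amp[ord, ord]
  # enforce exact point symmetry about the center (unpaired first row/col
  # of an even-sided spectrum carries the Nyquist terms and stays as is)
  sub <- if (side %% 2L == 0L) 2L:side else 1L:side
  amp[sub, sub] <- (amp[sub, sub] + amp[rev(sub), rev(sub)]) / 2
  sp <- spacing(mask)
  if (sp[1] != sp[2])
    warning("anisotropic lateral spacing: a um passband annulus assumes ",
            "square pixels; using dx = ", sp[2])
  new("PowerSpectrum", amplitude = amp, side = as.integer(side),
      spacing = sp[2])
}

#' Map a passband to frequency-space radii
#'
#' A spatial period T maps to the frequency radius `r = side * dx / T`
#' (micrometre mode, `dx` the lateral pixel size) or `r = side / T`
#' (pixel mode).  Returns the annulus radii `(rMin, rMax)` corresponding
#' to `(periodMax, periodMin)`; both must stay below the Nyquist radius
#' `side / 2`.
#'
#' @param band a [Passband-class].
#' @param side integer side of the square spectrum.
#' @param spacing lateral pixel size in micrometres; required for a
#'   micrometre band, ignored otherwise.
#' @return Named numeric: `c(rMin = ..., rMax = ...)` in frequency-space
#'   pixels.
#' @examples
#' bandToRadii(passband(5, 40, "um"), side = 512, spacing = 1.24)
#' bandToRadii(passband(4, 32, "px"), side = 512)
#' @export
bandToRadii <- function(band, side, spacing = NA_real_) {
  stopifnot(is(band, "Passband"))
  if (band@units == "um") {
    if (!is.finite(spacing) || spacing <= 0)
      stop("a micrometre passband needs the mask's pixel spacing in um")
    toR <- function(period) side * spacing / period
  } else {
    toR <- function(period) side / period
  }
  rMin <- toR(band@periodMax)
  rMax <- toR(band@periodMin)
  if (rMax >= side / 2)
    stop(sprintf(
      "period %g %s/cycle maps to frequency radius %g >= Nyquist (side/2 = %g)",
      band@periodMin, band@units, rMax, side / 2))
  c(rMin = rMin, rMax = rMax)
}

#' Polar profile of spectrum amplitude over direction
#'
#' For each of K equally spaced directions theta_k = k * 360 / K, collects
#' all amplitude pixels whose center lies inside the bandpass annulus
#' (`rMin <= r <= rMax`, which excludes the DC center pixel) and within
#' `sectorHalfwidth` degrees of the direction, and records the median
#' amplitude of that annular sector.  The median -- not the mean -- makes
#' the profile robust against the energy that a hard-edged binary mask
#' concentrates on the frequency axes.  Sectors left empty by the geometry
#' get radius 0; if more than 10% of sectors are empty the sector geometry
#' cannot support K directions and an error suggests widening the sector.
#'
#' @param ps a [PowerSpectrum-class].
#' @param band a [Passband-class] valid for `ps` (see [bandToRadii()]).
#' @param K number of directions (>= 8; default 360).
#' @param sectorHalfwidth angular half-width of each sector in degrees
#'   (default 1, giving overlapping 2-degree sectors that stabilize the
#'   median at small radii).
#' @return A [PolarProfile-class].
#' @export
polarProfile <- function(ps, band, K = 360, sectorHalfwidth = 1) {
  stopifnot(is(ps, "PowerSpectrum"), is(band, "Passband"))
  K <- as.integer(K)
  if (K < 8L) stop("need at least 8 directions (K >= 8)")
  side <- ps@side
  rr <- bandToRadii(band, side, ps@spacing)
  ctr <- side %/% 2L + 1L
  ky <- matrix(seq_len(side) - ctr, side, side)
  kx <- t(ky)
  rad <- sqrt(kx^2 + ky^2)
  sel <- rad >= rr[["rMin"]] & rad <= rr[["rMax"]]
  amp <- ps@amplitude[sel]
  ang <- (atan2(ky[sel], kx[sel]) * 180 / pi) %% 360
  o <- order(ang)
  ang <- ang[o]
  amp <- amp[o]
  thetas <- (seq_len(K) - 1) * 360 / K
  radii <- numeric(K)
  eps <- 1e-9
  pick <- function(lo, hi) {
    # inclusive circular angular window [lo, hi] over the sorted angles
    gather <- function(a, b) {
      i1 <- findInterval(a - eps, ang) + 1L
      i2 <- findInterval(b + eps, ang)
      if (i2 >= i1) seq.int(i1, i2) else integer(0)
    }
    if (lo < 0) c(gather(lo + 360, 360), gather(0, hi))
    else if (hi >= 360) c(gather(lo, 360), gather(0, hi - 360))
    else gather(lo, hi)
  }
  for (k in seq_len(K)) {
    idx <- pick(thetas[k] - sectorHalfwidth, thetas[k] + sectorHalfwidth)
    radii[k] <- if (length(idx)) stats::median(amp[idx]) else 0
  }
  nEmpty <- sum(vapply(seq_len(K), function(k) {
    length(pick(thetas[k] - sectorHalfwidth, thetas[k] + sectorHalfwidth)) == 0L
  }, logical(1)))
  if (nEmpty > 0.1 * K)
    stop("more than 10% of annular sectors are empty; ",
         "use a wider sectorHalfwidth or a broader passband")
  new("PolarProfile", angles = thetas, radii = radii,
      sectorHalfwidth = sectorHalfwidth, band = band)
}

#' Tortuosity score from a polar profile: ellipse aspect ratio
#'
#' Converts the (angle, radius) profile to planar points and fits an
#' origin-centered conic `x' Q x = 1` (three free coefficients, symmetric
#' Q) by linear least squares; the semi-axes are the reciprocal square
#' roots of Q's eigenvalues, and the tortuosity score is the aspect ratio
#' minor/major in (0, 1].  The profile is point-symmetric by construction,
#' so the ellipse center is fixed at the origin -- a free-center fit would
#' only absorb noise.  An isotropic (circular) profile gives exactly 1; an
#' anisotropic, directionally coherent profile gives a small value.  Radii
#' are normalized by their maximum before fitting (aspect ratio is
#' invariant to uniform scaling), and zero radii -- carrying no directional
#' information -- are dropped.
#'
#' If the fitted Q is not positive definite the profile is not
#' ellipse-like and the ratio of the smallest positive to the largest
#' radius is returned with a warning.
#'
#' @param profile a [PolarProfile-class] with >= 8 nonzero radii.
#' @return Tortuosity score tau in (0, 1].
#' @export
fitEllipseAspect <- function(profile) {
  stopifnot(is(profile, "PolarProfile"))
  r <- profile@radii
  th <- profile@angles * pi / 180
  nz <- r > 0
  if (sum(nz) < 8L)
    stop("ellipse fit needs at least 8 nonzero profile radii")
  if (diff(range(r)) == 0) return(1)
  rs <- r[nz] / max(r)
  x <- rs * cos(th[nz])
  y <- rs * sin(th[nz])
  D <- cbind(x * x, x * y, y * y)
  beta <- qr.solve(D, rep(1, length(x)))
  Q <- matrix(c(beta[1], beta[2] / 2, beta[2] / 2, beta[3]), 2L, 2L)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("polar profile is not ellipse-like; ",
            "falling back to min/max radius ratio")
    return(min(rs) / max(rs))
  }
  min(sqrt(min(ev) / max(ev)), 1)
}

#' Measure the tortuosity of a neurite mask
#'
#' Composition of [powerSpectrum()], [polarProfile()] and
#' [fitEllipseAspect()]: the degree of anisotropy in the power spectrum is
#' inversely proportional to the tortuosity of the neurite field, so the
#' minor:major aspect ratio of the fitted spectral ellipse increases from
#' near 0 (straight, directionally coherent neurites) towards 1
#' (maximally tortuous, isotropic field).
#'
#' @param mask a [NeuriteMask-class].
#' @param band a [Passband-class]; default 5-40 um/cycle, the corneal
#'   analysis band.  Use `passband(4, 32, "px")` for simulated masks.
#' @param K,sectorHalfwidth see [polarProfile()].
#' @param apodize see [powerSpectrum()].
#' @return tau in (0, 1], or `NA_real_` for an empty mask (no neurite
#'   signal; consumed by [gridTortuosity()] weighting as density 0).
#' @examples
#' m <- simulateMask(simulationConfig(side = 256, nLines = 12,
#'   segmentsMin = 10, segmentsMax = 30, alphaScale = 0, seed = 1))
#' measureTortuosity(m, passband(4, 32, "px"))
#' @export
measureTortuosity <- function(mask, band = passband(5, 40, "um"), K = 360,
                              sectorHalfwidth = 1, apodize = FALSE) {
  stopifnot(is(mask, "NeuriteMask"))
  if (sum(pixels(mask)) == 0) return(NA_real_)
  ps <- powerSpectrum(mask, apodize = apodize)
  prof <- polarProfile(ps, band, K = K, sectorHalfwidth = sectorHalfwidth)
  fitEllipseAspect(prof)
}

#' Density-weighted aggregate tortuosity
#'
#' Aggregates per-cell tortuosity over a grid, weighting each cell by its
#' neurite density so that sparse cells do not dominate:
#' `tau_net = sum(tau * rho) / sum(rho)` over cells with defined tau and
#' positive density.  Cells with no signal (tau undefined) contribute to
#' neither sum -- coercing them to 0 would cast a fake "perfectly
#' coherent" vote.
#'
#' @param tau numeric vector/matrix of per-cell tortuosity, NA where
#'   undefined.
#' @param rho numeric vector/matrix of per-cell densities in [0, 1].
#' @return The weighted mean tau_net.
#' @examples
#' aggregateTauNet(c(0.2, 0.6), c(0.1, 0.3))  # 0.5
#' @export
aggregateTauNet <- function(tau, rho) {
  stopifnot(length(tau) == length(rho))
  ok <- !is.na(tau) & rho > 0
  if (!any(ok)) stop("no neurite signal: no cell has a defined tortuosity")
  sum(tau[ok] * rho[ok]) / sum(rho[ok])
}

#' Grid-wise multi-scale tortuosity analysis
#'
#' Splits the mask into an n x n grid of rectangular cells (remainder
#' pixels go to the last row/column of cells); each cell's neurite density
#' rho is its fractional mask area and its tortuosity tau is
#' [measureTortuosity()] of the cell content.  The cell dimension sets the
#' length scale of the measurement: a 1 x 1 grid is the global tortuosity,
#' finer grids measure locally.  Each cell is re-embedded in its own
#' square and the band radii are recomputed for the cell side, so the
#' passband stays fixed in physical (or pixel-period) units across scales
#' and local and global measurements remain comparable.  Cells whose
#' tortuosity cannot be measured (no signal, or too little for a stable
#' profile) are excluded from the density-weighted aggregate.
#'
#' @inheritParams measureTortuosity
#' @param n grid divisions per side (>= 1); `n = 1` reduces to the
#'   whole-mask measurement.
#' @return A [GridTortuosityResult-class].
#' @export
gridTortuosity <- function(mask, n, band = passband(5, 40, "um"), K = 360,
                           sectorHalfwidth = 1, apodize = FALSE) {
  stopifnot(is(mask, "NeuriteMask"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  p <- pixels(mask)
  hN <- nrow(p) %/% n
  wN <- ncol(p) %/% n
  if (hN < 1L || wN < 1L) stop("grid too fine for the mask size")
  tau <- matrix(NA_real_, n, n)
  rho <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ri <- ((i - 1L) * hN + 1L):(if (i == n) nrow(p) else i * hN)
    for (j in seq_len(n)) {
      ci <- ((j - 1L) * wN + 1L):(if (j == n) ncol(p) else j * wN)
      cell <- p[ri, ci, drop = FALSE]
      rho[i, j] <- mean(cell)
      if (rho[i, j] > 0) {
        tau[i, j] <- tryCatch(
          measureTortuosity(neuriteMask(cell, spacing(mask)), band, K,
                            sectorHalfwidth, apodize),
          error = function(e) NA_real_)
      }
    }
  }
  tn <- aggregateTauNet(tau, rho)  # errors if every cell is empty
  new("GridTortuosityResult", n = n, tau = tau, rho = rho, tauNet = tn)
}
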