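test_that("power spectrum matches the direct double-sum DFT", {
  set.seed(1)
  # binary stripes of period 4: all energy on the horizontal frequency axis
  stripes <- neuriteMask(matrix(rep(c(1, 1, 0, 0), 4)[col(matrix(0, 16, 16))],
                                16, 16))
  ps <- powerSpectrum(stripes)
  oracle <- bruteDFTAmplitude(pixels(stripes))
  expect_lt(max(abs(amplitude(ps) - oracle)) / max(oracle), 1e-10)
  ctr <- 16 %/% 2 + 1
  offc <- amplitude(ps)
  offc[ctr, ctr] <- 0
  peak <- which(offc == max(offc), arr.ind = TRUE)
  expect_true(all(peak[, "row"] == ctr))             # ky = 0
  expect_true(all(sort(peak[, "col"]) == ctr + c(-4, 4)))  # kx = +/- N/4

  m <- neuriteMask(matrix(rbinom(16 * 16, 1, 0.3), 16, 16))
  expect_lt(max(abs(amplitude(powerSpectrum(m)) - bruteDFTAmplitude(pixels(m)))) /
              max(amplitude(powerSpectrum(m))), 1e-10)
})

test_that("constant image concentrates all energy in the DC bin", {
  ps <- powerSpectrum(neuriteMask(matrix(1, 16, 16)))
  a <- amplitude(ps)
  ctr <- 16 %/% 2 + 1
  expect_equal(a[ctr, ctr], 256)
  a[ctr, ctr] <- 0
  expect_lt(max(a), 1e-9 * 256)
})

test_that("spectrum amplitude is exactly point-symmetric for real input", {
  set.seed(2)
  for (n in c(16L, 17L)) {
    a <- amplitude(powerSpectrum(neuriteMask(matrix(rbinom(n^2, 1, 0.4), n, n))))
    ctr <- n %/% 2L + 1L
    sub <- if (n %% 2L == 0L) 2L:n else 1L:n
    expect_identical(a[sub, sub], a[rev(sub), rev(sub)])
  }
  expect_error(powerSpectrum(neuriteMask(matrix(1, 4, 4))), ">= 8")
})

test_that("passband maps to frequency radii and respects Nyquist", {
  expect_equal(bandToRadii(passband(5, 40, "um"), 512, 1.24),
               c(rMin = 512 * 1.24 / 40, rMax = 512 * 1.24 / 5))
  expect_equal(bandToRadii(passband(4, 32, "px"), 512), c(rMin = 16, rMax = 128))
  expect_error(bandToRadii(passband(2, 32, "px"), 512), "Nyquist")
  expect_error(bandToRadii(passband(5, 40, "um"), 512), "spacing")
  expect_error(passband(40, 5, "um"))
})

test_that("polar profile is flat for an isotropic annulus and symmetric", {
  side <- 64L
  ctr <- side %/% 2L + 1L
  r <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+"))
  amp <- matrix(0, side, side)
  amp[r >= 8 & r <= 24] <- 7
  ps <- new("PowerSpectrum", amplitude = amp, side = side, spacing = NA_real_)
  prof <- polarProfile(ps, passband(side / 24, side / 8, "px"), K = 72,
                       sectorHalfwidth = 3)
  expect_true(all(profileRadii(prof) == 7))

  set.seed(3)
  m <- neuriteMask(matrix(rbinom(64 * 64, 1, 0.2), 64, 64))
  prof <- polarProfile(powerSpectrum(m), passband(4, 16, "px"), K = 60,
                       sectorHalfwidth = 3)
  rr <- profileRadii(prof)
  expect_identical(rr[1:30], rr[31:60])   # radii[k] == radii[k + K/2]
})

test_that("parallel vertical lines put profile maxima on the horizontal axis", {
  img <- matrix(0, 64, 64)
  img[3:61, c(5, 14, 22, 31, 39, 50, 59)] <- 1  # aperiodic columns
  prof <- polarProfile(powerSpectrum(neuriteMask(img)), passband(4, 16, "px"))
  rr <- profileRadii(prof)
  th <- profileAngles(prof)
  expect_true(all(rr[th %in% c(0, 180)] >= max(rr) - 1e-9))
  expect_lt(max(rr[th %in% c(90, 270)]), 0.2 * max(rr))
})

test_that("degenerate sector geometry errors with guidance", {
  set.seed(4)
  m <- neuriteMask(matrix(rbinom(64 * 64, 1, 0.2), 64, 64))
  expect_error(
    polarProfile(powerSpectrum(m), passband(16, 20, "px"), K = 3600,
                 sectorHalfwidth = 0.01),
    "sector")
  expect_error(polarProfile(powerSpectrum(m), passband(4, 16, "px"), K = 4),
               "K >= 8")
})

test_that("ellipse aspect recovers exact ellipses and circles", {
  th <- (0:359) * pi / 180
  circ <- new("PolarProfile", angles = (0:359) * 1, radii = rep(7, 360),
              sectorHalfwidth = 1, band = passband(4, 32, "px"))
  expect_identical(fitEllipseAspect(circ), 1)

  ellipseR <- function(a, b, rot) {
    t <- th - rot
    a * b / sqrt(b^2 * cos(t)^2 + a^2 * sin(t)^2)
  }
  p <- new("PolarProfile", angles = (0:359) * 1,
           radii = ellipseR(2, 1, 0), sectorHalfwidth = 1,
           band = passband(4, 32, "px"))
  expect_equal(fitEllipseAspect(p), 0.5, tolerance = 1e-6)
  p@radii <- ellipseR(2, 1, 37 * pi / 180)
  expect_equal(fitEllipseAspect(p), 0.5, tolerance = 1e-6)
})

test_that("tau is in (0, 1] and robust to 90-degree rotation", {
  cfg <- simulationConfig(side = 256, nLines = 32, segmentsMin = 3,
                          segmentsMax = 6, alphaScale = 0.3, seed = 5)
  m <- simulateMask(cfg)
  band <- passband(4, 32, "px")
  tau <- measureTortuosity(m, band)
  expect_true(tau > 0 && tau <= 1)
  rot <- neuriteMask(t(pixels(m))[ncol(pixels(m)):1, ])
  expect_lt(abs(measureTortuosity(rot, band) - tau), 0.02)
  expect_true(is.na(measureTortuosity(neuriteMask(matrix(0, 32, 32)), band)))
})

test_that("grid aggregation implements density weighting", {
  expect_equal(aggregateTauNet(c(0.2, 0.6), c(0.1, 0.3)), 0.5)
  expect_equal(aggregateTauNet(matrix(c(0.2, NA, 0.6, NA), 2),
                               matrix(c(0.1, 0, 0.3, 0), 2)), 0.5)
  expect_error(aggregateTauNet(c(NA_real_, NA_real_), c(0, 0)), "no neurite")
})

test_that("grid tortuosity reduces to the whole-mask measurement at n = 1", {
  m <- simulateMask(simulationConfig(side = 256, nLines = 24, segmentsMin = 3,
                                     segmentsMax = 6, alphaScale = 0.2,
                                     seed = 6))
  band <- passband(4, 32, "px")
  g <- gridTortuosity(m, 1, band)
  expect_equal(tauNet(g), measureTortuosity(m, band))
  expect_equal(cellRho(g)[1, 1], mean(pixels(m)))
})

test_that("identical cell content gives tau_net equal to the cell tau", {
  tile <- pixels(simulateMask(simulationConfig(side = 128, nLines = 16,
                                               segmentsMin = 2, segmentsMax = 4,
                                               alphaScale = 0.3, seed = 7)))
  big <- rbind(cbind(tile, tile), cbind(tile, tile))
  band <- passband(4, 32, "px")
  g <- gridTortuosity(neuriteMask(big), 2, band)
  expect_equal(length(unique(round(as.vector(cellTau(g)), 12))), 1L)
  expect_equal(tauNet(g), cellTau(g)[1, 1])
  expect_equal(tauNet(g), measureTortuosity(neuriteMask(tile), band))
})

test_that("empty cells are excluded and renormalized, empty masks error", {
  tile <- pixels(simulateMask(simulationConfig(side = 128, nLines = 16,
                                               segmentsMin = 2, segmentsMax = 4,
                                               alphaScale = 0.3, seed = 8)))
  z <- matrix(0, 128, 128)
  one <- rbind(cbind(tile, z), cbind(z, z))
  two <- rbind(cbind(tile, z), cbind(z, tile))
  band <- passband(4, 32, "px")
  g1 <- gridTortuosity(neuriteMask(one), 2, band)
  g2 <- gridTortuosity(neuriteMask(two), 2, band)
  expect_equal(sum(is.na(cellTau(g1))), 3L)
  expect_equal(tauNet(g1), tauNet(g2))   # duplicated content renormalizes
  expect_error(gridTortuosity(neuriteMask(matrix(0, 64, 64)), 2, band),
               "no neurite")
})

test_that("the bandpass targets tortuosity feature sizes", {
  m <- sineLineMask(side = 512, period = 7.7, amp = 4, nLines = 24)
  inBand <- measureTortuosity(m, passband(6, 12, "px"))
  outBand <- suppressWarnings(measureTortuosity(m, passband(16, 64, "px")))
  expect_gt(inBand, outBand)
})
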