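# Independent brute-force oracles used to verify the implementation.

# Direct O(N^4) double-sum DFT amplitude with DC relocated to the center,
# straight from the transform definition.
bruteDFTAmplitude <- function(m) {
  N <- nrow(m)
  stopifnot(ncol(m) == N)
  ctr <- N %/% 2L + 1L
  ys <- 0:(N - 1)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      u <- i - ctr
      v <- j - ctr
      ph <- exp(-2i * pi * u * ys / N) %o% exp(-2i * pi * v * ys / N)
      out[i, j] <- Mod(sum(m * ph))
    }
  }
  out
}

# Flood-based topographic prominence of every regional-max plateau:
# prominence = peak value minus the highest threshold at which the
# connected region >= threshold containing the plateau reaches a strictly
# higher pixel (image minimum if none exists).  Returns the same marking
# convention as the package: one pixel per accepted plateau, nearest the
# plateau centroid.
brutePromMaxima <- function(img, promFrac, minIntensity = 0) {
  ny <- nrow(img)
  nx <- ncol(img)
  nbrs <- function(y, x) {
    d <- expand.grid(dy = -1:1, dx = -1:1)
    d <- d[!(d$dy == 0 & d$dx == 0), ]
    yy <- y + d$dy
    xx <- x + d$dx
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    cbind(yy[ok], xx[ok])
  }
  flood <- function(y0, x0, level, stopAbove) {
    # BFS over pixels >= level; returns TRUE if a pixel > stopAbove reached
    seen <- matrix(FALSE, ny, nx)
    queue <- list(c(y0, x0))
    seen[y0, x0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      if (img[p[1], p[2]] > stopAbove) return(TRUE)
      nb <- nbrs(p[1], p[2])
      for (r in seq_len(nrow(nb))) {
        if (!seen[nb[r, 1], nb[r, 2]] && img[nb[r, 1], nb[r, 2]] >= level) {
          seen[nb[r, 1], nb[r, 2]] <- TRUE
          queue <- c(queue, list(nb[r, , drop = TRUE]))
        }
      }
    }
    FALSE
  }
  plateauOf <- function(y0, x0) {
    v <- img[y0, x0]
    seen <- matrix(FALSE, ny, nx)
    seen[y0, x0] <- TRUE
    queue <- list(c(y0, x0))
    px <- list()
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      px[[length(px) + 1]] <- p
      nb <- nbrs(p[1], p[2])
      for (r in seq_len(nrow(nb))) {
        if (!seen[nb[r, 1], nb[r, 2]] && img[nb[r, 1], nb[r, 2]] == v) {
          seen[nb[r, 1], nb[r, 2]] <- TRUE
          queue <- c(queue, list(nb[r, , drop = TRUE]))
        }
      }
    }
    do.call(rbind, px)
  }
  out <- matrix(0L, ny, nx)
  thresh <- promFrac * max(img)
  done <- matrix(FALSE, ny, nx)
  levels <- sort(unique(as.vector(img)))
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      if (done[y, x]) next
      v <- img[y, x]
      nb <- nbrs(y, x)
      if (any(img[nb] > v)) next  # not a regional max
      pl <- plateauOf(y, x)
      done[pl] <- TRUE
      # highest level whose >= level region reaches a strictly higher pixel
      saddle <- min(img)
      for (lv in rev(levels[levels <= v])) {
        if (flood(y, x, lv, v)) {
          saddle <- lv
          break
        }
      }
      prom <- if (flood(y, x, min(img), v)) v - saddle else v - min(img)
      if (prom > thresh && v > minIntensity) {
        cy <- mean(pl[, 1])
        cx <- mean(pl[, 2])
        d <- (pl[, 1] - cy)^2 + (pl[, 2] - cx)^2
        idx <- (pl[, 2] - 1L) * ny + pl[, 1]
        best <- order(d, idx)[1]
        out[pl[best, 1], pl[best, 2]] <- 1L
      }
    }
  }
  out
}

# Per-pixel disk median with replicated edges, by direct enumeration.
bruteDiskMedian <- function(img, radius) {
  ny <- nrow(img)
  nx <- ncol(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  out <- img
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      yy <- pmin(pmax(y + offs$dy, 1), ny)
      xx <- pmin(pmax(x + offs$dx, 1), nx)
      out[y, x] <- stats::median(img[cbind(yy, xx)])
    }
  }
  out
}

# Least-squares (Kasa) circle fit; returns center and radius.
fitCircle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  coef <- qr.solve(A, b)
  list(cx = coef[1], cy = coef[2],
       r = sqrt(coef[3] + coef[1]^2 + coef[2]^2))
}

# Exact two-sided two-sample KS p-value by exhaustive enumeration of all
# choose(n + m, n) group assignments of the pooled sample.
enumKSp <- function(a, b) {
  ksD <- function(u, v) {
    pooled <- sort(unique(c(u, v)))
    max(abs(stats::ecdf(u)(pooled) - stats::ecdf(v)(pooled)))
  }
  dObs <- ksD(a, b)
  pooled <- c(a, b)
  n <- length(a)
  splits <- utils::combn(length(pooled), n)
  ds <- apply(splits, 2, function(idx) ksD(pooled[idx], pooled[-idx]))
  mean(ds >= dObs - 1e-12)
}

# Binary mask of horizontal sinusoidal lines y = y0 + amp * sin(2 pi x / P),
# with jittered offsets and phases so the spectrum is not a pure lattice.
sineLineMask <- function(side = 512, period = 8, amp = 4, nLines = 16,
                         seed = 1) {
  set.seed(seed)
  img <- matrix(0, side, side)
  y0s <- seq(side / (2 * nLines), side, by = side / nLines) +
    runif(nLines, -side / (4 * nLines), side / (4 * nLines))
  phases <- runif(nLines, 0, 2 * pi)
  xs <- seq_len(side)
  for (i in seq_len(nLines)) {
    ys <- round(y0s[i] + amp * sin(2 * pi * xs / period + phases[i]))
    ok <- ys >= 1 & ys <= side
    img[cbind(ys[ok], xs[ok])] <- 1
  }
  neuriteMask(img)
}

# Minimal little-endian uncompressed 8-bit grayscale multi-page TIFF writer
# with XResolution/YResolution and ImageDescription tags, used only to
# build metadata-bearing fixtures that exercise readStack()'s tag parsing.
writeTaggedTiff <- function(path, pages, xres, yres, description) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42)
  desc <- c(utf8ToInt(description), 0L)  # NUL-terminated ASCII
  # layout per page: [pixel data][desc][xres rational][yres rational][IFD]
  nTags <- 13L
  ifdSize <- 2L + nTags * 12L + 4L
  offset <- 8L
  offs <- list()
  for (k in seq_along(pages)) {
    h <- nrow(pages[[k]])
    wd <- ncol(pages[[k]])
    dataOff <- offset
    descOff <- dataOff + h * wd
    xrOff <- descOff + length(desc)
    yrOff <- xrOff + 8L
    ifdOff <- yrOff + 8L
    offs[[k]] <- list(data = dataOff, desc = descOff, xr = xrOff,
                      yr = yrOff, ifd = ifdOff)
    offset <- ifdOff + ifdSize
  }
  w4(offs[[1]]$ifd)  # offset of first IFD
  rational <- function(v) {
    den <- 1000000L
    c(as.integer(round(v * den)), den)
  }
  entry <- function(tag, type, count, value, asOffset = FALSE) {
    w2(tag)
    w2(type)
    w4(count)
    if (asOffset || type %in% c(4L)) {
      w4(value)
    } else {            # SHORT packed into the low bytes of the value field
      w2(value)
      w2(0)
    }
  }
  for (k in seq_along(pages)) {
    m <- pages[[k]]
    writeBin(as.raw(as.integer(t(m))), con)  # row-major strip
    writeBin(as.raw(desc), con)
    w4(rational(xres))
    w4(rational(yres))
    # IFD: tags in ascending order
    w2(nTags)
    entry(256, 4, 1, ncol(m))                 # ImageWidth
    entry(257, 4, 1, nrow(m))                 # ImageLength
    entry(258, 3, 1, 8)                       # BitsPerSample
    entry(259, 3, 1, 1)                       # Compression = none
    entry(262, 3, 1, 1)                       # Photometric = BlackIsZero
    entry(270, 2, length(desc), offs[[k]]$desc, asOffset = TRUE)
    entry(273, 4, 1, offs[[k]]$data)          # StripOffsets
    entry(277, 3, 1, 1)                       # SamplesPerPixel
    entry(278, 4, 1, nrow(m))                 # RowsPerStrip
    entry(279, 4, 1, nrow(m) * ncol(m))       # StripByteCounts
    entry(282, 5, 1, offs[[k]]$xr, asOffset = TRUE)   # XResolution
    entry(283, 5, 1, offs[[k]]$yr, asOffset = TRUE)   # YResolution
    w2(296)
    w2(3)
    w4(1)
    w2(1)                                     # ResolutionUnit = none
    w2(0)
    w4(if (k < length(pages)) offs[[k + 1]]$ifd else 0L)
  }
  invisible(path)
}

# a small valid GridTortuosityResult for I/O tests
makeGridResult <- function(tau, rho) {
  n <- nrow(tau)
  new("GridTortuosityResult", n = as.integer(n), tau = tau, rho = rho,
      tauNet = aggregateTauNet(tau, rho))
}
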