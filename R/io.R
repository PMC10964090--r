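#' Read a multi-page grayscale TIFF z-stack
#'
#' Pages become Z slices of the returned [ImageStack-class] in (Z, Y, X)
#' order.  Voxel spacing is resolved, in order of precedence, from: the
#' `spacing` override; an ImageJ-style `ImageDescription` tag
#' (`spacing=<dz>` with `unit=micron`) together with the X/Y resolution
#' tags; or a `<path>.spacing.yaml` sidecar as written by [writeStack()].
#' An explicit override always wins because microscopy TIFF metadata
#' dialects are unreliable.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing optional numeric(3) override, (dz, dy, dx) in
#'   micrometres.
#' @return An [ImageStack-class]; intensities are returned exactly as
#'   stored (in [0, 1] for integer TIFFs, as written by `tiff::readTIFF`).
#' @seealso [writeStack()]
#' @export
readStack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      stop("non-grayscale TIFF: page has ", dim(p)[3],
           " channels, expected 1")
  }
  d <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  if (is.null(spacing)) spacing <- .resolveSpacing(path, pages[[1]])
  if (is.null(spacing))
    stop("no voxel spacing: file '", path, "' carries no resolution/",
         "spacing metadata and no sidecar; supply spacing = c(dz, dy, dx)")
  imageStack(vox, spacing)
}

# spacing from ImageJ-style TIFF tags, else from a YAML sidecar
.resolveSpacing <- function(path, page1) {
  desc <- attr(page1, "description")
  xres <- attr(page1, "x.resolution")
  yres <- attr(page1, "y.resolution")
  if (!is.null(desc) && grepl("unit=micron", desc, fixed = TRUE) &&
      !is.null(xres) && xres > 0) {
    dz <- NA_real_
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2L) dz <- as.numeric(m[2])
    dx <- 1 / xres
    dy <- if (!is.null(yres) && yres > 0) 1 / yres else dx
    if (is.finite(dz) && dz > 0) return(c(dz, dy, dx))
  }
  sidecar <- paste0(path, ".spacing.yaml")
  if (file.exists(sidecar)) {
    s <- yaml::read_yaml(sidecar)
    return(c(s$dz, s$dy, s$dx))
  }
  NULL
}

#' Write an ImageStack as a multi-page TIFF
#'
#' Intensities must lie in [0, 1] and are stored as 16-bit grayscale
#' (values on the k/65535 grid round-trip exactly).  Because the TIFF
#' writer used here cannot emit resolution tags, the voxel spacing is
#' stored in a `<path>.spacing.yaml` sidecar which [readStack()] consumes.
#'
#' @param stack an [ImageStack-class] with intensities in [0, 1].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- voxels(stack)
  if (max(v) > 1)
    stop("writeStack stores 16-bit TIFF; rescale intensities to [0, 1]")
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  s <- spacing(stack)
  yaml::write_yaml(list(dz = s[1], dy = s[2], dx = s[3], unit = "micron"),
                   paste0(path, ".spacing.yaml"))
  invisible(path)
}

#' Write a binary neurite mask as an image file
#'
#' The mask is validated first, then stored as an 8-bit image with
#' foreground 255 (viewable in any image tool); [readMask()] maps values
#' > 127 back to 1, so the round trip is lossless.
#'
#' @param mask a [NeuriteMask-class].
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "NeuriteMask"))
  validObject(mask)
  img <- pixels(mask)  # 0/1; image writers map [0,1] -> 8-bit 0/255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "none")
  }
  invisible(path)
}

#' Read a binary neurite mask
#'
#' @param path a PNG or single-page TIFF mask file.
#' @param spacing numeric(2) pixel size (dy, dx) in micrometres.
#' @return A [NeuriteMask-class]; any stored value above half range maps
#'   to 1.
#' @export
readMask <- function(path, spacing = c(1, 1)) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  neuriteMask((img > 0.5) * 1, spacing)
}

#' Write grid-tortuosity results as a CSV table
#'
#' One row per image x grid configuration: image label, grid n, tau_net,
#' then the per-cell tau and rho flattened into `tau_<i>_<j>` /
#' `rho_<i>_<j>` columns.  When results with different grid sizes are
#' mixed, absent cells are left empty.
#'
#' @param results list of [GridTortuosityResult-class] objects.
#' @param path output CSV path.
#' @param labels character vector of image labels, recycled against
#'   `results`; defaults to the list names or a running index.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(results, path, labels = NULL) {
  stopifnot(is.list(results))
  if (is.null(labels)) {
    labels <- names(results)
    if (is.null(labels)) labels <- as.character(seq_along(results))
  }
  base <- c("image", "grid_n", "tau_net")
  if (length(results) == 0L) {
    writeLines(paste(base, collapse = ","), path)
    return(invisible(path))
  }
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    stopifnot(is(r, "GridTortuosityResult"))
    n <- gridSize(r)
    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    cells <- c(
      stats::setNames(cellTau(r)[cbind(ij$i, ij$j)],
                      sprintf("tau_%d_%d", ij$i, ij$j)),
      stats::setNames(cellRho(r)[cbind(ij$i, ij$j)],
                      sprintf("rho_%d_%d", ij$i, ij$j)))
    c(list(image = labels[[((k - 1L) %% length(labels)) + 1L]],
           grid_n = n, tau_net = tauNet(r)), as.list(cells))
  })
  cols <- base
  for (r in rows) cols <- union(cols, names(r))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    r[miss] <- NA
    as.data.frame(r[cols], check.names = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
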