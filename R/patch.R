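#' Detect tissue in a low-resolution RGB overview
#'
#' Thresholds saturation and brightness in HSV space: tissue is colored
#' (saturation above `satMin`) and not glass-white (value below `valMax`).
#' The raw mask is optionally cleaned with a median filter. Deterministic for
#' fixed parameters.
#'
#' @param x [Patch-class] or H x W x 3 RGB array in [0, 255].
#' @param satMin minimum HSV saturation for tissue; default 0.05.
#' @param valMax maximum HSV value (brightness, 0-1) for tissue; default 0.95.
#' @param medianRadius radius of the median filter applied to the binary
#'   mask; 0 disables it. Default 2.
#' @return logical H x W matrix, TRUE = tissue.
#' @export
#' @examples
#' white <- array(255, c(8, 8, 3))
#' any(detectTissue(white, medianRadius = 0))   # FALSE: glass only
detectTissue <- function(x, satMin = 0.05, valMax = 0.95, medianRadius = 2) {
  img <- .as_rgb_array(x)
  d <- dim(img)
  flat <- t(base::matrix(img, ncol = 3L))
  hsv_ <- grDevices::rgb2hsv(flat, maxColorValue = 255)
  mask <- matrix(hsv_["s", ] > satMin & hsv_["v", ] < valMax, d[1], d[2])
  if (medianRadius > 0 && min(d[1:2]) > 2 * medianRadius) {
    sm <- as.matrix(EBImage::medianFilter(mask * 1, size = medianRadius))
    mask <- sm > 0.5
  }
  mask
}

#' Convert a physical length to pixels
#'
#' @param sizeUm physical length in micrometers.
#' @param resolutionUmPerPx resolution in micrometers per pixel.
#' @return integer pixel count, `sizeUm / resolution` rounded half-up,
#'   minimum 1.
#' @export
#' @examples
#' patchSizePx(1000, 0.25)     # 4000
#' patchSizePx(1000, 0.2428)   # 4119
patchSizePx <- function(sizeUm, resolutionUmPerPx) {
  if (any(sizeUm <= 0) || any(resolutionUmPerPx <= 0))
    stop("physical size and resolution must be positive")
  pmax(1L, as.integer(floor(sizeUm / resolutionUmPerPx + 0.5)))
}

#' Generate a non-overlapping patch grid over a tissue mask
#'
#' Lays a regular grid of `patchPx`-sized, non-overlapping tiles over the
#' mask (stride = patch size, anchored at the origin), keeps the anchors
#' whose footprint contains at least `minTissueFraction` tissue, and caps the
#' result at `maxPatches` in row-major order. Deterministic.
#'
#' @param mask logical matrix from [detectTissue()].
#' @param patchPx patch side length in pixels.
#' @param minTissueFraction minimum tissue fraction in [0, 1]; default 0.5.
#' @param maxPatches cap on the number of anchors; default Inf.
#' @return A [TileGrid-class] whose anchor table carries the per-anchor
#'   tissue fraction.
#' @export
#' @examples
#' m <- matrix(TRUE, 100, 100)
#' anchors(generatePatchGrid(m, 50))   # 4 anchors
generatePatchGrid <- function(mask, patchPx, minTissueFraction = 0.5,
                              maxPatches = Inf) {
  mask <- as.matrix(mask)
  if (minTissueFraction < 0 || minTissueFraction > 1)
    stop("minTissueFraction must be in [0, 1]")
  patchPx <- as.integer(patchPx)
  H <- nrow(mask); W <- ncol(mask)
  if (patchPx > H || patchPx > W)
    stop("patch size exceeds the mask dimensions")
  rows <- seq(0L, H - patchPx, by = patchPx)
  cols <- seq(0L, W - patchPx, by = patchPx)
  # summed-area table for O(1) per-anchor tissue fractions
  cs <- apply(apply(mask * 1, 2, cumsum), 1, cumsum)  # cs[j, i] = sum to (i, j)
  boxsum <- function(r, c) {          # 0-based anchor, patchPx extent
    r2 <- r + patchPx; c2 <- c + patchPx
    s <- cs[c2, r2]
    if (r > 0) s <- s - cs[c2, r]
    if (c > 0) s <- s - cs[c, r2]
    if (r > 0 && c > 0) s <- s + cs[c, r]
    s
  }
  out <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  out$tissue_fraction <- mapply(boxsum, out$row, out$col) / patchPx^2
  out <- out[out$tissue_fraction >= minTissueFraction, , drop = FALSE]
  if (nrow(out) > maxPatches) out <- out[seq_len(maxPatches), , drop = FALSE]
  rownames(out) <- NULL
  new("TileGrid", patchPx = patchPx, anchors = out,
      imageDim = c(H, W))
}

.mirror_idx <- function(n, pad) {
  # reflection indices without repeating the edge pixel
  c(seq(pad + 1L, 2L, by = -1L)[seq_len(pad)], seq_len(n),
    seq(n - 1L, by = -1L, length.out = pad))
}

#' Mirror-pad an image or label matrix
#'
#' Pads by reflection without repeating the edge pixel (the first reflected
#' row is the second row of the input). The interior of the output equals the
#' input exactly.
#'
#' @param x [Patch-class], H x W x 3 array, or H x W matrix.
#' @param padPx pad width in pixels on every side; must satisfy
#'   `padPx < min(H, W)`.
#' @return padded object of the same kind as the input pixels.
#' @export
#' @examples
#' m <- matrix(1:9, 3, 3)
#' mirrorPad(m, 1)
mirrorPad <- function(x, padPx) {
  padPx <- as.integer(padPx)
  if (padPx < 0) stop("padPx must be non-negative")
  p <- pixels(x)
  d <- dim(p)
  H <- d[1]; W <- d[2]
  if (padPx >= min(H, W))
    stop("pad width must be smaller than the smallest image dimension")
  if (padPx == 0L) return(p)
  ri <- .mirror_idx(H, padPx)
  ci <- .mirror_idx(W, padPx)
  if (length(d) == 3L) p[ri, ci, , drop = FALSE] else p[ri, ci, drop = FALSE]
}

#' Extract context sub-patches tiling a patch
#'
#' Partitions the patch into non-overlapping `outPx` x `outPx` output windows
#' and returns, for each, the `subPx` x `subPx` sub-patch centered on it. The
#' extra context ring of width `(subPx - outPx)/2` is filled from the parent
#' image where the patch's origin makes that context available, and by
#' mirror reflection where the window runs past the image border.
#'
#' @param x [Patch-class] or H x W x 3 array; H and W must be divisible by
#'   `outPx`.
#' @param subPx sub-patch side (network input size), e.g. 270 or 256.
#' @param outPx output-window side (network output size), e.g. 80 or 164.
#'   `subPx - outPx` must be non-negative and even.
#' @param parent optional full H' x W' x 3 parent image supplying real
#'   context around the patch (the patch's `origin` locates it).
#' @return list of entries with elements `sub` (subPx x subPx x 3 array) and
#'   `anchor` (0-based (row, col) of the output window within the patch).
#' @seealso [stitchOutputs()]
#' @export
extractSubpatches <- function(x, subPx, outPx, parent = NULL) {
  subPx <- as.integer(subPx); outPx <- as.integer(outPx)
  if (outPx <= 0 || subPx < outPx) stop("need subPx >= outPx > 0")
  margin <- (subPx - outPx) / 2
  if (margin != floor(margin))
    stop("subPx - outPx must be even so sub-patches can be centered")
  margin <- as.integer(margin)
  p <- pixels(x)
  d <- dim(p)
  H <- d[1]; W <- d[2]
  if (H %% outPx != 0 || W %% outPx != 0)
    stop("patch dimensions must be divisible by the output window size")
  org <- if (is(x, "Patch")) origin(x) else c(0L, 0L)

  # context canvas: patch plus a margin ring, from the parent where
  # available, mirrored at image borders
  if (margin > 0L) {
    if (!is.null(parent)) {
      pp <- pixels(parent)
      big <- mirrorPad(pp, margin)   # errors if margin too large for parent
      canvas <- big[org[1] + seq_len(H + 2L * margin),
                    org[2] + seq_len(W + 2L * margin), , drop = FALSE]
    } else {
      canvas <- mirrorPad(p, margin)
    }
  } else {
    canvas <- p
  }

  out <- list()
  for (r in seq(0L, H - outPx, by = outPx)) {
    for (cc in seq(0L, W - outPx, by = outPx)) {
      sub <- canvas[r + seq_len(subPx), cc + seq_len(subPx), , drop = FALSE]
      out[[length(out) + 1L]] <- list(sub = sub,
                                      anchor = c(row = r, col = cc))
    }
  }
  out
}

#' Normalize 8-bit channels to [0, 1]
#'
#' @param x [Patch-class] or array in [0, 255].
#' @return numeric array of the same shape with values in [0, 1].
#' @export
#' @examples
#' normalizeChannels(array(51, c(2, 2, 3)))[1]   # 0.2
normalizeChannels <- function(x) {
  pixels(x) / 255
}

#' Stitch per-window outputs into a full-size map
#'
#' Mosaics a list of window outputs back into a single map covering
#' `fullDim`, verifying that the windows tile the extent exactly (each pixel
#' written once, no gaps). For instance label maps (`relabel = TRUE`),
#' per-window labels are offset so instance ids are globally unique, then
#' compacted to be consecutive from 1.
#'
#' @param outputs list of entries with elements `map` (matrix or
#'   H x W x C array) and `anchor` (0-based (row, col)); the shape
#'   [extractSubpatches()] returns with `sub` renamed to `map`.
#' @param fullDim integer (rows, cols) of the stitched map.
#' @param relabel make instance ids globally unique (TRUE, default, for
#'   label maps) or mosaic values untouched (FALSE, for images).
#' @return matrix (or array) of size `fullDim`; an [InstanceMap-class] when
#'   `relabel = TRUE`.
#' @export
stitchOutputs <- function(outputs, fullDim, relabel = TRUE) {
  fullDim <- as.integer(fullDim)
  first <- outputs[[1]]$map
  nd <- length(dim(first))
  if (is.null(dim(first))) stop("window outputs must be matrices or arrays")
  channels <- if (nd == 3L) dim(first)[3] else 1L
  zero <- if (relabel) 0L else vector(typeof(first), 1L)
  full <- array(zero, c(fullDim, channels))
  written <- matrix(FALSE, fullDim[1], fullDim[2])
  offset <- 0L
  for (w in outputs) {
    m <- w$map
    if (length(dim(m)) == 2L) m <- array(m, c(dim(m), 1L))
    a <- as.integer(w$anchor)
    h <- dim(m)[1]; wd <- dim(m)[2]
    if (a[1] < 0 || a[2] < 0 || a[1] + h > fullDim[1] ||
        a[2] + wd > fullDim[2])
      stop("window extends beyond the stitched extent")
    sel_r <- a[1] + seq_len(h); sel_c <- a[2] + seq_len(wd)
    if (any(written[sel_r, sel_c]))
      stop("windows overlap: each pixel must be written exactly once")
    written[sel_r, sel_c] <- TRUE
    if (relabel) {
      lm <- m
      pos <- lm > 0
      if (any(pos)) {
        lm[pos] <- lm[pos] + offset
        offset <- offset + max(m)
      }
      full[sel_r, sel_c, ] <- lm
    } else {
      full[sel_r, sel_c, ] <- m
    }
  }
  if (!all(written))
    stop("windows leave gaps: each pixel must be written exactly once")
  if (channels == 1L) {
    full <- full[, , 1]
    if (relabel) return(InstanceMap(full))
  }
  full
}

#' Read an RGB image from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param resolution micrometers per pixel recorded on the returned patch.
#' @return A [Patch-class] with 8-bit pixel values.
#' @export
readPatch <- function(path, resolution = 0.25) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("reading TIFF requires the 'tiff' package")
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  Patch(round(img * 255), resolution = resolution)
}

#' Write a patch as PNG or TIFF
#'
#' @param x [Patch-class] or H x W x 3 array in [0, 255].
#' @param path output path ending in .png, .tif or .tiff.
#' @return the path, invisibly.
#' @export
writePatch <- function(x, path) {
  img <- pixels(x) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = {
           if (!requireNamespace("tiff", quietly = TRUE))
             stop("writing TIFF requires the 'tiff' package")
           tiff::writeTIFF(img, path, bits.per.sample = 8L)
         },
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Tile an image into tissue patches with a manifest
#'
#' Convenience wrapper: detects tissue, converts the physical patch size to
#' pixels, generates the capped grid and returns the patches plus a manifest
#' table (patch id, anchor, tissue fraction, resolution).
#'
#' @param x [Patch-class] or RGB array of the (low-resolution) image.
#' @param sizeUm physical patch side in micrometers; default 1000.
#' @param resolutionUmPerPx resolution of `x`; taken from the patch when
#'   omitted.
#' @param minTissueFraction minimum tissue fraction; default 0.5.
#' @param maxPatches cap on patches; default 15.
#' @param ... passed to [detectTissue()].
#' @return list with `patches` (list of [Patch-class]) and `manifest`
#'   (data.frame).
#' @export
tilePatches <- function(x, sizeUm = 1000, resolutionUmPerPx = NULL,
                        minTissueFraction = 0.5, maxPatches = 15, ...) {
  if (is.null(resolutionUmPerPx)) {
    if (!is(x, "Patch"))
      stop("resolutionUmPerPx is required for bare arrays")
    resolutionUmPerPx <- resolution(x)
  }
  img <- pixels(x)
  mask <- detectTissue(img, ...)
  px <- patchSizePx(sizeUm, resolutionUmPerPx)
  grid <- generatePatchGrid(mask, px, minTissueFraction, maxPatches)
  a <- anchors(grid)
  patches <- lapply(seq_len(nrow(a)), function(i) {
    Patch(img[a$row[i] + seq_len(px), a$col[i] + seq_len(px), ,
              drop = FALSE],
          resolution = resolutionUmPerPx,
          origin = c(a$row[i], a$col[i]))
  })
  manifest <- data.frame(patch_id = seq_len(nrow(a)),
                         row = a$row, col = a$col,
                         tissue_fraction = a$tissue_fraction,
                         resolution_um_per_px = resolutionUmPerPx)
  list(patches = patches, manifest = manifest)
}
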