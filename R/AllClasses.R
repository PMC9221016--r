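#' @import methods
NULL

#' StainMatrix: stain absorption vectors for color deconvolution
#'
#' A 3x3 matrix whose rows are unit-norm stain absorption vectors over the
#' RGB channels: hematoxylin, eosin and DAB (or a residual third component).
#' Optical densities of a pixel are a non-negative linear combination of the
#' rows, so the inverse matrix projects RGB optical densities onto per-stain
#' densities (color deconvolution).
#'
#' @slot vectors 3x3 numeric matrix; rows = stains, columns = R, G, B.
#'   Rows must have Euclidean norm 1 (tolerance 1e-6) and the matrix must
#'   be invertible.
#' @seealso [heStainMatrix()], [rgbToHed()], [hedToRgb()]
#' @export
setClass("StainMatrix", representation(vectors = "matrix"))

setValidity("StainMatrix", function(object) {
  v <- object@vectors
  if (!is.numeric(v) || !identical(dim(v), c(3L, 3L)))
    return("vectors must be a numeric 3x3 matrix")
  if (any(!is.finite(v)))
    return("vectors must be finite")
  norms <- sqrt(rowSums(v^2))
  if (any(abs(norms - 1) > 1e-6))
    return("each stain vector must have Euclidean norm 1 (tolerance 1e-6)")
  if (abs(det(v)) < 1e-8 || !all(is.finite(solve(v))))
    return("stain matrix must be invertible")
  TRUE
})

#' Construct a StainMatrix
#'
#' Rows are normalized to unit Euclidean norm before validation, so callers
#' may pass unnormalized absorption vectors.
#'
#' @param vectors 3x3 numeric matrix, rows = stains over RGB.
#' @return A [StainMatrix-class] object.
#' @export
#' @examples
#' StainMatrix(diag(3))
StainMatrix <- function(vectors) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("stain vectors must be non-zero")
  vectors <- vectors / norms
  dimnames(vectors) <- list(c("hematoxylin", "eosin", "dab"),
                            c("R", "G", "B"))
  new("StainMatrix", vectors = vectors)
}

#' Default H&E(-DAB) stain matrix
#'
#' The Ruifrok-Johnston absorption vectors for hematoxylin, eosin and DAB,
#' row-normalized to unit length. This is the conventional matrix for color
#' deconvolution of H&E-stained tissue; override it when the scanner or
#' staining protocol calls for calibrated vectors.
#'
#' @return A [StainMatrix-class].
#' @export
#' @examples
#' heStainMatrix()
heStainMatrix <- function() {
  StainMatrix(rbind(
    c(0.65, 0.70, 0.29),
    c(0.07, 0.99, 0.11),
    c(0.27, 0.57, 0.78)))
}

setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix (rows: stains; columns: RGB)\n")
  print(round(object@vectors, 4))
})

#' Accessor for the stain vectors of a StainMatrix
#' @param x A [StainMatrix-class].
#' @return 3x3 numeric matrix.
#' @export
stainVectors <- function(x) {
  stopifnot(is(x, "StainMatrix"))
  x@vectors
}

#' Patch: an RGB image tile with physical-resolution metadata
#'
#' The unit all pipeline stages operate on: an 8-bit RGB pixel array plus the
#' microns-per-pixel resolution and the tile's 0-based (row, col) origin in
#' its parent image.
#'
#' @slot pixels H x W x 3 numeric array with values in [0, 255].
#' @slot resolution positive scalar, micrometers per pixel.
#' @slot origin integer length-2 vector, 0-based (row, col) offset in the
#'   parent image.
#' @seealso [Patch()], [generatePatch()], [extractSubpatches()]
#' @export
setClass("Patch", representation(pixels = "array",
                                 resolution = "numeric",
                                 origin = "integer"))

setValidity("Patch", function(object) {
  p <- object@pixels
  d <- dim(p)
  if (length(d) != 3L || d[3] != 3L) return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("patch must be at least 1 x 1")
  if (any(!is.finite(p)) || min(p) < 0 || max(p) > 255)
    return("pixel values must be finite and within [0, 255]")
  if (length(object@resolution) != 1L || object@resolution <= 0)
    return("resolution must be a positive scalar (um/px)")
  if (length(object@origin) != 2L || any(object@origin < 0L))
    return("origin must be a non-negative (row, col) pair")
  TRUE
})

#' Construct a Patch
#'
#' @param pixels H x W x 3 array in [0, 255], or an H x W matrix which is
#'   replicated to grayscale RGB.
#' @param resolution micrometers per pixel (default 0.25).
#' @param origin 0-based (row, col) offset in the parent image.
#' @return A [Patch-class].
#' @export
#' @examples
#' p <- Patch(array(255, c(8, 8, 3)), resolution = 0.25)
#' dim(pixels(p))
Patch <- function(pixels, resolution = 0.25, origin = c(0L, 0L)) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  storage.mode(pixels) <- "double"
  new("Patch", pixels = pixels, resolution = as.numeric(resolution),
      origin = as.integer(origin))
}

setMethod("show", "Patch", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Patch: %d x %d px, %.4f um/px, origin (%d, %d)\n",
              d[1], d[2], object@resolution,
              object@origin[1], object@origin[2]))
})

#' @describeIn Patch-class pixel array accessor (H x W x 3, values 0-255)
#' @param x A Patch.
#' @export
pixels <- function(x) {
  if (is(x, "Patch")) x@pixels else x
}

#' @describeIn Patch-class resolution accessor (um/px)
#' @export
resolution <- function(x) {
  stopifnot(is(x, "Patch"))
  x@resolution
}

#' @describeIn Patch-class origin accessor (0-based row, col)
#' @export
origin <- function(x) {
  stopifnot(is(x, "Patch"))
  x@origin
}

#' InstanceMap: per-pixel instance labels
#'
#' An H x W integer label image: 0 is background and labels 1..N mark nucleus
#' instances, each a 4-connected component. Labels are consecutive from 1.
#'
#' @slot labels H x W integer matrix.
#' @seealso [InstanceMap()], [recordsFromInstanceMap()], [labelComponents()]
#' @export
setClass("InstanceMap", representation(labels = "matrix"))

setValidity("InstanceMap", function(object) {
  m <- object@labels
  if (!is.integer(m)) return("labels must be an integer matrix")
  if (any(m < 0L)) return("labels must be non-negative")
  u <- sort(unique(as.vector(m[m > 0L])))
  if (length(u) && !identical(u, seq_len(length(u))))
    return("instance labels must be consecutive integers starting at 1")
  TRUE
})

#' Construct an InstanceMap
#'
#' @param labels integer matrix of instance labels (0 = background). Labels
#'   are compacted to be consecutive from 1 if they are not already.
#' @return An [InstanceMap-class].
#' @export
InstanceMap <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  u <- sort(unique(as.vector(labels[labels > 0L])))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  new("InstanceMap", labels = labels)
}

setMethod("show", "InstanceMap", function(object) {
  cat(sprintf("InstanceMap: %d x %d px, %d instances\n",
              nrow(object@labels), ncol(object@labels),
              nInstances(object)))
})

#' @describeIn InstanceMap-class label matrix accessor
#' @param x An InstanceMap (or a bare integer matrix, returned as-is).
#' @export
instanceLabels <- function(x) {
  if (is(x, "InstanceMap")) x@labels else x
}

#' @describeIn InstanceMap-class number of instances
#' @export
nInstances <- function(x) {
  max(0L, instanceLabels(x))
}

#' TileGrid: non-overlapping patch anchors over an image
#'
#' Anchors are 0-based (row, col) top-left corners of half-open
#' `patchPx` x `patchPx` extents, all within the parent image bounds.
#'
#' @slot patchPx integer patch side in pixels.
#' @slot anchors data.frame with columns `row`, `col` (0-based) and
#'   `tissue_fraction`.
#' @slot imageDim integer (rows, cols) of the parent mask/image.
#' @seealso [generatePatchGrid()]
#' @export
setClass("TileGrid", representation(patchPx = "integer",
                                    anchors = "data.frame",
                                    imageDim = "integer"))

setValidity("TileGrid", function(object) {
  a <- object@anchors
  if (!all(c("row", "col") %in% names(a)))
    return("anchors must have 'row' and 'col' columns")
  if (nrow(a)) {
    if (any(a$row < 0) || any(a$col < 0) ||
        any(a$row + object@patchPx > object@imageDim[1]) ||
        any(a$col + object@patchPx > object@imageDim[2]))
      return("anchor extents must lie within the parent image bounds")
    if (anyDuplicated(a[c("row", "col")]))
      return("anchors must be unique")
  }
  TRUE
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d anchors of %d px over a %d x %d image\n",
              nrow(object@anchors), object@patchPx,
              object@imageDim[1], object@imageDim[2]))
})

#' @describeIn TileGrid-class anchor table accessor
#' @param x A TileGrid.
#' @export
anchors <- function(x) {
  stopifnot(is(x, "TileGrid"))
  x@anchors
}
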