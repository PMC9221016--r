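#' @importFrom grDevices rgb2hsv hsv col2rgb
NULL

.as_rgb_array <- function(x) {
  p <- pixels(x)
  d <- dim(p)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected a 3-channel RGB image (H x W x 3)")
  storage.mode(p) <- "double"
  p
}

#' Convert an RGB image to HED optical densities
#'
#' Color deconvolution of an 8-bit RGB image into hematoxylin, eosin and
#' DAB/residual optical densities. Per-channel transmitted intensity I is
#' converted to optical density OD = -log10((I + eps) / (iMax + eps)) — the
#' eps offset avoids log(0) at I = 0 and makes pure white exactly zero OD —
#' and the OD triple is projected through the inverse stain matrix.
#'
#' @param x [Patch-class] or H x W x 3 array with values in [0, 255].
#' @param matrix A [StainMatrix-class]; default [heStainMatrix()].
#' @param eps offset added before the log to avoid log(0); default 1 on the
#'   0-255 scale.
#' @param iMax incident intensity; default 255.
#' @return H x W x 3 array of per-stain optical densities (finite everywhere).
#' @seealso [hedToRgb()], [augmentHed()]
#' @export
#' @examples
#' img <- array(255, c(4, 4, 3))       # pure white
#' range(rgbToHed(img))                # ~0 OD in all stain channels
rgbToHed <- function(x, matrix = heStainMatrix(), eps = 1, iMax = 255) {
  img <- .as_rgb_array(x)
  M <- stainVectors(matrix)
  d <- dim(img)
  od <- -log10((img + eps) / (iMax + eps))
  flat <- base::matrix(od, ncol = 3L)          # columns R, G, B
  hed <- flat %*% solve(M)
  if (any(!is.finite(hed))) stop("deconvolution produced non-finite values")
  array(hed, d)
}

#' Convert HED optical densities back to an RGB image
#'
#' Inverse of [rgbToHed()]: stain densities are recombined through the stain
#' matrix into per-channel optical densities, converted back to transmitted
#' intensities and clipped to the valid 8-bit range.
#'
#' @param hed H x W x 3 array of stain optical densities (finite).
#' @inheritParams rgbToHed
#' @return H x W x 3 array of integers in [0, 255].
#' @export
#' @examples
#' img <- hedToRgb(array(0, c(4, 4, 3)))   # zero absorption -> white
#' stopifnot(all(img == 255))
hedToRgb <- function(hed, matrix = heStainMatrix(), eps = 1, iMax = 255) {
  if (is(hed, "Patch")) hed <- pixels(hed)
  d <- dim(hed)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected a 3-channel HED image (H x W x 3)")
  if (any(!is.finite(hed))) stop("HED optical densities must be finite")
  M <- stainVectors(matrix)
  od <- base::matrix(hed, ncol = 3L) %*% M
  I <- (iMax + eps) * 10^(-od) - eps
  I <- round(pmin(pmax(I, 0), 255))
  array(I, d)
}

#' HED augmentation coefficients
#'
#' Per-channel linear transform parameters for stain-space augmentation:
#' each HED channel c is mapped to alpha_c * OD_c + beta_c, alpha
#' multiplicative (dimensionless) and beta additive in optical-density units.
#'
#' @slot alpha named numeric of length 3 (H, E, D).
#' @slot beta named numeric of length 3 (H, E, D).
#' @export
setClass("HedCoefficients",
         representation(alpha = "numeric", beta = "numeric"))

setValidity("HedCoefficients", function(object) {
  if (length(object@alpha) != 3L || length(object@beta) != 3L)
    return("alpha and beta must each have one value per HED channel")
  if (any(!is.finite(object@alpha)) || any(!is.finite(object@beta)))
    return("coefficients must be finite")
  if (any(object@alpha == 0))
    return("multiplicative coefficients must be non-zero")
  TRUE
})

#' Construct HED augmentation coefficients
#' @param alpha multiplicative coefficients, length 1 or 3 (H, E, D).
#' @param beta additive coefficients in OD units, length 1 or 3.
#' @return A [HedCoefficients-class].
#' @export
#' @examples
#' hedCoefficients()              # identity
#' hedCoefficients(alpha = c(1.05, 1, 1), beta = c(0.02, 0, 0))
hedCoefficients <- function(alpha = 1, beta = 0) {
  alpha <- rep_len(as.numeric(alpha), 3L)
  beta <- rep_len(as.numeric(beta), 3L)
  names(alpha) <- names(beta) <- c("H", "E", "D")
  new("HedCoefficients", alpha = alpha, beta = beta)
}

setMethod("show", "HedCoefficients", function(object) {
  cat("HedCoefficients\n  alpha:",
      paste(sprintf("%s=%.4g", names(object@alpha), object@alpha),
            collapse = " "),
      "\n  beta: ",
      paste(sprintf("%s=%.4g", names(object@beta), object@beta),
            collapse = " "), "\n")
})

.check_range <- function(r, what, exclude_zero = FALSE) {
  r <- as.numeric(r)
  if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
    stop(sprintf("%s must be a non-empty interval c(lo, hi)", what))
  if (exclude_zero && r[1] <= 0 && r[2] >= 0)
    stop(sprintf("%s must exclude 0", what))
  r
}

#' Sample HED augmentation coefficients
#'
#' Draws one multiplicative and one additive coefficient per HED channel,
#' independently and uniformly from the configured intervals. Sampling uses
#' the R random number generator, so results are reproducible under
#' [set.seed()]. Coefficients are sampled once per patch so stain appearance
#' stays consistent within a patch.
#'
#' @param alphaRange interval for the multiplicative coefficient; either
#'   c(lo, hi) shared by all channels or a list of three intervals (H, E, D).
#'   Must exclude 0. Default c(0.95, 1.05).
#' @param betaRange interval for the additive coefficient in OD units, same
#'   conventions. Default c(-0.05, 0.05).
#' @return A [HedCoefficients-class].
#' @export
#' @examples
#' set.seed(1)
#' sampleHedCoefficients()
sampleHedCoefficients <- function(alphaRange = c(0.95, 1.05),
                                  betaRange = c(-0.05, 0.05)) {
  expand <- function(r, what, exclude_zero) {
    if (!is.list(r)) r <- list(r, r, r)
    if (length(r) != 3L)
      stop(sprintf("%s must be one interval or a list of three", what))
    lapply(seq_along(r), function(i)
      .check_range(r[[i]], sprintf("%s[%d]", what, i), exclude_zero))
  }
  a <- expand(alphaRange, "alphaRange", exclude_zero = TRUE)
  b <- expand(betaRange, "betaRange", exclude_zero = FALSE)
  hedCoefficients(
    alpha = vapply(a, function(r) stats::runif(1, r[1], r[2]), 0),
    beta = vapply(b, function(r) stats::runif(1, r[1], r[2]), 0))
}

#' Linear stain-space augmentation
#'
#' Deconvolves an RGB image into HED optical densities, applies the linear
#' per-channel transform alpha * OD + beta, and reconverts to RGB. With
#' identity coefficients the output equals the input up to 8-bit quantization.
#'
#' @inheritParams rgbToHed
#' @param coeffs A [HedCoefficients-class], e.g. from
#'   [sampleHedCoefficients()].
#' @return H x W x 3 RGB array in [0, 255], same shape as the input.
#' @export
#' @examples
#' img <- array(rep(c(180, 120, 160), each = 16), c(4, 4, 3))
#' out <- augmentHed(img, hedCoefficients())   # identity
#' max(abs(out - img)) <= 2
augmentHed <- function(x, coeffs = sampleHedCoefficients(),
                       matrix = heStainMatrix()) {
  stopifnot(is(coeffs, "HedCoefficients"))
  hed <- rgbToHed(x, matrix = matrix)
  for (k in 1:3)
    hed[, , k] <- coeffs@alpha[k] * hed[, , k] + coeffs@beta[k]
  hedToRgb(hed, matrix = matrix)
}

#' Base augmentation policy
#'
#' The photometric/affine augmentation set used for training-time image
#' augmentation: affine transforms (flip, rotation by multiples of 90
#' degrees, scaling) that are applied identically to the image and any paired
#' instance label map, and photometric transforms (gaussian noise, gaussian
#' blur, median blur, brightness, saturation, contrast) applied to the image
#' only.
#'
#' @param transforms character vector of enabled transforms, a subset of
#'   `c("flip", "rotation", "scaling", "gaussian_noise", "gaussian_blur",
#'   "median_blur", "brightness", "saturation", "contrast")`.
#' @param prob named numeric of per-transform application probabilities;
#'   unnamed scalar applies to all. Default 1 (always apply when enabled).
#' @param params named list of per-transform parameter ranges overriding the
#'   defaults: `flip` (directions, subset of horizontal/vertical),
#'   `rotation` (angles, multiples of 90), `scaling` (factor range),
#'   `gaussian_noise` (sd range, 0-255 scale), `gaussian_blur` (sigma range),
#'   `median_blur` (radii), `brightness` (additive range, 0-255 scale),
#'   `saturation` (factor range), `contrast` (factor range).
#' @return A list with class "BaseAugmentationPolicy".
#' @seealso [augmentBase()]
#' @export
baseAugmentationPolicy <- function(transforms = c("flip", "rotation",
                                                  "scaling",
                                                  "gaussian_noise",
                                                  "gaussian_blur",
                                                  "median_blur",
                                                  "brightness", "saturation",
                                                  "contrast"),
                                   prob = 1, params = list()) {
  known <- c("flip", "rotation", "scaling", "gaussian_noise",
             "gaussian_blur", "median_blur", "brightness", "saturation",
             "contrast")
  transforms <- unique(as.character(transforms))
  bad <- setdiff(transforms, known)
  if (length(bad)) stop("unknown transforms: ", paste(bad, collapse = ", "))
  defaults <- list(flip = c("horizontal", "vertical"),
                   rotation = c(90, 180, 270),
                   scaling = c(0.8, 1.25),
                   gaussian_noise = c(0, 8),
                   gaussian_blur = c(0.5, 1.5),
                   median_blur = c(1, 2),
                   brightness = c(-26, 26),
                   saturation = c(0.8, 1.2),
                   contrast = c(0.75, 1.25))
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown parameter ranges: ",
                        paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  if (any(defaults$rotation %% 90 != 0))
    stop("rotation angles must be multiples of 90 degrees")
  if (is.null(names(prob)) && length(prob) == 1L) {
    prob <- stats::setNames(rep(prob, length(transforms)), transforms)
  } else {
    p <- stats::setNames(rep(1, length(transforms)), transforms)
    p[intersect(names(prob), transforms)] <-
      prob[intersect(names(prob), transforms)]
    prob <- p
  }
  if (any(prob < 0 | prob > 1)) stop("probabilities must be in [0, 1]")
  structure(list(transforms = transforms, prob = prob, params = defaults),
            class = "BaseAugmentationPolicy")
}

.rot90 <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

.apply_affine <- function(img, lab, op) {
  chans <- lapply(1:3, function(k) img[, , k])
  if (op$kind == "flip_h") {
    chans <- lapply(chans, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE])
    if (!is.null(lab)) lab <- lab[, rev(seq_len(ncol(lab))), drop = FALSE]
  } else if (op$kind == "flip_v") {
    chans <- lapply(chans, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE])
    if (!is.null(lab)) lab <- lab[rev(seq_len(nrow(lab))), , drop = FALSE]
  } else if (op$kind == "rot90") {
    chans <- lapply(chans, .rot90, k = op$k)
    if (!is.null(lab)) lab <- .rot90(lab, op$k)
  } else if (op$kind == "scale") {
    chans <- lapply(chans, .rescale_to, f = op$f, nearest = FALSE)
    if (!is.null(lab)) lab <- .rescale_to(lab, op$f, nearest = TRUE)
  }
  d <- dim(chans[[1]])
  out <- array(0, c(d, 3L))
  for (k in 1:3) out[, , k] <- chans[[k]]
  list(img = out, lab = lab)
}

# Rescale a matrix by factor f, then center-crop / zero-pad back to the
# original size; nearest-neighbor for label maps.
.rescale_to <- function(m, f, nearest = FALSE) {
  H <- nrow(m); W <- ncol(m)
  nH <- max(1L, round(H * f)); nW <- max(1L, round(W * f))
  r <- EBImage::resize(m, w = nH, h = nW,
                       filter = if (nearest) "none" else "bilinear")
  r <- as.matrix(r)
  if (nearest) storage.mode(r) <- storage.mode(m)
  out <- matrix(if (nearest) 0L else 0, H, W)
  # overlap of the rescaled canvas with the original, both centered
  ro <- max(0L, (nH - H) %/% 2L); co <- max(0L, (nW - W) %/% 2L)
  rt <- max(0L, (H - nH) %/% 2L); ct <- max(0L, (W - nW) %/% 2L)
  h <- min(H, nH); w <- min(W, nW)
  out[rt + seq_len(h), ct + seq_len(w)] <- r[ro + seq_len(h), co + seq_len(w)]
  out
}

.apply_photometric <- function(img, op) {
  if (op$kind == "gaussian_noise") {
    img <- img + array(stats::rnorm(length(img), 0, op$sd), dim(img))
  } else if (op$kind == "gaussian_blur") {
    for (k in 1:3)
      img[, , k] <- as.matrix(EBImage::gblur(img[, , k] / 255,
                                             sigma = op$sigma)) * 255
  } else if (op$kind == "median_blur") {
    for (k in 1:3)
      img[, , k] <- as.matrix(EBImage::medianFilter(
        pmin(pmax(img[, , k] / 255, 0), 1), size = op$size)) * 255
  } else if (op$kind == "brightness") {
    img <- img + op$delta
  } else if (op$kind == "saturation") {
    flat <- base::matrix(pmin(pmax(img, 0), 255), ncol = 3L)
    hsv_ <- grDevices::rgb2hsv(t(flat), maxColorValue = 255)
    hsv_["s", ] <- pmin(pmax(hsv_["s", ] * op$f, 0), 1)
    rgb_ <- grDevices::col2rgb(grDevices::hsv(hsv_["h", ], hsv_["s", ],
                                              hsv_["v", ]))
    img <- array(t(rgb_), dim(img))
  } else if (op$kind == "contrast") {
    mu <- mean(img)
    img <- (img - mu) * op$f + mu
  }
  pmin(pmax(img, 0), 255)
}

#' Apply the base augmentation policy to a patch (and paired label map)
#'
#' Each enabled transform is applied with its configured probability, with
#' parameters sampled from its configured range. Affine members (flip,
#' rotation by multiples of 90 degrees, scaling) transform the image and any
#' paired instance label map with one shared parameter set (nearest-neighbor
#' resampling for labels); photometric members touch the image only. Output
#' pixel values are clipped to [0, 255].
#'
#' @param x [Patch-class] or H x W x 3 RGB array in [0, 255].
#' @param labelMap optional [InstanceMap-class] or integer matrix matching
#'   the image height/width.
#' @param policy A [baseAugmentationPolicy()].
#' @return list with elements `image` (same type as input pixels) and
#'   `labelMap` (NULL if none supplied).
#' @export
#' @examples
#' set.seed(7)
#' img <- array(runif(48, 0, 255), c(4, 4, 3))
#' augmentBase(img, policy = baseAugmentationPolicy("flip"))$image
augmentBase <- function(x, labelMap = NULL,
                        policy = baseAugmentationPolicy()) {
  stopifnot(inherits(policy, "BaseAugmentationPolicy"))
  img <- .as_rgb_array(x)
  lab <- if (is.null(labelMap)) NULL else instanceLabels(labelMap)
  if (!is.null(lab) && !identical(dim(lab), dim(img)[1:2]))
    stop("label map dimensions must match the image")
  pr <- policy$params
  on <- function(name) name %in% policy$transforms &&
    stats::runif(1) < policy$prob[[name]]

  if (on("flip")) {
    dirs <- pr$flip
    dir <- dirs[sample.int(length(dirs), 1L)]
    kind <- if (dir == "horizontal") "flip_h" else "flip_v"
    res <- .apply_affine(img, lab, list(kind = kind))
    img <- res$img; lab <- res$lab
  }
  if (on("rotation")) {
    ang <- pr$rotation[sample.int(length(pr$rotation), 1L)]
    res <- .apply_affine(img, lab, list(kind = "rot90",
                                        k = as.integer(ang / 90) %% 4L))
    img <- res$img; lab <- res$lab
  }
  if (on("scaling")) {
    f <- stats::runif(1, pr$scaling[1], pr$scaling[2])
    res <- .apply_affine(img, lab, list(kind = "scale", f = f))
    img <- res$img; lab <- res$lab
  }
  if (on("gaussian_noise"))
    img <- .apply_photometric(img, list(kind = "gaussian_noise",
                                        sd = stats::runif(1,
                                                          pr$gaussian_noise[1],
                                                          pr$gaussian_noise[2])))
  if (on("gaussian_blur"))
    img <- .apply_photometric(img, list(kind = "gaussian_blur",
                                        sigma = stats::runif(1,
                                                             pr$gaussian_blur[1],
                                                             pr$gaussian_blur[2])))
  if (on("median_blur"))
    img <- .apply_photometric(img, list(
      kind = "median_blur",
      size = pr$median_blur[sample.int(length(pr$median_blur), 1L)]))
  if (on("brightness"))
    img <- .apply_photometric(img, list(kind = "brightness",
                                        delta = stats::runif(1,
                                                             pr$brightness[1],
                                                             pr$brightness[2])))
  if (on("saturation"))
    img <- .apply_photometric(img, list(kind = "saturation",
                                        f = stats::runif(1, pr$saturation[1],
                                                         pr$saturation[2])))
  if (on("contrast"))
    img <- .apply_photometric(img, list(kind = "contrast",
                                        f = stats::runif(1, pr$contrast[1],
                                                         pr$contrast[2])))
  img <- pmin(pmax(img, 0), 255)
  list(image = img,
       labelMap = if (is.null(labelMap)) NULL else
         if (is(labelMap, "InstanceMap")) InstanceMap(lab) else lab)
}
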