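#' Specification for a synthetic H&E-like patch
#'
#' Describes the study-like content of one generated patch: elliptical
#' nuclei of the canonical classes with class-dependent size, shape and
#' stain intensity, rendered through the stain model onto an eosin-tinted
#' background. Defaults emulate lung-tissue patches at 0.25 um/px:
#' inflammatory nuclei are small, round and strongly hematoxylin-stained;
#' cancer nuclei are large; "other" (stromal) nuclei are elongated.
#'
#' @param sizePx patch side in pixels; default 256.
#' @param resolution um/px; default 0.25.
#' @param nuclei named list (classes) of lists with elements `n` (count),
#'   `radius` (major-semiaxis range, px), `axisRatio` (minor/major range),
#'   `hOd` (mean hematoxylin OD range) and `eOd` (eosin OD range).
#' @param backgroundEOd eosin OD of the background tissue; default 0.08.
#' @param noiseSd Gaussian pixel-noise standard deviation on the 0-255
#'   scale; default 2.
#' @param minSeparation extra gap (px) enforced between nucleus borders;
#'   default 4.
#' @param seed optional integer seed (see [generatePatch()]).
#' @param maxAttempts rejection-sampling budget per nucleus; default 10000.
#' @return list with class "PatchSpec".
#' @export
patchSpec <- function(sizePx = 256, resolution = 0.25,
                      nuclei = list(
                        inflammatory = list(n = 12, radius = c(3.5, 5),
                                            axisRatio = c(0.75, 1),
                                            hOd = c(0.85, 1.0),
                                            eOd = c(0.05, 0.15)),
                        cancer = list(n = 6, radius = c(7.5, 10),
                                      axisRatio = c(0.8, 1),
                                      hOd = c(0.45, 0.65),
                                      eOd = c(0.1, 0.2)),
                        other = list(n = 4, radius = c(7, 9),
                                     axisRatio = c(0.3, 0.42),
                                     hOd = c(0.6, 0.8),
                                     eOd = c(0.1, 0.2))),
                      backgroundEOd = 0.08, noiseSd = 2,
                      minSeparation = 4, seed = NULL,
                      maxAttempts = 10000) {
  if (sizePx < 16) stop("patch must be at least 16 px")
  if (is.null(names(nuclei)) || any(!nzchar(names(nuclei))))
    stop("nuclei must be a named list of class specifications")
  for (nm in names(nuclei)) {
    sp <- nuclei[[nm]]
    need <- c("n", "radius", "axisRatio", "hOd", "eOd")
    miss <- setdiff(need, names(sp))
    if (length(miss))
      stop(sprintf("class '%s' is missing: %s", nm,
                   paste(miss, collapse = ", ")))
    if (sp$n < 0) stop("nucleus counts must be non-negative")
    if (max(sp$radius) * 2 + 4 > sizePx)
      stop(sprintf("class '%s' nuclei do not fit in the patch", nm))
  }
  structure(list(sizePx = as.integer(sizePx), resolution = resolution,
                 nuclei = nuclei, backgroundEOd = backgroundEOd,
                 noiseSd = noiseSd, minSeparation = minSeparation,
                 seed = seed, maxAttempts = maxAttempts),
            class = "PatchSpec")
}

.ellipse_pixels <- function(H, W, cx, cy, a, b, theta) {
  # 1-based pixel (row, col) indices inside the rotated ellipse
  rr <- max(1L, floor(cx - a)):min(H, ceiling(cx + a))
  cc <- max(1L, floor(cy - a)):min(W, ceiling(cy + a))
  g <- expand.grid(r = rr, c = cc)
  u <- (g$r - cx) * cos(theta) + (g$c - cy) * sin(theta)
  v <- -(g$r - cx) * sin(theta) + (g$c - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(g$r[inside], g$c[inside])
}

#' Generate a synthetic H&E-like patch with exact ground truth
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, renders
#' them through the stain model ([hedToRgb()]; nuclei carry hematoxylin and
#' eosin optical density, the background only eosin) and adds Gaussian pixel
#' noise. The instance map and cell records are exact by construction. Fully
#' reproducible: a non-NULL `seed` in the spec seeds the generator.
#'
#' @param spec A [patchSpec()].
#' @return list with `patch` ([Patch-class]), `instanceMap`
#'   ([InstanceMap-class]) and `records` ([cellRecords()]).
#' @export
#' @examples
#' out <- generatePatch(patchSpec(sizePx = 128, seed = 1,
#'   nuclei = list(inflammatory = list(n = 5, radius = c(3.5, 5),
#'     axisRatio = c(0.75, 1), hOd = c(0.85, 1), eOd = c(0.05, 0.15)))))
#' nrow(out$records)   # 5
generatePatch <- function(spec) {
  stopifnot(inherits(spec, "PatchSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- spec$sizePx; W <- spec$sizePx
  lab <- matrix(0L, H, W)
  hod <- matrix(0, H, W)
  eod <- matrix(spec$backgroundEOd, H, W)
  placed <- data.frame(cx = numeric(), cy = numeric(), a = numeric())
  classes <- character()
  nextLabel <- 0L
  for (nm in names(spec$nuclei)) {
    sp <- spec$nuclei[[nm]]
    for (k in seq_len(sp$n)) {
      ok <- FALSE
      for (att in seq_len(spec$maxAttempts)) {
        a <- stats::runif(1, sp$radius[1], sp$radius[2])
        b <- a * stats::runif(1, sp$axisRatio[1], sp$axisRatio[2])
        cx <- stats::runif(1, a + 2, H - a - 1)
        cy <- stats::runif(1, a + 2, W - a - 1)
        if (nrow(placed)) {
          dd <- sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2)
          if (any(dd < placed$a + a + spec$minSeparation)) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "could not place nucleus %d of class '%s' within %d attempts; ",
          k, nm, spec$maxAttempts),
          "reduce counts or sizes in the patch spec")
      theta <- stats::runif(1, 0, pi)
      px <- .ellipse_pixels(H, W, cx, cy, a, b, theta)
      nextLabel <- nextLabel + 1L
      lab[px] <- nextLabel
      hod[px] <- stats::runif(1, sp$hOd[1], sp$hOd[2])
      eod[px] <- stats::runif(1, sp$eOd[1], sp$eOd[2])
      placed <- rbind(placed, data.frame(cx = cx, cy = cy, a = a))
      classes <- c(classes, nm)
    }
  }
  od <- array(0, c(H, W, 3))
  od[, , 1] <- hod
  od[, , 2] <- eod
  rgb <- hedToRgb(od)
  if (spec$noiseSd > 0)
    rgb <- rgb + array(stats::rnorm(length(rgb), 0, spec$noiseSd), dim(rgb))
  rgb <- round(pmin(pmax(rgb, 0), 255))
  map <- InstanceMap(lab)
  records <- if (nextLabel > 0L)
    recordsFromInstanceMap(map, classes) else cellRecords()
  list(patch = Patch(rgb, resolution = spec$resolution),
       instanceMap = map, records = records)
}

.per_class <- function(x, classes, default = 0) {
  out <- stats::setNames(rep(default, length(classes)), classes)
  if (is.null(names(x))) {
    out[] <- rep_len(x, length(classes))
  } else {
    out[intersect(names(x), classes)] <- x[intersect(names(x), classes)]
  }
  out
}

#' Corrupt ground-truth records into predictions with known confusion
#'
#' Builds a prediction set from ground truth by (in order) dropping a
#' fraction of each class, relabeling a fraction of the kept cells,
#' jittering centroids, and adding spurious detections, while recording
#' exactly which cells were dropped, relabeled or invented. The implied
#' TP/FP/FN/TN per class follows in closed form from this bookkeeping and is
#' returned alongside, so evaluation output can be checked by integer
#' equality.
#'
#' The bookkeeping equals the evaluator's output provided matching pairs
#' every kept prediction with its own source cell: ground-truth centroids
#' must be mutually separated by more than the matching radius plus
#' `jitterPx`, `jitterPx` must not exceed the radius, and spurious cells are
#' kept at least `spuriousMinDist` (> radius) from every ground-truth
#' centroid.
#'
#' @param gt [cellRecords()] ground truth.
#' @param dropFraction fraction of cells to drop; scalar or named per class.
#' @param misclassFraction fraction of kept cells to relabel; scalar, named
#'   per source class, or a from x to matrix with named dimensions.
#'   Non-matrix forms relabel to a uniformly random other class.
#' @param jitterPx maximum absolute centroid perturbation per axis (uniform);
#'   default 0.
#' @param spuriousCount number of invented detections; default 0.
#' @param imageDim (rows, cols) bounds for spurious placement; required when
#'   `spuriousCount > 0`.
#' @param classes class universe; default the canonical three.
#' @param spuriousMinDist minimum distance from spurious cells to any
#'   ground-truth centroid; default 30 px.
#' @param seed optional integer seed.
#' @return list with `records` (the corrupted predictions) and
#'   `bookkeeping` (per class: TP, FP, FN, TN).
#' @export
corruptPredictions <- function(gt, dropFraction = 0, misclassFraction = 0,
                               jitterPx = 0, spuriousCount = 0,
                               imageDim = NULL,
                               classes = c("cancer", "inflammatory",
                                           "other"),
                               spuriousMinDist = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drop_ <- .per_class(dropFraction, classes)
  if (any(drop_ < 0 | drop_ > 1)) stop("drop fractions must be in [0, 1]")
  if (is.matrix(misclassFraction)) {
    mis <- misclassFraction
    if (is.null(rownames(mis)) || is.null(colnames(mis)))
      stop("a misclassification matrix needs named rows (from) and columns (to)")
    if (any(mis < 0) || any(rowSums(mis) > 1))
      stop("misclassification fractions per source class must sum to <= 1")
  } else {
    mm <- .per_class(misclassFraction, classes)
    if (any(mm < 0 | mm > 1)) stop("misclass fractions must be in [0, 1]")
    mis <- NULL
  }

  keep <- gt
  dropped <- gt[0, ]
  for (cl in classes) {
    idx <- which(keep$class == cl)
    nd <- round(drop_[[cl]] * length(idx))
    if (nd > 0) {
      sel <- idx[sample.int(length(idx), nd)]
      dropped <- rbind(dropped, keep[sel, ])
      keep <- keep[-sel, , drop = FALSE]
    }
  }

  pred <- keep
  pred$gt_class <- pred$class
  if (nrow(pred)) {
    if (!is.null(mis)) {
      for (from in rownames(mis)) for (to in colnames(mis)) {
        if (from == to || mis[from, to] == 0) next
        idx <- which(pred$gt_class == from & pred$class == pred$gt_class)
        nmis <- round(mis[from, to] * sum(pred$gt_class == from))
        nmis <- min(nmis, length(idx))
        if (nmis > 0)
          pred$class[idx[sample.int(length(idx), nmis)]] <- to
      }
    } else {
      for (cl in classes) {
        idx <- which(pred$gt_class == cl)
        nmis <- round(mm[[cl]] * length(idx))
        if (nmis > 0) {
          sel <- idx[sample.int(length(idx), nmis)]
          others <- setdiff(classes, cl)
          pred$class[sel] <- others[sample.int(length(others), nmis,
                                               replace = TRUE)]
        }
      }
    }
    if (jitterPx > 0) {
      pred$row <- pred$row + stats::runif(nrow(pred), -jitterPx, jitterPx)
      pred$col <- pred$col + stats::runif(nrow(pred), -jitterPx, jitterPx)
    }
  }

  spurious <- gt[0, ]
  if (spuriousCount > 0) {
    if (is.null(imageDim))
      stop("imageDim is required to place spurious detections")
    for (k in seq_len(spuriousCount)) {
      ok <- FALSE
      for (att in 1:10000) {
        r <- stats::runif(1, 0, imageDim[1] - 1)
        cc <- stats::runif(1, 0, imageDim[2] - 1)
        ref <- rbind(cbind(gt$row, gt$col),
                     cbind(spurious$row, spurious$col))
        if (nrow(ref) == 0 ||
            min(sqrt((ref[, 1] - r)^2 + (ref[, 2] - cc)^2)) >=
              spuriousMinDist) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place spurious detections at the required distance")
      spurious <- rbind(spurious, cellRecords(
        0L, r, cc, classes[sample.int(length(classes), 1L)], 0L))
    }
  }

  bookkeeping <- lapply(classes, function(t) {
    list(class = t,
         TP = sum(pred$gt_class == t & pred$class == t),
         FP = sum(pred$gt_class != t & pred$class == t) +
           sum(spurious$class == t),
         FN = sum(pred$gt_class == t & pred$class != t) +
           sum(dropped$class == t),
         TN = sum(pred$gt_class != t & pred$class != t) +
           sum(spurious$class != t))
  })
  names(bookkeeping) <- classes

  pred$gt_class <- NULL
  out <- rbind(pred, spurious)
  out$instance_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(records = out, bookkeeping = bookkeeping)
}

#' Specification for a synthetic survival cohort
#'
#' Emulates a TIL-validation cohort: 87 patients by default, each with a
#' handful of tumor-border patches (median 15, range 3-16), per-patch TIL
#' counts that are negative-binomially distributed with a group-dependent
#' mean (overdispersion is typical of cell counts), exponential
#' disease-specific survival with a planted hazard ratio for the high-TIL
#' group, and independent uniform censoring calibrated to a target rate.
#'
#' @param nPatients number of patients; default 87.
#' @param patchValues,patchProbs distribution of patches per patient;
#'   defaults put mass 0.55 on 15 and 0.12 on 16 with the rest spread over
#'   3-14, giving median 15 and range within 3-16.
#' @param tilMean named per-group negative-binomial mean TIL count per
#'   patch; default c(low = 6, high = 25).
#' @param tilDispersion negative-binomial size (dispersion); default 3.
#' @param pHigh probability a patient is in the high-TIL group; default 0.5.
#' @param baselineHazard events per month in the low group; default 0.012
#'   (median survival about 58 months).
#' @param hazardRatio planted hazard ratio of the high group relative to
#'   low (> 0); default 0.3 (strongly protective TILs).
#' @param censoringRate target fraction of censored patients in [0, 1);
#'   default 0.3.
#' @param seed optional integer seed.
#' @return list with class "CohortSpec".
#' @export
cohortSpec <- function(nPatients = 87,
                       patchValues = 3:16,
                       patchProbs = c(rep(0.33 / 12, 12), 0.55, 0.12),
                       tilMean = c(low = 6, high = 25),
                       tilDispersion = 3, pHigh = 0.5,
                       baselineHazard = 0.012, hazardRatio = 0.3,
                       censoringRate = 0.3, seed = NULL) {
  if (nPatients < 2) stop("need at least two patients")
  if (length(patchValues) != length(patchProbs))
    stop("patchValues and patchProbs must have the same length")
  if (hazardRatio <= 0) stop("hazard ratio must be positive")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoring rate must be in [0, 1)")
  tilMean <- unlist(tilMean)   # accept list input (e.g. from YAML profiles)
  if (!all(c("low", "high") %in% names(tilMean)))
    stop("tilMean must have 'low' and 'high' entries")
  structure(list(nPatients = as.integer(nPatients),
                 patchValues = patchValues,
                 patchProbs = patchProbs / sum(patchProbs),
                 tilMean = tilMean, tilDispersion = tilDispersion,
                 pHigh = pHigh, baselineHazard = baselineHazard,
                 hazardRatio = hazardRatio, censoringRate = censoringRate,
                 seed = seed),
            class = "CohortSpec")
}

#' Generate a synthetic survival cohort
#'
#' Draws group membership, per-patient patch counts, per-patch TIL counts
#' (negative binomial with group-dependent mean) and exponential survival
#' times with hazard `baselineHazard * hazardRatio^(group == high)`.
#' Censoring times are uniform on (0, u) with u solved so the expected
#' censoring fraction matches the spec. Reproducible per seed.
#'
#' @param spec A [cohortSpec()].
#' @return long-format data.frame with columns patient_id, patch_id,
#'   til_count, time_months, event and true_group (the planted group, for
#'   recovery experiments; not used by the analysis).
#' @export
#' @examples
#' co <- generateCohort(cohortSpec(nPatients = 10, seed = 1))
#' head(co)
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$nPatients
  group <- ifelse(stats::runif(n) < spec$pHigh, "high", "low")
  rate <- spec$baselineHazard * spec$hazardRatio^(group == "high")
  eventTime <- stats::rexp(n, rate = rate)
  event <- rep(1L, n)
  time <- eventTime
  if (spec$censoringRate > 0) {
    censFrac <- function(u) mean((1 - exp(-rate * u)) / (rate * u))
    u <- stats::uniroot(function(u) censFrac(u) - spec$censoringRate,
                        lower = 1e-6, upper = 1e8, tol = 1e-10)$root
    cens <- stats::runif(n, 0, u)
    event <- as.integer(eventTime <= cens)
    time <- pmin(eventTime, cens)
  }
  k <- sample(spec$patchValues, n, replace = TRUE, prob = spec$patchProbs)
  ids <- sprintf("P%03d", seq_len(n))
  idx <- rep.int(seq_len(n), k)
  data.frame(patient_id = ids[idx],
             patch_id = sequence(k),
             til_count = stats::rnbinom(length(idx),
                                        mu = spec$tilMean[group][idx],
                                        size = spec$tilDispersion),
             time_months = time[idx],
             event = event[idx],
             true_group = group[idx],
             stringsAsFactors = FALSE)
}
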