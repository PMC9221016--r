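#' Label 4-connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix.
#' @return An [InstanceMap-class] with consecutive labels.
#' @export
labelComponents <- function(mask) {
  mask <- as.matrix(mask) > 0
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  InstanceMap(lab)
}

#' Construct a cell-record table
#'
#' The tabular contract between the detector, the evaluator and external
#' tools: one row per cell with its instance id, 0-based centroid, class
#' label and pixel area.
#'
#' @param instance_id integer ids.
#' @param row,col numeric centroid coordinates (0-based pixels).
#' @param class character class labels.
#' @param area integer pixel areas.
#' @return data.frame with columns instance_id, row, col, class, area.
#' @export
cellRecords <- function(instance_id = integer(), row = numeric(),
                        col = numeric(), class = character(),
                        area = integer()) {
  df <- data.frame(instance_id = as.integer(instance_id),
                   row = as.numeric(row), col = as.numeric(col),
                   class = as.character(class), area = as.integer(area),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$area < 0)) stop("areas must be non-negative")
  df
}

.instance_stats <- function(lab) {
  # per-label pixel count, centroid (0-based) and moment eccentricity
  pos <- which(lab > 0L)
  if (!length(pos))
    return(data.frame(instance_id = integer(), row = numeric(),
                      col = numeric(), area = integer(), ecc = numeric()))
  H <- nrow(lab)
  ids <- lab[pos]
  r <- (pos - 1L) %% H          # 0-based row
  cc <- (pos - 1L) %/% H        # 0-based col
  n <- tabulate(ids)
  sr <- tapply(r, ids, sum); sc <- tapply(cc, ids, sum)
  mr <- sr / n; mc <- sc / n
  srr <- tapply(r^2, ids, sum); scc <- tapply(cc^2, ids, sum)
  src <- tapply(r * cc, ids, sum)
  u20 <- srr / n - mr^2
  u02 <- scc / n - mc^2
  u11 <- src / n - mr * mc
  disc <- sqrt(pmax((u20 - u02)^2 + 4 * u11^2, 0))
  l1 <- (u20 + u02 + disc) / 2
  l2 <- (u20 + u02 - disc) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  data.frame(instance_id = sort(unique(ids)), row = as.numeric(mr),
             col = as.numeric(mc), area = as.integer(n),
             ecc = as.numeric(ecc))
}

#' Build cell records from an instance map
#'
#' Centroid = mean pixel coordinate (0-based), area = pixel count.
#'
#' @param map An [InstanceMap-class] or integer label matrix.
#' @param classMap character vector of class labels, one per instance label
#'   1..N (named or positional).
#' @return [cellRecords()] data.frame, one row per instance.
#' @export
#' @examples
#' m <- matrix(0L, 5, 5); m[1:3, 1:3] <- 1L
#' recordsFromInstanceMap(m, "inflammatory")   # centroid (1, 1), area 9
recordsFromInstanceMap <- function(map, classMap) {
  lab <- instanceLabels(map)
  n <- max(0L, lab)
  if (n == 0L) return(cellRecords())
  if (!is.null(names(classMap))) {
    cls <- classMap[as.character(seq_len(n))]
  } else {
    cls <- rep_len(as.character(classMap), n)
  }
  if (any(is.na(cls)))
    stop("classMap must provide a class for every instance label")
  st <- .instance_stats(lab)
  cellRecords(st$instance_id, st$row, st$col, cls[st$instance_id], st$area)
}

#' Class scheme: mapping dataset classes to canonical labels
#'
#' Nucleus-classification datasets use different class vocabularies; for TIL
#' quantification every class is mapped onto the canonical set
#' \{cancer, inflammatory, other\}. Because the CoNSeP and MoNuSAC
#' vocabularies do not separate normal from neoplastic epithelium, both
#' normal-epithelial and neoplastic cells map to "cancer".
#'
#' @param scheme one of "canonical", "pannuke", "consep", "monusac", or a
#'   named character vector mapping class names to canonical labels.
#' @return named character vector with class "ClassScheme"; values are all
#'   in \{cancer, inflammatory, other\}.
#' @export
#' @examples
#' classScheme("pannuke")[["neoplastic"]]   # "cancer"
classScheme <- function(scheme = "canonical") {
  if (is.character(scheme) && length(scheme) == 1L && is.null(names(scheme))) {
    scheme <- switch(scheme,
      canonical = c(cancer = "cancer", inflammatory = "inflammatory",
                    other = "other"),
      pannuke = c(neoplastic = "cancer", epithelial = "cancer",
                  inflammatory = "inflammatory", connective = "other",
                  dead = "other"),
      consep = c("normal-epithelial" = "cancer",
                 "malignant-epithelial" = "cancer",
                 inflammatory = "inflammatory", fibroblast = "other",
                 muscle = "other", endothelial = "other", other = "other"),
      monusac = c(epithelial = "cancer", lymphocyte = "inflammatory",
                  neutrophil = "inflammatory", macrophage = "inflammatory"),
      stop("unknown scheme: ", scheme))
  }
  scheme <- vapply(scheme, as.character, "")
  if (is.null(names(scheme)) || any(!nzchar(names(scheme))))
    stop("a custom scheme must be a fully named character vector")
  bad <- setdiff(unique(scheme), c("cancer", "inflammatory", "other"))
  if (length(bad))
    stop("canonical labels must be cancer/inflammatory/other; got: ",
         paste(bad, collapse = ", "))
  structure(scheme, class = "ClassScheme")
}

#' Harmonize record classes onto the canonical labels
#'
#' Replaces each record's class by its canonical \{cancer, inflammatory,
#' other\} label under the given scheme. The number of records never changes
#' and the operation is idempotent when the scheme fixes canonical labels.
#'
#' @param records [cellRecords()] data.frame.
#' @param scheme A [classScheme()] (or argument accepted by it).
#' @return the records with canonical class labels.
#' @export
harmonizeClasses <- function(records, scheme = "canonical") {
  if (!inherits(scheme, "ClassScheme")) scheme <- classScheme(scheme)
  if (!nrow(records)) return(records)
  unknown <- setdiff(unique(records$class), names(scheme))
  if (length(unknown))
    stop("classes not covered by the scheme: ",
         paste(unknown, collapse = ", "))
  records$class <- unname(scheme[records$class])
  records
}

#' Default parameters for the baseline detector
#'
#' @param hThreshold hematoxylin OD above which a pixel is nuclear;
#'   default 0.3.
#' @param minAreaPx2 minimum instance area in px^2 at `refResolution`;
#'   default 30.
#' @param inflamMaxAreaPx2 area below which a round, strongly stained
#'   nucleus is called inflammatory; default 120 px^2 at `refResolution`.
#' @param inflamMaxEcc eccentricity bound for inflammatory; default 0.8.
#' @param inflamMinHOd minimum mean hematoxylin OD for inflammatory;
#'   default 0.4.
#' @param refResolution resolution (um/px) the area thresholds refer to;
#'   default 0.25. Thresholds are rescaled to the patch resolution.
#' @return named list of parameters.
#' @export
baselineParams <- function(hThreshold = 0.3, minAreaPx2 = 30,
                           inflamMaxAreaPx2 = 120, inflamMaxEcc = 0.8,
                           inflamMinHOd = 0.4, refResolution = 0.25) {
  list(hThreshold = hThreshold, minAreaPx2 = minAreaPx2,
       inflamMaxAreaPx2 = inflamMaxAreaPx2, inflamMaxEcc = inflamMaxEcc,
       inflamMinHOd = inflamMinHOd, refResolution = refResolution)
}

#' Rule-based baseline cell detector
#'
#' A deterministic, fully self-contained detector so the evaluation and
#' cohort stages can run end-to-end without a trained model: threshold the
#' hematoxylin channel of the color-deconvolved patch, fill holes, label
#' 4-connected components, drop instances below the minimum area, then
#' classify each instance by size, eccentricity and mean hematoxylin OD —
#' small round strongly stained nuclei are inflammatory, large nuclei are
#' cancer, the rest (e.g. elongated stromal nuclei) are other.
#'
#' This is a morphology heuristic, not a learned model; it is intended as
#' the pluggable-detector reference implementation and for testing.
#'
#' @param x [Patch-class] or H x W x 3 RGB array in [0, 255].
#' @param params [baselineParams()].
#' @param matrix [StainMatrix-class] for the deconvolution.
#' @return list with `instanceMap` ([InstanceMap-class]) and `records`
#'   ([cellRecords()]).
#' @export
detectCellsBaseline <- function(x, params = baselineParams(),
                                matrix = heStainMatrix()) {
  img <- .as_rgb_array(x)
  res <- if (is(x, "Patch")) resolution(x) else params$refResolution
  scale2 <- (params$refResolution / res)^2
  h <- rgbToHed(img, matrix = matrix)[, , 1]
  bw <- h > params$hThreshold
  bw <- as.matrix(EBImage::fillHull(bw * 1)) > 0
  lab <- instanceLabels(labelComponents(bw))
  n <- max(0L, lab)
  if (n == 0L)
    return(list(instanceMap = InstanceMap(lab), records = cellRecords()))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas >= params$minAreaPx2 * scale2)
  if (!length(keep))
    return(list(instanceMap = InstanceMap(matrix(0L, nrow(lab), ncol(lab))),
                records = cellRecords()))
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  st <- .instance_stats(lab)
  meanH <- as.numeric(tapply(h[lab > 0L], lab[lab > 0L], mean))
  cls <- ifelse(st$area >= params$inflamMaxAreaPx2 * scale2, "cancer",
         ifelse(st$ecc < params$inflamMaxEcc &
                  meanH > params$inflamMinHOd, "inflammatory", "other"))
  list(instanceMap = InstanceMap(lab),
       records = cellRecords(st$instance_id, st$row, st$col, cls, st$area))
}

#' Read / write cell records as CSV
#'
#' The CSV contract (columns instance_id, row, col, class, area) lets
#' externally trained detectors feed the evaluation and cohort stages
#' without code changes.
#'
#' @param path CSV file path.
#' @return [cellRecords()] data.frame.
#' @export
readCellRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("instance_id", "row", "col", "class", "area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell-record CSV is missing columns: ", paste(miss, collapse = ", "))
  cellRecords(df$instance_id, df$row, df$col, df$class, df$area)
}

#' @rdname readCellRecords
#' @param records [cellRecords()] data.frame.
#' @export
writeCellRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write cell records as GeoJSON
#'
#' Emits a FeatureCollection interoperable with common pathology viewers:
#' one feature per cell with a "classification" property. With an instance
#' map, each feature's geometry is the convex-hull polygon of the instance's
#' pixels; otherwise a point at the centroid. Coordinates are (x, y) =
#' (col, row) in pixels.
#'
#' @param records [cellRecords()] data.frame.
#' @param path output path.
#' @param map optional [InstanceMap-class] for polygon geometries.
#' @export
writeCellRecordsGeoJSON <- function(records, path, map = NULL) {
  features <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    geom <- NULL
    if (!is.null(map)) {
      lab <- instanceLabels(map)
      pos <- which(lab == rec$instance_id)
      if (length(pos) >= 3L) {
        H <- nrow(lab)
        xy <- cbind(x = (pos - 1L) %/% H, y = (pos - 1L) %% H)
        hull <- xy[grDevices::chull(xy), , drop = FALSE]
        ring <- rbind(hull, hull[1, , drop = FALSE])
        geom <- list(type = "Polygon",
                     coordinates = list(lapply(seq_len(nrow(ring)),
                       function(k) c(ring[k, 1], ring[k, 2]))))
      }
    }
    if (is.null(geom))
      geom <- list(type = "Point", coordinates = c(rec$col, rec$row))
    list(type = "Feature", geometry = geom,
         properties = list(instance_id = rec$instance_id,
                           classification = list(name = rec$class),
                           area = rec$area))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an instance map as PNG
#'
#' Labels up to 65535 are stored losslessly by splitting each 16-bit id into
#' a high and a low byte carried in the red and green channels.
#'
#' @param map [InstanceMap-class] or integer matrix (labels must fit in
#'   16 bits).
#' @param path PNG path.
#' @export
writeInstanceMap <- function(map, path) {
  lab <- instanceLabels(map)
  if (max(0L, lab) > 65535L) stop("labels exceed 16-bit range")
  d <- dim(lab)
  img <- array(0, c(d, 3L))
  img[, , 1] <- (lab %/% 256L) / 255
  img[, , 2] <- (lab %% 256L) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname writeInstanceMap
#' @export
readInstanceMap <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 2L)
    stop("not an instance-map PNG (expected high/low byte channels)")
  lab <- round(img[, , 1] * 255) * 256L + round(img[, , 2] * 255)
  InstanceMap(matrix(as.integer(lab), dim(img)[1], dim(img)[2]))
}
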