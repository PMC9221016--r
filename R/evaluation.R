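#' Match predicted to ground-truth cells by centroid distance
#'
#' One-to-one assignment between predicted and ground-truth cell centroids:
#' only pairs within `radiusPx` are eligible, the number of matches is
#' maximized, and among maximum matchings the total centroid distance is
#' minimized (optimal assignment, not greedy). Records are processed in
#' (gt id, pred id) order so ties resolve deterministically.
#'
#' @param pred,gt [cellRecords()] data.frames.
#' @param radiusPx matching radius in pixels (> 0). The convention is a
#'   physical radius converted via the patch resolution, e.g. 3 um = 12 px
#'   at 0.25 um/px; see [radiusPxFromUm()].
#' @return list with `pairs` (data.frame pred_id, gt_id, distance),
#'   `unmatchedPred`, `unmatchedGt` (integer id vectors) and `radiusPx`.
#' @export
matchCells <- function(pred, gt, radiusPx) {
  if (radiusPx <= 0) stop("matching radius must be positive")
  pred <- pred[order(pred$instance_id), , drop = FALSE]
  gt <- gt[order(gt$instance_id), , drop = FALSE]
  np <- nrow(pred); ng <- nrow(gt)
  empty <- data.frame(pred_id = integer(), gt_id = integer(),
                      distance = numeric())
  if (np == 0L || ng == 0L)
    return(list(pairs = empty, unmatchedPred = pred$instance_id,
                unmatchedGt = gt$instance_id, radiusPx = radiusPx))
  d <- sqrt(outer(pred$row, gt$row, "-")^2 + outer(pred$col, gt$col, "-")^2)
  N <- max(np, ng)
  penalty <- radiusPx * (N + 1)     # exceeds any feasible total distance
  C <- matrix(penalty, N, N)
  C[seq_len(np), seq_len(ng)] <- ifelse(d <= radiusPx, d, penalty)
  sol <- solveAssignment(C)
  pi_ <- sol$assignment[seq_len(np)]
  ok <- which(pi_ <= ng & d[cbind(seq_len(np), pmin(pi_, ng))] <= radiusPx)
  pairs <- data.frame(pred_id = pred$instance_id[ok],
                      gt_id = gt$instance_id[pi_[ok]],
                      distance = d[cbind(ok, pi_[ok])])
  pairs <- pairs[order(pairs$gt_id, pairs$pred_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatchedPred = setdiff(pred$instance_id, pairs$pred_id),
       unmatchedGt = setdiff(gt$instance_id, pairs$gt_id),
       radiusPx = radiusPx)
}

#' Convert a physical matching radius to pixels
#' @param radiusUm radius in micrometers (default 3).
#' @param resolutionUmPerPx resolution in um/px (default 0.25).
#' @return radius in pixels.
#' @export
radiusPxFromUm <- function(radiusUm = 3, resolutionUmPerPx = 0.25) {
  if (radiusUm <= 0 || resolutionUmPerPx <= 0)
    stop("radius and resolution must be positive")
  radiusUm / resolutionUmPerPx
}

#' Integrated detection/classification confusion counts for one class
#'
#' For a target class t, over matched pairs and unmatched cells:
#' TP = matched pairs with ground-truth class t classified t;
#' FP = matched pairs with ground-truth class other than t classified t,
#' plus falsely detected (unmatched predicted) cells classified t;
#' FN = matched pairs with ground-truth class t classified other than t,
#' plus ground-truth cells of class t not detected;
#' TN = matched pairs with ground-truth class other than t classified other
#' than t, plus falsely detected cells classified other than t.
#'
#' @param match result of [matchCells()].
#' @param pred,gt the record tables the match was computed from.
#' @param class target class t.
#' @return list with integer elements TP, TN, FP, FN and the class.
#' @export
confusionCounts <- function(match, pred, gt, class) {
  predClass <- stats::setNames(pred$class, pred$instance_id)
  gtClass <- stats::setNames(gt$class, gt$instance_id)
  ids <- c(match$pairs$pred_id, match$unmatchedPred)
  if (any(!as.character(ids) %in% names(predClass)))
    stop("match references prediction ids missing from the records")
  ids <- c(match$pairs$gt_id, match$unmatchedGt)
  if (any(!as.character(ids) %in% names(gtClass)))
    stop("match references ground-truth ids missing from the records")
  pc <- predClass[as.character(match$pairs$pred_id)]
  gc_ <- gtClass[as.character(match$pairs$gt_id)]
  up <- predClass[as.character(match$unmatchedPred)]
  ug <- gtClass[as.character(match$unmatchedGt)]
  t <- class
  list(class = t,
       TP = sum(gc_ == t & pc == t),
       FP = sum(gc_ != t & pc == t) + sum(up == t),
       FN = sum(gc_ == t & pc != t) + sum(ug == t),
       TN = sum(gc_ != t & pc != t) + sum(up != t))
}

#' Integrated metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP), recall =
#' TP/(TP+FN) and F1 = TP/(TP + 0.5 (FP+FN)). A zero denominator yields NA
#' (the undefined marker), never an error.
#'
#' @param counts list with TP, TN, FP, FN (e.g. from [confusionCounts()]).
#' @return list with accuracy, precision, recall, f1 (each in [0,1] or NA)
#'   and the counts.
#' @export
#' @examples
#' integratedMetrics(list(TP = 1, TN = 1, FP = 1, FN = 2))
integratedMetrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = safe(TP + TN, TP + TN + FP + FN),
       precision = safe(TP, TP + FP),
       recall = safe(TP, TP + FN),
       f1 = safe(TP, TP + 0.5 * (FP + FN)),
       counts = list(TP = TP, TN = TN, FP = FP, FN = FN))
}

#' F1 from estimated precision and recall
#'
#' Harmonic mean 2PR/(P+R), defined as 0 when P + R = 0. Used to turn
#' pathologist-estimated precision/recall (read off in 10% increments) into
#' a per-patch F1 score.
#'
#' @param precision,recall values in [0, 1].
#' @return F1 in [0, 1].
#' @export
#' @examples
#' f1FromEstimates(0.8, 0.5)   # ~0.615
f1FromEstimates <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("precision and recall must be in [0, 1]")
  s <- precision + recall
  ifelse(s == 0, 0, 2 * precision * recall / s)
}

#' Evaluate predictions against ground truth over a set of patches
#'
#' Matches cells per patch, accumulates the per-class confusion counts over
#' all patches (micro-averaging) and applies the integrated metrics to the
#' summed counts; per-patch metric reports are returned alongside.
#'
#' @param pred,gt named lists of [cellRecords()] data.frames; names are
#'   patch ids and must agree between the two lists.
#' @param radiusPx matching radius in pixels.
#' @param scheme optional [classScheme()] applied to both sides first.
#' @param classes classes to report; default
#'   c("inflammatory", "cancer").
#' @return list with `perClass` (named list of metric reports on the summed
#'   counts), `perPatch` (nested list patch -> class -> report) and `counts`
#'   (summed counts per class).
#' @export
evaluateDataset <- function(pred, gt, radiusPx,
                            scheme = NULL,
                            classes = c("inflammatory", "cancer")) {
  if (is.null(names(pred)) || is.null(names(gt)))
    stop("pred and gt must be named lists keyed by patch id")
  if (!setequal(names(pred), names(gt)))
    stop("patch ids of pred and gt do not match")
  ids <- names(gt)
  if (!is.null(scheme)) {
    pred <- lapply(pred, harmonizeClasses, scheme = scheme)
    gt <- lapply(gt, harmonizeClasses, scheme = scheme)
  }
  total <- lapply(classes, function(cl)
    list(class = cl, TP = 0L, TN = 0L, FP = 0L, FN = 0L))
  names(total) <- classes
  perPatch <- list()
  for (id in ids) {
    m <- matchCells(pred[[id]], gt[[id]], radiusPx)
    rep_ <- list()
    for (cl in classes) {
      cc <- confusionCounts(m, pred[[id]], gt[[id]], cl)
      for (k in c("TP", "TN", "FP", "FN"))
        total[[cl]][[k]] <- total[[cl]][[k]] + cc[[k]]
      rep_[[cl]] <- integratedMetrics(cc)
    }
    perPatch[[id]] <- rep_
  }
  list(perClass = lapply(total, integratedMetrics),
       perPatch = perPatch,
       counts = total)
}
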