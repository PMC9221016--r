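test_that("degenerate matchings behave as contracts state", {
  gt <- cellRecords(1:3, c(0, 10, 20), c(0, 10, 20),
                    rep("inflammatory", 3), rep(10L, 3))
  none <- matchCells(cellRecords(), gt, 5)
  expect_identical(nrow(none$pairs), 0L)
  expect_identical(none$unmatchedGt, 1:3)

  perfect <- matchCells(gt, gt, 5)
  expect_identical(nrow(perfect$pairs), 3L)
  expect_true(all(perfect$pairs$distance == 0))
  expect_length(perfect$unmatchedPred, 0)
  expect_error(matchCells(gt, gt, 0), "positive")
})

test_that("assignment cost equals exhaustive enumeration on jittered cells", {
  set.seed(51)
  for (case in 1:25) {
    n <- sample(2:4, 1)
    gt <- cellRecords(seq_len(n), runif(n, 0, 50), runif(n, 0, 50),
                      rep("other", n), rep(10L, n))
    pred <- gt
    pred$row <- pred$row + runif(n, -3, 3)
    pred$col <- pred$col + runif(n, -3, 3)
    radius <- 8
    m <- matchCells(pred, gt, radius)
    d <- sqrt(outer(pred$row, gt$row, "-")^2 +
                outer(pred$col, gt$col, "-")^2)
    penalty <- radius * (n + 1)
    C <- ifelse(d <= radius, d, penalty)
    expect_equal(sum(m$pairs$distance) + penalty * (n - nrow(m$pairs)),
                 brute_force_assignment_cost(C), tolerance = 1e-9)
  }
})

test_that("optimal matching never exceeds greedy assignment cost", {
  set.seed(52)
  for (case in 1:20) {
    n <- sample(3:8, 1); m_ <- sample(3:8, 1)
    pred <- cellRecords(seq_len(n), runif(n, 0, 30), runif(n, 0, 30),
                        rep("other", n), rep(10L, n))
    gt <- cellRecords(seq_len(m_), runif(m_, 0, 30), runif(m_, 0, 30),
                      rep("other", m_), rep(10L, m_))
    res <- matchCells(pred, gt, 10)
    d <- sqrt(outer(pred$row, gt$row, "-")^2 +
                outer(pred$col, gt$col, "-")^2)
    # compare under the shared unmatched-penalty objective: optimal total
    # cost must not exceed the greedy matching's total cost
    N <- max(n, m_)
    penalty <- 10 * (N + 1)
    gr <- greedy_match_distance(d, 10)
    optimal <- sum(res$pairs$distance) + penalty * (N - nrow(res$pairs))
    greedy <- gr$total + penalty * (N - gr$nMatched)
    expect_lte(optimal, greedy + 1e-9)
  }
})

test_that("the worked five-cell scenario yields the published counts", {
  sc <- worked_scenario()
  m <- matchCells(sc$pred, sc$gt, sc$radius)
  expect_identical(nrow(m$pairs), 3L)
  cc <- confusionCounts(m, sc$pred, sc$gt, "inflammatory")
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(1L, 1L, 2L, 1L))

  # brute-force enumeration of the five definitions over all cells
  pc <- setNames(sc$pred$class, sc$pred$instance_id)
  gc_ <- setNames(sc$gt$class, sc$gt$instance_id)
  for (t in c("inflammatory", "cancer")) {
    tp <- fp <- fn <- tn <- 0L
    for (k in seq_len(nrow(m$pairs))) {
      g <- gc_[[as.character(m$pairs$gt_id[k])]]
      p <- pc[[as.character(m$pairs$pred_id[k])]]
      if (g == t && p == t) tp <- tp + 1L
      if (g != t && p == t) fp <- fp + 1L
      if (g == t && p != t) fn <- fn + 1L
      if (g != t && p != t) tn <- tn + 1L
    }
    for (id in m$unmatchedPred)
      if (pc[[as.character(id)]] == t) fp <- fp + 1L else tn <- tn + 1L
    for (id in m$unmatchedGt)
      if (gc_[[as.character(id)]] == t) fn <- fn + 1L
    got <- confusionCounts(m, sc$pred, sc$gt, t)
    expect_identical(c(got$TP, got$FP, got$FN, got$TN), c(tp, fp, fn, tn))
  }
})

test_that("TP + FN equals the ground-truth class size (conservation)", {
  set.seed(53)
  for (s in 1:5) {
    gen <- generatePatch(small_patch_spec(seed = 60 + s, sizePx = 160,
                                          nInflam = 6, nCancer = 3,
                                          nOther = 2))
    cp <- corruptPredictions(gen$records, dropFraction = runif(1, 0, 0.4),
                             misclassFraction = runif(1, 0, 0.4),
                             jitterPx = 1.5, spuriousCount = sample(0:3, 1),
                             imageDim = c(160, 160), seed = 70 + s)
    m <- matchCells(cp$records, gen$records, 12)
    for (t in c("inflammatory", "cancer", "other")) {
      cc <- confusionCounts(m, cp$records, gen$records, t)
      expect_identical(cc$TP + cc$FN, sum(gen$records$class == t))
    }
  }
})

test_that("metrics are invariant to instance relabeling", {
  sc <- worked_scenario()
  m1 <- matchCells(sc$pred, sc$gt, sc$radius)
  base <- confusionCounts(m1, sc$pred, sc$gt, "inflammatory")
  pred2 <- sc$pred; pred2$instance_id <- rev(100 + seq_len(nrow(pred2)))
  gt2 <- sc$gt; gt2$instance_id <- rev(200 + seq_len(nrow(gt2)))
  m2 <- matchCells(pred2, gt2, sc$radius)
  cc2 <- confusionCounts(m2, pred2, gt2, "inflammatory")
  expect_identical(c(base$TP, base$FP, base$FN, base$TN),
                   c(cc2$TP, cc2$FP, cc2$FN, cc2$TN))
})

test_that("integrated metrics substitute counts exactly", {
  r <- integratedMetrics(list(TP = 1, TN = 1, FP = 1, FN = 2))
  expect_equal(r$accuracy, 0.40)
  expect_equal(r$precision, 0.50)
  expect_equal(r$recall, 1 / 3, tolerance = 1e-12)
  expect_equal(r$f1, 0.40)

  perfect <- integratedMetrics(list(TP = 7, TN = 0, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  void <- integratedMetrics(list(TP = 0, TN = 0, FP = 0, FN = 0))
  expect_true(all(is.na(unlist(void[c("accuracy", "precision",
                                      "recall", "f1")]))))
  expect_error(integratedMetrics(list(TP = -1, TN = 0, FP = 0, FN = 0)),
               "non-negative")
})

test_that("F1 from estimated precision/recall is the harmonic mean", {
  expect_equal(f1FromEstimates(0.9, 0.9), 0.9)
  expect_equal(f1FromEstimates(1.0, 0.0), 0)
  expect_equal(f1FromEstimates(0.8, 0.5), 2 * 0.8 * 0.5 / 1.3,
               tolerance = 1e-12)
  expect_equal(f1FromEstimates(0, 0), 0)
  expect_error(f1FromEstimates(1.1, 0.5), "\\[0, 1\\]")
})

test_that("dataset evaluation micro-averages counts across patches", {
  sc <- worked_scenario()
  one <- evaluateDataset(list(p = sc$pred), list(p = sc$gt), sc$radius)
  single <- integratedMetrics(confusionCounts(
    matchCells(sc$pred, sc$gt, sc$radius), sc$pred, sc$gt, "inflammatory"))
  expect_equal(one$perClass$inflammatory, single)

  # two identical patches leave micro-averaged metrics unchanged
  two <- evaluateDataset(list(a = sc$pred, b = sc$pred),
                         list(a = sc$gt, b = sc$gt), sc$radius)
  expect_equal(two$perClass$inflammatory[c("accuracy", "precision",
                                           "recall", "f1")],
               single[c("accuracy", "precision", "recall", "f1")])

  # second patch: perfect 3 inflammatory + 2 cancer -> counts 3/0/0/2;
  # summed with the worked 1/1/2/1 gives 4/1/2/3
  gtb <- cellRecords(1:5, c(5, 25, 45, 5, 45), c(5, 25, 45, 45, 5),
                     c(rep("inflammatory", 3), rep("cancer", 2)),
                     rep(10L, 5))
  mixed <- evaluateDataset(list(a = sc$pred, b = gtb),
                           list(a = sc$gt, b = gtb), sc$radius)
  counts <- mixed$perClass$inflammatory$counts
  expect_identical(unlist(counts),
                   c(TP = 4L, TN = 3L, FP = 1L, FN = 2L))
  expect_equal(mixed$perClass$inflammatory$precision, 0.8)
  expect_equal(mixed$perClass$inflammatory$recall, 2 / 3, tolerance = 1e-12)

  expect_error(evaluateDataset(list(a = sc$pred), list(b = sc$gt),
                               sc$radius), "do not match")
})

test_that("patch order does not change dataset metrics", {
  sc <- worked_scenario()
  gtb <- cellRecords(1:2, c(5, 30), c(5, 30), c("inflammatory", "cancer"),
                     rep(10L, 2))
  f <- evaluateDataset(list(a = sc$pred, b = gtb),
                       list(a = sc$gt, b = gtb), sc$radius)
  r <- evaluateDataset(list(b = gtb, a = sc$pred),
                       list(b = gtb, a = sc$gt), sc$radius)
  expect_equal(f$perClass, r$perClass)
})

test_that("physical matching radius converts through resolution", {
  expect_equal(radiusPxFromUm(3, 0.25), 12)
  expect_error(radiusPxFromUm(0), "positive")
})
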