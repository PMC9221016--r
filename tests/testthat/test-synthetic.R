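test_that("zero-nucleus specs give blank tissue with empty truth", {
  sp <- patchSpec(sizePx = 64, seed = 1,
                  nuclei = list(inflammatory = list(
                    n = 0, radius = c(3.5, 5), axisRatio = c(0.75, 1),
                    hOd = c(0.85, 1), eOd = c(0.05, 0.15))))
  out <- generatePatch(sp)
  expect_identical(nInstances(out$instanceMap), 0L)
  expect_identical(nrow(out$records), 0L)
  # background carries eosin only: pinkish, no strong hematoxylin
  h <- rgbToHed(out$patch)[, , 1]
  expect_lt(max(abs(h)), 0.1)
})

test_that("generated truth matches the requested class counts", {
  out <- generatePatch(small_patch_spec(seed = 2, nInflam = 10, nCancer = 5,
                                        nOther = 0, sizePx = 256))
  tab <- table(out$records$class)
  expect_identical(as.integer(tab[["inflammatory"]]), 10L)
  expect_identical(as.integer(tab[["cancer"]]), 5L)
  expect_identical(nrow(out$records), nInstances(out$instanceMap))
})

test_that("the patch generator is bit-reproducible per seed", {
  a <- generatePatch(small_patch_spec(seed = 3))
  b <- generatePatch(small_patch_spec(seed = 3))
  expect_identical(pixels(a$patch), pixels(b$patch))
  expect_identical(instanceLabels(a$instanceMap),
                   instanceLabels(b$instanceMap))
  expect_identical(a$records, b$records)
  c_ <- generatePatch(small_patch_spec(seed = 4))
  expect_false(identical(pixels(a$patch), pixels(c_$patch)))
})

test_that("unsatisfiable placement fails loudly", {
  sp <- patchSpec(sizePx = 64, seed = 5, maxAttempts = 200,
                  nuclei = list(cancer = list(
                    n = 50, radius = c(10, 12), axisRatio = c(0.9, 1),
                    hOd = c(0.5, 0.6), eOd = c(0.1, 0.2))))
  expect_error(generatePatch(sp), "could not place")
})

test_that("ground truth evaluated against itself is perfect", {
  out <- generatePatch(small_patch_spec(seed = 6))
  ev <- evaluateDataset(list(p = out$records), list(p = out$records),
                        radiusPx = 12,
                        classes = c("inflammatory", "cancer", "other"))
  for (cl in names(ev$perClass)) {
    m <- ev$perClass[[cl]]
    expect_equal(m$accuracy, 1)
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)
    expect_equal(m$f1, 1)
  }
})

test_that("zero corruption returns the ground truth unchanged", {
  out <- generatePatch(small_patch_spec(seed = 7))
  cp <- corruptPredictions(out$records, seed = 8)
  expect_equal(cp$records, out$records)
  bk <- cp$bookkeeping$inflammatory
  expect_identical(bk$FP + bk$FN, 0L)
})

test_that("dropping 2 of 10 inflammatory cells gives recall 0.8 exactly", {
  out <- generatePatch(small_patch_spec(seed = 9, nInflam = 10, nCancer = 4,
                                        nOther = 0, sizePx = 256))
  cp <- corruptPredictions(out$records,
                           dropFraction = c(inflammatory = 0.2), seed = 10)
  ev <- evaluateDataset(list(p = cp$records), list(p = out$records),
                        radiusPx = 12)
  expect_equal(ev$perClass$inflammatory$recall, 0.8)
  expect_equal(ev$perClass$inflammatory$precision, 1)
})

test_that("spurious cancer detections raise cancer FP by their count", {
  out <- generatePatch(small_patch_spec(seed = 11))
  base <- evaluateDataset(list(p = out$records), list(p = out$records),
                          radiusPx = 12)
  cp <- corruptPredictions(out$records, spuriousCount = 3,
                           imageDim = c(192, 192), classes = "cancer",
                           seed = 12)
  ev <- evaluateDataset(list(p = cp$records), list(p = out$records),
                        radiusPx = 12)
  expect_identical(ev$perClass$cancer$counts$FP,
                   base$perClass$cancer$counts$FP + 3L)
})

test_that("corruption bookkeeping equals evaluation counts exactly", {
  for (s in 1:8) {
    out <- generatePatch(small_patch_spec(seed = 20 + s))
    cp <- corruptPredictions(out$records,
                             dropFraction = runif(1, 0, 0.3),
                             misclassFraction = runif(1, 0, 0.3),
                             jitterPx = 1.5, spuriousCount = sample(0:4, 1),
                             imageDim = c(192, 192), seed = 40 + s)
    m <- matchCells(cp$records, out$records, 12)
    for (t in c("inflammatory", "cancer", "other")) {
      cc <- confusionCounts(m, cp$records, out$records, t)
      bk <- cp$bookkeeping[[t]]
      expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN),
                       as.integer(c(bk$TP, bk$FP, bk$FN, bk$TN)))
    }
  }
})

test_that("misclassification matrices relabel the exact planned counts", {
  out <- generatePatch(small_patch_spec(seed = 13, nInflam = 10, nCancer = 5,
                                        nOther = 0, sizePx = 256))
  mis <- matrix(0, 2, 2, dimnames = list(c("inflammatory", "cancer"),
                                         c("inflammatory", "cancer")))
  mis["inflammatory", "cancer"] <- 0.3
  cp <- corruptPredictions(out$records, misclassFraction = mis, seed = 14)
  expect_identical(cp$bookkeeping$inflammatory$FN, 3L)
  expect_identical(cp$bookkeeping$cancer$FP, 3L)
})

test_that("censoring-free cohorts have only events", {
  co <- generateCohort(cohortSpec(nPatients = 30, censoringRate = 0,
                                  seed = 15))
  expect_true(all(co$event == 1))
  expect_true(all(co$time_months > 0))
})

test_that("patch counts per patient match the cohort shape", {
  co <- generateCohort(cohortSpec(seed = 16))
  k <- table(co$patient_id)
  expect_identical(length(k), 87L)
  expect_equal(median(k), 15)
  expect_gte(min(k), 3)
  expect_lte(max(k), 16)
})

test_that("censoring calibration approaches the target rate", {
  set.seed(17)
  rates <- vapply(1:20, function(s) {
    co <- generateCohort(cohortSpec(nPatients = 100, seed = 100 + s))
    pv <- patient_view(co)
    mean(pv$event == 0)
  }, 0)
  expect_equal(mean(rates), 0.3, tolerance = 0.05)
})

test_that("high-TIL patients have higher TIL counts by construction", {
  co <- generateCohort(cohortSpec(seed = 18))
  m <- tapply(co$til_count, co$true_group, mean)
  expect_gt(m[["high"]], m[["low"]])
})

test_that("the cohort generator is reproducible per seed", {
  a <- generateCohort(cohortSpec(nPatients = 20, seed = 19))
  b <- generateCohort(cohortSpec(nPatients = 20, seed = 19))
  expect_identical(a, b)
})

test_that("cohort spec validates its inputs", {
  expect_error(cohortSpec(hazardRatio = 0), "positive")
  expect_error(cohortSpec(censoringRate = 1), "\\[0, 1\\)")
  expect_error(cohortSpec(nPatients = 1), "two patients")
  expect_error(cohortSpec(tilMean = c(a = 1, b = 2)), "low")
})
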