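test_that("tissue detection separates glass from stained tissue", {
  white <- array(255, c(20, 20, 3))
  expect_false(any(detectTissue(white)))
  pink <- array(rep(c(230, 160, 190), each = 400), c(20, 20, 3))
  expect_true(all(detectTissue(pink)))
})

test_that("half-tissue fixture yields tissue fraction 0.5", {
  img <- array(255, c(40, 40, 3))
  img[, 1:20, 1] <- 230; img[, 1:20, 2] <- 160; img[, 1:20, 3] <- 190
  m <- detectTissue(img, medianRadius = 0)
  expect_equal(mean(m), 0.5, tolerance = 0.01)
})

test_that("physical patch sizes convert with round-half-up", {
  expect_identical(patchSizePx(1000, 0.25), 4000L)
  expect_identical(patchSizePx(1000, 0.2428), 4119L)
  expect_identical(patchSizePx(0.5, 1.0), 1L)
  expect_identical(patchSizePx(1.25, 0.5), 3L)   # 2.5 rounds up
  expect_error(patchSizePx(-1, 0.25), "positive")
  expect_error(patchSizePx(10, 0), "positive")
})

test_that("patch grids respect tissue fraction, cap and bounds", {
  expect_identical(nrow(anchors(generatePatchGrid(matrix(FALSE, 60, 60),
                                                  30))), 0L)
  g <- generatePatchGrid(matrix(TRUE, 100, 100), 50, maxPatches = 15)
  expect_identical(nrow(anchors(g)), 4L)
  g2 <- generatePatchGrid(matrix(TRUE, 100, 100), 50, maxPatches = 3)
  expect_identical(nrow(anchors(g2)), 3L)
  expect_error(generatePatchGrid(matrix(TRUE, 10, 10), 20), "exceeds")
})

test_that("striped-mask anchors match a brute-force coverage count", {
  mask <- matrix(FALSE, 60, 90)
  mask[, rep(c(TRUE, FALSE), each = 15)] <- TRUE  # 15-col stripes
  g <- generatePatchGrid(mask, 30, minTissueFraction = 0.5)
  a <- anchors(g)
  # brute force: every grid anchor whose 30x30 footprint covers >= 0.5
  expected <- list()
  for (r in seq(0, 30, by = 30)) for (cc in seq(0, 60, by = 30)) {
    frac <- mean(mask[r + 1:30, cc + 1:30])
    if (frac >= 0.5) expected[[length(expected) + 1]] <- c(r, cc, frac)
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(a), nrow(expected))
  expect_equal(as.matrix(a), unname(expected), ignore_attr = TRUE)
})

test_that("raising the tissue threshold never adds anchors", {
  set.seed(13)
  mask <- matrix(runif(80 * 80) < 0.6, 80, 80)
  prev <- Inf
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    n <- nrow(anchors(generatePatchGrid(mask, 20, thr)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("mirror padding reflects without repeating the edge pixel", {
  m <- matrix(1:9, 3, 3)
  expect_identical(mirrorPad(m, 0), m)
  p <- mirrorPad(m, 1)
  expect_identical(dim(p), c(5L, 5L))
  expect_identical(p[2:4, 2:4], m)           # interior preserved
  expect_identical(p[1, 1], m[2, 2])         # diagonal reflection
  expect_identical(p[1, 2], m[2, 1])
  expect_identical(p[5, 5], m[2, 2])
  expect_error(mirrorPad(m, 3), "smaller")
})

test_that("center crop of a padded patch recovers the original bit-exactly", {
  set.seed(14)
  img <- array(sample(0:255, 3 * 400, replace = TRUE), c(20, 20, 3))
  p <- mirrorPad(img, 7)
  expect_identical(p[8:27, 8:27, ], img)
})

test_that("sub-patches tile the patch and carry the right context", {
  set.seed(15)
  parent <- array(sample(0:255, 3 * 300 * 300, replace = TRUE),
                  c(300, 300, 3))
  patch <- Patch(parent[101:260, 101:260, ], origin = c(100L, 100L))
  subs <- extractSubpatches(patch, 270, 80, parent = parent)
  expect_length(subs, 4L)
  # windows partition the patch
  expect_equal(sum(vapply(subs, function(s) 80 * 80, 0)), 160 * 160)
  # interior context comes straight from the parent image
  s <- subs[[1]]   # window anchored at (0, 0) in the patch = (100,100) parent
  expect_identical(s$sub, parent[(101 - 95):(101 + 174),
                                 (101 - 95):(101 + 174), ])
  # without a parent, the border context equals an explicit mirror pad
  subs2 <- extractSubpatches(patch, 270, 80)
  padded <- mirrorPad(pixels(patch), 95)
  expect_identical(subs2[[1]]$sub, padded[1:270, 1:270, ])
  expect_error(extractSubpatches(patch, 80, 270), "subPx >= outPx")
  expect_error(extractSubpatches(patch, 271, 80), "even")
  expect_error(extractSubpatches(patch, 270, 78), "divisible")
})

test_that("channel normalization is exact arithmetic", {
  expect_equal(normalizeChannels(array(255, c(2, 2, 3))),
               array(1, c(2, 2, 3)))
  expect_equal(normalizeChannels(array(0, c(2, 2, 3))),
               array(0, c(2, 2, 3)))
  expect_equal(normalizeChannels(array(51, c(1, 1, 3)))[1], 0.2)
})

test_that("stitching mosaics windows once and relabels instances uniquely", {
  one <- matrix(0L, 6, 6); one[2:3, 2:3] <- 1L
  st <- stitchOutputs(list(list(map = one, anchor = c(0, 0))), c(6, 6))
  expect_identical(instanceLabels(st), one)

  wins <- list(list(map = one, anchor = c(0, 0)),
               list(map = one, anchor = c(0, 6)),
               list(map = one, anchor = c(6, 0)),
               list(map = one, anchor = c(6, 6)))
  st4 <- stitchOutputs(wins, c(12, 12))
  expect_identical(nInstances(st4), 4L)

  expect_error(stitchOutputs(wins[1:3], c(12, 12)), "gaps")
  over <- list(list(map = matrix(0L, 8, 8), anchor = c(0, 0)),
               list(map = matrix(0L, 8, 8), anchor = c(4, 4)))
  expect_error(stitchOutputs(over, c(12, 12)), "overlap")
})

test_that("a randomly partitioned map stitches back up to label permutation", {
  # random blobs, each wholly inside one quadrant so no instance straddles
  # a window boundary
  set.seed(31)
  lab <- matrix(0L, 128, 128)
  id <- 0L
  for (qr in c(0, 64)) for (qc in c(0, 64)) {
    for (b in 1:3) {
      id <- id + 1L
      r0 <- qr + sample(1:54, 1); c0 <- qc + sample(1:54, 1)
      lab[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- id
    }
  }
  lab <- instanceLabels(InstanceMap(lab))   # compact overwritten labels
  wins <- list()
  for (r in c(0, 64)) for (cc in c(0, 64))
    wins[[length(wins) + 1]] <- list(map = lab[r + 1:64, cc + 1:64],
                                     anchor = c(r, cc))
  st <- instanceLabels(stitchOutputs(wins, c(128, 128)))
  # permutation-invariant comparison: identical partition of pixels
  key_a <- as.integer(factor(as.vector(lab), levels = unique(as.vector(lab))))
  key_b <- as.integer(factor(as.vector(st), levels = unique(as.vector(st))))
  expect_identical((as.vector(lab) > 0), (as.vector(st) > 0))
  expect_identical(key_a, key_b)
})

test_that("extract + stitch of the identity transform reproduces the patch", {
  set.seed(16)
  img <- array(sample(0:255, 3 * 160 * 160, replace = TRUE) + 0,
               c(160, 160, 3))
  subs <- extractSubpatches(Patch(img), 270, 80)
  wins <- lapply(subs, function(s)
    list(map = s$sub[96:175, 96:175, , drop = FALSE], anchor = s$anchor))
  st <- stitchOutputs(wins, c(160, 160), relabel = FALSE)
  expect_identical(st, img)
})

test_that("tilePatches emits patches with a consistent manifest", {
  gen <- generatePatch(small_patch_spec(seed = 77, sizePx = 128))
  res <- tilePatches(gen$patch, sizeUm = 8, minTissueFraction = 0,
                     maxPatches = 6)
  expect_lte(nrow(res$manifest), 6)
  expect_equal(length(res$patches), nrow(res$manifest))
  px <- patchSizePx(8, resolution(gen$patch))
  for (p in res$patches) expect_identical(dim(pixels(p))[1:2], c(px, px))
})
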