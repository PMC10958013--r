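test_that("placement draws sizes and contrasts from the regime ranges", {
  set.seed(1)
  cfgA <- sceneConfig("A", "full")
  obj <- placeObject(data.frame(x = numeric(0), y = numeric(0),
                                size = numeric(0), contrast = numeric(0)),
                     cfgA)
  expect_equal(obj$size, 15)
  expect_equal(obj$contrast, 1)

  cfgB <- sceneConfig("B", "full")
  empty <- obj[0, ]
  draws <- do.call(rbind, lapply(1:2000, function(i) placeObject(empty, cfgB)))
  expect_gte(min(draws$size), 10)
  expect_lte(max(draws$size), 30)
  expect_gte(min(draws$contrast), 0.098)
  expect_lte(max(draws$contrast), 1)
  # spans most of the range (uniform draws)
  expect_lt(min(draws$size), 11)
  expect_gt(max(draws$size), 29)
})

test_that("over-dense placement requests fail with a placement error", {
  cfg <- sceneConfig("A", "full", imageSize = 40L, maxTries = 500L)
  state <- data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                      contrast = numeric(0))
  expect_error({
    set.seed(2)
    for (i in 1:31) state <- rbind(state, placeObject(state, cfg))
  }, class = "placementError")
})

test_that("actions change counts by their multiplicity and take errors at zero", {
  set.seed(3)
  cfg <- sceneConfig("A", "desk")
  empty <- data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                      contrast = numeric(0))
  s1 <- applyAction(empty, "P", cfg)
  expect_equal(nrow(s1), 1L)
  s3 <- applyAction(applyAction(s1, "P", cfg), "P", cfg)
  shaken <- applyAction(s3, "S", cfg)
  expect_equal(nrow(shaken), 3L)
  expect_false(all(shaken$x == s3$x & shaken$y == s3$y))
  expect_equal(sort(shaken$size), sort(s3$size))
  expect_error(applyAction(empty, "T", cfg), class = "invalidActionError")
})

test_that("valid-action sampling is uniform over the allowed subset", {
  set.seed(4)
  cfg <- sceneConfig("A", "desk", maxObjects = 3L)
  atZero <- table(replicate(6000, sampleValidAction(0L, cfg)))
  expect_setequal(names(atZero), c("P", "S"))
  expect_gt(chisq.test(atZero)$p.value, 0.001)
  atMax <- table(replicate(6000, sampleValidAction(3L, cfg)))
  expect_setequal(names(atMax), c("T", "S"))
  mid <- table(replicate(9000, sampleValidAction(2L, cfg)))
  expect_setequal(names(mid), c("P", "T", "S"))
  expect_gt(chisq.test(mid)$p.value, 0.001)
})

test_that("rendering paints exact square footprints additively", {
  cfg <- sceneConfig("A", "full")
  empty <- data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                      contrast = numeric(0))
  expect_equal(sum(renderScene(empty, cfg)), 0)
  one <- data.frame(x = 101.37, y = 55.9, size = 15, contrast = 1)
  img1 <- renderScene(one, cfg)
  expect_equal(sum(img1 > 0), 225)  # 15 x 15 regardless of subpixel position
  expect_equal(max(img1), 1)
  two <- rbind(one, data.frame(x = 30, y = 200, size = 15, contrast = 0.5))
  img2 <- renderScene(two, cfg)
  other <- renderScene(two[2, ], cfg)
  expect_equal(img2, img1 + other)  # disjoint squares add
})

test_that("episodes start empty, respect the cap, and replay their count deltas", {
  cfg <- sceneConfig("A", "desk", maxObjects = 3L)
  sq <- simulateSequence(cfg, 180, seed = 5)
  expect_length(sq@actions, 180L)
  expect_equal(sq@counts[1], 0L)
  expect_true(all(sq@counts >= 0L & sq@counts <= 3L))
  delta <- c(P = 1L, T = -1L, S = 0L)[sq@actions]
  expect_equal(cumsum(c(0L, unname(delta))), sq@counts)
})

test_that("identical seeds reproduce episodes bit for bit", {
  cfg <- sceneConfig("B", "desk")
  a <- simulateSequence(cfg, 25, seed = 42)
  b <- simulateSequence(cfg, 25, seed = 42)
  expect_identical(a@actions, b@actions)
  expect_identical(a@states, b@states)
  expect_identical(a@images, b@images)
})

test_that("clearance margin holds across random states", {
  set.seed(6)
  cfg <- sceneConfig("B", "desk", maxObjects = 8L)
  minGap <- Inf
  for (i in 1:120) {
    sq <- simulateSequence(cfg, 12)
    st <- sq@states[[13]]
    n <- nrow(st)
    if (n < 2) next
    for (j in 1:(n - 1)) {
      gaps <- pmax(abs(st$x[j] - st$x[-(1:j)]) - (st$size[j] + st$size[-(1:j)]) / 2,
                   abs(st$y[j] - st$y[-(1:j)]) - (st$size[j] + st$size[-(1:j)]) / 2)
      minGap <- min(minGap, gaps)
    }
  }
  expect_gte(minGap, cfg@margin)
})

test_that("object centers are uniform over the image", {
  set.seed(7)
  cfg <- sceneConfig("A", "full")
  empty <- data.frame(x = numeric(0), y = numeric(0), size = numeric(0),
                      contrast = numeric(0))
  xs <- replicate(10000, placeObject(empty, cfg)$x)
  # uniform on [7.5, 236.5]; coarse 10-bin chi-square
  bins <- cut(xs, breaks = seq(7.5, 236.5, length.out = 11))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})

test_that("balanced sets are exactly balanced and correctly labeled", {
  cfg <- tinySceneA()
  bs <- balancedImageSet(cfg, 0:6, 9L, seed = 8)
  expect_equal(as.vector(table(imageCounts(bs))), rep(9L, 7))
  # label equals rendered object count: count bright blobs via intensity
  areas <- apply(imageArray(bs), 3, function(im) sum(im > 0))
  expect_equal(areas, imageCounts(bs) * 16)  # 4x4 px squares
})

test_that("mean intensity is a perfect count readout in regime A only", {
  cfgA <- tinySceneA()
  bsA <- balancedImageSet(cfgA, 0:8, 12L, seed = 9)
  icA <- intensityCovariates(bsA)
  expect_equal(icA$correlation, 1)
  expect_equal(icA$perCount$mean[icA$perCount$count == 0], 0)

  cfgB <- tinySceneB()
  bsB <- balancedImageSet(cfgB, 0:8, 40L, seed = 10)
  icB <- intensityCovariates(bsB)
  expect_lt(icB$correlation, 1)
  # adjacent-count intensity distributions overlap
  p <- icB$perCount
  overlap <- any(p$max[-nrow(p)] > p$min[-1])
  expect_true(overlap)
})

test_that("episodes and image sets can be written to disk", {
  skip_if_not_installed("png")
  dir <- withr::local_tempdir()
  sq <- simulateSequence(tinySceneA(), 5, seed = 11)
  meta <- writeSequences(sq, dir)
  expect_true(file.exists(meta))
  lines <- readLines(meta)
  expect_length(lines, 6L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_true(rec$action %in% c("P", "T", "S"))
  expect_true(file.exists(file.path(dir, rec$file)))
})
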