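# Pixel coding, labelling, class statistics, merging, semantic roles.

test_that("coding counts thresholds strictly below the pixel value", {
  # a* thresholds at 20 and 60 (levels 130, 170 in the default quantization)
  thrA <- thresholdsFrom(aStarLevel(c(20, 60)), 221, "a")
  thrL <- thresholdsFrom(c(40, 60), 101, "L")
  thrB <- thresholdsFrom(aStarLevel(c(0, 30)), 221, "b")
  lab <- labImageFrom(L = matrix(50, 1, 4),
                      a = matrix(c(10, 40, 70, 20), 1, 4),
                      b = matrix(10, 1, 4))
  coded <- encodePixels(lab, thrL, thrA, thrB)
  expect_equal(as.vector(coded@codes[, , 2]), c(0L, 1L, 2L, 0L))  # 20 == t1 -> 0
  expect_equal(nPartitions(coded), 3L)
})

test_that("coding agrees with a scalar interval-scan oracle", {
  set.seed(21)
  thr <- sort(sample(0:219, 3))
  vals <- matrix(sample(0:220, 200, replace = TRUE), 10, 20)
  got <- frostmap:::codeValues(vals, thr)
  want <- apply(vals, c(1, 2), function(v) sum(thr < v))
  expect_equal(got, want)
})

test_that("labelling is the base-n positional code and a bijection", {
  codes <- array(0L, dim = c(1, 2, 3))
  codes[1, 1, ] <- c(1L, 0L, 1L)
  codes[1, 2, ] <- c(1L, 1L, 1L)
  cm <- new("CodedImage", codes = codes, nPartitions = 2L)
  expect_equal(as.vector(labelMatrix(labelPixels(cm))), c(5L, 7L))

  codes3 <- array(c(2L, 1L, 0L), dim = c(1, 1, 3))
  cm3 <- new("CodedImage", codes = codes3, nPartitions = 3L)
  expect_equal(labelMatrix(labelPixels(cm3))[1, 1], 21L)

  # all code triplets for n = 2 give exactly 8 distinct labels (bijection)
  grid <- expand.grid(cL = 0:1, ca = 0:1, cb = 0:1)
  codesAll <- array(c(grid$cL, grid$ca, grid$cb), dim = c(8, 1, 3))
  cmAll <- new("CodedImage", codes = codesAll, nPartitions = 2L)
  labs <- as.vector(labelMatrix(labelPixels(cmAll)))
  expect_equal(sort(labs), 0:7)
})

test_that("class statistics match hand and loop oracles", {
  # two pixels at (0,0,0) and (6,0,0): mu = (3,0,0), sigma = (3 + 3) / (3 * 2)
  lab <- labImageFrom(L = matrix(c(0, 6), 1, 2), a = matrix(0, 1, 2),
                      b = matrix(0, 1, 2))
  lm <- new("LabelMap", labels = matrix(0L, 1, 2), nPartitions = 2L)
  st <- classStatistics(lab, lm)
  expect_equal(st$N, 2L)
  expect_equal(c(st$muL, st$mua, st$mub), c(3, 0, 0))
  expect_equal(st$sigma, 1)

  # single-pixel class
  lm2 <- new("LabelMap", labels = matrix(c(0L, 3L), 1, 2), nPartitions = 2L)
  st2 <- classStatistics(lab, lm2)
  expect_equal(st2$sigma, c(0, 0))
  expect_equal(st2$muL, c(0, 6))

  # random 20-pixel class vs scalar loop oracle, both variance forms
  set.seed(33)
  X <- matrix(rnorm(60, sd = 10), 20, 3)
  lab3 <- labImageFrom(matrix(pmin(pmax(X[, 1] + 50, 0), 100), 4, 5),
                       matrix(X[, 2], 4, 5), matrix(X[, 3], 4, 5))
  lm3 <- new("LabelMap", labels = matrix(0L, 4, 5), nPartitions = 2L)
  mu <- colMeans(matrix(labData(lab3), ncol = 3))
  dists <- apply(matrix(labData(lab3), ncol = 3), 1,
                 function(x) sqrt(sum((x - mu)^2)))
  expect_equal(classStatistics(lab3, lm3)$sigma, sum(dists) / (3 * 20),
               tolerance = 1e-9)
  expect_equal(classStatistics(lab3, lm3, "squared")$sigma,
               sum(dists^2) / (3 * 20), tolerance = 1e-9)
})

test_that("between-class separation is the mean squared mean difference", {
  a <- data.frame(muL = 1, mua = 2, mub = 3)
  b <- data.frame(muL = 1, mua = 2, mub = 3)
  expect_equal(betweenClassSeparation(a, b), 0)
  b2 <- data.frame(muL = 4, mua = 2, mub = 3)
  expect_equal(betweenClassSeparation(a, b2), 3)   # 9 / 3
  set.seed(3)
  x <- data.frame(muL = rnorm(1), mua = rnorm(1), mub = rnorm(1))
  y <- data.frame(muL = rnorm(1), mua = rnorm(1), mub = rnorm(1))
  expect_equal(betweenClassSeparation(x, y), betweenClassSeparation(y, x))

  st <- data.frame(label = 0:2, N = 1, muL = c(0, 3, 10), mua = 0, mub = 0,
                   sigma = 0)
  S <- separationMatrix(st)
  expect_equal(S, t(S))
  expect_equal(diag(S), c(`0` = 0, `1` = 0, `2` = 0))
  expect_equal(S["0", "1"], 3)
})

test_that("merging fires only for overlapping classes and keeps the tighter label", {
  # two tight, distant clusters: no merge
  set.seed(10)
  L1 <- rnorm(100, 20, 0.1); L2 <- rnorm(100, 80, 0.1)
  lab <- labImageFrom(matrix(c(L1, L2), 10, 20), matrix(0, 10, 20),
                      matrix(0, 10, 20))
  lm <- new("LabelMap", labels = matrix(c(rep(0L, 100), rep(5L, 100)), 10, 20),
            nPartitions = 2L)
  step <- mergeStep(lm, lab)
  expect_false(step$merged)

  # interleaved clusters, identical means, large spread: merge; the fused
  # class keeps the smaller-variance member's label
  Lx <- c(rnorm(100, 50, 8), rnorm(100, 50, 2))
  lab2 <- labImageFrom(matrix(pmin(pmax(Lx, 0), 100), 10, 20),
                       matrix(0, 10, 20), matrix(0, 10, 20))
  step2 <- mergeStep(lm, lab2)
  expect_true(step2$merged)
  expect_equal(sort(unique(as.vector(labelMatrix(step2$labels)))), 5L)
  expect_equal(step2$detail$keep, 5L)   # label 5 holds the sd = 2 cluster
})

test_that("merge-until-stable reaches full pairwise separation and terminates", {
  set.seed(77)
  centres <- rbind(c(20, -30, 10), c(70, 30, -40), c(50, 0, 60), c(90, -60, -10))
  n <- 120
  X <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(n * 3, sd = 0.5), n, 3), 2, centres[k, ], `+`)))
  lab <- labImageFrom(matrix(pmin(pmax(X[, 1], 0), 100), 24, 20),
                      matrix(X[, 2], 24, 20), matrix(X[, 3], 24, 20))
  truth <- matrix(rep(0:3, each = n), 24, 20)

  # already-separated classes: unchanged
  lm <- new("LabelMap", labels = truth, nPartitions = 2L)
  res <- mergeUntilStable(lm, lab)
  expect_equal(res$nMerges, 0L)
  expect_equal(labelMatrix(res$labels), truth)

  # over-segmented map (each class split in two): fragments merge back and
  # the stable state satisfies sigma_kh > max(sigma_k, sigma_h) for all pairs
  split <- truth
  split[1:12, ] <- split[1:12, ] + 4L
  lmS <- new("LabelMap", labels = split, nPartitions = 2L)
  resS <- mergeUntilStable(lmS, lab)
  st <- classStatistics(lab, resS$labels)
  S <- separationMatrix(st)
  for (i in seq_len(nrow(st))) for (j in seq_len(nrow(st))) {
    if (i < j) expect_gt(S[i, j], max(st$sigma[i], st$sigma[j]))
  }
  expect_lte(resS$nMerges, 8 - 1)

  # degenerate: all pixels identical collapses to one class
  flat <- labImageFrom(matrix(50, 6, 6), matrix(0, 6, 6), matrix(0, 6, 6))
  lmF <- new("LabelMap", labels = matrix(rep(0:3, 9), 6, 6), nPartitions = 2L)
  expect_equal(length(occupiedLabels(mergeUntilStable(lmF, flat)$labels)), 1L)
})

test_that("classification is invariant to pixel order", {
  set.seed(55)
  sc <- generateScene(sceneSpec(width = 64, height = 64, noiseSd = 1,
                                patchScale = 16, seed = 9))
  lab <- rgbToLab(sc$rgb)
  res <- classifyImage(lab, targetClasses = 4)
  perm <- sample(64 * 64)
  rgbP <- array(apply(sc$rgb, 3, function(p) p[perm]), dim = dim(sc$rgb))
  resP <- classifyImage(rgbToLab(rgbP), targetClasses = 4)
  m1 <- as.vector(labelMatrix(res$labels))[perm]
  m2 <- as.vector(labelMatrix(resP$labels))
  expect_equal(m1, m2)
})

test_that("forcing K = 1 collapses the image and oversized K errors out", {
  sc <- generateScene(sceneSpec(width = 48, height = 48, noiseSd = 1,
                                patchScale = 12, seed = 2))
  lab <- rgbToLab(sc$rgb)
  res1 <- classifyImage(lab, targetClasses = 1)
  expect_equal(length(occupiedLabels(res1$labels)), 1L)
  expect_error(classifyImage(lab, targetClasses = 1000), "only merges")
})

test_that("semantic roles follow the lightness/greenness/yellowness ordering", {
  st <- data.frame(label = c(3L, 9L, 17L, 21L), N = 100,
                   muL = c(70, 85, 76, 40),       # GO, DO, HD, SG
                   mua = c(-45, -12, -18, -7),
                   mub = c(37, 39, 35, 5),
                   sigma = 1)
  roles <- semanticMapping(st)
  expect_equal(unname(roles[c("3", "9", "17", "21")]), c("GO", "DO", "HD", "SG"))

  # permuting the rows does not change the assignment
  st2 <- st[c(4, 2, 1, 3), ]
  expect_equal(semanticMapping(st2)[names(roles)], roles)

  expect_error(semanticMapping(st[1:3, ]), "exactly 4")
})

test_that("damage report accounts areas and the usable-area rule", {
  roleMap <- matrix(c(rep("GO", 50), rep("HD", 20), rep("DO", 20),
                      rep("SG", 10)), 10, 10)
  rep <- damageReport(roleMap, areaPerPixel = 0.01, usableHdFraction = 0.5)
  expect_equal(sum(rep$perRole$fraction), 1)
  expect_equal(rep$totalAreaM2, 1)
  expect_equal(rep$usableAreaM2, 0.5 + 0.5 * 0.2)   # GO + w * HD
  expect_error(damageReport(matrix("XX", 2, 2)), "unknown role")
})
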