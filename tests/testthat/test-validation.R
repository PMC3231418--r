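# Sampling design, polygon scoring, error matrices and accuracy measures.

test_that("multinomial sample size follows the chi-square design formula", {
  # worst-case design with a supplied chi-square coefficient
  d <- sampleSize(c(0.35, 0.16, 0.16, 0.33), accuracy = 0.05, B = 6.36640,
                  class = 2)
  expect_equal(d$n, 343L)                      # ceil(6.36640 * .16 * .84 / .0025)
  expect_equal(d$fraction, 0.16)

  # default B is the chi-square quantile at 1 - b/k with 1 df
  d2 <- sampleSize(c(0.5, 0.5), accuracy = 0.05)
  expect_equal(d2$B, qchisq(1 - 0.05 / 2, df = 1))

  expect_warning(dz <- sampleSize(c(0, 1)), "degenerate")
  expect_equal(dz$n, 0L)
  expect_error(sampleSize(c(0.5, 0.5), accuracy = 0), "accuracy")

  # monotone in B; worst case is the fraction nearest 0.5
  n1 <- sampleSize(c(0.3, 0.7), B = 4)$n
  n2 <- sampleSize(c(0.3, 0.7), B = 8)$n
  expect_lte(n1, n2)
  d3 <- sampleSize(c(0.1, 0.4, 0.5), B = 6)
  expect_equal(d3$fraction, 0.5)
})

test_that("largest-remainder allocation sums to n and matches hand results", {
  expect_equal(allocateSamples(100, c(0.5, 0.5)), c(50L, 50L))
  expect_equal(allocateSamples(345, c(0.35, 0.16, 0.16, 0.33)),
               c(121L, 55L, 55L, 114L))
  set.seed(6)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    f <- diff(c(0, sort(runif(k - 1)), 1))
    n <- sample(10:500, 1)
    a <- allocateSamples(n, f)
    expect_equal(sum(a), n)
    expect_true(all(abs(a - n * f) < 1))       # within one unit of quota
  }
  expect_error(allocateSamples(10, c(-0.1, 1.1)), "non-negative")
})

test_that("polygon rasterization agrees with a ray-casting oracle", {
  set.seed(14)
  # an irregular pentagon on a 30 x 30 grid
  poly <- polygonSample("p1", "GO",
                        x = c(4.2, 25.7, 27.1, 14.0, 3.1),
                        y = c(3.8, 5.5, 22.3, 27.6, 18.9))
  idx <- rasterizePolygon(poly, c(30, 30))
  want <- which(outer(1:30, 1:30, Vectorize(function(r, c)
    oraclePointInPolygon(c, r, poly@vertices[, "x"], poly@vertices[, "y"]))))
  expect_equal(idx, want)

  outside <- polygonSample("p2", "GO", x = c(-3, 5, 5), y = c(1, 1, 5))
  expect_error(rasterizePolygon(outside, c(30, 30)),
               class = "frostmap_geometry_error")
})

twoRegionMap <- function() {
  # left half GO, right half SG, 20 x 20
  cbind(matrix("GO", 20, 10), matrix("SG", 20, 10))
}

test_that("overlap fractions sum to one and detect half-in rectangles", {
  m <- twoRegionMap()
  inGO <- polygonSample("a", "GO", x = c(1.5, 6.5, 6.5, 1.5),
                        y = c(2.5, 2.5, 8.5, 8.5))
  expect_equal(overlapFraction(inGO, m, "GO"), 1)
  expect_equal(overlapFraction(inGO, m, "SG"), 0)

  straddle <- polygonSample("b", "GO", x = c(6.5, 14.5, 14.5, 6.5),
                            y = c(2.5, 2.5, 8.5, 8.5))
  expect_equal(overlapFraction(straddle, m, "GO"), 0.5)
  expect_equal(overlapFraction(straddle, m, "SG"), 0.5)
  expect_equal(overlapFraction(straddle, m, "GO") +
                 overlapFraction(straddle, m, "SG"), 1)
})

test_that("polygon scoring implements the three fuzzy rules", {
  m <- twoRegionMap()
  # 100% overlap: absolutely correct on the diagonal
  s1 <- scorePolygon(polygonSample("a", "GO", x = c(1.5, 6.5, 6.5, 1.5),
                                   y = c(2.5, 2.5, 8.5, 8.5)), m)
  expect_equal(s1$outcome, "absolutely_correct")
  expect_equal(c(s1$row, s1$col), c("GO", "GO"))

  # GO reference polygon 60% GO / 40% SG: acceptable, row SG, column GO
  s2 <- scorePolygon(polygonSample("b", "GO", x = c(4.5, 14.5, 14.5, 4.5),
                                   y = c(2.5, 2.5, 8.5, 8.5)), m)
  expect_equal(s2$outcome, "acceptable")
  expect_equal(c(s2$row, s2$col), c("SG", "GO"))

  # DO reference polygon classified 80% GO: error, row GO, column DO
  m2 <- m; m2[3:8, 9:10] <- "DO"
  s3 <- scorePolygon(polygonSample("c", "DO", x = c(2.5, 10.5, 10.5, 2.5),
                                   y = c(2.5, 2.5, 8.5, 8.5)), m2)
  expect_equal(s3$outcome, "error")
  expect_equal(c(s3$row, s3$col), c("GO", "DO"))
})

test_that("the error matrix accumulates a hand-tallied mixed fixture", {
  m <- twoRegionMap()
  polys <- list(
    polygonSample("p1", "GO", x = c(1.5, 4.5, 4.5, 1.5), y = c(1.5, 1.5, 4.5, 4.5)),
    polygonSample("p2", "GO", x = c(1.5, 4.5, 4.5, 1.5), y = c(5.5, 5.5, 8.5, 8.5)),
    polygonSample("p3", "SG", x = c(12.5, 15.5, 15.5, 12.5), y = c(1.5, 1.5, 4.5, 4.5)),
    # GO polygon straddling: 2/3 GO -> acceptable (row SG, col GO)
    polygonSample("p4", "GO", x = c(4.5, 13.5, 13.5, 4.5), y = c(10.5, 10.5, 13.5, 13.5)),
    # GO polygon mostly SG: 1/3 GO -> error (row SG, col GO)
    polygonSample("p5", "GO", x = c(7.5, 16.5, 16.5, 7.5), y = c(14.5, 14.5, 17.5, 17.5)))
  fm <- buildErrorMatrix(polys, m, weighting = "unit")
  expect_equal(unname(fm@correct), c(2, 1))                 # GO, SG diagonals
  expect_equal(fm@acceptable["SG", "GO"], 1)
  expect_equal(fm@unacceptable["SG", "GO"], 1)
  expect_equal(grandTotal(fm), 5)

  # pixel weighting: grand total equals the sampled surface
  fmP <- buildErrorMatrix(polys, m, weighting = "pixel")
  expect_equal(grandTotal(fmP), sum(vapply(polys, function(p)
    length(rasterizePolygon(p, dim(m))), 0L)))

  # a perfectly classified polygon set gives a purely diagonal matrix
  fmD <- buildErrorMatrix(polys[1:3], m, weighting = "unit")
  expect_equal(sum(fmD@acceptable) + sum(fmD@unacceptable), 0)
})

test_that("the survey example matrix reproduces every published-style accuracy", {
  m <- exampleSurveyMatrix()
  expect_equal(overallAccuracy(m, "deterministic")$percent, 92)
  expect_equal(overallAccuracy(m, "fuzzy")$percent, 96)
  expect_equal(overallAccuracy(m, "deterministic")$numerator, 63400)
  expect_equal(grandTotal(m), 68800)

  # classifier's accuracy (rows) and commission errors
  cls <- c(GO = 91, DO = 90, HD = 92, SG = 94)
  clsF <- c(GO = 95, DO = 96, HD = 98, SG = 97)
  for (k in names(cls)) {
    det <- classifierAccuracy(m, k, "deterministic")
    fuz <- classifierAccuracy(m, k, "fuzzy")
    expect_equal(det$percent, unname(cls[k]))
    expect_equal(fuz$percent, unname(clsF[k]))
    expect_equal(det$complementPercent, 100 - unname(cls[k]))
  }
  expect_equal(classifierAccuracy(m, "DO")$numerator, 8800)
  expect_equal(classifierAccuracy(m, "DO")$denominator, 9800)
  expect_equal(classifierAccuracy(m, "DO", "fuzzy")$numerator, 9400)

  # expert's accuracy (columns) and omission errors
  exp_ <- c(GO = 94, DO = 81, HD = 82, SG = 100)
  expF <- c(GO = 97, DO = 93, HD = 91, SG = 100)
  for (k in names(exp_)) {
    expect_equal(expertAccuracy(m, k, "deterministic")$percent, unname(exp_[k]))
    expect_equal(expertAccuracy(m, k, "fuzzy")$percent, unname(expF[k]))
  }
  expect_equal(expertAccuracy(m, "GO")$proportion, 22600 / 24000)
  expect_equal(expertAccuracy(m, "HD")$numerator, 9200)
  expect_equal(expertAccuracy(m, "HD")$denominator, 11200)
})

test_that("fuzzy accuracies dominate deterministic ones and collapsing is exact", {
  set.seed(18)
  for (rep in 1:25) {
    m <- randomErrorMatrix(sample(3:5, 1))
    det <- deterministicMatrix(m)
    expect_equal(unname(diag(det)), unname(m@correct))
    expect_equal(det, m@acceptable + m@unacceptable + diag(m@correct) -
                   diag(diag(m@acceptable + m@unacceptable)))
    expect_lte(overallAccuracy(m, "deterministic")$proportion,
               overallAccuracy(m, "fuzzy")$proportion)
    for (k in matrixClasses(m)) {
      expect_lte(classifierAccuracy(m, k, "deterministic")$proportion,
                 classifierAccuracy(m, k, "fuzzy")$proportion)
      expect_lte(expertAccuracy(m, k, "deterministic")$proportion,
                 expertAccuracy(m, k, "fuzzy")$proportion)
      # commission/omission are exact complements before rounding
      expect_equal(classifierAccuracy(m, k)$complementProportion,
                   1 - classifierAccuracy(m, k)$proportion)
    }
  }
})

test_that("a ground-truth-perfect map scores 100% everywhere", {
  sc <- generateScene(sceneSpec(width = 128, height = 128, noiseSd = 0,
                                patchScale = 32, seed = 3))
  polys <- generatePolygons(sc$roles, perClass = 3, sizeRange = c(5, 8),
                            seed = 3)
  expect_setequal(unique(vapply(polys, slot, "", "role")),
                  unique(as.vector(sc$roles)))
  fm <- buildErrorMatrix(polys, sc$roles)
  expect_equal(overallAccuracy(fm, "deterministic")$percent, 100)
  for (k in matrixClasses(fm)) {
    expect_equal(classifierAccuracy(fm, k)$percent, 100)
    expect_equal(expertAccuracy(fm, k)$percent, 100)
    expect_equal(expertAccuracy(fm, k)$complementPercent, 0)
  }
})

test_that("error matrices round-trip through the a;u CSV format", {
  m <- exampleSurveyMatrix()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeErrorMatrixCsv(m, path)
  m2 <- readErrorMatrixCsv(path)
  expect_equal(m2@correct, m@correct)
  expect_equal(m2@acceptable, m@acceptable)
  expect_equal(m2@unacceptable, m@unacceptable)
})
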