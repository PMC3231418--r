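# Independent oracles: deliberately naive scalar/loop implementations used to
# verify the vectorized package code, plus small fixture builders.

# scalar RGB -> Lab, evaluated step by step
oracleRgbToLab <- function(r, g, b, maxValue = 255, white = equalEnergyWhite(),
                           lowBranch = "linear") {
  rn <- r / maxValue; gn <- g / maxValue; bn <- b / maxValue
  X <- 0.490 * rn + 0.310 * gn + 0.200 * bn
  Y <- 0.177 * rn + 0.813 * gn + 0.011 * bn
  Z <- 0.000 * rn + 0.010 * gn + 0.990 * bn
  f <- function(t) if (t > 0.008856) t^(1/3) else 7.787 * t + 16 / 116
  yr <- Y / white[2]
  L <- if (yr > 0.008856) 116 * yr^(1/3) - 16
       else if (lowBranch == "linear") 903.3 * yr else 903.3 * yr^(1/3)
  c(L = unname(L),
    a = unname(500 * (f(X / white[1]) - f(yr))),
    b = unname(200 * (f(yr) - f(Z / white[3]))))
}

# exhaustive-scan Otsu: argmax of the between-class variance over every
# candidate split, smallest level on ties
oracleOtsu <- function(counts) {
  L <- length(counts); N <- sum(counts)
  lv <- 0:(L - 1)
  p <- counts / N
  muT <- sum(lv * p)
  best <- NULL; bestVal <- -Inf
  for (t in 0:(L - 2)) {
    w <- sum(p[lv <= t])
    if (w <= 0 || w >= 1) next
    mu <- sum(lv[lv <= t] * p[lv <= t])
    val <- (muT * w - mu)^2 / (w * (1 - w))
    if (val > bestVal + 1e-12) { bestVal <- val; best <- t }
  }
  best
}

# exhaustive-scan fuzzy-entropy threshold: argmin of the normalized Shannon
# fuzziness, smallest level on ties
oracleFuzzy <- function(counts) {
  L <- length(counts); N <- sum(counts)
  lv <- 0:(L - 1)
  best <- NULL; bestVal <- Inf
  for (t in 0:(L - 2)) {
    lo <- lv <= t
    n1 <- sum(counts[lo]); n2 <- N - n1
    if (n1 == 0 || n2 == 0) next
    mu1 <- sum(lv[lo] * counts[lo]) / n1
    mu2 <- sum(lv[!lo] * counts[!lo]) / n2
    E <- 0
    for (i in lv[counts > 0]) {
      m <- if (i <= t) 1 / (1 + abs(i - mu1)) else 1 / (1 + abs(i - mu2))
      s <- 0
      if (m > 0 && m < 1) s <- -m * log(m) - (1 - m) * log(1 - m)
      E <- E + s * counts[i + 1]
    }
    E <- E / (N * log(2))
    if (E < bestVal - 1e-12) { bestVal <- E; best <- t }
  }
  best
}

# check that t is a fixpoint of the Isodata update on this histogram
isIsodataFixpoint <- function(counts, t) {
  lv <- 0:(length(counts) - 1)
  lo <- lv <= t
  mu1 <- sum(lv[lo] * counts[lo]) / sum(counts[lo])
  mu2 <- sum(lv[!lo] * counts[!lo]) / sum(counts[!lo])
  floor((mu1 + mu2) / 2) == t
}

# random histogram with mass at >= 2 levels
randomHistogram <- function(L) {
  counts <- rpois(L, lambda = sample(c(0.5, 2, 10), L, replace = TRUE))
  while (sum(counts > 0) < 2)
    counts <- counts + rpois(L, 0.5)
  counts
}

# even-odd point-in-polygon test for a single point (ray casting)
oraclePointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# LabImage built directly from a matrix of Lab triplets (bypasses conversion)
labImageFrom <- function(L, a, b) {
  arr <- array(c(L, a, b), dim = c(dim(as.matrix(L)), 3))
  new("LabImage", data = arr, whitePoint = unname(equalEnergyWhite()),
      lowBranch = "linear")
}

# ChannelThresholds built directly from raw threshold levels
thresholdsFrom <- function(thr, nLevels, channel = "") {
  new("ChannelThresholds", channel = channel, nLevels = as.integer(nLevels),
      thresholds = as.numeric(sort(thr)),
      components = data.frame(tIsodata = NA_integer_, tOtsu = NA_integer_,
                              tFuzzy = NA_integer_, fused = sort(thr)))
}

# a* value -> default quantized level (221 bins over [-110, 110])
aStarLevel <- function(x) round(x + 110)

# random valid fuzzy error matrix
randomErrorMatrix <- function(K = 4) {
  cls <- LETTERS[seq_len(K)]
  correct <- stats::setNames(sample(50:500, K), cls)
  acc <- matrix(sample(0:40, K * K, replace = TRUE), K, K)
  err <- matrix(sample(0:40, K * K, replace = TRUE), K, K)
  diag(acc) <- diag(err) <- 0
  fuzzyErrorMatrix(correct, acc, err)
}
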