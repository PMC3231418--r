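# Automatic histogram thresholding: Isodata, Otsu, fuzzy-entropy, and their
# fusion by averaging. All operate on a GreyHistogram; thresholds are integer
# grey levels in absolute units. A pixel with value v belongs to the lower
# region iff v <= t.

.degenerateStop <- function() {
  stop(errorCondition(
    "degenerate histogram: fewer than two occupied grey levels",
    class = c("frostmap_degenerate_histogram", "error", "condition")))
}

.checkThresholdable <- function(hist) {
  if (sum(hist@counts) == 0) stop("empty histogram: no pixels")
  if (nOccupied(hist) < 2L) .degenerateStop()
}

# Class means below/above t (absolute levels). Returns c(mu1, mu2); NA where
# a side is empty.
.classMeans <- function(levels, counts, t) {
  lo <- levels <= t
  n1 <- sum(counts[lo]); n2 <- sum(counts[!lo])
  c(if (n1 > 0) sum(levels[lo] * counts[lo]) / n1 else NA_real_,
    if (n2 > 0) sum(levels[!lo] * counts[!lo]) / n2 else NA_real_)
}

#' Threshold diagnostics across all candidate levels
#'
#' For every candidate threshold t, the cumulative probability w(t), first
#' moment mu(t), class means mu1(t), mu2(t), Otsu between-class variance
#' sigmaB2(t), and the fuzzy-entropy fuzziness E(t). Candidates are all
#' levels but the last; sigmaB2 and fuzziness are NA where a side of the
#' split is empty.
#'
#' @param hist a \linkS4class{GreyHistogram}
#' @return data.frame with columns t, w, mu, mu1, mu2, sigmaB2, fuzziness
#' @export
thresholdDiagnostics <- function(hist) {
  stopifnot(is(hist, "GreyHistogram"))
  levels <- histLevels(hist)
  counts <- hist@counts
  N <- sum(counts)
  if (N == 0) stop("empty histogram: no pixels")
  p <- counts / N
  w <- cumsum(p)
  mu <- cumsum(levels * p)
  muT <- mu[length(mu)]

  L <- length(levels)
  cand <- seq_len(L - 1L)             # t = levels[1] .. levels[L-1]
  tvals <- levels[cand]
  wv <- w[cand]; muv <- mu[cand]
  valid <- wv > 0 & wv < 1
  sigmaB2 <- rep(NA_real_, length(cand))
  sigmaB2[valid] <- (muT * wv[valid] - muv[valid])^2 / (wv[valid] * (1 - wv[valid]))

  # fuzziness E(t): memberships 1/(1 + |i - mu_side(t)|), Shannon function,
  # normalized by N ln 2 so E lies in [0, 1]; 0 ln 0 taken as 0.
  fuzz <- rep(NA_real_, length(cand))
  occ <- counts > 0
  for (j in which(valid)) {
    t <- tvals[j]
    m <- .classMeans(levels, counts, t)
    muF <- ifelse(levels <= t, 1 / (1 + abs(levels - m[1L])),
                  1 / (1 + abs(levels - m[2L])))
    S <- -muF * log(muF) - (1 - muF) * log(1 - muF)
    S[muF <= 0 | muF >= 1] <- 0
    fuzz[j] <- sum(S[occ] * counts[occ]) / (N * log(2))
  }

  data.frame(t = tvals, w = wv, mu = muv,
             mu1 = vapply(tvals, function(t) .classMeans(levels, counts, t)[1L], 0),
             mu2 = vapply(tvals, function(t) .classMeans(levels, counts, t)[2L], 0),
             sigmaB2 = sigmaB2, fuzziness = fuzz)
}

#' Isodata threshold
#'
#' Iterative threshold selection: starting from the integer part of the
#' histogram mean, the threshold is repeatedly moved to the integer part of
#' the midpoint of the two class means until it stops changing. The result is
#' a fixpoint t = floor((mu1(t) + mu2(t)) / 2).
#'
#' @param hist a \linkS4class{GreyHistogram} with mass at two or more levels
#' @param diagnostics if TRUE, attach the diagnostics table
#' @return list with elements \code{threshold} (integer grey level) and,
#'   when requested, \code{diagnostics}
#' @export
isodataThreshold <- function(hist, diagnostics = FALSE) {
  .checkThresholdable(hist)
  levels <- histLevels(hist)
  counts <- hist@counts
  N <- sum(counts)
  t <- floor(sum(levels * counts) / N)
  repeat {
    m <- .classMeans(levels, counts, t)
    tNew <- floor((m[1L] + m[2L]) / 2)
    if (tNew == t) break
    t <- tNew
  }
  out <- list(threshold = as.integer(t))
  if (diagnostics) out$diagnostics <- thresholdDiagnostics(hist)
  out
}

#' Otsu threshold
#'
#' Selects the level maximizing the between-class variance
#' sigmaB2(t) = [muT w(t) - mu(t)]^2 / (w(t) [1 - w(t)]) of the normalized
#' histogram; ties resolve to the smallest level.
#'
#' @inheritParams isodataThreshold
#' @return list with \code{threshold} and optional \code{diagnostics}
#' @export
otsuThreshold <- function(hist, diagnostics = FALSE) {
  .checkThresholdable(hist)
  d <- thresholdDiagnostics(hist)
  i <- which.max(d$sigmaB2)           # NA-safe: which.max ignores NA
  out <- list(threshold = as.integer(d$t[i]))
  if (diagnostics) out$diagnostics <- d
  out
}

#' Fuzzy-entropy threshold
#'
#' Selects the level minimizing the fuzziness of the image: each pixel's
#' membership to its side of the split is 1 / (1 + |i - mu_side(t)|), and the
#' fuzziness is the Shannon entropy of those memberships averaged over pixels
#' (normalized to [0, 1]). Ties resolve to the smallest level.
#'
#' @inheritParams isodataThreshold
#' @return list with \code{threshold} and optional \code{diagnostics}
#' @export
fuzzyThreshold <- function(hist, diagnostics = FALSE) {
  .checkThresholdable(hist)
  d <- thresholdDiagnostics(hist)
  i <- which.min(d$fuzziness)
  out <- list(threshold = as.integer(d$t[i]))
  if (diagnostics) out$diagnostics <- d
  out
}

#' Fused (combined) threshold
#'
#' Averages the Isodata, Otsu and fuzzy-entropy thresholds,
#' t = floor((tI + tO + tF) / 3), smoothing out the highest and lowest of the
#' three. This is the operating threshold applied to each spectral channel.
#'
#' @inheritParams isodataThreshold
#' @return list with \code{threshold} (fused), \code{tIsodata}, \code{tOtsu},
#'   \code{tFuzzy}
#' @export
combinedThreshold <- function(hist) {
  tI <- isodataThreshold(hist)$threshold
  tO <- otsuThreshold(hist)$threshold
  tF <- fuzzyThreshold(hist)$threshold
  list(threshold = as.integer(floor((tI + tO + tF) / 3)),
       tIsodata = tI, tOtsu = tO, tFuzzy = tF)
}

#' Successive multi-level thresholding of a channel
#'
#' Computes M strictly ordered fused thresholds. The first comes from the
#' full histogram; each further threshold is obtained by re-thresholding the
#' sub-histogram of the current partition with the largest
#' population-weighted within-partition variance (mirroring the variance
#' logic of the later class-merging stage). Partitions too small or
#' degenerate to threshold are skipped; if no partition can be split before M
#' thresholds are found, an error of class
#' \code{frostmap_split_error} is raised.
#'
#' @param values integer vector or matrix of quantized grey levels
#' @param M number of thresholds (>= 1); yields M + 1 partitions
#' @param nLevels total grey levels of the quantization
#' @param channel optional channel name stored in the result
#' @return a \linkS4class{ChannelThresholds}
#' @export
successiveThresholds <- function(values, M, nLevels = NULL, channel = "") {
  if (M < 1L) stop("M must be >= 1")
  v <- as.integer(values)
  full <- greyHistogram(v, nLevels = nLevels)
  nLevels <- length(full@counts)
  first <- combinedThreshold(full)
  thr <- first$threshold
  comp <- data.frame(tIsodata = first$tIsodata, tOtsu = first$tOtsu,
                     tFuzzy = first$tFuzzy, fused = first$threshold)

  while (length(thr) < M) {
    # partitions delimited by current thresholds, in level space
    bounds <- c(-1L, sort(thr), nLevels - 1L)
    scored <- list()
    for (k in seq_len(length(bounds) - 1L)) {
      lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
      inPart <- v > bounds[k] & v <= hi
      n <- sum(inPart)
      if (n < 2L) next
      pv <- v[inPart]
      if (length(unique(pv)) < 2L) next
      score <- n * stats::var(pv)
      scored[[length(scored) + 1L]] <- list(lo = lo, hi = hi, score = score)
    }
    if (length(scored) == 0L)
      stop(errorCondition(
        sprintf("no partition can be split further: %d of %d thresholds found",
                length(thr), M),
        class = c("frostmap_split_error", "error", "condition")))
    ord <- order(vapply(scored, `[[`, 0, "score"), decreasing = TRUE)
    placed <- FALSE
    for (k in ord) {
      part <- scored[[k]]
      sub <- try(subHistogram(full, part$lo, part$hi), silent = TRUE)
      if (inherits(sub, "try-error")) next
      res <- tryCatch(combinedThreshold(sub), error = function(e) NULL)
      if (is.null(res)) next
      # a threshold at the partition's upper edge would not split it
      if (res$threshold >= part$hi || res$threshold %in% thr) next
      thr <- c(thr, res$threshold)
      comp <- rbind(comp, data.frame(tIsodata = res$tIsodata,
                                     tOtsu = res$tOtsu, tFuzzy = res$tFuzzy,
                                     fused = res$threshold))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(errorCondition(
        sprintf("no partition can be split further: %d of %d thresholds found",
                length(thr), M),
        class = c("frostmap_split_error", "error", "condition")))
  }
  o <- order(thr)
  new("ChannelThresholds", channel = channel, nLevels = as.integer(nLevels),
      thresholds = as.numeric(thr[o]), components = comp[o, , drop = FALSE])
}
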