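# Pixel coding, labelling, class statistics and variance-driven merging.
#
# Each channel is partitioned by its fused thresholds; a pixel's three
# partition codes combine into a single label p = n^2 cL + n ca + cb. Classes
# are then merged while any pair's within-class spread reaches its
# between-class separation, and the number of thresholds grows dynamically
# when no merge happens at all.

#' Code pixels against per-channel thresholds
#'
#' A pixel's code in a channel is the number of thresholds strictly below its
#' quantized value: 0 for values at or below the first threshold, M for
#' values above the last. All three channels must carry the same number of
#' thresholds.
#'
#' @param lab a \linkS4class{LabImage}
#' @param thresholdsL,thresholdsA,thresholdsB \linkS4class{ChannelThresholds}
#'   for the L*, a* and b* channels (quantization is taken from their
#'   \code{nLevels})
#' @return a \linkS4class{CodedImage}
#' @export
encodePixels <- function(lab, thresholdsL, thresholdsA, thresholdsB) {
  thr <- list(L = thresholdsL, a = thresholdsA, b = thresholdsB)
  M <- unique(vapply(thr, function(x) length(thresholds(x)), 0L))
  if (length(M) != 1L)
    stop("all channels must carry the same number of thresholds")
  d <- dim(lab@data)
  codes <- array(0L, dim = d)
  for (k in 1:3) {
    ch <- c("L", "a", "b")[k]
    q <- quantizeChannel(lab, ch, nLevels = thr[[ch]]@nLevels)
    codes[, , k] <- codeValues(q, thresholds(thr[[ch]]))
  }
  new("CodedImage", codes = codes, nPartitions = M + 1L)
}

# number of thresholds strictly below each value (v <= t1 -> 0, v > tM -> M)
codeValues <- function(values, thr) {
  matrix(findInterval(as.vector(values) - 0.5, sort(thr)),
         nrow = nrow(values))
}

#' Combine channel codes into class labels
#'
#' With n = M + 1 partitions per channel and d = 3 channels there are n^3
#' possible classes; a pixel with codes (cL, ca, cb) gets label
#' p = n^2 cL + n ca + cb, a bijection between code triplets and 0 .. n^3 - 1.
#'
#' @param coded a \linkS4class{CodedImage}
#' @return a \linkS4class{LabelMap}
#' @export
labelPixels <- function(coded) {
  stopifnot(is(coded, "CodedImage"))
  n <- coded@nPartitions
  if (max(coded@codes) > n - 1L) stop("corrupt input: code exceeds M")
  p <- n^2 * coded@codes[, , 1L] + n * coded@codes[, , 2L] + coded@codes[, , 3L]
  new("LabelMap", labels = matrix(as.integer(p), nrow = dim(coded@codes)[1L]),
      nPartitions = n)
}

#' Per-class spectral statistics
#'
#' For every occupied class k: its population N_k, spectral mean
#' mu_k = (muL, mua, mub) over member pixels, and within-class spread
#' sigma_k. With \code{varianceForm = "as_printed"} (default) sigma_k is the
#' mean Euclidean distance of members to the class mean scaled by 1/d
#' (d = 3 channels); with \code{"squared"} it is the dimensionally consistent
#' mean squared deviation (1/(d N_k)) sum ||x - mu||^2, directly comparable
#' to the between-class separation.
#'
#' @param lab a \linkS4class{LabImage}
#' @param labels a \linkS4class{LabelMap} of the same size
#' @param varianceForm "as_printed" or "squared"
#' @return data.frame with columns label, N, muL, mua, mub, sigma
#' @export
classStatistics <- function(lab, labels, varianceForm = c("as_printed", "squared")) {
  varianceForm <- match.arg(varianceForm)
  lv <- as.vector(labelMatrix(labels))
  X <- matrix(lab@data, ncol = 3L)
  if (length(lv) != nrow(X)) stop("label map and image sizes differ")
  f <- factor(lv)
  N <- as.vector(table(f))
  mu <- rowsum(X, f) / N
  dev2 <- rowSums((X - mu[as.integer(f), , drop = FALSE])^2)
  if (varianceForm == "as_printed") dev2 <- sqrt(dev2)
  sigma <- as.vector(rowsum(dev2, f)) / (3 * N)
  data.frame(label = as.integer(levels(f)), N = N,
             muL = mu[, 1L], mua = mu[, 2L], mub = mu[, 3L],
             sigma = sigma, row.names = NULL)
}

#' Between-class spectral separation
#'
#' sigma_kh = (1/d) ||mu_k - mu_h||^2, the mean squared difference of the two
#' class means over the d = 3 channels; symmetric and zero for identical
#' means.
#'
#' @param a,b single rows of a \code{\link{classStatistics}} table
#' @return non-negative numeric
#' @export
betweenClassSeparation <- function(a, b) {
  ((a$muL - b$muL)^2 + (a$mua - b$mua)^2 + (a$mub - b$mub)^2) / 3
}

#' Pairwise separation matrix
#'
#' @param stats a \code{\link{classStatistics}} table
#' @return symmetric matrix of sigma_kh with zero diagonal, dimnames = labels
#' @export
separationMatrix <- function(stats) {
  mu <- as.matrix(stats[, c("muL", "mua", "mub")])
  G <- tcrossprod(mu)
  sq <- diag(G)
  S <- (outer(sq, sq, `+`) - 2 * G) / 3
  S[S < 0] <- 0                      # round-off guard
  dimnames(S) <- list(stats$label, stats$label)
  S
}

# candidate pairs and violations; returns NULL when no pair qualifies
.mergeCandidates <- function(stats, S, all = FALSE) {
  K <- nrow(stats)
  if (K < 2L) return(NULL)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  sk <- stats$sigma[idx[, 1L]]
  sh <- stats$sigma[idx[, 2L]]
  skh <- S[idx]
  viol <- pmax(sk, sh) - skh
  qual <- if (all) rep(TRUE, length(viol)) else viol >= 0
  if (!any(qual)) return(NULL)
  best <- which(qual)[which.max(viol[qual])]
  i <- idx[best, 1L]; j <- idx[best, 2L]
  # merged class keeps the label of the smaller-variance member
  keepFirst <- stats$sigma[i] <= stats$sigma[j]
  list(keep = stats$label[if (keepFirst) i else j],
       drop = stats$label[if (keepFirst) j else i],
       sigmaK = sk[best], sigmaH = sh[best], sigmaKH = skh[best],
       violation = viol[best])
}

#' One merging step
#'
#' Any pair of classes with sigma_k >= sigma_kh or sigma_h >= sigma_kh (their
#' spectral spread reaching their separation, i.e. overlapping classes) is a
#' merge candidate; the pair with the greatest violation
#' max(sigma_k, sigma_h) - sigma_kh merges first, and the fused class keeps
#' the label of the smaller-variance member.
#'
#' @param labels a \linkS4class{LabelMap}
#' @param lab the \linkS4class{LabImage} the labels refer to
#' @param varianceForm passed to \code{\link{classStatistics}}
#' @return list(labels, merged = logical, detail = merge record or NULL)
#' @export
mergeStep <- function(labels, lab, varianceForm = c("as_printed", "squared")) {
  varianceForm <- match.arg(varianceForm)
  stats <- classStatistics(lab, labels, varianceForm)
  if (nrow(stats) < 2L)
    return(list(labels = labels, merged = FALSE, detail = NULL))
  cand <- .mergeCandidates(stats, separationMatrix(stats))
  if (is.null(cand))
    return(list(labels = labels, merged = FALSE, detail = NULL))
  list(labels = relabel(labels, cand$drop, cand$keep), merged = TRUE,
       detail = cand)
}

relabel <- function(labels, from, to) {
  m <- labelMatrix(labels)
  m[m == from] <- as.integer(to)
  new("LabelMap", labels = m, nPartitions = labels@nPartitions)
}

#' Merge classes until all pairs are separated
#'
#' Repeats \code{\link{mergeStep}} (recomputing statistics after every merge)
#' until every remaining pair satisfies sigma_kh > sigma_k and
#' sigma_kh > sigma_h. Terminates in at most (initial classes - 1) merges.
#'
#' @inheritParams mergeStep
#' @return list(labels, nMerges, trace = data.frame of merge decisions)
#' @export
mergeUntilStable <- function(labels, lab, varianceForm = c("as_printed", "squared")) {
  varianceForm <- match.arg(varianceForm)
  trace <- list()
  repeat {
    step <- mergeStep(labels, lab, varianceForm)
    if (!step$merged) break
    labels <- step$labels
    trace[[length(trace) + 1L]] <- as.data.frame(step$detail)
  }
  list(labels = labels, nMerges = length(trace),
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

# force-merge closest (largest violation, possibly negative) pairs down to K
forceMergeTo <- function(labels, lab, K, varianceForm = "as_printed") {
  trace <- list()
  repeat {
    stats <- classStatistics(lab, labels, varianceForm)
    if (nrow(stats) <= K) break
    cand <- .mergeCandidates(stats, separationMatrix(stats), all = TRUE)
    labels <- relabel(labels, cand$drop, cand$keep)
    trace[[length(trace) + 1L]] <- as.data.frame(cand)
  }
  list(labels = labels,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Unsupervised classification of a Lab image
#'
#' The full dynamic-clustering pipeline: fused successive thresholds on each
#' channel (starting with M = 1 threshold per channel), pixel coding and
#' labelling, then merging until stable. If no merge occurred at all the
#' partition is considered too coarse: M is incremented on all channels and
#' the process restarts, until a fusion occurs (or \code{maxThresholds} is
#' reached, or no channel partition can be split further). When
#' \code{targetClasses} is given and more classes remain, the pair with the
#' largest max(sigma_k, sigma_h) - sigma_kh is force-merged repeatedly until
#' exactly that many remain; asking for more classes than remain is an error
#' (the method only merges).
#'
#' @param lab a \linkS4class{LabImage}
#' @param targetClasses optional number of classes K to force-merge down to
#' @param varianceForm "as_printed" or "squared", see
#'   \code{\link{classStatistics}}
#' @param maxThresholds cap on thresholds per channel for the dynamic restart
#' @param minPopulation classes smaller than this are first absorbed into
#'   their nearest class by separation (default 1: keep all)
#' @return list with elements \code{labels} (\linkS4class{LabelMap}),
#'   \code{stats} (class statistics of the final map), \code{thresholds}
#'   (list of \linkS4class{ChannelThresholds}), \code{M}, \code{nMerges},
#'   \code{trace}
#' @export
classifyImage <- function(lab, targetClasses = NULL,
                          varianceForm = c("as_printed", "squared"),
                          maxThresholds = 4L, minPopulation = 1L) {
  varianceForm <- match.arg(varianceForm)
  stopifnot(is(lab, "LabImage"))
  q <- list(L = quantizeChannel(lab, "L"),
            a = quantizeChannel(lab, "a"),
            b = quantizeChannel(lab, "b"))
  nl <- c(L = 101L, a = 221L, b = 221L)

  M <- 1L
  result <- NULL
  repeat {
    thr <- tryCatch(
      lapply(c(L = "L", a = "a", b = "b"), function(ch)
        successiveThresholds(q[[ch]], M, nLevels = nl[[ch]], channel = ch)),
      frostmap_split_error = function(e) NULL)
    if (is.null(thr)) break                    # cannot refine further
    coded <- encodePixels(lab, thr$L, thr$a, thr$b)
    labels <- labelPixels(coded)
    ms <- mergeUntilStable(labels, lab, varianceForm)
    result <- list(labels = ms$labels, thresholds = thr, M = M,
                   nMerges = ms$nMerges, trace = ms$trace)
    if (ms$nMerges > 0L || M >= maxThresholds) break
    M <- M + 1L
  }
  if (is.null(result)) stop("image could not be partitioned")

  labels <- result$labels
  if (minPopulation > 1L) {
    repeat {
      stats <- classStatistics(lab, labels, varianceForm)
      small <- which(stats$N < minPopulation)
      if (length(small) == 0L || nrow(stats) < 2L) break
      S <- separationMatrix(stats)
      i <- small[1L]
      j <- setdiff(order(S[i, ]), i)[1L]
      labels <- relabel(labels, stats$label[i], stats$label[j])
    }
  }

  if (!is.null(targetClasses)) {
    nNow <- length(occupiedLabels(labels))
    if (targetClasses > nNow)
      stop(sprintf(
        "cannot produce %d classes: only %d remain and the method only merges",
        targetClasses, nNow))
    fm <- forceMergeTo(labels, lab, targetClasses, varianceForm)
    labels <- fm$labels
    result$trace <- rbind(result$trace, fm$trace)
  }

  result$labels <- labels
  result$stats <- classStatistics(lab, labels, varianceForm)
  result
}

#' Map four spectral classes to crop-damage roles
#'
#' Assigns the four agronomic roles: SG (shady ground) is the class with the
#' lowest mean lightness; among the rest, GO (green, healthy oat) has the
#' most negative mean a* (greenest); DO (dried oat) has the most positive
#' mean b* (yellowest) of the remaining two; HD (half-dried) is the
#' remainder. The mapping is a convenience heuristic emitted with the
#' statistics so an expert can override it; ties resolve by class label order
#' with a warning.
#'
#' @param stats a \code{\link{classStatistics}} table with exactly 4 rows
#' @return named character vector, names = class labels, values in
#'   c("GO", "DO", "HD", "SG")
#' @export
semanticMapping <- function(stats) {
  if (nrow(stats) != 4L)
    stop(sprintf("semantic mapping needs exactly 4 classes, got %d", nrow(stats)))
  stats <- stats[order(stats$label), ]
  roles <- rep(NA_character_, 4L)
  tieWarn <- function(x) {
    if (anyDuplicated(round(x, 10)) ) warning("tied class statistics; roles assigned by label order")
    which.min(x)
  }
  sg <- tieWarn(stats$muL)
  roles[sg] <- "SG"
  rest <- setdiff(1:4, sg)
  go <- rest[tieWarn(stats$mua[rest])]
  roles[go] <- "GO"
  rest <- setdiff(rest, go)
  do_ <- rest[tieWarn(-stats$mub[rest])]
  roles[do_] <- "DO"
  roles[setdiff(rest, do_)] <- "HD"
  stats::setNames(roles, stats$label)
}

#' Convert a label map to a role map
#'
#' @param labels a \linkS4class{LabelMap}
#' @param roles named character vector mapping label -> role (as returned by
#'   \code{\link{semanticMapping}})
#' @return character matrix of roles, same shape as the label map
#' @export
applyRoles <- function(labels, roles) {
  m <- labelMatrix(labels)
  occ <- unique(as.vector(m))
  if (!all(as.character(occ) %in% names(roles)))
    stop("corrupt input: label map contains labels without a role")
  matrix(unname(roles[as.character(m)]), nrow = nrow(m))
}

#' Frost-damage area report
#'
#' Per-role pixel counts, fractions and ground areas, and the usable
#' (harvestable) area: all of the green-oat area plus a fraction w of the
#' half-dried area. Field experts put the usable share of half-dried plants
#' at roughly 40-60%, hence the default w = 0.5.
#'
#' @param roleMap character matrix of roles (from \code{\link{applyRoles}})
#' @param areaPerPixel ground area of one pixel in square metres
#' @param usableHdFraction w in [0, 1], usable share of the HD class
#' @return list with \code{perRole} data.frame (role, pixels, fraction,
#'   areaM2), \code{totalAreaM2}, \code{usableAreaM2}
#' @export
damageReport <- function(roleMap, areaPerPixel = 1, usableHdFraction = 0.5) {
  if (usableHdFraction < 0 || usableHdFraction > 1)
    stop("usableHdFraction must lie in [0, 1]")
  known <- c("GO", "DO", "HD", "SG")
  if (!all(as.vector(roleMap) %in% known))
    stop("corrupt input: unknown role in map")
  tab <- table(factor(roleMap, levels = known))
  n <- sum(tab)
  perRole <- data.frame(role = known, pixels = as.vector(tab),
                        fraction = as.vector(tab) / n,
                        areaM2 = as.vector(tab) * areaPerPixel)
  usable <- perRole$areaM2[perRole$role == "GO"] +
    usableHdFraction * perRole$areaM2[perRole$role == "HD"]
  list(perRole = perRole, totalAreaM2 = n * areaPerPixel,
       usableAreaM2 = usable, usableHdFraction = usableHdFraction)
}
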