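# Accuracy assessment of the thematic map: multinomial sample-size design,
# polygon sample units scored against the classified map under fuzzy rules,
# deterministic and fuzzy error matrices, and the derived accuracy measures.

#' Multinomial sample-size design
#'
#' Number of reference sample units required for a k-class map at accuracy b:
#' n = ceiling(B Pi (1 - Pi) / b^2), where Pi is the image fraction of the
#' class of interest and B the chi-square quantile with 1 degree of freedom
#' at probability 1 - b/k. By default the worst-case class (the supplied
#' fraction maximizing Pi (1 - Pi)) is used.
#'
#' @param fractions per-class image-surface fractions, each in [0, 1]
#' @param accuracy b, the desired accuracy (default 0.05 for 95% confidence)
#' @param nClasses k, number of classes (default: length of fractions)
#' @param B chi-square coefficient; computed from \code{qchisq(1 - b/k, 1)}
#'   when NULL, but may be supplied to match a printed table
#' @param class optional index of the class whose fraction should be used
#'   instead of the worst case
#' @return list with n (required sample units), B, fraction used, and the
#'   per-class largest-remainder allocation of n
#' @examples
#' sampleSize(c(0.35, 0.16, 0.16, 0.33), accuracy = 0.05, B = 6.36640,
#'            class = 2)$n   # 343
#' @export
sampleSize <- function(fractions, accuracy = 0.05, nClasses = length(fractions),
                       B = NULL, class = NULL) {
  if (accuracy <= 0 || accuracy >= 1) stop("accuracy must lie in (0, 1)")
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (is.null(B)) B <- stats::qchisq(1 - accuracy / nClasses, df = 1)
  if (B <= 0) stop("B must be positive")
  Pi <- if (is.null(class)) fractions[which.max(fractions * (1 - fractions))]
        else fractions[class]
  if (Pi == 0 || Pi == 1) {
    warning("degenerate class fraction (0 or 1): zero sample units required")
    n <- 0L
  } else {
    n <- as.integer(ceiling(B * Pi * (1 - Pi) / accuracy^2))
  }
  list(n = n, B = B, fraction = Pi,
       allocation = if (n > 0 && abs(sum(fractions) - 1) < 1e-8)
         allocateSamples(n, fractions) else NULL)
}

#' Largest-remainder apportionment of sample units
#'
#' @param n total sample units
#' @param fractions per-class fractions summing to 1
#' @return integer vector of per-class counts summing to n
#' @export
allocateSamples <- function(n, fractions) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Fraction of a polygon's pixels carrying a role
#'
#' @param poly a \linkS4class{PolygonSample}
#' @param roleMap character matrix of classified roles
#' @param role the role to measure
#' @return fraction in [0, 1]
#' @export
overlapFraction <- function(poly, roleMap, role) {
  px <- rasterizePolygon(poly, dim(roleMap))
  mean(roleMap[px] == role)
}

#' Score one polygon against the classified map under the fuzzy rules
#'
#' With f the overlap between the polygon and its reference class on the
#' classified map: f = 1 is absolutely correct (a diagonal count); 0.5 <= f
#' < 1 is acceptable, counted in the left (acceptable) counter of the cell
#' whose row is the majority non-reference classified role; f < 0.5 is an
#' error, counted in the right (unacceptable) counter of the cell whose row
#' is the majority classified role. Columns are always the reference class.
#'
#' @param poly a \linkS4class{PolygonSample} (its role is the reference)
#' @param roleMap character matrix of classified roles
#' @return list(outcome, row, col, pixels)
#' @export
scorePolygon <- function(poly, roleMap) {
  px <- rasterizePolygon(poly, dim(roleMap))
  got <- roleMap[px]
  if (anyNA(got)) stop("corrupt map: unlabelled pixels within polygon")
  f <- mean(got == poly@role)
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
  if (f == 1) {
    list(outcome = "absolutely_correct", row = poly@role, col = poly@role,
         pixels = length(px))
  } else if (f >= 0.5) {
    list(outcome = "acceptable", row = majority(got[got != poly@role]),
         col = poly@role, pixels = length(px))
  } else {
    row <- majority(got)
    # with 3+ classes the reference can still be the plurality while
    # covering under half the polygon; attribute the error to the leading
    # wrong class so it stays off-diagonal
    if (row == poly@role) row <- majority(got[got != poly@role])
    list(outcome = "error", row = row, col = poly@role, pixels = length(px))
  }
}

#' Build the fuzzy error matrix from scored polygons
#'
#' Accumulates \code{\link{scorePolygon}} outcomes over all sample units.
#' With \code{weighting = "pixel"} (default) each polygon contributes its
#' pixel count, so the grand total is the sampled surface; with
#' \code{"unit"} each polygon counts once.
#'
#' @param polys list of \linkS4class{PolygonSample}
#' @param roleMap character matrix of classified roles
#' @param classes class name order of the matrix (default: sorted union of
#'   reference and map roles)
#' @param weighting "pixel" or "unit"
#' @return a \linkS4class{FuzzyErrorMatrix}
#' @export
buildErrorMatrix <- function(polys, roleMap, classes = NULL,
                             weighting = c("pixel", "unit")) {
  weighting <- match.arg(weighting)
  if (is.null(classes))
    classes <- sort(unique(c(vapply(polys, slot, "", "role"),
                             as.vector(roleMap))))
  K <- length(classes)
  correct <- stats::setNames(numeric(K), classes)
  acc <- err <- matrix(0, K, K, dimnames = list(classes, classes))
  for (p in polys) {
    s <- scorePolygon(p, roleMap)
    w <- if (weighting == "pixel") s$pixels else 1
    if (s$outcome == "absolutely_correct") {
      correct[s$col] <- correct[s$col] + w
    } else if (s$outcome == "acceptable") {
      acc[s$row, s$col] <- acc[s$row, s$col] + w
    } else {
      err[s$row, s$col] <- err[s$row, s$col] + w
    }
  }
  new("FuzzyErrorMatrix", correct = correct, acceptable = acc,
      unacceptable = err)
}

#' Construct a fuzzy error matrix from counts
#'
#' @param correct named numeric vector of diagonal (absolutely correct)
#'   counts; names are the class labels
#' @param acceptable,unacceptable K x K matrices of off-diagonal counts
#'   (rows = classified, columns = reference); diagonals must be zero
#' @return a \linkS4class{FuzzyErrorMatrix}
#' @export
fuzzyErrorMatrix <- function(correct, acceptable, unacceptable) {
  K <- length(correct)
  cls <- names(correct)
  dimnames(acceptable) <- dimnames(unacceptable) <- list(cls, cls)
  new("FuzzyErrorMatrix", correct = correct,
      acceptable = as.matrix(acceptable), unacceptable = as.matrix(unacceptable))
}

#' Collapse to the deterministic error matrix
#'
#' Off-diagonal (acceptable; unacceptable) pairs are summed; the diagonal is
#' kept. Rows classify, columns reference.
#'
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @return K x K numeric matrix
#' @export
deterministicMatrix <- function(m) {
  out <- m@acceptable + m@unacceptable
  diag(out) <- m@correct
  out
}

#' Grand total of an error matrix
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @return total sample-unit count
#' @export
grandTotal <- function(m) sum(deterministicMatrix(m))

# nearest-integer percent (round half up, matching reported tables)
asPercent <- function(p) floor(100 * p + 0.5)

.accuracyResult <- function(num, den, what) {
  if (den == 0)
    stop(sprintf("undefined %s: zero total", what))
  p <- num / den
  structure(list(numerator = num, denominator = den, proportion = p,
                 percent = asPercent(p),
                 complementPercent = 100 - asPercent(p),
                 complementProportion = 1 - p),
            class = "frostmap_accuracy")
}

#' @export
print.frostmap_accuracy <- function(x, ...) {
  cat(sprintf("%s / %s = %.4f (%d%%)\n",
              format(x$numerator, big.mark = ","),
              format(x$denominator, big.mark = ","),
              x$proportion, x$percent))
  invisible(x)
}

#' Overall map accuracy
#'
#' Deterministic: sum of the major diagonal over the grand total. Fuzzy:
#' diagonal plus all acceptable counts over the grand total.
#'
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @param mode "deterministic" or "fuzzy"
#' @return a \code{frostmap_accuracy} (numerator, denominator, proportion,
#'   nearest-integer percent)
#' @export
overallAccuracy <- function(m, mode = c("deterministic", "fuzzy")) {
  mode <- match.arg(mode)
  num <- sum(m@correct) + if (mode == "fuzzy") sum(m@acceptable) else 0
  .accuracyResult(num, grandTotal(m), "overall accuracy")
}

#' Classifier's (user's) accuracy and commission error
#'
#' For one class: the diagonal count (plus, in fuzzy mode, the acceptable
#' counts of its row) divided by the row total, i.e. all units the
#' classifier put in that class. The commission error (wrongly including
#' area in the class) is its complement.
#'
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @param class class name
#' @param mode "deterministic" or "fuzzy"
#' @return a \code{frostmap_accuracy}; commission error is
#'   \code{complementPercent}
#' @export
classifierAccuracy <- function(m, class, mode = c("deterministic", "fuzzy")) {
  mode <- match.arg(mode)
  det <- deterministicMatrix(m)
  num <- m@correct[class] + if (mode == "fuzzy") sum(m@acceptable[class, ]) else 0
  .accuracyResult(unname(num), sum(det[class, ]),
                  sprintf("classifier accuracy for %s", class))
}

#' Expert's (producer's) accuracy and omission error
#'
#' For one class: the diagonal count (plus, in fuzzy mode, the acceptable
#' counts of its column) divided by the column total, i.e. all reference
#' units of that class. The omission error (excluding area from the class it
#' belongs to) is its complement.
#'
#' @inheritParams classifierAccuracy
#' @return a \code{frostmap_accuracy}; omission error is
#'   \code{complementPercent}
#' @export
expertAccuracy <- function(m, class, mode = c("deterministic", "fuzzy")) {
  mode <- match.arg(mode)
  det <- deterministicMatrix(m)
  num <- m@correct[class] + if (mode == "fuzzy") sum(m@acceptable[, class]) else 0
  .accuracyResult(unname(num), sum(det[, class]),
                  sprintf("expert accuracy for %s", class))
}

#' All accuracy measures of an error matrix
#'
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @return data.frame with one row per class and mode, plus overall rows
#' @export
accuracyReport <- function(m) {
  cls <- matrixClasses(m)
  rows <- list()
  for (mode in c("deterministic", "fuzzy")) {
    o <- overallAccuracy(m, mode)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = "overall", class = NA_character_, mode = mode,
      numerator = o$numerator, denominator = o$denominator,
      percent = o$percent, errorPercent = NA_real_)
    for (cl in cls) {
      ca <- classifierAccuracy(m, cl, mode)
      ea <- expertAccuracy(m, cl, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = "classifier", class = cl, mode = mode,
        numerator = ca$numerator, denominator = ca$denominator,
        percent = ca$percent, errorPercent = ca$complementPercent)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = "expert", class = cl, mode = mode,
        numerator = ea$numerator, denominator = ea$denominator,
        percent = ea$percent, errorPercent = ea$complementPercent)
    }
  }
  do.call(rbind, rows)
}

# "a;u" cell formatting used for display and CSV round-trip
formatErrorMatrix <- function(m) {
  K <- length(m@correct)
  out <- matrix("", K, K, dimnames = dimnames(m@acceptable))
  for (i in seq_len(K)) for (j in seq_len(K))
    out[i, j] <- if (i == j) format(m@correct[i])
                 else sprintf("%s;%s", format(m@acceptable[i, j]),
                              format(m@unacceptable[i, j]))
  out
}

#' Write an error matrix as CSV with "a;u" pair cells
#' @param m a \linkS4class{FuzzyErrorMatrix}
#' @param path output path
#' @return invisibly, the path
#' @export
writeErrorMatrixCsv <- function(m, path) {
  utils::write.csv(formatErrorMatrix(m), path, quote = TRUE)
  invisible(path)
}

#' Read an error matrix written by \code{\link{writeErrorMatrixCsv}}
#' @param path CSV path
#' @return a \linkS4class{FuzzyErrorMatrix}
#' @export
readErrorMatrixCsv <- function(path) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                         colClasses = "character")
  cls <- rownames(raw)
  K <- length(cls)
  correct <- stats::setNames(numeric(K), cls)
  acc <- err <- matrix(0, K, K, dimnames = list(cls, cls))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    cell <- raw[i, j]
    if (i == j) correct[i] <- as.numeric(cell)
    else {
      parts <- as.numeric(strsplit(cell, ";", fixed = TRUE)[[1L]])
      acc[i, j] <- parts[1L]; err[i, j] <- parts[2L]
    }
  }
  fuzzyErrorMatrix(correct, acc, err)
}
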