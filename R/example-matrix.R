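#' Example fuzzy error matrix from a frost-damage survey
#'
#' A synthetic 4-class (GO, DO, HD, SG) fuzzy error matrix representative of
#' a polygon-based, pixel-weighted accuracy assessment of an oat frost-damage
#' map. It is reconstructed to be consistent with a published survey's
#' marginal totals (diagonal counts, row/column totals and their fuzzy
#' counterparts, and two worked off-diagonal cells); the two off-diagonal
#' cells those marginals do not pin down were fixed by setting the DO-row
#' confusion with GO to zero. Useful as a worked example for the accuracy
#' operations: its overall deterministic accuracy is 63,400/68,800 = 92% and
#' its fuzzy overall accuracy 66,200/68,800 = 96%.
#'
#' @return a \linkS4class{FuzzyErrorMatrix} over classes GO, DO, HD, SG
#' @examples
#' m <- exampleSurveyMatrix()
#' overallAccuracy(m, "deterministic")$percent   # 92
#' classifierAccuracy(m, "DO", "fuzzy")$percent  # 96
#' @export
exampleSurveyMatrix <- function() {
  cls <- c("GO", "DO", "HD", "SG")
  correct <- stats::setNames(c(22600, 8800, 9200, 22800), cls)
  acc <- matrix(0, 4, 4, dimnames = list(cls, cls))
  err <- acc
  # rows = classified, columns = reference; cells are (acceptable, error)
  acc["GO", "DO"] <- 600;  err["GO", "DO"] <- 600
  acc["GO", "HD"] <- 400;  err["GO", "HD"] <- 600
  acc["DO", "HD"] <- 600;  err["DO", "HD"] <- 400
  acc["HD", "DO"] <- 600;  err["HD", "DO"] <- 200
  acc["SG", "GO"] <- 600;  err["SG", "GO"] <- 800
  fuzzyErrorMatrix(correct, acc, err)
}
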