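#' Confusion matrix of per-cell nucleolus counts
#'
#' Cross-tabulates true against predicted per-cell counts over the class
#' range 0..max observed.
#'
#' @param true_counts,pred_counts paired integer vectors of equal length.
#' @return Integer matrix of class \code{"CountConfusion"}, rows = true
#'   count, columns = predicted count, dimnames 0..max.
#' @export
countConfusion <- function(true_counts, pred_counts) {
  if (length(true_counts) != length(pred_counts))
    stop("'true_counts' and 'pred_counts' must have equal length")
  stopifnot(all(true_counts >= 0), all(pred_counts >= 0))
  kmax <- max(true_counts, pred_counts, 0)
  cls <- 0:kmax
  m <- matrix(0L, length(cls), length(cls), dimnames = list(
    true = as.character(cls), predicted = as.character(cls)))
  for (i in seq_along(true_counts))
    m[true_counts[i] + 1L, pred_counts[i] + 1L] <-
      m[true_counts[i] + 1L, pred_counts[i] + 1L] + 1L
  structure(m, class = c("CountConfusion", class(m)))
}

#' Per-class precision, sensitivity and specificity
#'
#' One-vs-rest scores for one count class: precision = TP / (TP + FP),
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). An empty
#' denominator yields \code{NA} (an undefined score is flagged, not
#' reported as 0).
#'
#' @param confusion a \code{"CountConfusion"} matrix.
#' @param class_k the count class (e.g. 2 for "two nucleoli").
#' @return Named numeric: precision, sensitivity, specificity.
#' @export
classScores <- function(confusion, class_k) {
  key <- as.character(class_k)
  if (!key %in% rownames(confusion))
    stop("class ", class_k, " outside the matrix range")
  tp <- confusion[key, key]
  fp <- sum(confusion[, key]) - tp
  fn <- sum(confusion[key, ]) - tp
  tn <- sum(confusion) - tp - fp - fn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(precision = div(tp, tp + fp),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp))
}

#' Pixel-overlap scores of two binary masks
#'
#' Dice coefficient, pixel precision and pixel recall of a predicted mask
#' against a reference mask. Two empty masks have Dice 1 (a message notes
#' the convention).
#'
#' @param pred_mask,true_mask aligned 0/1 matrices.
#' @return Named numeric: dice, precision, recall (NA when undefined).
#' @export
maskOverlapScores <- function(pred_mask, true_mask) {
  stopifnot(identical(dim(pred_mask), dim(true_mask)))
  np <- sum(pred_mask == 1); nt <- sum(true_mask == 1)
  inter <- sum(pred_mask == 1 & true_mask == 1)
  if (np == 0 && nt == 0) {
    message("both masks empty: Dice defined as 1")
    return(c(dice = 1, precision = NA_real_, recall = NA_real_))
  }
  c(dice = 2 * inter / (np + nt),
    precision = if (np == 0) NA_real_ else inter / np,
    recall = if (nt == 0) NA_real_ else inter / nt)
}
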