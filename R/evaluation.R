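#' Confusion statistics of software vs reference (visual) calls
#'
#' Counts the confusion matrix of binary verdicts (software against the
#' adjudicated visual reference) and derives sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP) and accuracy = (TP+TN)/N. A statistic whose
#' denominator class is empty is reported as `NA`, never as 0 or 1.
#' Percentage renderings round half-up to one decimal.
#'
#' @param software,reference vectors of verdicts; anything equal to
#'   `"positive"`, `TRUE` or 1 counts as positive.
#' @return A [ConfusionSummary-class].
#' @examples
#' # 73 concordant positives, 19 false positives, 577 concordant negatives
#' cs <- confusionFromCounts(tp = 73, fp = 19, fn = 0, tn = 577)
#' sensitivity(cs); specificity(cs); accuracy(cs)
#' @export
confusionFromCalls <- function(software, reference) {
  if (length(software) == 0L) stop("empty call list")
  if (length(software) != length(reference))
    stop("software and reference call lists differ in length")
  s <- .asPositive(software)
  r <- .asPositive(reference)
  confusionFromCounts(tp = sum(s & r), fp = sum(s & !r),
                      fn = sum(!s & r), tn = sum(!s & !r))
}

.asPositive <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("positive", "pos", "true", "1")
}

#' @rdname confusionFromCalls
#' @param tp,fp,fn,tn confusion counts.
#' @export
confusionFromCounts <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0L) stop("empty confusion table")
  new("ConfusionSummary", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = (tp + tn) / total)
}

#' Percent rendering of a confusion summary
#'
#' @param x a [ConfusionSummary-class].
#' @return named numeric vector `sensitivity`, `specificity`, `accuracy` in
#'   percent, rounded half-up to one decimal (`NA` where undefined).
#' @export
confusionPercent <- function(x) {
  c(sensitivity = pctHalfUp(x@sensitivity),
    specificity = pctHalfUp(x@specificity),
    accuracy = pctHalfUp(x@accuracy))
}

#' Titer concordance within a tolerance
#'
#' Fraction of call pairs whose software and reference titer levels differ
#' by at most `tolerance` steps. Levels are integer indices into the
#' configured titer steps; `-1` encodes "negative". By assay
#' reproducibility convention a tolerance of 1 titer level is used.
#'
#' @param software,reference integer titer levels.
#' @param tolerance non-negative integer.
#' @return Fraction in [0,1].
#' @export
titerConcordance <- function(software, reference, tolerance = 1L) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (length(software) != length(reference))
    stop("level lists differ in length")
  if (length(software) == 0L) stop("empty level list")
  mean(abs(software - reference) <= tolerance)
}

#' Evaluate a calls CSV against its reference columns
#'
#' Reads a CSV with columns `sample_id`, `software_verdict`,
#' `reference_verdict` and optionally `software_titer`, `reference_titer`
#' (integer levels, -1 = negative), and returns the confusion summary plus,
#' when titers are present, the +/-1-level concordance.
#'
#' @param path CSV file.
#' @return list with `confusion` ([ConfusionSummary-class]), `percent`
#'   (named vector) and optionally `titer_concordance`.
#' @export
evaluateCallsCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "software_verdict", "reference_verdict")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("calls CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty calls CSV")
  cs <- confusionFromCalls(df$software_verdict, df$reference_verdict)
  out <- list(confusion = cs, percent = confusionPercent(cs))
  if (all(c("software_titer", "reference_titer") %in% colnames(df)))
    out$titer_concordance <- titerConcordance(df$software_titer,
                                              df$reference_titer, 1L)
  out
}
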