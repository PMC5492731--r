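## Scoring detector output against ground truth: confusion counts and the
## four headline rates (sensitivity, specificity, error rate, accuracy).

#' Tally confusion counts
#'
#' Compares per-slot detector decisions with per-slot ground-truth
#' occupancy, aligned one-to-one.
#'
#' @param records data.frame of monitoring records (with an \code{hd}
#'   column) or a 0/1 vector of decisions.
#' @param truth 0/1 (or logical) vector of true occupancy, same length.
#' @return list of class \code{"ConfusionCounts"} with \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}.
#' @export
tallyConfusion <- function(records, truth) {
  hd <- if (is.data.frame(records)) records$hd else records
  hd <- as.integer(hd)
  truth <- as.integer(truth)
  if (length(hd) != length(truth))
    stop("records and truth must align one-to-one (",
         length(hd), " vs ", length(truth), " slots)")
  if (!all(hd %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    stop("decisions and truth must be 0/1 flags")
  structure(list(tp = sum(hd == 1L & truth == 1L),
                 fp = sum(hd == 1L & truth == 0L),
                 tn = sum(hd == 0L & truth == 0L),
                 fn = sum(hd == 0L & truth == 1L)),
            class = "ConfusionCounts")
}

#' Confusion counts from known totals
#'
#' @param tp,fp,tn,fn non-negative integers.
#' @return list of class \code{"ConfusionCounts"}.
#' @rdname tallyConfusion
#' @export
confusionCounts <- function(tp, fp, tn, fn) {
  counts <- list(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(unlist(counts) < 0)) stop("counts must be non-negative")
  structure(counts, class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat("ConfusionCounts:\n")
  cat(sprintf("            Positive  Negative  Total\n"))
  cat(sprintf("  True      %8d  %8d  %5d\n", x$tp, x$tn, x$tp + x$tn))
  cat(sprintf("  False     %8d  %8d  %5d\n", x$fp, x$fn, x$fp + x$fn))
  cat(sprintf("  Total     %8d  %8d  %5d\n", x$tp + x$fp, x$tn + x$fn,
              x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Detection performance metrics
#'
#' Computes, as percentages:
#' sensitivity = 100 TP / (FN + TP); specificity = 100 TN / (FP + TN);
#' error rate = 100 FP / (FP + TP); accuracy = 100 (TP + TN) / total.
#' A metric whose denominator is zero is undefined and reported as
#' \code{NA}, never as zero. Values are kept at full precision; the print
#' method shows one decimal (half-up), the reporting convention.
#'
#' @param counts a \code{"ConfusionCounts"} object.
#' @return list of class \code{"MetricReport"} with \code{sensitivity},
#'   \code{specificity}, \code{errorRate}, \code{accuracy} (percent).
#' @examples
#' detectionMetrics(confusionCounts(tp = 9108, fp = 222,
#'                                  tn = 4283, fn = 118))
#' @export
detectionMetrics <- function(counts) {
  stopifnot(inherits(counts, "ConfusionCounts"))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total < 1) stop("at least one classified case is required")
  structure(list(
    sensitivity = rate(counts$tp, counts$fn + counts$tp),
    specificity = rate(counts$tn, counts$fp + counts$tn),
    errorRate = rate(counts$fp, counts$fp + counts$tp),
    accuracy = rate(counts$tp + counts$tn, total)),
    class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    sprintf("%.1f%%", roundHalfUp(v, 1))
  cat("Detection performance:\n")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  error rate: ", fmt(x$errorRate), "\n")
  cat("  accuracy:   ", fmt(x$accuracy), "\n")
  invisible(x)
}

#' Read per-slot ground truth
#'
#' Ground truth is a TSV with columns \code{slot} and \code{occupied}
#' (0/1), the machine-readable stand-in for a manual review of the scene.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{slot} and \code{occupied}.
#' @export
readTruth <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("slot", "occupied") %in% names(tr)))
    stop("truth file must have columns 'slot' and 'occupied'")
  tr
}

#' Write an evaluation report
#'
#' TSV with a counts block (true/false by positive/negative) followed by a
#' metrics block at one-decimal rounding.
#'
#' @param counts a \code{"ConfusionCounts"}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEvaluationReport <- function(counts, path) {
  m <- detectionMetrics(counts)
  lines <- c(
    "block\tname\tvalue",
    sprintf("counts\ttrue_positive\t%d", counts$tp),
    sprintf("counts\ttrue_negative\t%d", counts$tn),
    sprintf("counts\tfalse_positive\t%d", counts$fp),
    sprintf("counts\tfalse_negative\t%d", counts$fn),
    sprintf("counts\ttotal\t%d", counts$tp + counts$tn + counts$fp + counts$fn),
    sprintf("metrics\tsensitivity_pct\t%.1f", roundHalfUp(m$sensitivity, 1)),
    sprintf("metrics\tspecificity_pct\t%.1f", roundHalfUp(m$specificity, 1)),
    sprintf("metrics\terror_rate_pct\t%.1f", roundHalfUp(m$errorRate, 1)),
    sprintf("metrics\taccuracy_pct\t%.1f", roundHalfUp(m$accuracy, 1)))
  writeLines(lines, path)
  invisible(path)
}
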