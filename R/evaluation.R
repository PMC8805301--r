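#' Confusion counts from predicted and actual labels
#'
#' Cross-tabulates binary verdicts against ground truth; "positive" means
#' ice-contaminated.
#'
#' @param predicted,actual Logical vectors of equal, non-zero length.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(predicted, actual) {
  predicted <- as.logical(predicted)
  actual <- as.logical(actual)
  if (length(predicted) != length(actual)) stop("predicted and actual lengths differ")
  if (length(predicted) == 0) stop("empty input")
  if (anyNA(predicted) || anyNA(actual)) stop("NA verdicts are not allowed here; filter nonpredictable cases first")
  confusion_counts(tp = sum(predicted & actual), fp = sum(predicted & !actual),
                   tn = sum(!predicted & !actual), fn = sum(!predicted & actual))
}

#' @rdname confusion
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  x <- c(tp = unname(tp), fp = unname(fp), tn = unname(tn), fn = unname(fn))
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

metric_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  num / den
}

#' Classification metrics
#'
#' The three standard metrics over confusion counts: accuracy is the fraction
#' of true classifications among all, sensitivity the fraction of true
#' positives among actual positives, specificity the fraction of true
#' negatives among actual negatives. A zero denominator yields `NA` with a
#' warning rather than a number.
#'
#' @param c A `confusion_counts` object.
#' @return Fraction in \[0, 1\], or `NA` when undefined.
#' @export
accuracy <- function(c) {
  metric_or_na(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn, "accuracy")
}

#' @rdname accuracy
#' @export
sensitivity <- function(c) metric_or_na(c$tp, c$tp + c$fn, "sensitivity")

#' @rdname accuracy
#' @export
specificity <- function(c) metric_or_na(c$tn, c$tn + c$fp, "specificity")

binom_ci <- function(p, n, level = 0.95) {
  if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Evaluate a detector against gold labels
#'
#' Produces the standard benchmark report: confusion counts and the three
#' metrics with normal-approximation binomial 95% confidence intervals.
#' Nonpredictable verdicts (`NA`) are excluded from the counts and reported
#' separately, mirroring the exclusion of data sets whose resolution cuts off
#' all candidate windows.
#'
#' @param verdicts Logical vector (TRUE = contaminated), `NA` for
#'   nonpredictable datasets.
#' @param gold Logical gold-standard labels, same length.
#' @param level Confidence level (default 0.95).
#' @return A list of class `detector_report`: `counts` (`confusion_counts`),
#'   `metrics` (data frame with value, ci_lo, ci_hi per metric),
#'   `n_excluded`.
#' @export
evaluate_detector <- function(verdicts, gold, level = 0.95) {
  if (length(gold) == 0) stop("empty gold label set")
  if (length(verdicts) != length(gold)) stop("verdicts and gold lengths differ")
  usable <- !is.na(verdicts)
  cc <- confusion(verdicts[usable], gold[usable])
  metr <- list(accuracy = accuracy(cc), sensitivity = sensitivity(cc),
               specificity = specificity(cc))
  nn <- list(accuracy = cc$tp + cc$tn + cc$fp + cc$fn,
             sensitivity = cc$tp + cc$fn, specificity = cc$tn + cc$fp)
  metrics <- do.call(rbind, lapply(names(metr), function(m) {
    ci <- binom_ci(metr[[m]], nn[[m]], level)
    data.frame(metric = m, value = metr[[m]], n = nn[[m]],
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  structure(list(counts = cc, metrics = metrics, n_excluded = sum(!usable)),
            class = "detector_report")
}

#' @export
print.detector_report <- function(x, ...) {
  print(x$counts)
  df <- x$metrics
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s %.3f  (95%% CI %.3f-%.3f, n=%d)\n",
                df$metric[i], df$value[i], df$ci_lo[i], df$ci_hi[i], df$n[i]))
  }
  if (x$n_excluded > 0) cat("  nonpredictable datasets excluded:", x$n_excluded, "\n")
  invisible(x)
}

#' Write a detector report as CSV
#' @param report A `detector_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- report$metrics
  df$tp <- report$counts$tp; df$fp <- report$counts$fp
  df$tn <- report$counts$tn; df$fn <- report$counts$fn
  df$n_excluded <- report$n_excluded
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
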