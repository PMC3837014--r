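# Precision-recall benchmarking: sweep calling thresholds over a labeled
# sequence set, computing one confusion summary per threshold, and select
# an operating point by a stated rule.

#' Confusion counts for a set of solenoid calls
#'
#' Sequences absent from `calls` (or called `FALSE`) count as predicted
#' negative. Every call id must be present in the labels.
#'
#' @param calls Data frame with columns `id` and `is_solenoid` (logical),
#'   one row per predicted sequence.
#' @param labels Data frame with columns `id` and `is_positive` (logical),
#'   one row per benchmark sequence.
#' @return Named integer vector `c(TP, FP, FN, TN)`; the four counts sum to
#'   `nrow(labels)`.
#' @export
#' @examples
#' labels <- data.frame(id = c("a", "b", "c"),
#'                      is_positive = c(TRUE, TRUE, FALSE))
#' calls <- data.frame(id = "a", is_solenoid = TRUE)
#' confusion_counts(calls, labels)  # TP 1, FP 0, FN 1, TN 1
confusion_counts <- function(calls, labels) {
  stopifnot(all(c("id", "is_positive") %in% names(labels)))
  if (anyDuplicated(labels$id)) stop("duplicated ids in labels")
  unknown <- setdiff(calls$id, labels$id)
  if (length(unknown))
    stop("call id not present in labels: ", paste(unknown, collapse = ", "))
  pred <- labels$id %in% calls$id[calls$is_solenoid]
  truth <- labels$is_positive
  c(TP = sum(pred & truth), FP = sum(pred & !truth),
    FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

#' Precision and recall from confusion counts
#'
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`. With zero
#' predicted positives the precision is undefined and reported as `NA`
#' (never 0 or 1), which keeps extreme thresholds from appearing as
#' spurious full-precision operating points.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Named numeric vector `c(precision, recall)`; precision may be `NA`.
#' @export
#' @examples
#' precision_recall(59, 206, 70)   # the printed 0.22 / 0.46 worked example
precision_recall <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  TP <- unname(TP); FP <- unname(FP); FN <- unname(FN)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  c(precision = precision, recall = recall)
}

#' Precision-recall sweep over calling thresholds
#'
#' Scans every sequence once, then re-applies hit calling and chaining per
#' threshold on the cached profiles — semantically identical to rescanning
#' at each threshold, only cheaper. The default thresholds are 0.80 to 0.90
#' in steps of 0.01.
#'
#' @param net An `ard_net` (or a fitted [solenoid_net()] model).
#' @param labeled Labeled set: list with `sequences` (named character
#'   vector) and `labels` (data frame `id`, `is_positive`); at least one
#'   positive and one negative are required.
#' @param thresholds Numeric vector of thresholds in (0, 1).
#' @param params A [calling_params()] supplying the chaining rule; its
#'   threshold field is overridden by each swept value.
#' @param shifts Passed to [scan_sequence()].
#' @param profiles Optional pre-computed list of profiles (keyed by id), to
#'   share scans across sweeps.
#' @return Data frame of class `pr_curve`: one row per threshold with
#'   columns `threshold`, `TP`, `FP`, `FN`, `precision`, `recall`.
#' @export
pr_sweep <- function(net, labeled, thresholds = seq(0.80, 0.90, by = 0.01),
                     params = calling_params(), shifts = TRUE,
                     profiles = NULL) {
  net <- as_ard_net(net)
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0 & thresholds < 1))
  labels <- labeled$labels
  stopifnot(all(c("id", "is_positive") %in% names(labels)))
  if (!any(labels$is_positive) || all(labels$is_positive))
    stop("labeled set must contain at least one positive and one negative")
  if (is.null(profiles)) {
    seqs <- labeled$sequences[labels$id]
    profiles <- mapply(function(s, id) scan_sequence(net, s, id, shifts = shifts),
                       seqs, labels$id, SIMPLIFY = FALSE)
  } else {
    if (is.null(names(profiles)) || !all(labels$id %in% names(profiles)))
      stop("pre-computed profiles must be named by sequence id and cover the labeled set")
    profiles <- profiles[labels$id]
  }
  rows <- lapply(thresholds, function(th) {
    p <- params; p$threshold <- th
    called <- vapply(profiles, function(pr) classify_profile(pr, p)$is_solenoid,
                     logical(1))
    calls <- data.frame(id = labels$id, is_solenoid = unname(called))
    cc <- confusion_counts(calls, labels)
    pr <- precision_recall(cc["TP"], cc["FP"], cc["FN"])
    data.frame(threshold = th, TP = cc[["TP"]], FP = cc[["FP"]],
               FN = cc[["FN"]], precision = pr[["precision"]],
               recall = pr[["recall"]])
  })
  structure(do.call(rbind, rows), class = c("pr_curve", "data.frame"))
}

#' Select an operating point from a precision-recall curve
#'
#' Two selection rules are supported: `"max-recall-at-full-precision"`
#' (among full-precision points, the best recall) and
#' `"max-precision-times-recall"`. Ties prefer the lower threshold. If the
#' first rule finds no full-precision point, the highest-precision point is
#' returned with attribute `"warning"` set.
#'
#' @param curve A `pr_curve` from [pr_sweep()].
#' @param rule Selection rule.
#' @return One row of the curve; attribute `"warning"` carries a message
#'   when the rule could not be satisfied exactly.
#' @export
select_operating_point <- function(curve,
                                   rule = c("max-recall-at-full-precision",
                                            "max-precision-times-recall")) {
  rule <- match.arg(rule)
  stopifnot(nrow(curve) >= 1L)
  defined <- !is.na(curve$precision)
  if (rule == "max-recall-at-full-precision") {
    full <- defined & curve$precision == 1
    if (any(full)) {
      sub <- curve[full, , drop = FALSE]
      sub <- sub[order(-sub$recall, sub$threshold), , drop = FALSE]
      return(sub[1, , drop = FALSE])
    }
    if (!any(defined)) {
      out <- curve[order(curve$threshold), , drop = FALSE][1, , drop = FALSE]
    } else {
      sub <- curve[defined, , drop = FALSE]
      out <- sub[order(-sub$precision, sub$threshold), , drop = FALSE][1, , drop = FALSE]
    }
    attr(out, "warning") <- "no full-precision point on the curve"
    return(out)
  }
  score <- ifelse(defined, curve$precision * curve$recall, -Inf)
  out <- curve[order(-score, curve$threshold), , drop = FALSE][1, , drop = FALSE]
  out
}

#' Plot a precision-recall curve
#'
#' @param x A `pr_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pr_curve <- function(x, ...) {
  ok <- !is.na(x$precision)
  graphics::plot(x$recall[ok], x$precision[ok], type = "b",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "recall", ylab = "precision", ...)
  graphics::text(x$recall[ok], x$precision[ok],
                 labels = sprintf("%.2f", x$threshold[ok]),
                 pos = 4, cex = 0.7)
  invisible(x)
}

#' Read a labeled set (FASTA + two-column label TSV)
#'
#' @param fasta Path to the sequences.
#' @param labels_tsv Path to a headerless two-column TSV: sequence id,
#'   0/1 label.
#' @return List with `sequences` and `labels` as used by [pr_sweep()].
#' @export
read_labeled_set <- function(fasta, labels_tsv) {
  seqs <- read_fasta(fasta)
  lab <- utils::read.table(labels_tsv, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  missing <- setdiff(lab$id, names(seqs))
  if (length(missing))
    stop("label id without a sequence: ", paste(missing, collapse = ", "))
  list(sequences = seqs,
       labels = data.frame(id = lab$id, is_positive = lab$label == 1L))
}
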