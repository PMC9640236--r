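# Segmentation evaluation: Dice, specificity, sensitivity and F1 from pixel
# confusion counts, with per-case (volume-pooled) and per-class aggregation.

#' Pixel confusion counts
#'
#' @param pred_mask,gt_mask Binary arrays of identical shape.
#' @return List with integer fields TP, TN, FP, FN.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("prediction and ground truth shapes differ")
  p <- as.vector(pred_mask)
  g <- as.vector(gt_mask)
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1)))
    stop("confusion_counts expects binary masks")
  tp <- sum(p == 1 & g == 1)
  tn <- sum(p == 0 & g == 0)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Dice similarity coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} for prediction support A and ground-truth
#' support B; 1 by convention when both are empty (so per-case means stay
#' defined on slices lacking a tissue).
#'
#' @inheritParams confusion_counts
#' @return Value in \[0, 1\].
#' @export
dice_score <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("prediction and ground truth shapes differ")
  a <- sum(pred_mask == 1)
  b <- sum(gt_mask == 1)
  if (a + b == 0) return(1)
  2 * sum(pred_mask == 1 & gt_mask == 1) / (a + b)
}

#' Specificity, sensitivity and F1 from confusion counts
#'
#' specificity = TN/(TN+FP); sensitivity = TP/(TP+FN);
#' F1 = 2TP/(2TP+FP+FN). A zero denominator returns 1 with a warning
#' (nothing of the relevant kind to classify).
#'
#' @param counts A list from [confusion_counts()].
#' @return Value in \[0, 1\].
#' @export
specificity <- function(counts) {
  den <- counts$TN + counts$FP
  if (den == 0) {
    warning("specificity undefined (no negatives); returning 1")
    return(1)
  }
  counts$TN / den
}

#' @rdname specificity
#' @export
sensitivity <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) {
    warning("sensitivity undefined (no positives); returning 1")
    return(1)
  }
  counts$TP / den
}

#' @rdname specificity
#' @export
f1_score <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) {
    warning("F1 undefined (both masks empty); returning 1")
    return(1)
  }
  2 * counts$TP / den
}

metrics_one <- function(pred_bin, gt_bin) {
  cc <- confusion_counts(pred_bin, gt_bin)
  c(dice = dice_score(pred_bin, gt_bin),
    specificity = suppressWarnings(specificity(cc)),
    sensitivity = suppressWarnings(sensitivity(cc)),
    f1 = suppressWarnings(f1_score(cc)))
}

#' Evaluate predictions case by case
#'
#' Computes Dice, specificity, sensitivity and F1 per class for every case,
#' pooling all pixels of a case (its slices form one volume) before counting.
#' The summary averages each metric over cases (and, if a `fold` column is
#' supplied, first within and then across folds, mirroring cross-validated
#' reporting).
#'
#' @param predictions Named list (by case id) of integer class masks:
#'   matrices or (H, W, S) arrays.
#' @param ground_truths Named list with the same cases and shapes.
#' @param class_ids Integer vector of foreground class ids (default: all
#'   classes present in the ground truth).
#' @param class_names Optional names for `class_ids`.
#' @param folds Optional named vector mapping case id to fold index.
#' @return A `metrics_report`: list with `per_case` and `summary` data
#'   frames.
#' @export
evaluate_cases <- function(predictions, ground_truths, class_ids = NULL,
                           class_names = NULL, folds = NULL) {
  cases <- names(ground_truths)
  if (is.null(cases) || !all(cases %in% names(predictions)))
    stop("missing case: predictions must cover all ground-truth cases")
  if (is.null(class_ids)) {
    class_ids <- sort(unique(unlist(lapply(ground_truths, function(m)
      setdiff(unique(as.vector(m)), 0)))))
  }
  if (is.null(class_names)) class_names <- paste0("class", class_ids)
  rows <- list()
  for (cs in cases) {
    p <- predictions[[cs]]
    g <- ground_truths[[cs]]
    if (!identical(dim(p), dim(g)))
      stop("shape mismatch for case ", cs)
    for (j in seq_along(class_ids)) {
      m <- metrics_one((p == class_ids[j]) * 1, (g == class_ids[j]) * 1)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cs, class = class_names[j],
        fold = if (is.null(folds)) NA_integer_ else folds[[cs]],
        dice = m["dice"], specificity = m["specificity"],
        sensitivity = m["sensitivity"], f1 = m["f1"],
        row.names = NULL)
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- function(df) {
    out <- stats::aggregate(df[c("dice", "specificity", "sensitivity", "f1")],
                            by = list(class = df$class), FUN = mean)
    out[match(class_names, out$class), , drop = FALSE]
  }
  if (!is.null(folds)) {
    by_fold <- lapply(split(per_case, per_case$fold), agg)
    summary <- by_fold[[1]]
    for (m in c("dice", "specificity", "sensitivity", "f1"))
      summary[[m]] <- rowMeans(vapply(by_fold, function(d) d[[m]],
                                      numeric(nrow(summary))))
  } else {
    summary <- agg(per_case)
  }
  rownames(summary) <- NULL
  structure(list(per_case = per_case, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", length(unique(x$per_case$case_id)),
      " cases)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write a metrics report
#'
#' @param report A `metrics_report`.
#' @param path Output CSV path (per-class summary; the per-case table goes
#'   to `<path base>_per_case.csv`).
#' @export
write_metrics_report <- function(report, path) {
  utils::write.csv(report$summary, path, row.names = FALSE)
  base <- sub("\\.csv$", "", path)
  utils::write.csv(report$per_case, paste0(base, "_per_case.csv"),
                   row.names = FALSE)
  invisible(path)
}
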