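#' Confusion matrix for the three-class land classification
#'
#' Tallies true/predicted label pairs into a 3 x 3 matrix with the fixed
#' class order NOT_SUITABLE, LOW, HIGH (rows = truth, columns = prediction).
#'
#' @param truth,predicted Character vectors of class labels (or factors).
#' @return A `confusion_matrix` object wrapping the count matrix.
#' @export
#' @examples
#' confusion_matrix(c("HIGH", "LOW"), c("HIGH", "HIGH"))
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length.",
      class = "cropsense_validation_error"
    )
  }
  if (!length(truth)) {
    abort("cannot build a confusion matrix from zero samples.",
      class = "cropsense_validation_error"
    )
  }
  assert_land_class(truth, "truth")
  assert_land_class(predicted, "predicted")
  tab <- table(
    truth = factor(truth, levels = land_classes()),
    predicted = factor(predicted, levels = land_classes())
  )
  structure(
    list(counts = unclass(tab), n = length(truth)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = truth, cols = predicted\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Long tibble with `truth`, `predicted`, `n`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    dplyr::rename(n = "Freq")
}

# one-vs-rest TP/FP/FN/TN counts for one class
ovr_counts <- function(cm, class) {
  i <- match(class, land_classes())
  if (is.na(i)) {
    abort(paste0("unknown class: ", class), class = "cropsense_validation_error")
  }
  tp <- cm$counts[i, i]
  fp <- sum(cm$counts[-i, i])
  fn <- sum(cm$counts[i, -i])
  tn <- sum(cm$counts[-i, -i])
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(paste0(what, " undefined (zero denominator); returning 0."))
    return(0)
  }
  num / den
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest metrics per the standard definitions: precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the harmonic mean
#' `2 P R / (P + R)`. A zero denominator yields 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param class Class label, one of [land_classes()].
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm, class) {
  k <- ovr_counts(cm, class)
  p <- safe_ratio(k[["tp"]], k[["tp"]] + k[["fp"]], "precision")
  r <- safe_ratio(k[["tp"]], k[["tp"]] + k[["fn"]], "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' F1 score from a precision/recall pair
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The harmonic mean, or 0 when both are 0.
#' @export
#' @examples
#' f1_score(0.95, 0.97)
f1_score <- function(precision, recall) {
  assert_scalar_number(precision, "precision", 0, 1)
  assert_scalar_number(recall, "recall", 0, 1)
  if (precision + recall == 0) {
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Overall classification accuracy
#'
#' Multiclass accuracy as the fraction of correctly classified samples
#' (matrix trace over total); in the binary one-vs-rest view this equals
#' `(TP + TN)/(TP + TN + FP + FN)`.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  if (cm$n == 0) {
    abort("empty confusion matrix.", class = "cropsense_validation_error")
  }
  sum(diag(cm$counts)) / cm$n
}

#' Classification report
#'
#' Per-class precision, recall and F1 plus overall accuracy, in the layout
#' of a standard classification report. Values are unrounded; use
#' `digits` when printing only.
#'
#' @param cm A [confusion_matrix()].
#' @return A tibble (class `classification_report`) with one row per class
#'   and columns `class`, `precision`, `recall`, `f1`, `support`, plus an
#'   `accuracy` attribute.
#' @export
classification_report <- function(cm) {
  rows <- purrr::map_dfr(land_classes(), function(cls) {
    m <- precision_recall_f1(cm, cls)
    tibble(
      class = cls,
      precision = m[["precision"]],
      recall = m[["recall"]],
      f1 = m[["f1"]],
      support = sum(cm$counts[match(cls, land_classes()), ])
    )
  })
  structure(rows,
    accuracy = accuracy(cm),
    class = c("classification_report", class(rows))
  )
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  cat("Classification report\n")
  df <- as.data.frame(x)
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("accuracy: %.*f\n", digits, attr(x, "accuracy")))
  invisible(x)
}

#' Regression error metrics
#'
#' Mean absolute error `MAE = (1/n) sum |y_i - yhat_i|` and root mean
#' squared error `RMSE = sqrt((1/n) sum (y_i - yhat_i)^2)`.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return A tibble with columns `mae`, `rmse`, `n`.
#' @export
#' @examples
#' regression_errors(c(1, 2, 3), c(2, 2, 2))
regression_errors <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("actual and predicted must have equal length.",
      class = "cropsense_validation_error"
    )
  }
  if (!length(actual)) {
    abort("cannot compute errors on zero observations.",
      class = "cropsense_validation_error"
    )
  }
  e <- actual - predicted
  tibble(
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    n = length(e)
  )
}

#' Percent RMSE improvement over a baseline
#'
#' `100 * (baseline - proposed) / baseline`, the arithmetic used to compare
#' a forecaster against published baselines (e.g. baseline RMSE 1.41 vs
#' proposed 0.19 gives 86.5%).
#'
#' @param baseline_rmse Baseline RMSE, must be > 0.
#' @param proposed_rmse Proposed model RMSE.
#' @param digits Decimal places for the reported percentage (default 1).
#' @return Percentage improvement (positive means the proposal is better).
#' @export
#' @examples
#' percent_improvement(1.41, 0.19)
percent_improvement <- function(baseline_rmse, proposed_rmse, digits = 1) {
  assert_scalar_number(baseline_rmse, "baseline_rmse")
  if (baseline_rmse <= 0) {
    abort("`baseline_rmse` must be positive.", class = "cropsense_validation_error")
  }
  assert_scalar_number(proposed_rmse, "proposed_rmse")
  round(100 * (baseline_rmse - proposed_rmse) / baseline_rmse, digits)
}
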