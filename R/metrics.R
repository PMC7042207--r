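#' One-vs-rest confusion counts
#'
#' For each class g, the true/false positive/negative counts of the
#' one-vs-rest decomposition: TP + FN equals the class size and
#' TP + FP + TN + FN equals n for every class.
#'
#' @param y_true,y_pred equal-length label vectors; every prediction must
#'   lie in the class set.
#' @param classes class set (default: classes seen in `y_true`).
#' @return object of class `confusion_summary`: integer matrix `counts`
#'   (classes x TP/FP/TN/FN), `table` (the full cross-tabulation), `n`.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(y_true))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  n <- length(y_true)
  counts <- t(vapply(classes, function(g) {
    tp <- sum(y_true == g & y_pred == g)
    fp <- sum(y_true != g & y_pred == g)
    fn <- sum(y_true == g & y_pred != g)
    c(TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn)
  }, integer(4)))
  tab <- table(factor(y_true, classes), factor(y_pred, classes),
               dnn = c("true", "predicted"))
  structure(list(counts = counts, table = tab, n = n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' Per-class sensitivity, specificity, precision and efficiency
#'
#' From one-vs-rest counts: `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
#' `PRE = TP/(TP+FP)`, and efficiency `EFF = sqrt(SEN * SPE)` — the
#' geometric mean summarising sensitivity and specificity jointly. All are
#' reported in percent at full precision; `PRE` is undefined (NA) for a
#' class never predicted, and undefined entries are excluded from the
#' macro averages. Overall accuracy is `sum(TP) / n * 100`.
#'
#' Printing rounds to 2 decimals with round-half-away-from-zero; the
#' stored values stay at full precision (so efficiencies derived from
#' exact count ratios round correctly).
#'
#' @param cm a [confusion()] summary.
#' @return object of class `class_metrics`: data.frame `per_class`
#'   (SEN/SPE/PRE/EFF in percent), named vector `macro`, scalar
#'   `accuracy`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_summary"))
  k <- cm$counts
  sen <- k[, "TP"] / (k[, "TP"] + k[, "FN"]) * 100
  spe <- k[, "TN"] / (k[, "TN"] + k[, "FP"]) * 100
  pre <- ifelse(k[, "TP"] + k[, "FP"] > 0,
                k[, "TP"] / (k[, "TP"] + k[, "FP"]) * 100, NA_real_)
  eff <- sqrt(sen * spe)
  per_class <- data.frame(SEN = sen, SPE = spe, PRE = pre, EFF = eff,
                          row.names = rownames(k))
  structure(list(per_class = per_class,
                 macro = c(SEN = mean(sen), SPE = mean(spe),
                           PRE = mean(pre, na.rm = TRUE), EFF = mean(eff)),
                 accuracy = sum(k[, "TP"]) / cm$n * 100),
            class = "class_metrics")
}

#' Round half away from zero
#'
#' The tie-breaking rule used for all reported 2-decimal values (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.class_metrics <- function(x, ...) {
  tab <- t(as.matrix(x$per_class))
  tab <- cbind(tab, Average = x$macro[rownames(tab)])
  out <- format(round_away(tab, 2), nsmall = 2)
  out[is.na(tab)] <- "-"
  cat(sprintf("Accuracy: %.2f%%\n", round_away(x$accuracy, 2)))
  print(out, quote = FALSE)
  invisible(x)
}

#' Macro average excluding undefined entries
#'
#' Arithmetic mean over the defined (non-NA) per-class values — the rule
#' used for the Average column of the report tables, where precision is
#' undefined for classes never predicted.
#'
#' @param values numeric vector, possibly with NA.
#' @return scalar mean.
#' @export
macro_average <- function(values) mean(values, na.rm = TRUE)

#' Evaluate a classifier's predictions on one set
#'
#' Bundles [confusion()] and [class_metrics()] into one report object.
#'
#' @inheritParams confusion
#' @return object of class `classifier_report` containing the
#'   `confusion_summary` and `class_metrics`.
#' @export
classifier_report <- function(y_true, y_pred, classes = NULL) {
  cm <- confusion(y_true, y_pred, classes)
  structure(list(confusion = cm, metrics = class_metrics(cm)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}
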