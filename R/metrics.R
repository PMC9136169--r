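# Confusion matrix and classification metric panel -----------------------

#' Build a binary confusion matrix
#'
#' Counts are laid out with the non-faller class (label 1) as positive:
#' `tp` = non-fallers classified as non-fallers, `tn` = recurrent fallers
#' classified as recurrent fallers.
#'
#' @param truth,pred Integer vectors of true and predicted labels (0/1).
#' @return A `confusion_matrix` object with fields `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("`truth` and `pred` must match in length")
  if (!all(truth %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L))) {
    abort("labels must be 0 (recurrent faller) or 1 (non-faller)")
  }
  structure(
    list(
      tp = sum(truth == 1L & pred == 1L),
      fn = sum(truth == 1L & pred == 0L),
      fp = sum(truth == 0L & pred == 1L),
      tn = sum(truth == 0L & pred == 0L)
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("non_faller", "recurrent_faller"),
                              predicted = c("non_faller", "recurrent_faller")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den, what, notes) {
  if (den == 0) {
    notes$add(what)
    return(NaN)
  }
  num / den
}

#' Classification metric panel from a confusion matrix
#'
#' Computes the full per-class panel (sensitivity, specificity, precision,
#' recall, F1) for both classes by swapping the positive-class role, plus
#' overall accuracy and the Matthews correlation coefficient
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. A metric
#' whose denominator is zero is undefined: it is reported as `NaN` and a
#' warning names it, rather than being silently coerced to 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A list with `per_class` (tibble: one row per class and metric),
#'   `accuracy`, and `mcc`.
#' @export
#' @examples
#' cm <- confusion_matrix(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 0, 1, 0, 0, 0))
#' classification_metrics(cm)
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) abort("empty confusion matrix")
  notes <- local({
    undefined <- character(0)
    list(add = function(x) undefined <<- c(undefined, x),
         get = function() undefined)
  })
  panel_for <- function(tp, fn, fp, tn, class) {
    sens <- safe_ratio(tp, tp + fn, paste0(class, ":sensitivity"), notes)
    spec <- safe_ratio(tn, tn + fp, paste0(class, ":specificity"), notes)
    prec <- safe_ratio(tp, tp + fp, paste0(class, ":precision"), notes)
    f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) {
      notes$add(paste0(class, ":f1"))
      NaN
    } else 2 * prec * sens / (prec + sens)
    tibble::tibble(class = class, sensitivity = sens, specificity = spec,
                   precision = prec, recall = sens, f1 = f1)
  }
  per_class <- dplyr::bind_rows(
    panel_for(cm$tp, cm$fn, cm$fp, cm$tn, "non_faller"),
    panel_for(cm$tn, cm$fp, cm$fn, cm$tp, "recurrent_faller")
  )
  accuracy <- (cm$tp + cm$tn) / total
  denom <- sqrt(prod(c(cm$tp + cm$fp, cm$tp + cm$fn,
                       cm$tn + cm$fp, cm$tn + cm$fn) * 1.0))
  mcc <- if (denom == 0) {
    notes$add("mcc")
    NaN
  } else (cm$tp * cm$tn - cm$fp * cm$fn) / denom
  und <- notes$get()
  if (length(und)) {
    warn(paste0("undefined metric(s) (zero denominator): ",
                paste(und, collapse = ", ")))
  }
  list(per_class = per_class, accuracy = accuracy, mcc = mcc,
       undefined = und)
}
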