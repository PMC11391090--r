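#' Accuracy and macro-averaged precision/recall/F1
#'
#' Per class `c`: `P_c = TP_c / (TP_c + FP_c)`, `R_c = TP_c / (TP_c + FN_c)`,
#' `F1_c = 2 P_c R_c / (P_c + R_c)`; each macro metric is the unweighted mean
#' over the two classes. A 0/0 is set to 0 with a warning.
#'
#' @param truth Character vector of true labels (`depressed` / `control`).
#' @param predicted Character vector of predicted labels.
#' @return A `metrics_report` object: accuracy, the three macro metrics,
#'   a per-class tibble and the confusion counts.
#' @export
metrics_report <- function(truth, predicted) {
  assert_that(length(truth) == length(predicted) && length(truth) > 0,
              "evaluation set must be non-empty")
  classes <- c("depressed", "control")
  assert_that(all(truth %in% classes) && all(predicted %in% classes),
              "labels must be 'depressed' or 'control'")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, " (0/0) set to 0", call. = FALSE)
      0
    } else num / den
  }
  per_class <- purrr::map(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    p <- safe_div(tp, tp + fp, paste0("precision[", cl, "]"))
    r <- safe_div(tp, tp + fn, paste0("recall[", cl, "]"))
    f1 <- safe_div(2 * p * r, p + r, paste0("F1[", cl, "]"))
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   precision = p, recall = r, f1 = f1)
  }) |> dplyr::bind_rows()
  structure(
    list(accuracy = mean(truth == predicted),
         macro_precision = mean(per_class$precision),
         macro_recall = mean(per_class$recall),
         macro_f1 = mean(per_class$f1),
         per_class = per_class,
         n = length(truth),
         confusion = table(truth = factor(truth, classes),
                           predicted = factor(predicted, classes))),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  accuracy=%.4f  macroP=%.4f  macroR=%.4f  macroF1=%.4f\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report into one row per metric
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble with `metric` and `value`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "macro_precision", "macro_recall", "macro_f1"),
    value = c(x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1)
  )
}

#' @rdname tidy.metrics_report
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1)
}
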