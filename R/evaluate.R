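# Classification accuracy evaluation: confusion matrix, producer's and user's
# accuracy, overall accuracy and kappa.

#' Confusion matrix from predicted and reference labels
#'
#' Rows are classification results, columns the reference; `a_ij` counts units
#' classified as class i whose reference class is j.
#'
#' @param pred,ref Equal-length label vectors (character or factor).
#' @param classes Class order; defaults to the canonical study classes plus
#'   any further labels encountered.
#' @return Integer matrix of class `fvc_confusion` (rows = classified,
#'   columns = reference).
#' @export
confusion_matrix <- function(pred, ref, classes = NULL) {
  if (!length(pred) || length(pred) != length(ref)) {
    stop("pred and ref must be non-empty vectors of equal length")
  }
  pred <- as.character(pred); ref <- as.character(ref)
  if (is.null(classes)) {
    seen <- unique(c(pred, ref))
    classes <- c(intersect(fvc_classes(), seen),
                 sort(setdiff(seen, fvc_classes())))
  }
  m <- table(factor(pred, levels = classes), factor(ref, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(classified = classes, reference = classes))
  class(m) <- c("fvc_confusion", class(m))
  m
}

#' Accuracy report from a confusion matrix
#'
#' With rows as classification results and columns as reference:
#' producer's accuracy `PA_i = a_ii / a_ti` (column totals, 1 - omission),
#' user's accuracy `UA_i = a_ii / a_it` (row totals, 1 - commission), overall
#' accuracy `OA = sum(a_ii) / N`, and the chance-corrected
#' `kappa = (N * sum(a_ii) - sum(a_ti * a_it)) / (N^2 - sum(a_ti * a_it))`.
#' PA for a class absent from the reference is `NA` (undefined), likewise UA
#' for a class never predicted.
#'
#' @param cm Square counts matrix (rows = classified, columns = reference).
#' @return Object of class `accuracy_report`: list with `PA`, `UA`, `OA`,
#'   `kappa`, `N`.
#' @export
accuracy_report <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("cm must be a square matrix")
  }
  if (any(cm < 0)) stop("counts must be nonnegative")
  N <- sum(cm)
  if (N <= 0) stop("empty confusion matrix")
  diagm <- diag(cm)
  a_it <- rowSums(cm)  # classified totals
  a_ti <- colSums(cm)  # reference totals
  PA <- ifelse(a_ti > 0, diagm / a_ti, NA_real_)
  UA <- ifelse(a_it > 0, diagm / a_it, NA_real_)
  OA <- sum(diagm) / N
  chance <- sum(a_ti * a_it)
  kappa <- (N * sum(diagm) - chance) / (N^2 - chance)
  structure(list(PA = PA, UA = UA, OA = OA, kappa = kappa, N = N),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  tab <- rbind(PA = round(x$PA, 3), UA = round(x$UA, 3))
  print(tab)
  cat(sprintf("OA %.3f  kappa %.3f  (N = %d)\n", x$OA, x$kappa, x$N))
  invisible(x)
}

#' Evaluate predicted against reference labels
#'
#' Convenience wrapper building the confusion matrix and its accuracy report.
#'
#' @inheritParams confusion_matrix
#' @return List with `confusion` ([confusion_matrix()]) and `accuracy`
#'   ([accuracy_report()]).
#' @export
evaluate_classification <- function(pred, ref, classes = NULL) {
  cm <- confusion_matrix(pred, ref, classes)
  list(confusion = cm, accuracy = accuracy_report(cm))
}
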