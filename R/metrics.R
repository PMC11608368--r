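#' Classification metrics for cell-type annotation
#'
#' The three clean-set metrics used throughout — overall accuracy, Cohen's
#' kappa, and macro-averaged F1 — plus the attack success rate. All operate on
#' two aligned label vectors and return a scalar.
#'
#' * `accuracy_score`: fraction of exact matches.
#' * `cohens_kappa`: `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o`
#'   and the chance agreement `p_e` given by the product of row and column
#'   marginals of the confusion matrix (Cohen's unweighted form). Returns 1
#'   in the degenerate case `p_e = p_o = 1` (a single shared class).
#' * `macro_f1`: unweighted mean over the classes present in `y_true` of the
#'   per-class F1 `2PR/(P + R)`, with F1 defined as 0 when `P + R = 0`.
#'
#' @param y_true,y_pred character vectors of equal positive length.
#' @return a scalar: accuracy and macro-F1 in `[0, 1]`, kappa in `[-1, 1]`.
#' @examples
#' accuracy_score(c("a", "a", "b"), c("a", "b", "b"))
#' cohens_kappa(c("a", "a", "b", "b"), c("a", "b", "a", "b"))  # chance: 0
#' macro_f1(c("a", "b", "b"), c("a", "b", "a"))
#' @name annotation-metrics
NULL

.check_pair <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true (", length(y_true), ") and y_pred (", length(y_pred),
         ") must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty label vectors", call. = FALSE)
}

#' @rdname annotation-metrics
#' @export
accuracy_score <- function(y_true, y_pred) {
  .check_pair(y_true, y_pred)
  mean(as.character(y_true) == as.character(y_pred))
}

#' @rdname annotation-metrics
#' @export
cohens_kappa <- function(y_true, y_pred) {
  .check_pair(y_true, y_pred)
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  tt <- factor(as.character(y_true), levels = classes)
  pp <- factor(as.character(y_pred), levels = classes)
  cm <- table(tt, pp)
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(if (p_o >= 1) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' @rdname annotation-metrics
#' @export
macro_f1 <- function(y_true, y_pred) {
  .check_pair(y_true, y_pred)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  f1s <- vapply(unique(y_true), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1s)
}

#' Attack success rate
#'
#' The fraction of triggered, originally non-target cells that the (possibly
#' backdoored) model annotates as the target label. An attack succeeds on a
#' cell exactly when the trigger flips its prediction to the target class, so
#' the denominator must contain no cell that already carried the target
#' label.
#'
#' @param y_pred_on_poisoned predicted labels for the triggered cells.
#' @param original_labels their true (pre-attack) labels; must not contain
#'   `target_label`.
#' @param target_label the attack's target class.
#' @return proportion in `[0, 1]`.
#' @examples
#' attack_success_rate(c("pp", "pp", "alpha"), c("alpha", "beta", "beta"), "pp")
#' @export
attack_success_rate <- function(y_pred_on_poisoned, original_labels,
                                target_label) {
  .check_pair(original_labels, y_pred_on_poisoned)
  if (any(as.character(original_labels) == target_label)) {
    stop("original_labels must not contain the target label '", target_label,
         "'", call. = FALSE)
  }
  mean(as.character(y_pred_on_poisoned) == target_label)
}
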