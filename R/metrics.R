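#' Binary classification metrics
#'
#' Confusion-matrix metrics for a binary problem where 1 marks the active
#' (positive) class: tp/fp/fn/tn counts, precision, recall, F1, accuracy,
#' Matthews correlation coefficient, Cohen's kappa, and (when scores are
#' supplied) AUC computed from the Mann-Whitney rank statistic. Zero
#' denominators follow the usual conventions: precision/recall/F1 are 0 when
#' undefined, MCC and kappa are 0 when a marginal is degenerate, and AUC is
#' NA (with a message) when the truth has a single class.
#'
#' @param truth 0/1 vector (or logical) of true labels.
#' @param pred 0/1 vector (or logical) of predicted labels.
#' @param scores optional numeric scores in [0, 1] for AUC.
#' @return named list: tp, fp, fn, tn, precision, recall, f1, accuracy, mcc,
#'   kappa, auc.
#' @examples
#' m <- classificationMetrics(c(1,1,0,0), c(1,0,0,0))
#' m$recall  # 0.5
#' @export
classificationMetrics <- function(truth, pred, scores = NULL) {
  truth <- .toBinary(truth, "truth")
  pred <- .toBinary(pred, "pred")
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  n <- tp + fp + fn + tn

  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- (tp + tn) / n

  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0

  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else 0

  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) {
      stop("scores must match truth in length", call. = FALSE)
    }
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    if (n1 == 0 || n0 == 0) {
      message("classificationMetrics: single-class truth, AUC undefined")
    } else {
      r <- rank(scores)
      auc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = precision, recall = recall, f1 = f1,
       accuracy = accuracy, mcc = mcc, kappa = kappa, auc = auc)
}

.toBinary <- function(x, name) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    return(as.integer(x %in% c("1", "active", "TRUE")))
  }
  if (!all(x %in% c(0, 1))) {
    stop("'", name, "' must be binary (0/1, logical, or active/inactive)",
         call. = FALSE)
  }
  as.integer(x)
}
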