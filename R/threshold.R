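#' Threshold continuous scores into class labels
#'
#' `label = 1` (viable) iff `score > threshold`; a score exactly at the
#' threshold is called nonviable. The conservative tie rule reflects the
#' sorting intent: borderline seeds are discarded with the nonviable stream.
#'
#' @param scores Numeric score vector.
#' @param threshold Decision threshold in (0, 1).
#' @return Integer vector of 0/1 labels.
#' @export
classify_scores <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must be in (0, 1)", class = "hsisort_error_model")
  }
  as.integer(scores > threshold)
}

#' Shift the decision threshold for predicted-viable purity
#'
#' Raises the 0.5 decision cut on a 0.01 grid until the predicted-viable
#' group (calibration scores at or above the candidate cut) reaches the
#' requested purity -- the fraction of that group that is truly viable.
#' Scores exactly at the candidate cut are counted in the group, so the
#' returned threshold clears every offending score. If even the grid
#' maximum (0.99) cannot reach the target, that maximum is returned with
#' `reached = FALSE`.
#'
#' @param scores Calibration-split scores.
#' @param labels True 0/1 labels for those scores.
#' @param purity_target Required purity in (0, 1].
#' @param grid_step,grid_max Threshold grid resolution and upper end.
#' @return A list: `threshold`, `reached` (logical), `purity` achieved.
#' @export
shift_threshold <- function(scores, labels, purity_target = 1,
                            grid_step = 0.01, grid_max = 0.99) {
  if (purity_target <= 0 || purity_target > 1) {
    abort("purity_target must be in (0, 1]", class = "hsisort_error_model")
  }
  stopifnot(length(scores) == length(labels))
  grid <- seq(0.5, grid_max, by = grid_step)
  for (t in grid) {
    sel <- scores >= t - 1e-12
    purity <- if (any(sel)) mean(labels[sel] == 1) else 1
    if (purity >= purity_target) {
      return(list(threshold = t, reached = TRUE, purity = purity))
    }
  }
  sel <- scores >= grid_max - 1e-12
  warn("purity target unreachable; returning the grid maximum threshold")
  list(threshold = grid_max, reached = FALSE,
       purity = if (any(sel)) mean(labels[sel] == 1) else 1)
}

#' Confusion matrix and accuracies
#'
#' Counts the 2x2 confusion matrix with viable (1) as the positive class and
#' reports overall accuracy and the viable-class accuracy Acc.v = TP /
#' (number of truly viable).
#'
#' @param estimate Predicted 0/1 labels.
#' @param truth True 0/1 labels.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `acc_viable` (both as fractions in `[0, 1]`).
#' @export
evaluate_classification <- function(estimate, truth) {
  if (length(estimate) != length(truth)) {
    abort("estimate/truth length mismatch", class = "hsisort_error_model")
  }
  if (!all(estimate %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    abort("labels must be 0 or 1", class = "hsisort_error_model")
  }
  tp <- sum(estimate == 1 & truth == 1)
  fp <- sum(estimate == 1 & truth == 0)
  tn <- sum(estimate == 0 & truth == 0)
  fn <- sum(estimate == 0 & truth == 1)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(truth),
    acc_viable = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
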