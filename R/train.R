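#' Train the viability classifier on a spectra table
#'
#' Front end tying the model pieces together: takes a split spectra table,
#' preprocesses the calibration rows (freezing the MSC reference to the mean
#' calibration spectrum when needed), selects the latent-variable count by
#' venetian-blind cross-validation, fits the NIPALS PLS-DA model, and shifts
#' the decision threshold on the calibration scores to reach the requested
#' predicted-viable purity.
#'
#' @param table Spectra tibble with `label` and `split` columns (see
#'   [split_calibration_validation()]).
#' @param preprocess A [preprocess_spec()]. The default mean normalisation
#'   keeps the band geometry of the spectra, so the fitted coefficient
#'   curve remains chemically interpretable; scatter-whitening transforms
#'   (SNV/MSC) classify equally well here but relocate coefficient weight
#'   away from the absorption bands.
#' @param max_lv,folds Passed to [select_lv()].
#' @param purity_target Passed to [shift_threshold()]. The default 0.95
#'   trades a little viable recall for a mostly-pure viable stream.
#' @param seed Integer seed for CV fold assignment.
#' @return A fitted `"plsda_model"` carrying the preprocessing spec, the
#'   shifted threshold, the CV error curve and training metadata.
#' @export
train_viability_model <- function(table, preprocess = preprocess_spec("mean_norm"),
                                  max_lv = 15, folds = 10,
                                  purity_target = 0.95, seed = 1L) {
  cal <- table %>% filter(.data$split == "calibration")
  if (nrow(cal) < 4) abort("calibration split too small", class = "hsisort_error_model")
  X_raw <- spectra_matrix(cal)
  if (preprocess$method == "msc" && is.null(preprocess$reference)) {
    preprocess$reference <- colMeans(X_raw)
  }
  X <- apply_preprocess(X_raw, preprocess)
  y <- cal$label
  sel <- select_lv(X, y, max_lv = max_lv, folds = folds, seed = seed)
  model <- fit_pls(X, y, n_lv = sel$n_lv)
  model$preprocess <- preprocess
  model$cv <- sel$error
  cal_scores <- predict_scores(model, X)
  shift <- shift_threshold(cal_scores, y, purity_target = purity_target)
  model$threshold <- shift$threshold
  model$threshold_reached <- shift$reached
  model$metadata <- list(
    n_calibration = nrow(cal),
    n_validation = sum(table$split == "validation"),
    varieties = unique(cal$variety),
    purity_target = purity_target, cv_folds = folds, cv_seed = seed)
  model
}

#' Score and classify a spectra table with a fitted model
#'
#' Applies the model's preprocessing, computes continuous scores and
#' thresholded class labels for every row.
#'
#' @param object A `"plsda_model"`.
#' @param newdata Spectra tibble (or matrix of raw spectra).
#' @param ... Unused.
#' @return The input metadata columns (when a tibble) plus `score` and
#'   `predicted` columns.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X_raw <- if (is.data.frame(newdata)) spectra_matrix(newdata) else as.matrix(newdata)
  X <- apply_preprocess(X_raw, object$preprocess)
  scores <- predict_scores(object, X)
  predicted <- classify_scores(scores, object$threshold)
  if (is.data.frame(newdata)) {
    meta <- newdata[!grepl("^wl_", names(newdata))]
    dplyr::bind_cols(tibble::as_tibble(meta),
                     tibble::tibble(score = scores, predicted = predicted))
  } else {
    tibble::tibble(score = scores, predicted = predicted)
  }
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variables, %d bands, threshold %.2f (%s)\n",
              x$n_lv, length(x$coefficients), x$threshold, x$preprocess$method))
  cat(sprintf("  X variance explained: %.1f%%\n",
              100 * tail(x$x_var_explained, 1)))
  invisible(x)
}

#' Tidy the fitted regression-coefficient vector
#'
#' One row per band: wavelength, regression coefficient, and whether the
#' band is a local extremum of `|b|` (the chemically interpreted peaks).
#'
#' @param x A `"plsda_model"`.
#' @param ... Unused.
#' @return A tibble `wavelength`, `coefficient`, `is_peak`.
#' @export
tidy.plsda_model <- function(x, ...) {
  b <- x$coefficients
  wl <- x$wavelengths %||% seq_along(b)
  ab <- abs(b)
  is_peak <- vapply(seq_along(ab), function(i) {
    lo <- max(1, i - 1); hi <- min(length(ab), i + 1)
    ab[i] == max(ab[lo:hi]) && ab[i] > 0
  }, logical(1))
  tibble::tibble(wavelength = wl, coefficient = b, is_peak = is_peak)
}

#' One-row model summary
#'
#' @param x A `"plsda_model"`.
#' @param ... Unused.
#' @return A tibble with `n_lv`, `threshold`, `preprocess`,
#'   `x_var_explained`, `cv_error` (at the selected LV count).
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(
    n_lv = x$n_lv, threshold = x$threshold,
    preprocess = x$preprocess$method,
    x_var_explained = tail(x$x_var_explained, 1),
    cv_error = if (!is.null(x$cv)) x$cv$error[x$n_lv] else NA_real_)
}

#' Evaluate a model on one split of a spectra table
#'
#' @param model A `"plsda_model"`.
#' @param table Split spectra tibble with labels.
#' @param split Which split to evaluate (`"validation"` by default).
#' @return One-row metrics tibble from [evaluate_classification()].
#' @export
assess_model <- function(model, table, split = "validation") {
  rows <- table %>% filter(.data$split == !!split, !is.na(.data$label))
  if (nrow(rows) == 0) abort("no labelled rows in that split", class = "hsisort_error_model")
  pred <- predict(model, rows)
  evaluate_classification(pred$predicted, rows$label)
}

#' Compare preprocessing methods on one spectra table
#'
#' Fits one model per preprocessing method and reports the selected
#' latent-variable count, shifted threshold and viable-class accuracy on the
#' calibration and validation splits -- the standard model-comparison table
#' of a chemometric classification study.
#'
#' @param table Split spectra tibble.
#' @param methods Character vector of preprocessing method names.
#' @param ... Passed to [train_viability_model()].
#' @return A tibble: `preprocessing`, `n_lv`, `threshold`,
#'   `cal_acc_viable`, `val_acc_viable` (percent).
#' @export
preprocessing_report <- function(table,
                                 methods = c("mean_norm", "max_norm", "range_norm",
                                             "msc", "snv", "sg1", "sg2"), ...) {
  purrr::map(methods, function(m) {
    model <- train_viability_model(table, preprocess = preprocess_spec(m), ...)
    cal <- assess_model(model, table, "calibration")
    val <- assess_model(model, table, "validation")
    tibble::tibble(preprocessing = m, n_lv = model$n_lv,
                   threshold = model$threshold,
                   cal_acc_viable = 100 * cal$acc_viable,
                   val_acc_viable = 100 * val$acc_viable)
  }) %>% dplyr::bind_rows()
}
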