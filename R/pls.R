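#' Fit a PLS regression on a 0/1 class code (NIPALS)
#'
#' Core fitting routine of the viability classifier. Class membership is
#' coded `0` (nonviable) / `1` (viable) and regressed on the spectra with
#' partial least squares: `Y = X b + E`, where the latent structure
#' `X = T P' + E_X`, `Y = U Q' + E_Y` is extracted component by component
#' with the NIPALS algorithm (weights from the X'y covariance, scores,
#' loadings, then deflation of X and y). The regression vector is composed
#' as `b = W (P' W)^-1 q`, so score-space regression and the compact linear
#' predictor agree. X and y are mean-centred internally; predictions add the
#' centres back.
#'
#' @param X Numeric matrix of (preprocessed) spectra, rows = samples.
#' @param y Numeric 0/1 class code per row.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, bands)`.
#' @param max_iter,tol NIPALS per-component iteration cap and convergence
#'   tolerance (single-response fits converge in one pass).
#' @return An object of class `"plsda_model"`: regression vector
#'   `coefficients`, `intercept` (training mean of y), centring vectors,
#'   weight/loading/score matrices, per-component explained-X-variance and
#'   residual norms, decision `threshold` (0.5 until shifted), and the
#'   `preprocess` spec (filled by [train_viability_model()]).
#' @export
fit_pls <- function(X, y, n_lv, max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); nb <- ncol(X)
  if (length(y) != n) abort("X/y length mismatch", class = "hsisort_error_model")
  if (n_lv < 1 || n_lv > min(n - 1, nb)) {
    abort(sprintf("n_lv must be in [1, %d]", min(n - 1, nb)),
          class = "hsisort_error_model")
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  if (all(abs(Xc) < 1e-300)) {
    abort("X has zero variance", class = "hsisort_error_model")
  }
  yc <- y - y_center

  W <- matrix(0, nb, n_lv); P <- matrix(0, nb, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  x_res_norm <- numeric(n_lv); x_var_explained <- numeric(n_lv)
  total_ss <- sum(Xc^2)
  Xd <- Xc; yd <- yc
  for (h in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)[, 1]
    if (sqrt(sum(w^2)) < 1e-300) {
      abort(sprintf("no remaining X/y covariance at component %d", h),
            class = "hsisort_error_model")
    }
    w <- w / sqrt(sum(w^2))
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      t_h <- Xd %*% w
      # single-response NIPALS: the y-weight step reproduces w, so the
      # loop converges immediately; kept for the documented contract
      w_new <- crossprod(Xd, yd)[, 1]
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((t_h - t_old)^2)) < tol) break
      t_old <- t_h
      w <- w_new
      if (it == max_iter) {
        abort(sprintf("NIPALS failed to converge at component %d", h),
              class = "hsisort_error_model")
      }
    }
    tt <- sum(t_h^2)
    p_h <- crossprod(Xd, t_h)[, 1] / tt
    q_h <- sum(yd * t_h) / tt
    Xd <- Xd - t_h %*% t(p_h)
    yd <- yd - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
    x_res_norm[h] <- sqrt(sum(Xd^2))
    x_var_explained[h] <- 1 - sum(Xd^2) / total_ss
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(
    list(coefficients = b, intercept = y_center, x_center = x_center,
         weights = W, x_loadings = P, y_loadings = q, scores = Tm,
         n_lv = as.integer(n_lv), x_res_norm = x_res_norm,
         x_var_explained = x_var_explained,
         wavelengths = if (!is.null(colnames(X)) && all(grepl("^wl_", colnames(X))))
           parse_band_names(colnames(X)) else NULL,
         threshold = 0.5, threshold_reached = TRUE,
         preprocess = preprocess_spec("none"), cv = NULL, metadata = list()),
    class = "plsda_model")
}

# regression vector truncated to the first h components
pls_coefficients <- function(model, h = model$n_lv) {
  stopifnot(h >= 1, h <= model$n_lv)
  W <- model$weights[, seq_len(h), drop = FALSE]
  P <- model$x_loadings[, seq_len(h), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), model$y_loadings[seq_len(h)]))
}

#' Continuous class scores for new spectra
#'
#' `y_hat = (X - x_center) b + intercept`; unbounded reals centred near the
#' 0/1 class codes. `X` must already carry the model's preprocessing.
#'
#' @param model A `"plsda_model"`.
#' @param X Preprocessed spectra matrix with the model's band count.
#' @param n_lv Optionally score with a truncated number of components.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, X, n_lv = model$n_lv) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients)) {
    abort(sprintf("band mismatch: model has %d bands, data %d",
                  length(model$coefficients), ncol(X)),
          class = "hsisort_error_model")
  }
  b <- if (n_lv == model$n_lv) model$coefficients else pls_coefficients(model, n_lv)
  unname(drop(sweep(X, 2, model$x_center) %*% b)) + model$intercept
}

#' Select the number of latent variables by cross-validation
#'
#' Venetian-blind k-fold cross-validation: fold membership cycles through
#' the rows (`fold = ((row + offset) mod k) + 1`) with a seeded random
#' offset. For each fold a model with `max_lv` components is fitted on the
#' remaining rows and every truncation `1..max_lv` is scored on the held-out
#' rows; the selected count minimises the misclassification error at the
#' 0.5 threshold, ties resolved toward fewer components.
#'
#' @param X Preprocessed spectra matrix.
#' @param y 0/1 class codes.
#' @param max_lv Largest component count to consider.
#' @param folds Number of venetian-blind folds.
#' @param seed Integer seed for the fold offset.
#' @return A list: `n_lv` (selected), `error` (tibble `lv`, `error` of
#'   length `max_lv`).
#' @export
select_lv <- function(X, y, max_lv = 15, folds = 10, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (max_lv < 1) abort("max_lv must be >= 1", class = "hsisort_error_model")
  if (folds > n) abort("more folds than rows", class = "hsisort_error_model")
  max_lv <- min(max_lv, ncol(X), n - ceiling(n / folds) - 1)
  withr::local_seed(seed)
  offset <- sample.int(folds, 1) - 1L
  fold <- ((seq_len(n) - 1L + offset) %% folds) + 1L
  errs <- matrix(NA_real_, folds, max_lv)
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], n_lv = max_lv)
    for (h in seq_len(max_lv)) {
      sc <- predict_scores(m, X[!tr, , drop = FALSE], n_lv = h)
      errs[f, h] <- sum((sc > 0.5) != (y[!tr] == 1))
    }
  }
  curve <- colSums(errs) / n
  list(n_lv = which.min(curve),
       error = tibble::tibble(lv = seq_len(max_lv), error = curve))
}
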