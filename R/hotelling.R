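#' Hotelling's T-squared outlier screen on the first two principal components
#'
#' Projects column-centred spectra onto their first two principal components
#' and flags rows whose T-squared statistic exceeds the F-distribution ellipse
#' bound `2 (n - 1) / (n - 2) * qF(confidence; 2, n - 2)`. The conventional
#' screening confidence in chemometrics workflows is 98.9%, under which about
#' 1.1% of well-behaved samples fall outside the ellipse.
#'
#' @param X Numeric matrix of spectra (rows = samples, >= 3 rows).
#' @param confidence Confidence level in (0, 1); default 0.989.
#' @return A tibble with one row per sample: `sample`, `t2`, `limit`,
#'   `outlier`.
#' @export
hotelling_screen <- function(X, confidence = 0.989) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) abort("need at least 3 rows", class = "hsisort_error_model")
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must be in (0, 1)", class = "hsisort_error_model")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  lambda <- apply(scores, 2, var)
  lambda[lambda == 0] <- Inf            # degenerate axis contributes 0
  t2 <- rowSums(sweep(scores^2, 2, lambda, `/`))
  p <- ncol(scores)
  limit <- p * (n - 1) / (n - p) * qf(confidence, p, n - p)
  tibble::tibble(sample = seq_len(n), t2 = t2, limit = limit,
                 outlier = t2 > limit)
}
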