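#' Spectral preprocessing specification
#'
#' Declares one of the row-wise preprocessing transforms applied to spectra
#' before model fitting: no-op, mean/max/range normalisation, multiplicative
#' scatter correction (MSC), standard normal variate (SNV), or first/second
#' Savitzky-Golay derivatives. SG derivatives are taken with respect to the
#' band index (one step per band); the default window of 11 points with a
#' quadratic polynomial is a common compromise between noise suppression and
#' peak fidelity.
#'
#' @param method One of `"none"`, `"mean_norm"`, `"max_norm"`,
#'   `"range_norm"`, `"msc"`, `"snv"`, `"sg1"`, `"sg2"`.
#' @param window Odd SG window length (> `poly_order`).
#' @param poly_order SG polynomial order.
#' @param reference Reference spectrum for MSC. May be left `NULL` at
#'   specification time; the model-fitting front end freezes the mean
#'   calibration spectrum into it.
#' @return A list of class `"preprocess_spec"`.
#' @export
preprocess_spec <- function(method = c("none", "mean_norm", "max_norm",
                                       "range_norm", "msc", "snv", "sg1", "sg2"),
                            window = 11, poly_order = 2, reference = NULL) {
  method <- match.arg(method)
  if (method %in% c("sg1", "sg2")) {
    if (window %% 2 == 0 || window <= poly_order) {
      abort("SG window must be odd and greater than the polynomial order",
            class = "hsisort_error_preprocess")
    }
  }
  if (!is.null(reference) && method != "msc") {
    abort("a reference spectrum is only meaningful for msc",
          class = "hsisort_error_preprocess")
  }
  structure(list(method = method, window = as.integer(window),
                 poly_order = as.integer(poly_order), reference = reference),
            class = "preprocess_spec")
}

#' Apply a preprocessing transform row-wise
#'
#' @param X Numeric matrix, rows = spectra.
#' @param spec A [preprocess_spec()]. For `"msc"` the spec must carry a
#'   reference spectrum of matching length.
#' @return The transformed matrix (same shape).
#' @details Row-wise definitions: `mean_norm`: `x / mean(x)`; `max_norm`:
#'   `x / max(x)` (error if `max(x) <= 0`); `range_norm`:
#'   `(x - min) / (max - min)` (error on constant rows); `snv`:
#'   `(x - mean) / sd` with the sample (n-1) standard deviation (error on
#'   zero-variance rows); `msc`: least-squares fit `x = a * reference + b`
#'   per row, corrected spectrum `(x - b) / a`; `sg1`/`sg2`: Savitzky-Golay
#'   derivative via [signal::sgolayfilt()], full-length output with
#'   polynomial edge fitting.
#' @export
apply_preprocess <- function(X, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  X <- as.matrix(X)
  nb <- ncol(X)
  out <- switch(spec$method,
    none = X,
    mean_norm = {
      m <- rowMeans(X)
      if (any(m == 0)) abort("mean_norm on a zero-mean row", class = "hsisort_error_preprocess")
      X / m
    },
    max_norm = {
      mx <- apply(X, 1, max)
      if (any(mx <= 0)) abort("max_norm on a row with max <= 0", class = "hsisort_error_preprocess")
      X / mx
    },
    range_norm = {
      mn <- apply(X, 1, min); mx <- apply(X, 1, max)
      if (any(mx == mn)) abort("range_norm on a constant row", class = "hsisort_error_preprocess")
      (X - mn) / (mx - mn)
    },
    snv = {
      m <- rowMeans(X)
      s <- apply(X, 1, sd)
      if (any(s == 0)) abort("snv on a zero-variance row", class = "hsisort_error_preprocess")
      (X - m) / s
    },
    msc = {
      ref <- spec$reference
      if (is.null(ref)) abort("msc requires a reference spectrum", class = "hsisort_error_preprocess")
      if (length(ref) != nb) abort("msc reference length != band count", class = "hsisort_error_preprocess")
      t(apply(X, 1, function(x) {
        fit <- lm.fit(cbind(1, ref), x)
        b <- fit$coefficients[[1]]; a <- fit$coefficients[[2]]
        if (!is.finite(a) || a == 0) abort("msc fit degenerate", class = "hsisort_error_preprocess")
        (x - b) / a
      }))
    },
    sg1 = sg_deriv(X, spec, 1L),
    sg2 = sg_deriv(X, spec, 2L)
  )
  dimnames(out) <- dimnames(X)
  out
}

sg_deriv <- function(X, spec, m) {
  if (spec$window > ncol(X)) {
    abort("SG window longer than the spectrum", class = "hsisort_error_preprocess")
  }
  t(apply(X, 1, function(x) {
    signal::sgolayfilt(x, p = spec$poly_order, n = spec$window, m = m, ts = 1)
  }))
}

# rows that a given preprocessing method cannot handle (used by pixel-wise
# prediction to divert degenerate spectra instead of erroring)
preprocess_degenerate_rows <- function(X, spec) {
  switch(spec$method,
    snv = apply(X, 1, sd) == 0,
    range_norm = apply(X, 1, max) == apply(X, 1, min),
    max_norm = apply(X, 1, max) <= 0,
    mean_norm = rowMeans(X) == 0,
    rep(FALSE, nrow(X))
  )
}
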