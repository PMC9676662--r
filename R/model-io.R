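#' Serialise a fitted model to YAML
#'
#' Writes the full model (coefficient vector, centres, loadings, threshold,
#' preprocessing spec, metadata) to a single human-readable YAML file and
#' reads it back losslessly to full double precision.
#'
#' @param model A `"plsda_model"`.
#' @param path YAML file path.
#' @return `read_model()` returns the model; `write_model()` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  payload <- list(
    coefficients = as.numeric(model$coefficients),
    intercept = model$intercept,
    x_center = as.numeric(model$x_center),
    weights = as.numeric(model$weights), x_loadings = as.numeric(model$x_loadings),
    y_loadings = as.numeric(model$y_loadings),
    n_lv = model$n_lv,
    x_res_norm = as.numeric(model$x_res_norm),
    x_var_explained = as.numeric(model$x_var_explained),
    wavelengths = if (is.null(model$wavelengths)) NULL else as.numeric(model$wavelengths),
    threshold = model$threshold, threshold_reached = model$threshold_reached,
    preprocess = list(method = model$preprocess$method,
                      window = model$preprocess$window,
                      poly_order = model$preprocess$poly_order,
                      reference = if (is.null(model$preprocess$reference)) NULL
                                  else as.numeric(model$preprocess$reference)),
    metadata = model$metadata)
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- yaml::read_yaml(path)
  nb <- length(p$coefficients)
  pre <- preprocess_spec(p$preprocess$method, window = p$preprocess$window,
                         poly_order = p$preprocess$poly_order)
  pre$reference <- if (is.null(p$preprocess$reference)) NULL
                   else as.numeric(p$preprocess$reference)
  structure(
    list(coefficients = as.numeric(p$coefficients), intercept = p$intercept,
         x_center = as.numeric(p$x_center),
         weights = matrix(as.numeric(p$weights), nb, p$n_lv),
         x_loadings = matrix(as.numeric(p$x_loadings), nb, p$n_lv),
         y_loadings = as.numeric(p$y_loadings), scores = NULL,
         n_lv = as.integer(p$n_lv),
         x_res_norm = as.numeric(p$x_res_norm),
         x_var_explained = as.numeric(p$x_var_explained),
         wavelengths = if (is.null(p$wavelengths)) NULL else as.numeric(p$wavelengths),
         threshold = p$threshold, threshold_reached = isTRUE(p$threshold_reached),
         preprocess = pre, cv = NULL, metadata = p$metadata),
    class = "plsda_model")
}
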