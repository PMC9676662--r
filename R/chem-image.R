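#' Pixel-wise chemical image from a fitted model
#'
#' Scores every masked pixel of a calibrated cube through the model: each
#' pixel spectrum is preprocessed with the model's own preprocessing (the
#' regression vector was fitted on preprocessed spectra, so projecting raw
#' pixels would be inconsistent) and then projected through the regression
#' vector. Background pixels are undefined (`NA`). Pixels whose spectrum is
#' degenerate for the preprocessing (e.g. constant spectrum under SNV) are
#' assigned the nonviable score floor 0 and counted in an anomaly tally.
#'
#' @param model A `"plsda_model"`.
#' @param cube A calibrated [spectral_cube()].
#' @param mask Logical `lines x pixels` seed mask (e.g. the `"mask"`
#'   attribute of [segment_seeds()]).
#' @return An object of class `"chemical_image"`: `prediction` (real map,
#'   `NA` off-mask), `mask`, `binary` (`NULL` until [binarize()]),
#'   `threshold`, `anomalies` count.
#' @export
predict_pixelwise <- function(model, cube, mask) {
  stopifnot(inherits(model, "plsda_model"), inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  stopifnot(is.matrix(mask), all(dim(mask) == d[1:2]))
  prediction <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask)
  anomalies <- 0L
  if (length(idx)) {
    X_raw <- matrix(cube$values, nrow = d[1] * d[2])[idx, , drop = FALSE]
    degenerate <- preprocess_degenerate_rows(X_raw, model$preprocess)
    scores <- rep(0, length(idx))           # nonviable score floor
    anomalies <- sum(degenerate)
    if (any(!degenerate)) {
      X <- apply_preprocess(X_raw[!degenerate, , drop = FALSE], model$preprocess)
      scores[!degenerate] <- predict_scores(model, X)
    }
    prediction[idx] <- scores
  }
  structure(list(prediction = prediction, mask = mask, binary = NULL,
                 threshold = NA_real_, anomalies = anomalies),
            class = "chemical_image")
}

#' Binarise a chemical image
#'
#' Fills the viable map: `binary = (prediction > threshold) & mask`, with
#' the same tie rule as [classify_scores()] (a pixel exactly at the
#' threshold is nonviable).
#'
#' @param image A `"chemical_image"`.
#' @param threshold Decision threshold; defaults to the value used by the
#'   model that produced the image when supplied.
#' @return The image with `binary` and `threshold` filled.
#' @export
binarize <- function(image, threshold = 0.5) {
  stopifnot(inherits(image, "chemical_image"))
  image$binary <- !is.na(image$prediction) & image$prediction > threshold & image$mask
  image$threshold <- threshold
  image
}

#' Morphological area opening of a binary map
#'
#' Removes 4-connected foreground components smaller than `min_area`.
#' Never adds pixels.
#'
#' @param binary Logical matrix, or a `"chemical_image"` whose `binary` map
#'   is opened in place.
#' @param min_area Minimum component area in pixels (>= 1).
#' @return Same type as the input.
#' @export
area_open <- function(binary, min_area) {
  if (inherits(binary, "chemical_image")) {
    if (is.null(binary$binary)) abort("binarize() the image first",
                                      class = "hsisort_error_image")
    binary$binary <- area_open(binary$binary, min_area)
    return(binary)
  }
  stopifnot(is.matrix(binary), min_area >= 1)
  if (min_area == 1 || !any(binary)) return(binary)
  labels <- label_components(binary)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  binary & matrix(labels %in% keep, nrow(binary), ncol(binary))
}

#' Per-seed viability decision from the cleaned binary map
#'
#' A seed is called viable when the fraction of viable pixels within its
#' footprint is at least `fraction` (>= rule, so exactly the fraction
#' counts as viable).
#'
#' @param image A binarised (and typically area-opened) `"chemical_image"`,
#'   or a logical viable map.
#' @param regions Region tibble from [segment_seeds()].
#' @param fraction Required viable-pixel fraction, in (0, 1].
#' @return A tibble `region_id`, `viable_fraction`, `decision` (0/1).
#' @export
seed_decision <- function(image, regions, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "hsisort_error_image")
  }
  viable <- if (inherits(image, "chemical_image")) {
    if (is.null(image$binary)) abort("binarize() the image first",
                                     class = "hsisort_error_image")
    image$binary
  } else image
  stopifnot(is.matrix(viable))
  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    px <- regions$pixels[[i]]
    if (max(px[, 1]) > nrow(viable) || max(px[, 2]) > ncol(viable) || min(px) < 1) {
      abort("region outside the map extent", class = "hsisort_error_image")
    }
    vf <- mean(viable[px])
    tibble::tibble(region_id = regions$region_id[i], viable_fraction = vf,
                   decision = as.integer(vf >= fraction))
  })
  dplyr::bind_rows(rows)
}

#' Write chemical-image visualisations
#'
#' Writes three PNGs plus an annotation CSV: the prediction heat map
#' (grey-to-red ramp, higher red intensity = more viable), the binary viable
#' map, and an overlay marking each region centroid (green cross = viable
#' decision, red = nonviable). Annotations (region id, centroid, decision)
#' are written as CSV and returned invisibly.
#'
#' @param image A binarised `"chemical_image"`.
#' @param regions Region tibble.
#' @param decisions Decision tibble from [seed_decision()].
#' @param dir Output directory (created if needed).
#' @return The annotation tibble, invisibly.
#' @export
render_outputs <- function(image, regions, decisions, dir) {
  stopifnot(inherits(image, "chemical_image"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create output directory %s", dir),
          class = "hsisort_error_io")
  }
  pred <- image$prediction
  val <- pmin(pmax(ifelse(is.na(pred), 0, pred), 0), 1)
  rgb <- array(0, dim = c(nrow(val), ncol(val), 3))
  rgb[, , 1] <- val                         # red channel carries the score
  rgb[, , 2] <- 0.25 * val
  rgb[, , 3] <- 0.25 * val
  png::writePNG(rgb, file.path(dir, "prediction.png"))
  bin <- if (is.null(image$binary)) matrix(FALSE, nrow(val), ncol(val)) else image$binary
  png::writePNG(bin * 1, file.path(dir, "binary.png"))

  overlay <- rgb
  ann <- dplyr::left_join(regions %>%
                            select("region_id", "centroid_line", "centroid_pixel"),
                          decisions, by = "region_id")
  for (i in seq_len(nrow(ann))) {
    cl <- round(ann$centroid_line[i]); cp <- round(ann$centroid_pixel[i])
    ch <- if (isTRUE(ann$decision[i] == 1)) 2 else 1   # green viable, red not
    for (dd in -2:2) {
      l <- min(max(cl + dd, 1), nrow(val)); p <- min(max(cp + dd, 1), ncol(val))
      overlay[l, cp, ] <- 0; overlay[cl, p, ] <- 0
      overlay[l, cp, ch] <- 1; overlay[cl, p, ch] <- 1
    }
  }
  png::writePNG(overlay, file.path(dir, "overlay.png"))
  ann_out <- ann %>% select("region_id", "centroid_line", "centroid_pixel",
                            "viable_fraction", "decision")
  readr::write_csv(ann_out, file.path(dir, "annotations.csv"), na = "")
  invisible(ann_out)
}

#' @export
print.chemical_image <- function(x, ...) {
  cat(sprintf("<chemical_image> %dx%d, %d masked pixels%s, %d anomalies\n",
              nrow(x$prediction), ncol(x$prediction), sum(x$mask),
              if (!is.null(x$binary)) sprintf(", %d viable (t=%.2f)",
                                              sum(x$binary), x$threshold) else "",
              x$anomalies))
  invisible(x)
}
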