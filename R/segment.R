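#' 4-connected component labelling
#'
#' Labels connected foreground components of a logical matrix using
#' 4-connectivity. Labels are 1..n in scan-line order of each component's
#' first pixel.
#'
#' @param mask Logical matrix (`lines x pixels`).
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .label4_cpp(mask)
}

#' Segment seed footprints from a calibrated cube
#'
#' Thresholds the band-mean reflectance image against the dark belt
#' background, labels 4-connected components and removes components smaller
#' than `min_area` (area opening). This automatic rule stands in for manual
#' ROI drawing, which is not reproducible.
#'
#' @param cube A calibrated [spectral_cube()].
#' @param threshold Background threshold on the band-mean image.
#' @param min_area Minimum component area in pixels.
#' @return A tibble of regions sorted in scan-line order, with columns
#'   `region_id`, `area`, `centroid_line`, `centroid_pixel`, `min_line`,
#'   `max_line`, `min_pixel`, `max_pixel` (1-based, inclusive) and a
#'   `pixels` list-column of `(line, pixel)` matrices. The binary mask
#'   (after area opening) is attached as attribute `"mask"`. An empty scene
#'   yields a zero-row tibble, not an error.
#' @export
segment_seeds <- function(cube, threshold = 0.2, min_area = 20) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$state == "raw") {
    abort("segment_seeds() expects a calibrated cube", class = "hsisort_error_cube")
  }
  d <- dim(cube$values)
  score <- matrix(rowMeans(matrix(cube$values, nrow = d[1] * d[2])), d[1], d[2])
  mask <- score > threshold
  labels <- label_components(mask)
  regions <- region_table(labels, min_area)
  keep_mask <- labels > 0 & labels %in% regions$label
  regions <- regions %>%
    mutate(region_id = sprintf("R%03d", row_number())) %>%
    select("region_id", "area", "centroid_line", "centroid_pixel",
           "min_line", "max_line", "min_pixel", "max_pixel", "pixels")
  attr(regions, "mask") <- keep_mask
  regions
}

# summarise labelled components >= min_area, scan-line order
region_table <- function(labels, min_area) {
  idx <- which(labels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(label = integer(), area = integer(),
                          centroid_line = double(), centroid_pixel = double(),
                          min_line = integer(), max_line = integer(),
                          min_pixel = integer(), max_pixel = integer(),
                          pixels = list()))
  }
  lab <- labels[idx]
  ord <- order(lab, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; lab <- lab[ord]
  split_idx <- split(seq_len(nrow(idx)), lab)
  rows <- purrr::map(split_idx, function(ii) {
    px <- idx[ii, , drop = FALSE]
    colnames(px) <- c("line", "pixel")
    tibble::tibble(area = nrow(px),
                   centroid_line = mean(px[, 1]), centroid_pixel = mean(px[, 2]),
                   min_line = min(px[, 1]), max_line = max(px[, 1]),
                   min_pixel = min(px[, 2]), max_pixel = max(px[, 2]),
                   pixels = list(px))
  })
  out <- dplyr::bind_rows(rows) %>%
    mutate(label = as.integer(names(split_idx))) %>%
    filter(.data$area >= min_area) %>%
    arrange(.data$min_line, .data$min_pixel)
  out
}

#' Extract per-region mean spectra
#'
#' Averages the cube spectra over each region's pixels (plain arithmetic mean
#' per band) and returns one row per region as a wide spectra table with
#' `wl_*` band columns plus sample metadata.
#'
#' @param cube A calibrated [spectral_cube()].
#' @param regions Region tibble from [segment_seeds()] (or any tibble with a
#'   `pixels` list-column of `(line, pixel)` matrices).
#' @param metadata Optional tibble with `nrow(regions)` rows of per-sample
#'   metadata (e.g. `seed_id`, `side`, `variety`, `label`); defaults to
#'   region ids with unknown labels.
#' @return A spectra tibble: metadata columns, a `split` column
#'   (`"unassigned"`), then one `wl_*` column per band.
#' @export
extract_mean_spectra <- function(cube, regions, metadata = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  if (nrow(regions) == 0) {
    abort("no regions to extract", class = "hsisort_error_region")
  }
  spectra <- purrr::map(regions$pixels, function(px) {
    if (nrow(px) == 0) abort("empty region", class = "hsisort_error_region")
    if (max(px[, 1]) > d[1] || max(px[, 2]) > d[2] || min(px) < 1) {
      abort("region outside cube extent", class = "hsisort_error_region")
    }
    flat_rows <- px[, 1] + (px[, 2] - 1) * d[1]
    m <- matrix(cube$values, nrow = d[1] * d[2])[flat_rows, , drop = FALSE]
    colMeans(m)
  })
  mat <- do.call(rbind, spectra)
  colnames(mat) <- band_names(cube$wavelengths)
  if (is.null(metadata)) {
    metadata <- tibble::tibble(
      seed_id = if ("region_id" %in% names(regions)) regions$region_id
                else sprintf("R%03d", seq_len(nrow(regions))),
      side = "A", variety = "V1", label = NA_integer_)
  }
  stopifnot(nrow(metadata) == nrow(regions))
  dplyr::bind_cols(tibble::as_tibble(metadata),
                   tibble::tibble(split = "unassigned"),
                   tibble::as_tibble(mat))
}

#' Band matrix and wavelengths of a spectra table
#'
#' Helpers shared by all model-facing code: `spectra_matrix()` pulls the
#' `wl_*` columns as a numeric matrix, `spectra_wavelengths()` parses the
#' band centres back out of the column names (so CSV round-trips preserve
#' the grid).
#'
#' @param table A spectra tibble with `wl_*` columns.
#' @return A numeric matrix / numeric vector of wavelengths.
#' @export
spectra_matrix <- function(table) {
  cols <- grep("^wl_", names(table), value = TRUE)
  if (!length(cols)) {
    abort("no wl_* band columns in table", class = "hsisort_error_table")
  }
  as.matrix(table[cols])
}

#' @rdname spectra_matrix
#' @export
spectra_wavelengths <- function(table) {
  parse_band_names(grep("^wl_", names(table), value = TRUE))
}
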