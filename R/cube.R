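#' Wavelength grid for a line-scan NIR camera
#'
#' Validates a vector of band-centre wavelengths. The supported sensor range
#' is 900--1700 nm; grids must be strictly increasing and carry at least 8
#' bands.
#'
#' @param centers Numeric vector of band centres in nanometres.
#' @return The validated numeric vector, classed `"wavelength_grid"`.
#' @export
#' @examples
#' wl <- wavelength_grid(seq(905, 1695, length.out = 32))
wavelength_grid <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 8) {
    abort("a wavelength grid needs at least 8 bands", class = "hsisort_error_grid")
  }
  if (anyNA(centers) || any(!is.finite(centers))) {
    abort("wavelengths must be finite", class = "hsisort_error_grid")
  }
  if (any(diff(centers) <= 0)) {
    abort("wavelengths must be strictly increasing", class = "hsisort_error_grid")
  }
  if (min(centers) < 900 || max(centers) > 1700) {
    abort("wavelengths must lie within [900, 1700] nm", class = "hsisort_error_grid")
  }
  structure(centers, class = "wavelength_grid")
}

#' Default NIR wavelength grid
#'
#' Evenly spaced band centres spanning the 900--1700 nm sensor range.
#'
#' @param n_bands Number of bands.
#' @return A [wavelength_grid()].
#' @export
default_wavelengths <- function(n_bands = 64) {
  wavelength_grid(seq(905, 1695, length.out = n_bands))
}

#' Hyperspectral cube
#'
#' A line-scan hyperspectral cube: a 3-D array of `lines x pixels x bands`
#' with a wavelength grid, a calibration state, and a provenance record of
#' every transform applied. States only ever advance
#' `raw -> reflectance -> preprocessed`.
#'
#' @param values 3-D numeric array, `lines x pixels x bands`. Raw cubes hold
#'   sensor counts; calibrated cubes hold relative reflectance.
#' @param wavelengths A [wavelength_grid()] (or numeric vector coerced to one)
#'   with length equal to `dim(values)[3]`.
#' @param state One of `"raw"`, `"reflectance"`, `"preprocessed"`.
#' @param provenance Character vector describing applied transforms.
#' @return An object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(values, wavelengths,
                          state = c("raw", "reflectance", "preprocessed"),
                          provenance = character()) {
  state <- match.arg(state)
  if (!is.array(values) || length(dim(values)) != 3) {
    abort("cube values must be a 3-D array (lines x pixels x bands)",
          class = "hsisort_error_cube")
  }
  if (!all(is.finite(values))) {
    abort("cube values must all be finite", class = "hsisort_error_cube")
  }
  if (!inherits(wavelengths, "wavelength_grid")) {
    wavelengths <- wavelength_grid(wavelengths)
  }
  if (dim(values)[3] != length(wavelengths)) {
    abort(sprintf("band axis length (%d) != wavelength count (%d)",
                  dim(values)[3], length(wavelengths)),
          class = "hsisort_error_cube")
  }
  structure(
    list(values = values, wavelengths = wavelengths, state = state,
         provenance = as.character(provenance)),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d lines x %d pixels x %d bands [%s]\n",
              d[1], d[2], d[3], x$state))
  cat(sprintf("  wavelengths: %.1f..%.1f nm\n",
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  }
  invisible(x)
}

n_lines  <- function(cube) dim(cube$values)[1]
n_pixels <- function(cube) dim(cube$values)[2]
n_bands  <- function(cube) dim(cube$values)[3]

# enforce the one-way state machine raw -> reflectance -> preprocessed
advance_state <- function(cube, to) {
  order <- c(raw = 1L, reflectance = 2L, preprocessed = 3L)
  if (order[[to]] < order[[cube$state]]) {
    abort(sprintf("illegal cube state transition %s -> %s", cube$state, to),
          class = "hsisort_error_cube")
  }
  cube$state <- to
  cube
}

add_provenance <- function(cube, what) {
  cube$provenance <- c(cube$provenance, what)
  cube
}

#' Flatten a cube to a spectra matrix
#'
#' Rows are pixels in column-major `(line, pixel)` order: the row for pixel
#' `(l, p)` is `l + (p - 1) * lines`. Columns are bands.
#'
#' @param cube A [spectral_cube()].
#' @return A `(lines*pixels) x bands` matrix.
#' @export
as_spectra_matrix <- function(cube) {
  d <- dim(cube$values)
  m <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- band_names(cube$wavelengths)
  m
}

band_names <- function(wavelengths) {
  sprintf("wl_%.1f", as.numeric(wavelengths))
}

parse_band_names <- function(nms) {
  as.numeric(sub("^wl_", "", nms))
}

#' White/dark reference frames
#'
#' Paired reference frames for two-point reflectance calibration: the white
#' frame is acquired from a >99% reflectance Teflon board, the dark frame
#' with the lens covered. Both are `pixels x bands` count matrices and the
#' white minus dark difference must be strictly positive wherever it is used.
#'
#' @param white,dark Numeric matrices, `pixels x bands`, same shape.
#' @return An object of class `"reference_frames"`.
#' @export
reference_frames <- function(white, dark) {
  white <- as.matrix(white); dark <- as.matrix(dark)
  if (!identical(dim(white), dim(dark))) {
    abort("white and dark reference frames must have identical shape",
          class = "hsisort_error_refs")
  }
  if (!all(is.finite(white)) || !all(is.finite(dark))) {
    abort("reference frames must be finite", class = "hsisort_error_refs")
  }
  structure(list(white = white, dark = dark), class = "reference_frames")
}

#' @export
print.reference_frames <- function(x, ...) {
  cat(sprintf("<reference_frames> %d pixels x %d bands\n",
              nrow(x$white), ncol(x$white)))
  invisible(x)
}
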