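#' Endmember specification for the two seed classes
#'
#' Describes the viable and nonviable class mean reflectance spectra as a
#' smooth baseline minus Gaussian absorption features. The class contrast has
#' two parts, both stronger for nonviable seeds being *darker*: (i) deeper
#' absorption at the three diagnostic bands 1415 nm (C-H, carbohydrates),
#' 1475 nm (N-H first overtone, proteins) and 1605 nm (O-H first overtone,
#' moisture), and (ii) a small broadband reflectance offset, so the nonviable
#' mean is lower across the 1425--1670 nm window. The `contrast` multiplier
#' scales both parts; the feature *positions* are fixed chemistry, but the
#' depths are free simulator parameters.
#'
#' @param features Tibble with columns `center` (nm), `width` (nm, Gaussian
#'   sigma), `depth_viable` (absorption depth of the viable class) and
#'   `depth_delta` (extra depth for the nonviable class, >= 0).
#' @param shared_features Tibble of features common to both classes
#'   (`center`, `width`, `depth`).
#' @param class_offset Broadband reflectance drop of the nonviable class.
#' @param side_offset Small reflectance offset distinguishing seed side B
#'   from side A.
#' @return A list of class `"endmember_spec"`.
#' @export
endmember_spec <- function(
    features = tibble::tibble(
      center = c(1415, 1475, 1605),
      width = c(20, 18, 26),
      depth_viable = c(0.14, 0.12, 0.18),
      depth_delta = c(0.050, 0.045, 0.060)),
    shared_features = tibble::tibble(
      center = c(1190), width = c(40), depth = c(0.04)),
    class_offset = 0.015,
    side_offset = 0.004) {
  need <- c(1415, 1475, 1605)
  if (!all(need %in% features$center)) {
    abort("features must include centers 1415, 1475 and 1605 nm",
          class = "hsisort_error_endmember")
  }
  if (any(features$depth_delta < 0)) {
    abort("depth_delta must be >= 0 (nonviable absorbs at least as deeply)",
          class = "hsisort_error_endmember")
  }
  structure(list(features = features, shared_features = shared_features,
                 class_offset = class_offset, side_offset = side_offset),
            class = "endmember_spec")
}

gaussian_bump <- function(wl, center, width) exp(-((wl - center)^2) / (2 * width^2))

# smooth seed-coat baseline over the grid, gently decreasing towards the
# long-wavelength end
endmember_baseline <- function(wl) {
  u <- (wl - 900) / 800
  0.72 - 0.10 * u - 0.05 * u^2
}

#' Build the class mean spectra
#'
#' Evaluates the endmember specification on a wavelength grid and returns the
#' viable and nonviable class mean reflectance spectra.
#'
#' @param spec An [endmember_spec()].
#' @param wavelengths A [wavelength_grid()].
#' @param contrast Non-negative multiplier on the class contrast (feature
#'   depth difference and broadband offset). `contrast = 0` makes the two
#'   classes identical.
#' @return A list with `viable` and `nonviable` numeric spectra (both in
#'   (0, 1)) and the grid.
#' @export
make_endmembers <- function(spec = endmember_spec(),
                            wavelengths = default_wavelengths(),
                            contrast = 1) {
  wl <- as.numeric(wavelengths)
  ctr <- c(spec$features$center, spec$shared_features$center)
  if (any(ctr < min(wl) | ctr > max(wl))) {
    abort("absorption feature center outside the wavelength grid",
          class = "hsisort_error_endmember")
  }
  base <- endmember_baseline(wl)
  for (i in seq_len(nrow(spec$shared_features))) {
    f <- spec$shared_features[i, ]
    base <- base - f$depth * gaussian_bump(wl, f$center, f$width)
  }
  viable <- base
  nonviable <- base - contrast * spec$class_offset
  for (i in seq_len(nrow(spec$features))) {
    f <- spec$features[i, ]
    g <- gaussian_bump(wl, f$center, f$width)
    viable <- viable - f$depth_viable * g
    nonviable <- nonviable - (f$depth_viable + contrast * f$depth_delta) * g
  }
  if (any(viable <= 0 | viable >= 1) || any(nonviable <= 0 | nonviable >= 1)) {
    abort("endmember spectra left (0, 1); reduce depths/offset",
          class = "hsisort_error_endmember")
  }
  list(viable = viable, nonviable = nonviable, wavelengths = wavelengths)
}
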