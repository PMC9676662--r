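#' Two-point reflectance calibration
#'
#' Converts a raw-count cube to relative reflectance against the white and
#' dark references, per element:
#' `R = (X_raw - X_dark) / (X_ref - X_dark)`.
#' The result is clipped to `clip` (default `[0, 1.2]`: a little headroom
#' over the Teflon white tolerates specular pixels while bounding outliers).
#'
#' @param cube A raw [spectral_cube()].
#' @param refs [reference_frames()] covering the cube's pixel/band extent.
#' @param clip Length-2 numeric clipping range.
#' @return A [spectral_cube()] with `state = "reflectance"`.
#' @export
calibrate_reflectance <- function(cube, refs, clip = c(0, 1.2)) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(refs, "reference_frames"))
  if (cube$state != "raw") {
    abort("calibrate_reflectance() expects a raw cube", class = "hsisort_error_cube")
  }
  d <- dim(cube$values)
  if (nrow(refs$white) != d[2] || ncol(refs$white) != d[3]) {
    abort(sprintf("reference frames are %dx%d but cube needs %dx%d (pixels x bands)",
                  nrow(refs$white), ncol(refs$white), d[2], d[3]),
          class = "hsisort_error_refs")
  }
  denom <- refs$white - refs$dark
  bad <- which(denom <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("white - dark is not positive at pixel %d, band %d",
                  bad[1, 1], bad[1, 2]),
          class = "hsisort_error_refs")
  }
  flat <- matrix(cube$values, nrow = d[1])          # columns = (pixel, band)
  flat <- sweep(flat, 2, as.vector(refs$dark), `-`)
  flat <- sweep(flat, 2, as.vector(denom), `/`)
  flat <- pmin(pmax(flat, clip[1]), clip[2])
  out <- spectral_cube(array(flat, dim = d), cube$wavelengths,
                       state = "reflectance", provenance = cube$provenance)
  add_provenance(out, sprintf("reflectance calibration (clip [%g, %g])",
                              clip[1], clip[2]))
}

#' 3x3 spatial median filter
#'
#' Filters every band independently with a 3x3 spatial median to suppress
#' impulse noise. Edges use reflect padding (the out-of-frame neighbour is
#' the edge pixel itself).
#'
#' @param cube A calibrated or preprocessed [spectral_cube()].
#' @return The filtered cube (state unchanged).
#' @export
median_filter3 <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$state == "raw") {
    abort("median_filter3() expects a calibrated cube", class = "hsisort_error_cube")
  }
  d <- dim(cube$values)
  if (d[1] < 3 || d[2] < 3) {
    abort("spatial extent must be at least 3x3", class = "hsisort_error_cube")
  }
  out <- cube
  out$values <- .median3x3_cpp(cube$values, dim(cube$values))
  add_provenance(out, "3x3 spatial median filter")
}
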