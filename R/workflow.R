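#' From a rendered scene to a labelled spectra table
#'
#' Convenience wrapper chaining the batch pipeline on a synthetic scene:
#' reflectance calibration, 3x3 median filter, segmentation, mean-spectrum
#' extraction, and labelling of each found region with the ground-truth
#' class of the nearest truth centroid.
#'
#' @param scene An `"hsi_scene"` from [render_scene()].
#' @param threshold,min_area Segmentation parameters.
#' @param variety Variety code stored in the table.
#' @return A labelled spectra tibble (one row per found seed footprint)
#'   with the filtered cube and the region table attached as attributes
#'   `"cube"` and `"regions"`.
#' @export
scene_to_spectra <- function(scene, threshold = 0.2, min_area = 20,
                             variety = "V1") {
  filt <- median_filter3(calibrate_reflectance(scene$cube, scene$refs))
  regions <- segment_seeds(filt, threshold = threshold, min_area = min_area)
  if (nrow(regions) == 0) {
    abort("segmentation found no seeds", class = "hsisort_error_region")
  }
  truth <- scene$truth
  mi <- purrr::map_int(seq_len(nrow(regions)), function(i) {
    which.min((truth$centroid_line - regions$centroid_line[i])^2 +
              (truth$centroid_pixel - regions$centroid_pixel[i])^2)
  })
  if (anyDuplicated(mi)) {
    abort("regions could not be matched 1:1 to truth seeds",
          class = "hsisort_error_region")
  }
  meta <- tibble::tibble(seed_id = truth$seed_id[mi], side = truth$side[mi],
                         variety = variety, label = truth$class[mi])
  out <- extract_mean_spectra(filt, regions, metadata = meta)
  attr(out, "cube") <- filt
  attr(out, "regions") <- regions
  out
}

#' Simulate a labelled spectra table in scene chunks
#'
#' Renders `n_scenes` independent scenes of `n_seeds` each (memory-light
#' chunks of one belt run), pushes each through [scene_to_spectra()] and
#' stacks the rows with unique seed ids.
#'
#' @param n_seeds Seeds per scene.
#' @param n_scenes Number of scenes.
#' @param seed Base random seed; scene `i` uses `seed + i`.
#' @param ... Passed to [render_scene()] (e.g. `contrast`, `noise`,
#'   `sides`).
#' @return A labelled spectra tibble.
#' @export
simulate_spectra_table <- function(n_seeds, n_scenes = 1, seed = 1L, ...) {
  purrr::map(seq_len(n_scenes), function(i) {
    sc <- render_scene(n_seeds, seed = seed + i, ...)
    scene_to_spectra(sc) %>%
      mutate(seed_id = sprintf("C%02d_%s", i, .data$seed_id))
  }) %>% dplyr::bind_rows()
}
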