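#' Write and read pipeline tables as CSV
#'
#' All tabular artifacts (per-seed spectra tables, assay tables, reports) are
#' UTF-8 CSV with an explicit header row. Missing labels are written as empty
#' fields, never as 0/1 sentinels. Writing refuses duplicate sample keys: the
#' key is `(seed_id, side)` when both columns are present, else `seed_id`
#' alone.
#'
#' @param table A data frame.
#' @param path CSV file path.
#' @return `write_table()` returns `path` invisibly; `read_table()` returns a
#'   tibble.
#' @export
write_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  key <- intersect(c("seed_id", "side"), names(table))
  if (length(key)) {
    dup <- duplicated(table[key])
    if (any(dup)) {
      abort(sprintf("duplicate sample id(s): %s",
                    paste(unique(do.call(paste, c(table[dup, key, drop = FALSE], sep = "/"))),
                          collapse = ", ")),
            class = "hsisort_error_table")
    }
  }
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such table: %s", path), class = "hsisort_error_io")
  }
  readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
}

#' Run configuration for the online sorting loop
#'
#' Physical and algorithmic settings for acquisition and the streaming sort
#' loop. Defaults follow the rig conventions: conveyor belt at 49 mm/s and
#' 17 ms line exposure, so one scan line is acquired every exposure period
#' and the along-track line pitch is `belt_speed * exposure / 1000` mm.
#'
#' @param belt_speed Belt speed, mm/s (> 0).
#' @param exposure Line exposure time, ms (> 0).
#' @param frame_height Lines per processing frame in the streaming loop.
#' @param mask_threshold Background threshold on the band-mean reflectance
#'   image used for seed segmentation.
#' @param min_area Minimum connected-component area (pixels) kept by
#'   segmentation and by morphological area opening.
#' @param viable_fraction Fraction of viable pixels within a seed needed to
#'   call the seed viable.
#' @param actuation_distance Distance from field-of-view exit to the suction
#'   nozzle, mm; actuation delay is `actuation_distance / belt_speed`.
#' @param seed Integer random seed recorded with the run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(belt_speed = 49, exposure = 17, frame_height = 64,
                       mask_threshold = 0.2, min_area = 20,
                       viable_fraction = 0.5, actuation_distance = 100,
                       seed = 1L) {
  if (belt_speed <= 0) abort("belt_speed must be > 0", class = "hsisort_error_config")
  if (exposure <= 0) abort("exposure must be > 0", class = "hsisort_error_config")
  if (frame_height < 1) abort("frame_height must be >= 1", class = "hsisort_error_config")
  structure(list(belt_speed = belt_speed, exposure = exposure,
                 frame_height = as.integer(frame_height),
                 mask_threshold = mask_threshold, min_area = as.integer(min_area),
                 viable_fraction = viable_fraction,
                 actuation_distance = actuation_distance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# lines scanned per simulated second
lines_per_second <- function(config) 1000 / config$exposure

# along-track line pitch in mm
line_pitch_mm <- function(config) config$belt_speed * config$exposure / 1000
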