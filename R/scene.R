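#' Render a synthetic line-scan hyperspectral seed scene
#'
#' Generates a raw-count cube, matching white/dark reference frames and a
#' ground-truth table for a belt scene of elliptical seeds from two classes
#' (viable / nonviable). Per-seed scatter follows the standard chemometric
#' nuisance model: a multiplicative factor `a ~ lognormal(0, sigma_a)`, an
#' additive offset `b ~ N(0, sigma_b)` and a linear baseline tilt across the
#' band axis, plus i.i.d. per-pixel sensor noise -- exactly the distortions
#' the MSC/SNV/derivative preprocessing suite is meant to remove. Raw counts
#' are `dark + (white - dark) * reflectance`, rounded to integers, so
#' two-point calibration is a genuine inversion up to quantisation.
#'
#' @param n_seeds Number of physical seeds to place.
#' @param wavelengths A [wavelength_grid()].
#' @param spec An [endmember_spec()].
#' @param contrast Class-contrast multiplier passed to [make_endmembers()].
#' @param noise Either a single number `0` (disable all noise) or a list with
#'   elements `pixel` (reflectance sd per pixel/band), `sigma_a`
#'   (lognormal sdlog of the multiplicative scatter), `sigma_b` (sd of the
#'   additive offset) and `tilt` (sd of the per-seed linear baseline tilt).
#' @param prop_viable Proportion of seeds that are viable (count is rounded).
#' @param sides 1 or 2; with 2, every seed is rendered a second time (side B)
#'   in a second scan pass appended below the first, with independent scatter
#'   draws and a small side-specific spectral offset.
#' @param pixels Across-track frame width in pixels.
#' @param max_lines Optional cap on scene length; if the layout cannot place
#'   all seeds within it, an error is raised.
#' @param seed Integer random seed; identical seeds give identical scenes.
#' @return A list of class `"hsi_scene"` with elements `cube` (raw
#'   [spectral_cube()]), `refs` ([reference_frames()]), `truth` (tibble with
#'   one row per seed and side: id, side, class, chemistry triple,
#'   germination outcome, centroid, area and a `footprint` list-column of
#'   `(line, pixel)` matrices), and `endmembers`.
#' @export
render_scene <- function(n_seeds, wavelengths = default_wavelengths(),
                         spec = endmember_spec(), contrast = 1,
                         noise = list(pixel = 0.01, sigma_a = 0.08,
                                      sigma_b = 0.01, tilt = 0.01),
                         prop_viable = 0.5, sides = 1, pixels = 160,
                         max_lines = NULL, seed = 1L) {
  if (is.numeric(noise) && length(noise) == 1 && noise == 0) {
    noise <- list(pixel = 0, sigma_a = 0, sigma_b = 0, tilt = 0)
  }
  stopifnot(n_seeds >= 1, sides %in% c(1, 2))
  withr::local_seed(seed)

  em <- make_endmembers(spec, wavelengths, contrast = contrast)
  wl <- as.numeric(wavelengths)
  B <- length(wl)
  u <- (seq_len(B) - 1) / (B - 1) - 0.5 # tilt coordinate across bands

  # class assignment and latent chemistry (clamped so classes stay disjoint)
  n_viable <- round(n_seeds * prop_viable)
  class <- sample(c(rep(1L, n_viable), rep(0L, n_seeds - n_viable)))
  chem_mean <- ifelse(class == 1L, 0.70, 0.45)
  draw_chem <- function() pmin(pmax(rnorm(n_seeds, 0, 0.05), -0.10), 0.10) + chem_mean
  carb <- draw_chem(); prot <- draw_chem(); moist <- draw_chem()
  germ_p <- plogis(10 * ((carb + prot + moist) / 3 - 0.575))
  germination <- rbinom(n_seeds, 1, germ_p)

  # grid layout with jittered elliptical footprints (aspect 1.5-2 along track)
  cell_w <- 16L; cell_h <- 26L; margin <- 2L
  per_row <- max(1L, (pixels - 2L * margin) %/% cell_w)
  n_rows <- ceiling(n_seeds / per_row)
  pass_lines <- n_rows * cell_h + 2L * margin
  lines <- pass_lines * sides
  if (!is.null(max_lines) && lines > max_lines) {
    abort(sprintf("cannot place %d seeds disjointly within %d lines (need %d)",
                  n_seeds, max_lines, lines), class = "hsisort_error_layout")
  }

  place_footprints <- function() {
    fp <- vector("list", n_seeds)
    for (s in seq_len(n_seeds)) {
      row <- (s - 1L) %/% per_row
      col <- (s - 1L) %% per_row
      placed <- FALSE
      for (try in 1:50) {
        rb <- runif(1, 3.2, 4.8)              # across-track semi-axis
        ra <- rb * runif(1, 1.5, 2.0)         # along-track semi-axis
        cl0 <- margin + row * cell_h + cell_h / 2 + runif(1, -1.5, 1.5)
        cp0 <- margin + col * cell_w + cell_w / 2 + runif(1, -1.5, 1.5)
        if (cl0 - ra < margin + row * cell_h + 1 ||
            cl0 + ra > margin + (row + 1) * cell_h - 1 ||
            cp0 - rb < margin + col * cell_w + 1 ||
            cp0 + rb > min(pixels - 1, margin + (col + 1) * cell_w - 1)) next
        ll <- seq(floor(cl0 - ra), ceiling(cl0 + ra))
        pp <- seq(floor(cp0 - rb), ceiling(cp0 + rb))
        g <- expand.grid(line = ll, pixel = pp)
        keep <- ((g$line - cl0) / ra)^2 + ((g$pixel - cp0) / rb)^2 <= 1
        px <- as.matrix(g[keep, , drop = FALSE])
        storage.mode(px) <- "integer"
        if (nrow(px) < 8) next
        fp[[s]] <- px
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("layout cannot place all seeds disjointly (retries exhausted)",
              class = "hsisort_error_layout")
      }
    }
    fp
  }

  refl <- array(0.06, dim = c(lines, pixels, B)) # dark belt background

  truth_rows <- list()
  for (side_i in seq_len(sides)) {
    side <- c("A", "B")[side_i]
    offset_lines <- (side_i - 1L) * pass_lines
    fp <- place_footprints()
    a <- rlnorm(n_seeds, 0, noise$sigma_a)
    b <- rnorm(n_seeds, 0, noise$sigma_b)
    tilt <- rnorm(n_seeds, 0, noise$tilt)
    side_off <- if (side == "B") spec$side_offset else 0
    for (s in seq_len(n_seeds)) {
      base_spec <- (if (class[s] == 1L) em$viable else em$nonviable) + side_off
      px <- fp[[s]]
      px[, "line"] <- px[, "line"] + offset_lines
      spectra <- a[s] * matrix(base_spec, nrow(px), B, byrow = TRUE) +
        b[s] + tilt[s] * matrix(u, nrow(px), B, byrow = TRUE)
      idx <- cbind(px[rep(seq_len(nrow(px)), B), , drop = FALSE],
                   band = rep(seq_len(B), each = nrow(px)))
      refl[idx] <- as.vector(spectra)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        seed_id = sprintf("S%03d", s), side = side, class = class[s],
        carbohydrate = carb[s], protein = prot[s], moisture = moist[s],
        germination = germination[s],
        centroid_line = mean(px[, "line"]), centroid_pixel = mean(px[, "pixel"]),
        area = nrow(px), footprint = list(px))
    }
  }
  if (noise$pixel > 0) {
    refl <- refl + array(rnorm(length(refl), 0, noise$pixel), dim = dim(refl))
  }
  refl <- pmax(refl, 0.001)

  # sensor model: dark current + fixed-pattern noise; smooth lamp profile
  dark <- matrix(120, pixels, B) + matrix(rnorm(pixels * B, 0, 2), pixels, B)
  dark <- pmax(round(dark), 0)
  lamp <- 3000 * (0.55 + 0.45 * exp(-((wl - 1300) / 250)^2))
  white <- dark + matrix(lamp, pixels, B, byrow = TRUE)
  white <- round(white)

  gain <- white - dark
  raw <- array(0, dim = c(lines, pixels, B))
  flat_refl <- matrix(refl, nrow = lines)             # columns = (pixel, band)
  flat_raw <- sweep(flat_refl, 2, as.vector(gain), `*`)
  flat_raw <- sweep(flat_raw, 2, as.vector(dark), `+`)
  raw <- array(pmax(round(flat_raw), 0), dim = c(lines, pixels, B))

  cube <- spectral_cube(raw, wavelengths, state = "raw",
                        provenance = sprintf("synthetic scene (seed=%d, contrast=%g, sides=%d)",
                                             seed, contrast, sides))
  truth <- dplyr::bind_rows(truth_rows) %>%
    arrange(.data$side, .data$centroid_line, .data$centroid_pixel)
  structure(list(cube = cube, refs = reference_frames(white, dark),
                 truth = truth, endmembers = em,
                 params = list(contrast = contrast, noise = noise,
                               sides = sides, seed = seed)),
            class = "hsi_scene")
}

#' @export
print.hsi_scene <- function(x, ...) {
  cat(sprintf("<hsi_scene> %d seed footprints (%d viable), cube %s\n",
              nrow(x$truth), sum(x$truth$class == 1L),
              paste(dim(x$cube$values), collapse = "x")))
  invisible(x)
}

#' Write a rendered scene to disk
#'
#' Writes the raw cube and reference frames as ENVI pairs and the truth table
#' (without footprint pixel sets) as CSV.
#'
#' @param scene An `"hsi_scene"` from [render_scene()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cube(scene$cube, file.path(dir, "scene"))
  write_reference_frames(scene$refs, scene$cube$wavelengths,
                         file.path(dir, "reference"))
  write_table(scene$truth %>% select(-"footprint"), file.path(dir, "truth.csv"))
  invisible(dir)
}
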