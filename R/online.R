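#' Split a cube into ordered acquisition frames
#'
#' Partitions the line axis into consecutive frames of `frame_height` lines
#' (the final frame may be shorter); concatenating the frames reproduces the
#' cube exactly. This realises line-scan acquisition: the belt advances one
#' line per exposure period and the processing loop is triggered once per
#' frame.
#'
#' @param cube A [spectral_cube()].
#' @param frame_height Lines per frame (>= 1).
#' @return A list of 3-D arrays, each with attribute `start_line`.
#' @export
stream_frames <- function(cube, frame_height) {
  stopifnot(inherits(cube, "spectral_cube"), frame_height >= 1)
  L <- n_lines(cube)
  starts <- seq(1L, L, by = as.integer(frame_height))
  purrr::map(starts, function(s) {
    e <- min(s + frame_height - 1L, L)
    f <- cube$values[s:e, , , drop = FALSE]
    attr(f, "start_line") <- s
    f
  })
}

#' Run the streaming online sorting loop
#'
#' Emulates the online flowchart: frames arrive in scan order; each line is
#' calibrated against the references, median-filtered (using its already
#' received neighbours, with reflect padding at the true cube edges), and
#' thresholded into a seed/background line. Open seed blobs are stitched
#' across line and frame boundaries by 4-connectivity (pixel-column overlap
#' with the blob's previous line). When a blob receives no pixels on the
#' current line it has fully exited the field of view and is decided
#' immediately: its pixels are scored through the model, binarised at the
#' model threshold, area-opened, and reduced to a per-seed decision -- the
#' identical operations batch processing applies to the whole cube, so
#' streaming and batch decisions agree exactly for every frame height.
#'
#' @param cube A raw [spectral_cube()] (the full scan; frames are cut
#'   internally), or a list of frames from [stream_frames()].
#' @param refs [reference_frames()].
#' @param model A fitted `"plsda_model"`.
#' @param config A [run_config()]; uses `frame_height`, `mask_threshold`,
#'   `min_area`, `viable_fraction` and the timing fields.
#' @return A list: `events` -- tibble with one sort event per detected seed
#'   (`event_id`, `decision`, `viable_fraction`, `area`, `centroid_line`,
#'   `centroid_pixel`, `closure_line`, `time_s`, `open_at_end`); `log` --
#'   one row per frame; `duration_s` -- simulated scan duration.
#' @export
run_online <- function(cube, refs, model, config = run_config()) {
  frames <- if (inherits(cube, "spectral_cube")) {
    stream_frames(cube, config$frame_height)
  } else cube
  P <- dim(frames[[1]])[2]; B <- dim(frames[[1]])[3]
  if (nrow(refs$white) != P || ncol(refs$white) != B) {
    abort("reference/frame shape mismatch", class = "hsisort_error_refs")
  }
  denom <- refs$white - refs$dark
  if (any(denom <= 0)) abort("white - dark not positive", class = "hsisort_error_refs")
  lps <- lines_per_second(config)
  delay_s <- config$actuation_distance / config$belt_speed

  cal <- list()          # calibrated lines (P x B matrices)
  filt <- list()         # filtered lines
  blobs <- list()        # active blobs: list(pixels, last_cols)
  events <- list()
  log_rows <- list()
  next_blob <- 0L

  filter_line <- function(l, total) {
    lo <- max(1L, l - 1L); hi <- min(total, l + 1L)
    slab <- array(0, dim = c(3L, P, B))
    slab[1, , ] <- cal[[lo]]
    slab[2, , ] <- cal[[l]]
    slab[3, , ] <- cal[[hi]]
    out <- .median3x3_cpp(slab, dim(slab))
    matrix(out[2, , ], P, B)
  }

  close_blob <- function(blob, closure_line, open_at_end) {
    px <- blob$pixels
    if (nrow(px) < config$min_area) return(NULL)
    X_raw <- do.call(rbind, purrr::map(seq_len(nrow(px)),
                                       function(i) filt[[px[i, 1]]][px[i, 2], ]))
    degenerate <- preprocess_degenerate_rows(X_raw, model$preprocess)
    scores <- rep(0, nrow(px))
    if (any(!degenerate)) {
      Xp <- apply_preprocess(X_raw[!degenerate, , drop = FALSE], model$preprocess)
      scores[!degenerate] <- predict_scores(model, Xp)
    }
    viable <- scores > model$threshold
    # area opening restricted to the blob's bounding box
    bb_l <- range(px[, 1]); bb_p <- range(px[, 2])
    local <- matrix(FALSE, bb_l[2] - bb_l[1] + 1L, bb_p[2] - bb_p[1] + 1L)
    local[cbind(px[viable, 1] - bb_l[1] + 1L, px[viable, 2] - bb_p[1] + 1L)] <- TRUE
    local <- area_open(local, config$min_area)
    vf <- sum(local) / nrow(px)
    tibble::tibble(
      decision = as.integer(vf >= config$viable_fraction),
      viable_fraction = vf, area = nrow(px),
      centroid_line = mean(px[, 1]), centroid_pixel = mean(px[, 2]),
      closure_line = closure_line,
      time_s = closure_line / lps + delay_s,
      open_at_end = open_at_end)
  }

  total <- sum(purrr::map_int(frames, ~ dim(.x)[1]))
  if (total < 3) abort("stream too short to filter", class = "hsisort_error_cube")
  received <- 0L
  filtered <- 0L

  process_filtered_line <- function(l) {
    fl <- filter_line(l, total)
    filt[[l]] <<- fl
    mask_line <- rowMeans(fl) > config$mask_threshold
    r <- rle(mask_line)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    touched <- character()
    for (k in runs) {
      cols <- starts[k]:ends[k]
      hit <- names(blobs)[purrr::map_lgl(blobs, ~ any(.x$last_cols %in% cols))]
      px_new <- cbind(line = rep(l, length(cols)), pixel = cols)
      if (length(hit) == 0) {
        next_blob <<- next_blob + 1L
        id <- sprintf("B%04d", next_blob)
        blobs[[id]] <<- list(pixels = px_new, new_cols = cols)
        touched <- c(touched, id)
      } else {
        id <- hit[1]
        if (length(hit) > 1) {          # merge blobs joined by this run
          for (other in hit[-1]) {
            blobs[[id]]$pixels <<- rbind(blobs[[id]]$pixels, blobs[[other]]$pixels)
            blobs[[id]]$last_cols <<- union(blobs[[id]]$last_cols,
                                            blobs[[other]]$last_cols)
            nc <- blobs[[other]]$new_cols
            if (!is.null(nc)) blobs[[id]]$new_cols <<- union(blobs[[id]]$new_cols, nc)
            blobs[[other]] <<- NULL
            touched <- setdiff(touched, other)
          }
        }
        blobs[[id]]$pixels <<- rbind(blobs[[id]]$pixels, px_new)
        blobs[[id]]$new_cols <<- union(blobs[[id]]$new_cols %||% integer(), cols)
        touched <- union(touched, id)
      }
    }
    # close blobs with no pixels on this line
    emitted <- 0L
    for (id in setdiff(names(blobs), touched)) {
      ev <- close_blob(blobs[[id]], closure_line = l, open_at_end = FALSE)
      if (!is.null(ev)) { events[[length(events) + 1L]] <<- ev; emitted <- emitted + 1L }
      blobs[[id]] <<- NULL
    }
    # roll the line: this line's columns become the stitch set
    for (id in names(blobs)) {
      blobs[[id]]$last_cols <<- blobs[[id]]$new_cols %||% integer()
      blobs[[id]]$new_cols <<- NULL
    }
    emitted
  }

  for (fi in seq_along(frames)) {
    f <- frames[[fi]]
    h <- dim(f)[1]
    for (j in seq_len(h)) {
      received <- received + 1L
      flat <- matrix(f[j, , ], P, B)
      cal[[received]] <- pmin(pmax((flat - refs$dark) / denom, 0), 1.2)
    }
    emitted <- 0L
    while (filtered < min(received - 1L, total)) {
      filtered <- filtered + 1L
      emitted <- emitted + process_filtered_line(filtered)
    }
    log_rows[[fi]] <- tibble::tibble(
      frame = fi, start_line = attr(f, "start_line") %||% NA_integer_,
      lines = h, active_blobs = length(blobs), events_emitted = emitted)
  }
  while (filtered < total) {              # flush: last line has no successor
    filtered <- filtered + 1L
    process_filtered_line(filtered)
  }
  for (id in names(blobs)) {              # blobs still open at stream end
    ev <- close_blob(blobs[[id]], closure_line = total, open_at_end = TRUE)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  ev <- if (length(events)) {
    dplyr::bind_rows(events) %>%
      arrange(.data$closure_line, .data$centroid_pixel) %>%
      mutate(event_id = sprintf("E%03d", row_number())) %>%
      select("event_id", dplyr::everything())
  } else {
    tibble::tibble(event_id = character(), decision = integer(),
                   viable_fraction = double(), area = integer(),
                   centroid_line = double(), centroid_pixel = double(),
                   closure_line = integer(), time_s = double(),
                   open_at_end = logical())
  }
  list(events = ev, log = dplyr::bind_rows(log_rows),
       duration_s = total / lps)
}

#' Batch report for a finished online run
#'
#' Matches sort events to ground-truth seeds by centroid proximity, reuses
#' [evaluate_classification()] for the confusion matrix, and summarises
#' throughput from the timing model (simulated seconds, never wall clock).
#'
#' @param run Result of [run_online()].
#' @param truth Scene truth tibble (one row per seed and side present in
#'   the scanned cube).
#' @param config The [run_config()] used for the run.
#' @return A list: `matched` (events joined to truth), `confusion`
#'   (one-row metrics tibble), `throughput` (tibble with `duration_s`,
#'   `n_seeds`, `seeds_per_second`).
#' @export
batch_report <- function(run, truth, config = run_config()) {
  ev <- run$events
  if (nrow(ev) != nrow(truth)) {
    abort(sprintf("event/truth mismatch: %d events for %d seeds",
                  nrow(ev), nrow(truth)), class = "hsisort_error_online")
  }
  match_idx <- purrr::map_int(seq_len(nrow(ev)), function(i) {
    d2 <- (truth$centroid_line - ev$centroid_line[i])^2 +
      (truth$centroid_pixel - ev$centroid_pixel[i])^2
    which.min(d2)
  })
  if (anyDuplicated(match_idx)) {
    abort("could not match events to distinct seeds", class = "hsisort_error_online")
  }
  matched <- ev %>% mutate(truth_class = truth$class[match_idx],
                           seed_id = truth$seed_id[match_idx],
                           side = truth$side[match_idx])
  list(matched = matched,
       confusion = evaluate_classification(matched$decision, matched$truth_class),
       throughput = tibble::tibble(
         duration_s = run$duration_s, n_seeds = nrow(ev),
         seeds_per_second = nrow(ev) / run$duration_s))
}
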