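#' Read and write hyperspectral cubes (ENVI header + BIL)
#'
#' Cubes are stored in the ENVI convention used across HSI tooling: a plain
#' text `.hdr` file describing the layout plus a band-interleaved-by-line
#' (`.bil`) binary payload. Raw-count cubes whose values are all integers in
#' `[0, 65535]` are written as unsigned 16-bit (ENVI data type 12); all other
#' cubes as little-endian doubles (type 5), so write/read round-trips are
#' bit-exact. The cube state and provenance are carried in the header.
#'
#' @param cube A [spectral_cube()].
#' @param path Path to the `.hdr` or `.bil` file, or a basename without
#'   extension; the sibling file is derived.
#' @return `read_cube()` returns a [spectral_cube()]; `write_cube()` returns
#'   `path` (the `.hdr` file) invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  base <- sub("\\.(hdr|bil)$", "", path)
  d <- dim(cube$values)
  use_u16 <- cube$state == "raw" &&
    all(cube$values >= 0 & cube$values < 65536 & cube$values == round(cube$values))
  hdr <- c(
    "ENVI",
    "description = {hsisort cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    sprintf("data type = %d", if (use_u16) 12L else 5L),
    "interleave = bil",
    "byte order = 0",
    sprintf("cube state = %s", cube$state),
    sprintf("provenance = {%s}", paste(cube$provenance, collapse = "; ")),
    sprintf("wavelength units = nm"),
    sprintf("wavelength = {%s}",
            paste(format(as.numeric(cube$wavelengths), digits = 17, trim = TRUE),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(base, ".hdr"))
  # BIL order: line-major, within a line band-major, samples fastest
  payload <- as.vector(aperm(cube$values, c(2, 3, 1)))
  con <- file(paste0(base, ".bil"), "wb")
  on.exit(close(con))
  if (use_u16) {
    writeBin(as.integer(payload), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(payload), con, size = 8, endian = "little")
  }
  invisible(paste0(base, ".hdr"))
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  base <- sub("\\.(hdr|bil)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  bil_path <- paste0(base, ".bil")
  if (!file.exists(hdr_path)) {
    abort(sprintf("missing ENVI header: %s", hdr_path), class = "hsisort_error_io")
  }
  if (!file.exists(bil_path)) {
    abort(sprintf("missing BIL payload: %s", bil_path), class = "hsisort_error_io")
  }
  hdr <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave", "wavelength")
  missing <- setdiff(need, names(hdr))
  if (length(missing)) {
    abort(sprintf("ENVI header missing field(s): %s", paste(missing, collapse = ", ")),
          class = "hsisort_error_io")
  }
  P <- as.integer(hdr[["samples"]]); L <- as.integer(hdr[["lines"]])
  B <- as.integer(hdr[["bands"]])
  if (tolower(hdr[["interleave"]]) != "bil") {
    abort("only BIL interleave is supported", class = "hsisort_error_io")
  }
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != B) {
    abort(sprintf("wavelength count mismatch: header declares %d bands but lists %d wavelengths",
                  B, length(wl)), class = "hsisort_error_io")
  }
  dtype <- as.integer(hdr[["data type"]])
  n <- as.double(L) * P * B
  con <- file(bil_path, "rb")
  on.exit(close(con))
  payload <- switch(as.character(dtype),
    "12" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    "5"  = readBin(con, "double", n = n, size = 8, endian = "little"),
    abort(sprintf("unsupported ENVI data type %d", dtype), class = "hsisort_error_io")
  )
  if (length(payload) != n) {
    abort(sprintf("BIL payload truncated: expected %.0f values, read %d", n, length(payload)),
          class = "hsisort_error_io")
  }
  if (!all(is.finite(payload))) {
    abort("non-finite values in BIL payload", class = "hsisort_error_io")
  }
  arr <- aperm(array(payload, dim = c(P, B, L)), c(3, 1, 2))
  state <- hdr[["cube state"]] %||% "raw"
  prov <- hdr[["provenance"]] %||% ""
  prov <- if (nzchar(prov)) strsplit(prov, "; ", fixed = TRUE)[[1]] else character()
  spectral_cube(arr, wavelength_grid(wl), state = state, provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal ENVI header parser: "key = value" lines, {...} values may span lines
parse_envi_header <- function(path) {
  raw <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(raw)) {
    line <- raw[[i]]
    if (grepl("=", line, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      if (startsWith(val, "{")) {
        while (!grepl("\\}", val) && i < length(raw)) {
          i <- i + 1L
          val <- paste(val, trimws(raw[[i]]))
        }
        val <- gsub("[{}]", "", val)
      }
      out[[tolower(key)]] <- trimws(val)
    }
    i <- i + 1L
  }
  out
}

#' Write/read white+dark reference frames
#'
#' Stored as a pair of single-line ENVI cubes (`<base>_white.hdr/.bil`,
#' `<base>_dark.hdr/.bil`) on the same wavelength grid as the scene cube.
#'
#' @param refs A [reference_frames()].
#' @param wavelengths The [wavelength_grid()] the frames were acquired on.
#' @param base Basename (no extension) for the four files.
#' @return `read_reference_frames()` returns a [reference_frames()];
#'   `write_reference_frames()` returns `base` invisibly.
#' @export
write_reference_frames <- function(refs, wavelengths, base) {
  stopifnot(inherits(refs, "reference_frames"))
  as_cube <- function(m) {
    spectral_cube(array(m, dim = c(1L, nrow(m), ncol(m))), wavelengths,
                  state = "raw")
  }
  write_cube(as_cube(refs$white), paste0(base, "_white"))
  write_cube(as_cube(refs$dark), paste0(base, "_dark"))
  invisible(base)
}

#' @rdname write_reference_frames
#' @export
read_reference_frames <- function(base) {
  w <- read_cube(paste0(base, "_white"))
  d <- read_cube(paste0(base, "_dark"))
  reference_frames(w$values[1, , ], d$values[1, , ])
}
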