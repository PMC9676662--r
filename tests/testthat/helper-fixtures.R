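# shared fixtures: everything is generated in code, no stored data

tiny_grid <- function(n = 16) default_wavelengths(n)

# small deterministic cube with known payload
tiny_cube <- function(lines = 6, pixels = 5, bands = 16, state = "raw",
                      seed = 1) {
  set.seed(seed)
  vals <- array(sample.int(4000, lines * pixels * bands, replace = TRUE),
                dim = c(lines, pixels, bands))
  if (state != "raw") vals <- vals / 4000
  spectral_cube(vals, tiny_grid(bands), state = state)
}

# flat references: white = 1000 counts over dark = 100
flat_refs <- function(pixels = 5, bands = 16, white = 1000, dark = 100) {
  reference_frames(matrix(white, pixels, bands), matrix(dark, pixels, bands))
}

# brute-force 3x3 median with edge-replicating padding, one band
oracle_median3 <- function(band) {
  L <- nrow(band); P <- ncol(band)
  out <- band
  for (l in seq_len(L)) {
    for (p in seq_len(P)) {
      ll <- pmin(pmax(l + (-1:1), 1), L)
      pp <- pmin(pmax(p + (-1:1), 1), P)
      out[l, p] <- median(band[ll, pp])
    }
  }
  out
}

# brute-force 4-connected labelling by BFS
oracle_label4 <- function(mask) {
  L <- nrow(mask); P <- ncol(mask)
  lab <- matrix(0L, L, P)
  nextlab <- 0L
  for (l0 in seq_len(L)) for (p0 in seq_len(P)) {
    if (!mask[l0, p0] || lab[l0, p0] != 0) next
    nextlab <- nextlab + 1L
    queue <- list(c(l0, p0)); lab[l0, p0] <- nextlab
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        l <- q[1] + d[1]; p <- q[2] + d[2]
        if (l >= 1 && l <= L && p >= 1 && p <= P && mask[l, p] && lab[l, p] == 0) {
          lab[l, p] <- nextlab
          queue[[length(queue) + 1]] <- c(l, p)
        }
      }
    }
  }
  lab
}

# canonicalise a labelling for comparison: map labels to pixel-set signatures
label_signature <- function(lab) {
  sets <- split(which(lab > 0), lab[lab > 0])
  unname(sets[order(vapply(sets, min, numeric(1)))])
}

# concatenate frame arrays along the line axis
abind_lines <- function(...) {
  frames <- list(...)
  d <- dim(frames[[1]])
  out <- array(0, dim = c(sum(vapply(frames, function(f) dim(f)[1], numeric(1))),
                          d[2], d[3]))
  at <- 0
  for (f in frames) {
    out[at + seq_len(dim(f)[1]), , ] <- f
    at <- at + dim(f)[1]
  }
  out
}

# small labelled spectra table straight from the generator
small_spectra_table <- function(n_seeds = 24, seed = 42, ...) {
  sc <- render_scene(n_seeds, seed = seed, ...)
  scene_to_spectra(sc)
}
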