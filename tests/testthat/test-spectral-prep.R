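test_that("reflectance calibration maps the reference points correctly", {
  refs <- flat_refs(5, 16, white = 1000, dark = 100)
  grid <- tiny_grid(16)
  make <- function(v) spectral_cube(array(v, c(4, 5, 16)), grid, state = "raw")
  expect_equal(unique(as.vector(
    calibrate_reflectance(make(1000), refs)$values)), 1.0)
  expect_equal(unique(as.vector(
    calibrate_reflectance(make(100), refs)$values)), 0.0)
  expect_equal(unique(as.vector(
    calibrate_reflectance(make(550), refs)$values)), 0.5)
  # clipping bounds
  expect_equal(max(calibrate_reflectance(make(4000), refs)$values), 1.2)
  expect_equal(min(calibrate_reflectance(make(0), refs)$values), 0)
  # degenerate reference must name the offending element
  bad <- reference_frames(matrix(100, 5, 16), matrix(100, 5, 16))
  expect_error(calibrate_reflectance(make(500), bad), "pixel 1, band 1")
  # state machine: cannot calibrate twice
  r <- calibrate_reflectance(make(550), refs)
  expect_error(calibrate_reflectance(r, refs), "raw cube")
})

test_that("median filter matches the brute-force 9-element oracle", {
  set.seed(8)
  cube <- spectral_cube(array(runif(10 * 9 * 8), c(10, 9, 8)),
                        tiny_grid(8), state = "reflectance")
  filt <- median_filter3(cube)
  for (b in c(1, 5, 8)) {
    expect_equal(filt$values[, , b], oracle_median3(cube$values[, , b]))
  }
  # constant band unchanged; single impulse erased
  const <- spectral_cube(array(0.4, c(6, 6, 8)), tiny_grid(8), "reflectance")
  expect_equal(median_filter3(const)$values, const$values)
  imp <- const
  imp$values[3, 3, 2] <- 10
  expect_equal(median_filter3(imp)$values[3, 3, 2], 0.4)
  tiny <- spectral_cube(array(0.1, c(2, 5, 8)), tiny_grid(8), "reflectance")
  expect_error(median_filter3(tiny), "at least 3x3")
})

test_that("4-connected labelling matches a BFS oracle on random masks", {
  set.seed(15)
  for (i in 1:5) {
    mask <- matrix(runif(30 * 20) < 0.4, 30, 20)
    expect_identical(label_signature(label_components(mask)),
                     label_signature(oracle_label4(mask)))
  }
  # diagonal touching does NOT connect under 4-connectivity
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m)), 2)
})

test_that("segmentation recovers the generator footprints exactly without noise", {
  sc <- render_scene(5, noise = 0, seed = 77)
  refl <- calibrate_reflectance(sc$cube, sc$refs)
  regions <- segment_seeds(refl, threshold = 0.2, min_area = 20)
  expect_equal(nrow(regions), 5)
  key <- function(px) unname(sort(as.numeric(px[, 1] + 1000 * px[, 2])))
  truth_sets <- lapply(sc$truth$footprint, key)
  region_sets <- lapply(regions$pixels, key)
  for (rs in region_sets) {
    expect_true(any(vapply(truth_sets, identical, logical(1), rs)))
  }
  # all-background scene -> empty region list, no error
  bg <- spectral_cube(array(0.05, c(10, 10, 8)), tiny_grid(8), "reflectance")
  expect_equal(nrow(segment_seeds(bg)), 0)
  # small speck removed by the area opening
  sp <- bg
  sp$values[5, 5:7, ] <- 0.9
  expect_equal(nrow(segment_seeds(sp, min_area = 20)), 0)
  expect_equal(nrow(segment_seeds(sp, min_area = 3)), 1)
})

test_that("mean-spectrum extraction equals the brute-force pixel loop", {
  sc <- render_scene(4, seed = 55)
  refl <- calibrate_reflectance(sc$cube, sc$refs)
  regions <- segment_seeds(refl)
  tbl <- extract_mean_spectra(refl, regions)
  X <- spectra_matrix(tbl)
  for (i in seq_len(nrow(regions))) {
    px <- regions$pixels[[i]]
    acc <- 0
    for (j in seq_len(nrow(px))) acc <- acc + refl$values[px[j, 1], px[j, 2], ]
    expect_equal(unname(X[i, ]), acc / nrow(px), tolerance = 1e-12)
  }
  # identical-pixel region returns that spectrum; two-pixel region the average
  cube <- spectral_cube(array(0.25, c(6, 6, 8)), tiny_grid(8), "reflectance")
  cube$values[2, 3, ] <- seq(0.1, 0.8, length.out = 8)
  r1 <- tibble::tibble(region_id = "R001",
                       pixels = list(cbind(line = c(2, 2), pixel = c(2, 4))))
  got <- spectra_matrix(extract_mean_spectra(cube, r1))
  expect_equal(unname(got[1, ]), rep(0.25, 8))
  r2 <- tibble::tibble(region_id = "R001",
                       pixels = list(cbind(line = c(2, 2), pixel = c(3, 4))))
  got2 <- spectra_matrix(extract_mean_spectra(cube, r2))
  expect_equal(unname(got2[1, ]), (seq(0.1, 0.8, length.out = 8) + 0.25) / 2)
  bad <- tibble::tibble(region_id = "R001",
                        pixels = list(cbind(line = 99, pixel = 1)))
  expect_error(extract_mean_spectra(cube, bad), "outside cube extent")
})

test_that("preprocessing transforms satisfy their closed-form identities", {
  expect_equal(drop(apply_preprocess(rbind(c(2, 4, 6)),
                                     preprocess_spec("range_norm"))),
               c(0, 0.5, 1))
  expect_equal(drop(apply_preprocess(rbind(c(1, 2, 3)),
                                     preprocess_spec("snv"))),
               c(-1, 0, 1))
  expect_equal(drop(apply_preprocess(rbind(c(2, 4, 6)),
                                     preprocess_spec("mean_norm"))),
               c(0.5, 1, 1.5))
  expect_equal(drop(apply_preprocess(rbind(c(2, 4, 8)),
                                     preprocess_spec("max_norm"))),
               c(0.25, 0.5, 1))
  # msc inverts an affine distortion exactly
  set.seed(2)
  ref <- runif(20)
  x <- 2 * ref + 5
  got <- drop(apply_preprocess(rbind(x), preprocess_spec("msc", reference = ref)))
  expect_equal(got, ref, tolerance = 1e-12)
  # errors on degenerate rows
  expect_error(apply_preprocess(rbind(c(1, 1, 1)), preprocess_spec("snv")),
               "zero-variance")
  expect_error(apply_preprocess(rbind(c(2, 2, 2)), preprocess_spec("range_norm")),
               "constant")
  expect_error(apply_preprocess(rbind(c(-1, -2, -3)), preprocess_spec("max_norm")),
               "max")
  expect_error(preprocess_spec("sg1", window = 4), "odd")
})

test_that("Savitzky-Golay derivatives reproduce polynomial derivatives", {
  i <- 0:40
  lin <- 3 + 0.7 * i
  quad <- 1 + 0.5 * i + 0.25 * i^2
  sg1 <- preprocess_spec("sg1", window = 11, poly_order = 2)
  sg2 <- preprocess_spec("sg2", window = 11, poly_order = 2)
  d1 <- drop(apply_preprocess(rbind(lin), sg1))
  expect_equal(d1, rep(0.7, 41), tolerance = 1e-10)   # slope per band step
  d2lin <- drop(apply_preprocess(rbind(lin), sg2))
  expect_equal(d2lin, rep(0, 41), tolerance = 1e-10)
  d2 <- drop(apply_preprocess(rbind(quad), sg2))
  expect_equal(d2, rep(0.5, 41), tolerance = 1e-8)    # analytic 2nd derivative
})

test_that("SNV output rows always standardise and MSC fixes its own reference", {
  set.seed(3)
  X <- matrix(runif(40 * 25), 40, 25)
  S <- apply_preprocess(X, preprocess_spec("snv"))
  expect_equal(rowMeans(S), rep(0, 40), tolerance = 1e-12)
  expect_equal(apply(S, 1, sd), rep(1, 40), tolerance = 1e-12)
  ref <- colMeans(X)
  M <- apply_preprocess(rbind(ref), preprocess_spec("msc", reference = ref))
  expect_equal(drop(M), unname(ref), tolerance = 1e-12)
})

test_that("segmentation finds every seed across increasing noise levels", {
  for (sd_px in c(0, 0.01, 0.03)) {
    sc <- render_scene(8, seed = 90,
                       noise = list(pixel = sd_px, sigma_a = 0.08,
                                    sigma_b = 0.01, tilt = 0.01))
    filt <- median_filter3(calibrate_reflectance(sc$cube, sc$refs))
    expect_equal(nrow(segment_seeds(filt)), 8)
  }
})
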