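# one small trained scene shared across the blocks in this file
sc <- render_scene(12, seed = 201)
tbl_raw <- scene_to_spectra(sc)
tbl0 <- split_calibration_validation(tbl_raw, seed = 202)
model <- train_viability_model(tbl0, max_lv = 5, folds = 4, seed = 203)
filt <- attr(tbl_raw, "cube")
regions <- attr(tbl_raw, "regions")

test_that("pixel-wise prediction equals the per-pixel scoring loop", {
  mask <- attr(regions, "mask")
  img <- predict_pixelwise(model, filt, mask)
  expect_s3_class(img, "chemical_image")
  expect_true(all(is.na(img$prediction[!mask])))
  expect_true(all(is.finite(img$prediction[mask])))
  idx <- which(mask, arr.ind = TRUE)
  take <- idx[seq(1, nrow(idx), length.out = 25), , drop = FALSE]
  for (i in seq_len(nrow(take))) {
    x <- filt$values[take[i, 1], take[i, 2], ]
    xp <- apply_preprocess(rbind(x), model$preprocess)
    expect_equal(img$prediction[take[i, 1], take[i, 2]],
                 predict_scores(model, xp), tolerance = 1e-12)
  }
})

test_that("constant-spectrum masks give constant maps; empty masks give empty maps", {
  cal_row <- spectra_matrix(tbl_raw)[1, ]
  cube <- spectral_cube(
    array(rep(cal_row, each = 36), c(6, 6, length(cal_row))),
    filt$wavelengths, state = "reflectance")
  mask <- matrix(TRUE, 6, 6)
  img <- predict_pixelwise(model, cube, mask)
  s <- predict_scores(model, apply_preprocess(rbind(cal_row), model$preprocess))
  expect_equal(unique(as.vector(img$prediction)), s, tolerance = 1e-12)
  empty <- predict_pixelwise(model, cube, matrix(FALSE, 6, 6))
  expect_true(all(is.na(empty$prediction)))
  expect_equal(empty$anomalies, 0)
})

test_that("degenerate pixel spectra fall to the nonviable floor and are tallied", {
  snv_model <- model
  snv_model$preprocess <- preprocess_spec("snv")
  cube <- spectral_cube(array(0.5, c(4, 4, length(model$coefficients))),
                        filt$wavelengths, state = "reflectance")
  img <- predict_pixelwise(snv_model, cube, matrix(TRUE, 4, 4))
  expect_equal(img$anomalies, 16)
  expect_equal(unique(as.vector(img$prediction)), 0)
})

test_that("binarisation applies the shared strict-inequality tie rule", {
  img <- predict_pixelwise(model, filt, attr(regions, "mask"))
  b_hi <- binarize(img, 0.55)
  expect_true(all(b_hi$binary[!b_hi$mask] == FALSE))
  v <- img$prediction[attr(regions, "mask")][1]
  at <- binarize(img, v)       # threshold exactly at a pixel's value
  px <- which(img$prediction == v, arr.ind = TRUE)[1, ]
  expect_false(at$binary[px[1], px[2]])
  const <- img
  const$prediction[const$mask] <- 0.9
  expect_equal(binarize(const, 0.55)$binary, const$mask)
  const$prediction[const$mask] <- 0.1
  expect_equal(sum(binarize(const, 0.55)$binary), 0)
})

test_that("area opening matches brute-force labelling and never adds pixels", {
  set.seed(23)
  for (i in 1:5) {
    bin <- matrix(runif(40 * 30) < 0.35, 40, 30)
    opened <- area_open(bin, 6)
    lab <- oracle_label4(bin)
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[sizes >= 6])
    expect_equal(opened, matrix(lab %in% keep, 40, 30))
    expect_true(all(opened <= bin))
  }
  two <- matrix(FALSE, 6, 6); two[2, 2:3] <- TRUE
  expect_equal(sum(area_open(two, 5)), 0)
  expect_equal(area_open(two, 1), two)
})

test_that("seed decisions use the >= fraction rule and are monotone in f", {
  mask <- attr(regions, "mask")
  img <- area_open(binarize(predict_pixelwise(model, filt, mask),
                            model$threshold), 20)
  d1 <- seed_decision(img, regions, 0.5)
  expect_equal(nrow(d1), nrow(regions))
  # all/none boundary cases on a crafted map
  full <- img; full$binary <- mask
  expect_true(all(seed_decision(full, regions)$decision == 1))
  none <- img; none$binary <- mask & FALSE
  expect_true(all(seed_decision(none, regions)$decision == 0))
  # exactly f * area viable counts as viable
  r1 <- regions[1, ]
  px <- r1$pixels[[1]]
  half <- img
  half$binary <- mask & FALSE
  k <- ceiling(nrow(px) / 2)
  half$binary[px[seq_len(k), , drop = FALSE]] <- TRUE
  f_exact <- k / nrow(px)
  expect_equal(seed_decision(half, r1, f_exact)$decision, 1L)
  # monotone: raising f never flips 0 -> 1
  fs <- c(0.2, 0.4, 0.6, 0.8, 1)
  dec <- vapply(fs, function(f) seed_decision(img, regions, f)$decision,
                integer(nrow(regions)))
  expect_true(all(apply(dec, 1, function(r) all(diff(r) <= 0))))
  bad <- tibble::tibble(region_id = "X",
                        pixels = list(cbind(line = 10000, pixel = 1)))
  expect_error(seed_decision(img, bad), "outside the map")
})

test_that("pixel-map route and mean-spectrum route agree on noise-free scenes", {
  nf <- render_scene(10, noise = 0, seed = 211)
  tbl_nf <- scene_to_spectra(nf)
  tbl <- split_calibration_validation(tbl_nf, seed = 212)
  m <- train_viability_model(tbl, max_lv = 4, folds = 4, seed = 213)
  filt_nf <- attr(tbl_nf, "cube")
  reg_nf <- attr(tbl_nf, "regions")
  img <- area_open(binarize(predict_pixelwise(m, filt_nf, attr(reg_nf, "mask")),
                            m$threshold), 20)
  pix_dec <- seed_decision(img, reg_nf, 0.5)$decision
  mean_dec <- predict(m, tbl)$predicted
  expect_equal(pix_dec, mean_dec)
})

test_that("render_outputs writes the three maps plus annotations", {
  dir <- withr::local_tempdir()
  mask <- attr(regions, "mask")
  img <- area_open(binarize(predict_pixelwise(model, filt, mask),
                            model$threshold), 20)
  dec <- seed_decision(img, regions)
  ann <- render_outputs(img, regions, dec, file.path(dir, "out"))
  files <- list.files(file.path(dir, "out"))
  expect_setequal(files, c("prediction.png", "binary.png", "overlay.png",
                           "annotations.csv"))
  expect_equal(nrow(ann), nrow(regions))
  p <- png::readPNG(file.path(dir, "out", "prediction.png"))
  expect_equal(dim(p)[1:2], dim(img$prediction))
  # empty scene: files still written, empty annotation layer
  empty_img <- binarize(predict_pixelwise(model, filt,
                                          matrix(FALSE, nrow(mask), ncol(mask))), 0.5)
  ann0 <- render_outputs(empty_img, regions[0, ], dec[0, ], file.path(dir, "empty"))
  expect_equal(nrow(ann0), 0)
  expect_true(file.exists(file.path(dir, "empty", "overlay.png")))
})
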