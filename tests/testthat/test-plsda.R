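test_that("Hotelling screen is calibrated and rejects bad confidence", {
  set.seed(1)
  X <- matrix(rnorm(1000 * 2), 1000, 2)
  hs <- hotelling_screen(X, 0.989)
  # population rate 1.1%; binomial MC error ~0.33% -> allow 3 sigma
  expect_lt(abs(mean(hs$outlier) - 0.011), 3 * sqrt(0.011 * 0.989 / 1000))
  # the column mean has T^2 = 0
  Xm <- rbind(colMeans(X), X)
  hs2 <- hotelling_screen(Xm)
  expect_equal(hs2$t2[1], 0, tolerance = 1e-10)
  expect_false(hs2$outlier[1])
  expect_error(hotelling_screen(X, 1.2), "confidence")
  expect_error(hotelling_screen(X[1:2, ]), "at least 3")
})

test_that("calibration/validation split reproduces the canonical 2:1 layout", {
  # 306 + 306 double-sided spectra = 612 samples over 306 seeds
  tbl <- tibble::tibble(
    seed_id = rep(sprintf("s%03d", 1:306), each = 2),
    side = rep(c("A", "B"), 306),
    variety = "V2",
    label = rep(c(rep(1L, 153), rep(0L, 153)), each = 2),
    split = "unassigned")
  out <- split_calibration_validation(tbl, cal_fraction = 2 / 3, seed = 4)
  expect_equal(sum(out$split == "calibration"), 408)
  expect_equal(sum(out$split == "validation"), 204)
  # both sides of one seed stay together
  per_seed <- out %>% dplyr::distinct(seed_id, split)
  expect_equal(nrow(per_seed), 306)
  # stratification: half viable in each split
  expect_equal(sum(out$label[out$split == "calibration"]), 204)
  # fraction 1 -> empty validation
  all_cal <- split_calibration_validation(tbl, cal_fraction = 1, seed = 4)
  expect_equal(sum(all_cal$split == "validation"), 0)
  # unbalanced input refused under balanced = TRUE
  bad <- tbl
  bad$label[1:2] <- 0L
  expect_error(split_calibration_validation(bad), "downsample")
  expect_silent(split_calibration_validation(bad, balanced = FALSE, seed = 1))
})

test_that("NIPALS agrees with least squares at full rank and fits exactly", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  m <- fit_pls(X, y, n_lv = 8)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(m$coefficients), unname(ols[-1]), tolerance = 1e-6)
  # exact-fit limit: y linear in full-rank X
  yl <- drop(X %*% runif(8)) + 3
  ml <- fit_pls(X, yl, n_lv = 8)
  expect_equal(predict_scores(ml, X), yl, tolerance = 1e-8)
  # deflation diagnostics: explained variance non-decreasing, residual
  # norm non-increasing
  expect_true(all(diff(m$x_var_explained) >= -1e-12))
  expect_true(all(diff(m$x_res_norm) <= 1e-12))
  expect_error(fit_pls(matrix(1, 10, 4), rnorm(10), 2), "zero variance")
})

test_that("NIPALS predictions match an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  X <- matrix(rnorm(40 * 25), 40, 25)
  colnames(X) <- paste0("V", 1:25)
  y <- rnorm(40)
  Xn <- matrix(rnorm(12 * 25), 12, 25)
  colnames(Xn) <- colnames(X)
  for (ncomp in c(2, 5)) {
    m <- fit_pls(X, y, n_lv = ncomp)
    ref <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression", scale = FALSE)
    p_ref <- drop(predict(ref, Xn)$predict[, 1, ncomp])
    expect_equal(unname(predict_scores(m, Xn)), unname(p_ref), tolerance = 1e-6)
  }
})

test_that("score prediction honours centring and the dot-product definition", {
  set.seed(9)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- rbinom(25, 1, 0.5)
  m <- fit_pls(X, y, n_lv = 3)
  # training mean spectrum scores at the training mean response
  expect_equal(predict_scores(m, rbind(colMeans(X))), mean(y), tolerance = 1e-10)
  # duplicates score identically; explicit loop oracle
  Xn <- X[c(3, 3, 7), ]
  sc <- predict_scores(m, Xn)
  expect_equal(sc[1], sc[2])
  loop <- apply(Xn, 1, function(x) sum((x - m$x_center) * m$coefficients) + m$intercept)
  expect_equal(sc, loop, tolerance = 1e-12)
  expect_error(predict_scores(m, Xn[, 1:5]), "band mismatch")
})

test_that("LV selection runs the error curve to its documented tie rule", {
  set.seed(10)
  # noiseless separable: one informative direction
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(y + 0, matrix(rnorm(n * 9, sd = 0.05), n, 9))
  sel <- select_lv(X, y, max_lv = 5, folds = 5, seed = 2)
  expect_equal(nrow(sel$error), 5)
  expect_equal(sel$error$error[sel$n_lv], 0)
  expect_equal(sel$n_lv, min(which(sel$error$error == 0))) # fewest-LV tie rule
  expect_error(select_lv(X, y, max_lv = 5, folds = 100), "folds")
})

test_that("LV selection lands near the generator's intrinsic dimension", {
  # structure: class contrast + multiplicative + additive + tilt ~ 4 dims
  picks <- vapply(1:10, function(i) {
    tbl <- simulate_spectra_table(30, seed = 800 + i)
    X <- apply_preprocess(spectra_matrix(tbl), preprocess_spec("none"))
    select_lv(X, tbl$label, max_lv = 10, folds = 5, seed = i)$n_lv
  }, numeric(1))
  expect_lte(abs(median(picks) - 4), 2)
})

test_that("classification threshold and tie rule behave as documented", {
  expect_equal(classify_scores(0.6, 0.5), 1L)
  expect_equal(classify_scores(0.52, 0.53), 0L)
  expect_equal(classify_scores(0.5, 0.5), 0L)     # tie -> nonviable
  expect_error(classify_scores(0.5, 1.5), "threshold")
})

test_that("threshold shifting reaches purity on the 0.01 grid, monotonically", {
  # perfectly separated -> stays at 0.5
  sep <- shift_threshold(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                         c(0, 0, 0, 1, 1, 1), purity_target = 1)
  expect_equal(sep$threshold, 0.5)
  expect_true(sep$reached)
  # one nonviable at 0.51 forces 0.52
  s <- c(0.1, 0.2, 0.51, 0.7, 0.8, 0.9)
  l <- c(0, 0, 0, 1, 1, 1)
  expect_equal(shift_threshold(s, l, purity_target = 1)$threshold, 0.52)
  # monotone in the purity target over random score sets
  set.seed(12)
  for (i in 1:20) {
    sc <- runif(50)
    lb <- rbinom(50, 1, 0.5)
    ts <- vapply(c(0.5, 0.7, 0.9, 1), function(pt) {
      suppressWarnings(shift_threshold(sc, lb, purity_target = pt)$threshold)
    }, numeric(1))
    expect_true(all(diff(ts) >= 0))
  }
  expect_error(shift_threshold(s, l, purity_target = 0), "purity_target")
  # unreachable target returns the grid maximum with a warning
  expect_warning(
    out <- shift_threshold(rep(0.99, 4), c(0, 0, 1, 1), purity_target = 1),
    "unreachable")
  expect_false(out$reached)
  expect_equal(out$threshold, 0.99)
})

test_that("raising the threshold never increases the false-viable count", {
  set.seed(14)
  sc <- runif(200)
  truth <- rbinom(200, 1, 0.5)
  fv <- vapply(seq(0.5, 0.95, by = 0.05), function(t) {
    ev <- evaluate_classification(classify_scores(sc, t), truth)
    ev$fp
  }, numeric(1))
  expect_true(all(diff(fv) <= 0))
})

test_that("confusion metrics match a hand-counted oracle", {
  set.seed(13)
  est <- rbinom(200, 1, 0.5)
  tr <- rbinom(200, 1, 0.5)
  ev <- evaluate_classification(est, tr)
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in 1:200) {
    if (est[i] == 1 && tr[i] == 1) tp <- tp + 1
    if (est[i] == 1 && tr[i] == 0) fp <- fp + 1
    if (est[i] == 0 && tr[i] == 0) tn <- tn + 1
    if (est[i] == 0 && tr[i] == 1) fn <- fn + 1
  }
  expect_equal(unlist(ev[c("tp", "fp", "tn", "fn")]),
               c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(ev$accuracy, (tp + tn) / 200)
  expect_equal(ev$acc_viable, tp / (tp + fn))
  perfect <- evaluate_classification(tr, tr)
  expect_equal(perfect$acc_viable, 1)
  expect_equal(perfect$fp + perfect$fn, 0)
  none <- evaluate_classification(rep(0, 200), tr)
  expect_equal(none$acc_viable, 0)
  expect_error(evaluate_classification(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("the trained model round-trips through its YAML serialisation", {
  tbl <- small_spectra_table(24, seed = 61)
  tbl <- split_calibration_validation(tbl, seed = 62)
  m <- train_viability_model(tbl, max_lv = 5, folds = 4, seed = 63)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "model.yaml")
  write_model(m, p)
  back <- read_model(p)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$threshold, m$threshold)
  expect_equal(back$preprocess$method, m$preprocess$method)
  pr1 <- predict(m, tbl)
  pr2 <- predict(back, tbl)
  expect_equal(pr1$score, pr2$score)
  # broom-style accessors
  expect_named(glance(m),
               c("n_lv", "threshold", "preprocess", "x_var_explained", "cv_error"))
  expect_equal(nrow(tidy(m)), length(m$coefficients))
})

test_that("the preprocessing comparison report covers every method", {
  tbl <- small_spectra_table(24, seed = 71)
  tbl <- split_calibration_validation(tbl, seed = 72)
  rep <- preprocessing_report(tbl, methods = c("mean_norm", "snv", "sg1"),
                              max_lv = 5, folds = 4, seed = 73)
  expect_equal(rep$preprocessing, c("mean_norm", "snv", "sg1"))
  expect_true(all(rep$val_acc_viable >= 0 & rep$val_acc_viable <= 100))
  expect_true(all(rep$threshold >= 0.5))
})
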