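test_that("the polynomial schedule hits its anchor points", {
  expect_equal(poly_lr(0, 1000), 0.01)
  expect_equal(poly_lr(1000, 1000), 0)
  # closed form at the midpoint: 0.01 * 0.5^0.9
  expect_equal(poly_lr(500, 1000), 0.01 * 2^-0.9, tolerance = 1e-12)
  lrs <- poly_lr(0:100, 100)
  expect_true(all(diff(lrs) <= 0))
  expect_error(poly_lr(101, 100), "total_iter")
})

test_that("intensity normalization maps the range onto [0, 1]", {
  v <- array(c(2, 6, 10, 4), c(1, 2, 2))
  nv <- normalize_intensity(v)
  expect_equal(nv[1, 2, 1], 0.5)
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 1)
  set.seed(600)
  r <- array(rnorm(24, sd = 7), c(2, 3, 4))
  expect_equal(normalize_intensity(normalize_intensity(r)),
               normalize_intensity(r), tolerance = 1e-12)
  expect_warning(cv <- normalize_intensity(array(3, c(2, 2, 2))),
                 "constant")
  expect_true(all(cv == 0.5))
  expect_error(normalize_intensity(array(c(1, Inf), c(1, 1, 2))),
               "non-finite")
})

test_that("stratified folds balance classes and partition the data", {
  labels <- rep(0:2, each = 20)
  f <- stratified_kfold(labels, 5, seed = 2)
  expect_equal(unname(table(f$fold)), rep(12L, 5), ignore_attr = TRUE)
  per <- table(f$label, f$fold)
  expect_true(all(per == 4))
  expect_setequal(f$index, seq_along(labels))
  expect_identical(f, stratified_kfold(labels, 5, seed = 2))
  expect_false(identical(f$fold, stratified_kfold(labels, 5, seed = 3)$fold))
  expect_error(stratified_kfold(c(0, 0, 1), 2, 1), "fewer than")
})

test_that("training is seed-deterministic and logs the polynomial schedule", {
  ds <- tiny_dataset(n = 8, seed = 10)
  cfg <- fast_config(seed = 4)
  a <- train_model(ds, cfg)
  b <- train_model(ds, cfg)
  expect_lte(abs(a$final_loss - b$final_loss), 1e-6)
  expect_identical(a$trace$loss, b$trace$loss)
  expect_identical(a$params, b$params)
  total <- nrow(a$trace)
  expect_equal(a$trace$lr,
               poly_lr(0:(total - 1), total, cfg$initial_lr, cfg$power))
})

test_that("disabling weight decay changes the loss trace", {
  ds <- tiny_dataset(n = 8, seed = 10)
  with_wd <- train_model(ds, fast_config(seed = 4, weight_decay = 5e-2))
  without <- train_model(ds, fast_config(seed = 4, weight_decay = 0))
  expect_false(isTRUE(all.equal(with_wd$trace$loss, without$trace$loss)))
})

test_that("every fusion variant trains and emits K-class probabilities", {
  ds <- tiny_dataset(n = 8, K = 2, seed = 12)
  for (v in c("proposed", "early", "intermediate", "late",
              "image_only", "ehr_only")) {
    fit <- train_model(ds, fast_config(seed = 5, fusion_variant = v,
                                       epochs = 1L))
    pred <- predict_sample(fit, ds$volume[[1]], ehr_matrix(ds)[1, ])
    expect_length(pred$probs, 2)
    expect_lte(abs(sum(pred$probs) - 1), 1e-6)
  }
  expect_error(build_fusion_variant("mystery", ds, fast_config()),
               "unknown fusion variant")
})

test_that("the record-only model is blind to the volume and vice versa", {
  ds <- tiny_dataset(n = 8, K = 2, seed = 13)
  cfg <- fast_config(seed = 6, epochs = 1L)
  ehr_fit <- train_model(ds, cfg, build_fusion_variant("ehr_only", ds, cfg))
  g <- input_gradient(ehr_fit, ds$volume[[1]], ehr_matrix(ds)[1, ])
  expect_true(all(g$dvolume == 0))
  expect_gt(max(abs(g$dehr)), 0)

  img_fit <- train_model(ds, cfg, build_fusion_variant("image_only", ds, cfg))
  x1 <- ehr_matrix(ds)[1, ]
  p1 <- predict_sample(img_fit, ds$volume[[1]], x1)
  p2 <- predict_sample(img_fit, ds$volume[[1]], rev(x1))
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
  gi <- input_gradient(img_fit, ds$volume[[1]], x1)
  expect_true(all(gi$dehr == 0))
})

test_that("the ablation grid yields one cross-validated row per setting", {
  ds <- tiny_dataset(n = 12, K = 2, seed = 14)
  grid <- tidyr::crossing(SAM = c(FALSE, TRUE), TAM = FALSE, CAM = FALSE)
  tab <- run_ablation(ds, grid, fast_config(seed = 7, epochs = 1L))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("SAM", "TAM", "CAM", "accuracy_mean",
                    "accuracy_sd") %in% names(tab)))
  expect_true(all(tab$accuracy_mean >= 0 & tab$accuracy_mean <= 1))
})

test_that("the head sweep evaluates valid counts and skips invalid ones", {
  ds <- tiny_dataset(n = 12, K = 2, seed = 15)
  cfg <- fast_config(seed = 8, epochs = 1L, channels = 6L, n_heads = 1L)
  tab <- head_sweep(ds, c(1, 4, 6), cfg)
  expect_equal(tab$skipped, c(FALSE, TRUE, FALSE))
  expect_match(tab$reason[2], "not divisible")
  ok <- dplyr::filter(tab, !skipped)
  expect_true(all(ok$accuracy_mean >= 0 & ok$accuracy_mean <= 1))
  tab2 <- head_sweep(ds, c(1, 4, 6), cfg)
  expect_identical(tab, tab2)
})

test_that("divergence aborts with a diagnostic instead of silent NaNs", {
  ds <- tiny_dataset(n = 8, K = 2, seed = 16)
  expect_error(train_model(ds, fast_config(seed = 9, initial_lr = 1e4)),
               "diverged")
})

test_that("invalid training configurations are rejected early", {
  expect_error(train_config(initial_lr = 0), "positive")
  expect_error(train_config(n_folds = 1), "at least 2")
  expect_error(train_config(fusion_variant = "hologram"))
})
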