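test_that("labels are balanced within one for any n and K", {
  ds <- generate_dataset(synth_config(n_samples = 60, n_classes = 3,
                                      volume_shape = c(4, 8, 8),
                                      n_ehr_features = 4, seed = 3,
                                      signal_mode = "image_only"))
  expect_equal(unname(table(ds$label)), rep(20L, 3), ignore_attr = TRUE)
  for (case in list(c(11, 2), c(25, 4), c(9, 3))) {
    for (mode in c("image_only", "ehr_only", "fusion_xor")) {
      d <- generate_dataset(synth_config(
        n_samples = case[1], n_classes = case[2],
        volume_shape = c(4, 6, 6), n_ehr_features = 3,
        signal_mode = mode, seed = 1))
      counts <- table(factor(d$label, levels = 0:(case[2] - 1)))
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("identical configurations reproduce identical datasets", {
  cfg <- synth_config(n_samples = 10, volume_shape = c(4, 8, 8),
                      n_ehr_features = 6, seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$volume, b$volume)
  expect_identical(ehr_matrix(a), ehr_matrix(b))
  expect_identical(a$label, b$label)
})

test_that("all voxels lie in [0, 1] and records are complete", {
  for (mode in c("image_only", "ehr_only", "fusion_xor")) {
    ds <- generate_dataset(synth_config(
      n_samples = 8, volume_shape = c(4, 8, 8), n_ehr_features = 5,
      signal_mode = mode, noise_sd = 0.4, seed = 2))
    rng <- range(unlist(ds$volume))
    expect_gte(rng[1], 0)
    expect_lte(rng[2], 1)
    expect_false(anyNA(ehr_matrix(ds)))
    expect_false(anyNA(ds$label))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(volume_shape = c(0, 8, 8)), "positive")
  expect_error(synth_config(n_classes = 1), "at least 2")
  expect_error(synth_config(n_samples = 1, n_classes = 2), "at least")
  expect_error(synth_config(signal_mode = "telepathy"))
  expect_error(synth_config(noise_sd = -1), ">= 0")
})

test_that("fusion mode hides the label from the image digit alone", {
  ds <- generate_dataset(synth_config(n_samples = 1000, noise_sd = 0,
                                      volume_shape = c(4, 8, 8),
                                      n_ehr_features = 5, seed = 7))
  # plug-in mutual information from the label x image-digit contingency table
  tab <- table(ds$label, ds$bit_image) / nrow(ds)
  px <- rowSums(tab); py <- colSums(tab)
  mi <- sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
  expect_lt(mi, 0.01)
})

test_that("a logistic model on the records alone stays at chance in fusion mode", {
  ds <- generate_dataset(synth_config(n_samples = 1000, seed = 5,
                                      volume_shape = c(4, 8, 8),
                                      n_ehr_features = 6))
  X <- ehr_matrix(ds)
  tr <- 1:500; te <- 501:1000
  fit <- suppressWarnings(
    glm.fit(cbind(1, X[tr, ]), ds$label[tr], family = binomial()))
  pred <- as.integer(cbind(1, X[te, ]) %*% fit$coefficients > 0)
  acc <- mean(pred == ds$label[te])
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / length(te)))
})

test_that("datasets roundtrip through NIfTI + CSV within float tolerance", {
  ds <- generate_dataset(synth_config(n_samples = 10, seed = 4,
                                      volume_shape = c(4, 6, 6),
                                      n_ehr_features = 4))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$subject_id, ds$subject_id)
  expect_identical(back$label, ds$label)
  expect_equal(ehr_matrix(back), ehr_matrix(ds))
  dv <- max(abs(unlist(back$volume) - unlist(ds$volume)))
  expect_lte(dv, 1e-6)
})

test_that("corrupt dataset directories are rejected", {
  ds <- generate_dataset(synth_config(n_samples = 4, seed = 4,
                                      volume_shape = c(4, 6, 6),
                                      n_ehr_features = 3))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  # duplicated subject id in the CSV
  ehr <- readr::read_csv(file.path(dir, "ehr.csv"), show_col_types = FALSE)
  ehr$subject_id[2] <- ehr$subject_id[1]
  readr::write_csv(ehr, file.path(dir, "ehr.csv"))
  expect_error(read_dataset(dir), "duplicated")
  # empty directory is an error, not an empty dataset
  expect_error(read_dataset(withr::local_tempdir()), "manifest")
  # duplicated ids refuse to write at all
  ds2 <- ds
  ds2$subject_id[2] <- ds2$subject_id[1]
  expect_error(write_dataset(ds2, withr::local_tempdir()), "duplicated")
})
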