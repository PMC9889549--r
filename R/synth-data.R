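#' Configuration for the paired volume + clinical-record simulator
#'
#' Describes a synthetic cohort of subjects, each carrying a 3D image volume
#' (a desk-scale stand-in for a T1-weighted MRI) and a numeric clinical
#' feature vector (an EHR-style record), together with a class label. The
#' class signal can be planted in the image alone, in the clinical record
#' alone, or split across both so that only a model that fuses the two
#' modalities can recover it.
#'
#' @param n_samples Number of subjects. Labels are assigned round-robin, so
#'   class counts are balanced within one.
#' @param n_classes Number of disease-risk classes `K` (at least 2).
#' @param volume_shape Integer vector `(D, H, W)`: slices, height, width.
#' @param n_ehr_features Number of clinical features `F`. The default of 17
#'   mirrors a typical diabetes-cohort record (demographics, labs,
#'   cognitive-test scores).
#' @param signal_mode One of `"image_only"`, `"ehr_only"`, `"fusion_xor"`.
#'   In `image_only` the label is encoded by the intensity of a planted
#'   hyperintense blob; in `ehr_only` by a linear shift of the clinical
#'   features; in `fusion_xor` by a modular (XOR-style) combination of one
#'   image-borne digit (blob location) and one record-borne digit, so that
#'   neither modality alone carries label information.
#' @param signal_strength Dimensionless effect size (>= 0) separating the
#'   class-conditional distributions.
#' @param noise_sd Standard deviation of the additive Gaussian voxel noise.
#' @param seed Integer seed; the same configuration always yields the same
#'   dataset.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_samples = 300L,
                         n_classes = 2L,
                         volume_shape = c(8L, 16L, 16L),
                         n_ehr_features = 17L,
                         signal_mode = c("fusion_xor", "image_only", "ehr_only"),
                         signal_strength = 3,
                         noise_sd = 0.05,
                         seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  volume_shape <- as.integer(volume_shape)
  n_ehr_features <- as.integer(n_ehr_features)
  if (length(volume_shape) != 3L || any(volume_shape <= 0L)) {
    stop("volume_shape must be three positive integers (D, H, W)", call. = FALSE)
  }
  if (n_classes < 2L) stop("n_classes must be at least 2", call. = FALSE)
  if (n_samples < n_classes) {
    stop("n_samples must be at least n_classes", call. = FALSE)
  }
  if (n_ehr_features < 1L) stop("n_ehr_features must be >= 1", call. = FALSE)
  if (signal_strength < 0) stop("signal_strength must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(n_samples = n_samples, n_classes = n_classes,
         volume_shape = volume_shape, n_ehr_features = n_ehr_features,
         signal_mode = signal_mode, signal_strength = signal_strength,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# squared distance of every voxel to a centre, on the (D, H, W) grid
blob_r2 <- function(shape, centre) {
  d <- (seq_len(shape[1]) - centre[1])^2
  h <- (seq_len(shape[2]) - centre[2])^2
  w <- (seq_len(shape[3]) - centre[3])^2
  outer(outer(d, h, `+`), w, `+`)
}

#' Generate a paired volume + clinical-record dataset
#'
#' Produces one row per subject: the volume as a list-column of `(D, H, W)`
#' arrays with voxels in `[0, 1]`, clinical features `f1..fF`, the class
#' label, and the ground-truth latent digits (`bit_image`, `bit_ehr`) and
#' blob geometry used to plant the signal. The latents are simulation
#' ground truth for evaluation only; models never see them.
#'
#' Volumes consist of a dim background, a Gaussian hyperintense blob whose
#' intensity (`image_only`) or location (`fusion_xor`) carries the signal,
#' and additive Gaussian noise, clipped to `[0, 1]`. Clinical features are
#' standard normal with a class-dependent mean shift on the first few
#' features when the record carries signal.
#'
#' @param config A [synth_config()].
#' @return A tibble of class `paired_dataset` with the configuration stored
#'   in `attr(, "config")`.
#' @export
#' @examples
#' ds <- generate_dataset(synth_config(n_samples = 12, seed = 7))
#' dplyr::count(ds, label)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  K <- config$n_classes
  shape <- config$volume_shape
  Fn <- config$n_ehr_features
  s <- config$signal_strength
  labels <- (seq_len(n) - 1L) %% K

  withr::with_seed(config$seed, {
    sigma <- max(1, min(shape) / 3)
    contrast <- min(1, s / 3)
    # unit direction carrying the record-borne signal (first <=3 features)
    ndir <- min(3L, Fn)
    u <- c(rep(1 / sqrt(ndir), ndir), rep(0, Fn - ndir))

    vols <- vector("list", n)
    ehr <- matrix(stats::rnorm(n * Fn), n, Fn)
    bit_image <- rep(NA_integer_, n)
    bit_ehr <- rep(NA_integer_, n)
    centres <- matrix(0, n, 3)

    rand_centre <- function() {
      m <- pmax(1.5, sigma)
      c(stats::runif(1, m, shape[1] - m + 1),
        stats::runif(1, m, shape[2] - m + 1),
        stats::runif(1, m, shape[3] - m + 1))
    }

    for (i in seq_len(n)) {
      k <- labels[i]
      if (config$signal_mode == "image_only") {
        amp <- 0.25 + 0.55 * contrast * k / max(K - 1L, 1L)
        centre <- rand_centre()
        bit_image[i] <- k
      } else if (config$signal_mode == "ehr_only") {
        amp <- 0.5
        centre <- rand_centre()
        delta <- 2 * s * (k / max(K - 1L, 1L) - 0.5)
        ehr[i, ] <- ehr[i, ] + delta * u
        bit_ehr[i] <- k
      } else { # fusion_xor: label = (image digit + record digit) mod K
        d_img <- sample.int(K, 1L) - 1L
        d_ehr <- (k - d_img) %% K
        # the image digit is coded by blob intensity (feature content, not
        # location): attention pooling is permutation-invariant over
        # positions, so content is what a fused encoder can exchange
        amp <- 0.25 + 0.55 * contrast * d_img / max(K - 1L, 1L)
        centre <- rand_centre()
        delta <- 2 * s * (d_ehr / max(K - 1L, 1L) - 0.5)
        ehr[i, ] <- ehr[i, ] + delta * u
        bit_image[i] <- d_img
        bit_ehr[i] <- d_ehr
      }
      centres[i, ] <- centre
      vol <- 0.15 + amp * exp(-blob_r2(shape, centre) / (2 * sigma^2))
      if (config$noise_sd > 0) {
        vol <- vol + stats::rnorm(length(vol), sd = config$noise_sd)
      }
      vols[[i]] <- array(pmin(pmax(vol, 0), 1), shape)
    }

    colnames(ehr) <- paste0("f", seq_len(Fn))
    ds <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      label = as.integer(labels),
      volume = vols
    )
    ds <- dplyr::bind_cols(ds, tibble::as_tibble(ehr))
    ds$bit_image <- bit_image
    ds$bit_ehr <- bit_ehr
    ds$blob_d <- centres[, 1]; ds$blob_h <- centres[, 2]; ds$blob_w <- centres[, 3]
    ds$blob_sigma <- sigma
    attr(ds, "config") <- config
    class(ds) <- c("paired_dataset", class(ds))
    ds
  })
}

#' Extract the clinical feature matrix of a dataset
#' @param dataset A `paired_dataset`.
#' @return Numeric matrix (n subjects x F features).
#' @export
ehr_matrix <- function(dataset) {
  cols <- grep("^f[0-9]+$", names(dataset), value = TRUE)
  as.matrix(dataset[, cols])
}

#' Voxel mask of the planted blob of one subject
#' @param dataset A `paired_dataset`.
#' @param i Row index of the subject.
#' @param radius_factor Mask radius in units of the blob sigma.
#' @return Logical `(D, H, W)` array.
#' @export
blob_mask <- function(dataset, i, radius_factor = 1.5) {
  shape <- dim(dataset$volume[[i]])
  centre <- c(dataset$blob_d[i], dataset$blob_h[i], dataset$blob_w[i])
  blob_r2(shape, centre) <= (radius_factor * dataset$blob_sigma[i])^2
}

#' Write a paired dataset to disk
#'
#' Volumes go to one gzipped NIfTI file per subject, clinical features and
#' labels to `ehr.csv` (`subject_id,label,f1..fF`), simulation latents to
#' `latents.csv`, and a JSON manifest records the files and configuration.
#'
#' @param dataset A `paired_dataset`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, directory) {
  if (anyDuplicated(dataset$subject_id)) {
    stop("duplicated subject ids in dataset", call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- paste0("vol_", dataset$subject_id, ".nii.gz")
  for (i in seq_len(nrow(dataset))) {
    RNifti::writeNifti(dataset$volume[[i]], file.path(directory, files[i]))
  }
  ehr <- dplyr::select(tibble::as_tibble(dataset), "subject_id", "label",
                       dplyr::matches("^f[0-9]+$"))
  readr::write_csv(ehr, file.path(directory, "ehr.csv"))
  latents <- dplyr::select(tibble::as_tibble(dataset), "subject_id",
                           "bit_image", "bit_ehr", "blob_d", "blob_h",
                           "blob_w", "blob_sigma")
  readr::write_csv(latents, file.path(directory, "latents.csv"))
  cfg <- attr(dataset, "config")
  manifest <- list(
    n_samples = nrow(dataset),
    volume_shape = dim(dataset$volume[[1]]),
    volume_files = files,
    ehr_csv = "ehr.csv",
    latents_csv = "latents.csv",
    config = if (!is.null(cfg)) unclass(cfg)
  )
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a paired dataset written by [write_dataset()]
#' @param directory Directory holding `manifest.json`.
#' @return A `paired_dataset` tibble.
#' @export
read_dataset <- function(directory) {
  path <- file.path(directory, "manifest.json")
  if (!file.exists(path)) {
    stop("no manifest.json in ", directory, " (not a dataset directory)",
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  ehr <- readr::read_csv(file.path(directory, manifest$ehr_csv),
                         show_col_types = FALSE)
  if (anyDuplicated(ehr$subject_id)) {
    stop("duplicated subject ids in ", manifest$ehr_csv, call. = FALSE)
  }
  if (length(manifest$volume_files) != nrow(ehr)) {
    stop("manifest lists ", length(manifest$volume_files),
         " volumes but ehr.csv has ", nrow(ehr), " subjects", call. = FALSE)
  }
  shape <- as.integer(manifest$volume_shape)
  vols <- vector("list", nrow(ehr))
  for (i in seq_along(manifest$volume_files)) {
    f <- file.path(directory, manifest$volume_files[i])
    if (!file.exists(f)) stop("missing volume file: ", f, call. = FALSE)
    v <- as.array(RNifti::readNifti(f))
    if (!identical(dim(v), shape)) {
      stop("volume ", basename(f), " has shape ",
           paste(dim(v), collapse = "x"), ", manifest says ",
           paste(shape, collapse = "x"), call. = FALSE)
    }
    vols[[i]] <- array(as.numeric(v), shape)
  }
  ds <- tibble::as_tibble(ehr)
  ds$label <- as.integer(ds$label)
  ds <- dplyr::relocate(ds, "subject_id", "label")
  ds$volume <- vols
  ds <- dplyr::relocate(ds, "volume", .after = "label")
  lat_path <- file.path(directory, manifest$latents_csv %||% "latents.csv")
  if (file.exists(lat_path)) {
    lat <- readr::read_csv(lat_path, show_col_types = FALSE)
    ds <- dplyr::left_join(ds, lat, by = "subject_id")
  }
  if (!is.null(manifest$config)) {
    cfg <- manifest$config
    attr(ds, "config") <- structure(
      list(n_samples = as.integer(cfg$n_samples),
           n_classes = as.integer(cfg$n_classes),
           volume_shape = as.integer(cfg$volume_shape),
           n_ehr_features = as.integer(cfg$n_ehr_features),
           signal_mode = cfg$signal_mode,
           signal_strength = cfg$signal_strength,
           noise_sd = cfg$noise_sd, seed = as.integer(cfg$seed)),
      class = "synth_config")
  }
  class(ds) <- c("paired_dataset", class(ds))
  ds
}
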