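# Training engine: SGD with momentum and L2 weight decay, polynomial
# learning-rate decay anchored on the total optimizer-step count,
# stratified k-fold cross-validation, and the experiment drivers
# (ablation grid, head-number sweep, fusion-variant comparison).

#' Training configuration
#'
#' Defaults follow the optimization protocol of the framework (initial
#' learning rate 0.01 with polynomial decay of power 0.9, momentum 0.9,
#' weight decay 1e-4, 5-fold cross-validation) at desk scale: batch size 8
#' and 20 epochs suit the small synthetic volumes used throughout; see
#' [paper_scale_config()] for the GPU-scale profile (batch 32, 100
#' epochs).
#'
#' @param initial_lr Initial learning rate.
#' @param power Exponent of the polynomial decay.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty applied inside the optimizer step.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param n_folds Cross-validation folds (>= 2).
#' @param seed Master seed: fold splits, initialization and batch order all
#'   derive from it.
#' @param component_flags Named list of booleans `SAM`, `TAM`, `CAM`
#'   activating the spatial, temporal and cross-attention blocks; an
#'   inactive block is an identity pass-through.
#' @param n_heads Decoder attention heads; must divide `channels`.
#' @param fusion_variant One of `"proposed"`, `"early"`, `"intermediate"`,
#'   `"late"`, `"image_only"`, `"ehr_only"`.
#' @param channels Backbone output channels `C`.
#' @param backbone_name Registered backbone architecture.
#' @param scaled_attention Use `1/sqrt(C)` logit scaling in the intra-modal
#'   blocks (off by default; raw inner-product logits).
#' @param cross_mode Cross-attention candidate set (see [affinity()]).
#' @param max_steps Optional cap on total optimizer steps; when set it also
#'   anchors the polynomial decay.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 0.01, power = 0.9, momentum = 0.9,
                         weight_decay = 1e-4, batch_size = 8L, epochs = 20L,
                         n_folds = 5L, seed = 1L,
                         component_flags = list(SAM = TRUE, TAM = TRUE,
                                                CAM = TRUE),
                         n_heads = 6L, fusion_variant = "proposed",
                         channels = 12L, backbone_name = "tiny_cnn",
                         scaled_attention = FALSE,
                         cross_mode = "exclude_self", max_steps = NULL) {
  if (initial_lr <= 0 || power <= 0 || momentum < 0 || weight_decay < 0) {
    stop("rates must be positive (momentum/weight decay nonnegative)",
         call. = FALSE)
  }
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  fusion_variant <- match.arg(fusion_variant, fusion_variants())
  structure(list(
    initial_lr = initial_lr, power = power, momentum = momentum,
    weight_decay = weight_decay, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), n_folds = as.integer(n_folds),
    seed = as.integer(seed), component_flags = component_flags,
    n_heads = as.integer(n_heads), fusion_variant = fusion_variant,
    channels = as.integer(channels), backbone_name = backbone_name,
    scaled_attention = scaled_attention, cross_mode = cross_mode,
    max_steps = if (!is.null(max_steps)) as.integer(max_steps)
  ), class = "train_config")
}

#' GPU-scale training profile
#'
#' The full-scale protocol (batch size 32, 100 epochs, 256 x 256 x 170
#' volumes) used for real MRI cohorts. Documented for completeness; it is
#' far beyond a desk CPU and not exercised by the package tests.
#'
#' @param ... Overrides forwarded to [train_config()].
#' @export
paper_scale_config <- function(...) {
  train_config(batch_size = 32L, epochs = 100L, ...)
}

#' Polynomial learning-rate decay
#'
#' `initial_lr * (1 - iter/total_iter)^power`: monotone non-increasing from
#' `initial_lr` at step 0 to exactly 0 at the final step.
#'
#' @param iter Optimizer step, `0 <= iter <= total_iter`.
#' @param total_iter Total number of optimizer steps.
#' @param initial_lr Initial learning rate.
#' @param power Decay exponent.
#' @return Learning rate.
#' @export
poly_lr <- function(iter, total_iter, initial_lr = 0.01, power = 0.9) {
  if (any(iter < 0) || any(iter > total_iter)) {
    stop("iter must lie in [0, total_iter]", call. = FALSE)
  }
  initial_lr * (1 - iter / total_iter)^power
}

#' Min-max normalize a volume to [0, 1]
#'
#' Maps the minimum to 0 and maximum to 1. A constant volume has no
#' dynamic range and maps to 0.5 everywhere, with a warning.
#'
#' @param volume Finite numeric array.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(volume) {
  if (!all(is.finite(volume))) {
    stop("volume contains non-finite values", call. = FALSE)
  }
  lo <- min(volume); hi <- max(volume)
  if (hi == lo) {
    warning("constant volume: no dynamic range, mapping to 0.5",
            call. = FALSE)
    return(array(0.5, dim(volume)))
  }
  (volume - lo) / (hi - lo)
}

#' Stratified k-fold assignment
#'
#' Shuffles within each class and deals members to folds round-robin, so
#' per-class counts differ by at most one across folds.
#'
#' @param labels Integer class labels.
#' @param n_folds Number of folds.
#' @param seed Seed; identical seeds give identical assignments.
#' @return Tibble with `index`, `label`, `fold` (folds `1..n_folds`).
#' @export
stratified_kfold <- function(labels, n_folds, seed = 1L) {
  tab <- table(labels)
  if (any(tab < n_folds)) {
    small <- names(tab)[tab < n_folds]
    stop("class(es) ", paste(small, collapse = ", "), " have fewer than ",
         n_folds, " members", call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (k in unique(labels)) {
      idx <- which(labels == k)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  tibble::tibble(index = seq_along(labels), label = as.integer(labels),
                 fold = fold)
}

model_cfg_from <- function(dataset, config) {
  K <- length(unique(dataset$label))
  model_config(
    K = K, n_ehr = ncol(ehr_matrix(dataset)),
    volume_shape = dim(dataset$volume[[1]]),
    channels = config$channels, n_heads = config$n_heads,
    flags = config$component_flags, variant = config$fusion_variant,
    backbone_name = config$backbone_name,
    scaled_attention = config$scaled_attention,
    cross_mode = config$cross_mode, seed = config$seed
  )
}

#' Build an untrained model of a named fusion variant
#'
#' All variants share the volumetric backbone and (where applicable) the
#' record embedding; they differ in where the two modalities meet: at the
#' input (`early`, pooled image feature concatenated with the record), at
#' the feature level (`intermediate`, per-modality linear maps summed), or
#' before the classifier (`late`, single-head attention over the stacked
#' modality representations). `image_only`/`ehr_only` drop one branch
#' entirely, and `proposed` is the full attention-fusion framework.
#'
#' @param name Variant name.
#' @param dataset A `paired_dataset` (supplies shapes and class count).
#' @param config A [train_config()].
#' @return An untrained `risk_model`.
#' @export
build_fusion_variant <- function(name, dataset, config = train_config()) {
  if (!name %in% fusion_variants()) {
    stop("unknown fusion variant '", name, "'; registered: ",
         paste(fusion_variants(), collapse = ", "), call. = FALSE)
  }
  config$fusion_variant <- name
  cfg <- model_cfg_from(dataset, config)
  ini <- init_model_params(cfg)
  X <- ehr_matrix(dataset)
  scaler <- list(mean = colMeans(X), sd = pmax(apply(X, 2, stats::sd), 1e-8))
  structure(list(params = ini$params, cfg = cfg, bb = ini$bb,
                 scaler = scaler, config = config,
                 trace = tibble::tibble(), trained = FALSE),
            class = "risk_model")
}

#' Train a risk model
#'
#' Minibatch SGD with momentum, L2 weight decay applied inside the
#' optimizer step, and polynomial learning-rate decay over the total step
#' count. Fully deterministic given the configuration seed: fold-free
#' training on the supplied dataset with seeded initialization and batch
#' order.
#'
#' @param dataset A `paired_dataset` (the training split).
#' @param config A [train_config()].
#' @param model Optional pre-built (untrained) model from
#'   [build_fusion_variant()]; by default one is built from `config`.
#' @return A fitted `risk_model` with a per-iteration `trace` tibble
#'   (`iter`, `epoch`, `lr`, `loss`).
#' @export
train_model <- function(dataset, config = train_config(), model = NULL) {
  if (is.null(model)) {
    model <- build_fusion_variant(config$fusion_variant, dataset, config)
  }
  params <- model$params
  cfg <- model$cfg
  bb <- model$bb
  n <- nrow(dataset)
  X <- ehr_matrix(dataset)
  Xs <- sweep(sweep(X, 2, model$scaler$mean), 2, model$scaler$sd, `/`)
  labels <- dataset$label
  K <- cfg$K
  bsz <- min(config$batch_size, n)
  steps_per_epoch <- ceiling(n / bsz)
  total_iter <- config$max_steps %||% (config$epochs * steps_per_epoch)
  vel <- plist_zeros_like(params)
  trace <- vector("list", total_iter)

  withr::with_seed(config$seed + 1000L, {
    iter <- 0L
    epoch <- 0L
    done <- FALSE
    while (!done) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1L) * bsz + 1L):min(b * bsz, n)]
        lr <- poly_lr(iter, total_iter, config$initial_lr, config$power)
        G <- NULL
        loss <- 0
        for (i in idx) {
          fw <- model_fw(dataset$volume[[i]], Xs[i, ], params, cfg, bb)
          li <- -log(max(fw$probs[labels[i] + 1L], 1e-12))
          loss <- loss + li
          dlogits <- fw$probs
          dlogits[labels[i] + 1L] <- dlogits[labels[i] + 1L] - 1
          bw <- model_bw(dlogits, fw, params, cfg, bb)
          G <- if (is.null(G)) bw$grads else plist_axpy(G, bw$grads)
        }
        loss <- loss / length(idx)
        if (!is.finite(loss)) {
          stop("training diverged at iter ", iter, " (loss = ", loss,
               "); reduce the learning rate", call. = FALSE)
        }
        G <- plist_scale(G, 1 / length(idx))
        for (nm in names(params)) {
          g <- G[[nm]] + config$weight_decay * params[[nm]]
          vel[[nm]] <- config$momentum * vel[[nm]] - lr * g
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        iter <- iter + 1L
        trace[[iter]] <- c(iter = iter, epoch = epoch, lr = lr, loss = loss)
        if (iter >= total_iter) { done <- TRUE; break }
      }
    }
  })

  model$params <- params
  model$trace <- tibble::as_tibble(do.call(rbind, trace))
  model$trained <- TRUE
  model$final_loss <- model$trace$loss[nrow(model$trace)]
  model
}

#' Stratified cross-validation of one configuration
#'
#' Splits the dataset with [stratified_kfold()], trains on each training
#' split and evaluates on the held-out fold.
#'
#' @param dataset A `paired_dataset`.
#' @param config A [train_config()].
#' @return A `cv_result`: list with `folds` (per-fold metrics tibble) and
#'   `report` (a `metrics_report`).
#' @export
cross_validate <- function(dataset, config = train_config()) {
  folds <- stratified_kfold(dataset$label, config$n_folds, config$seed)
  per_fold <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- dataset[folds$fold != f, ]
    te <- dataset[folds$fold == f, ]
    fit <- train_model(tr, config)
    per_fold[[f]] <- dplyr::mutate(evaluate_fold(fit, te), fold = f,
                                   .before = 1)
  }
  folds_tbl <- dplyr::bind_rows(per_fold)
  structure(list(folds = folds_tbl, report = aggregate_folds(folds_tbl),
                 config = config),
            class = "cv_result")
}

#' Ablation over the attention components
#'
#' Cross-validates every requested SAM/TAM/CAM combination (all eight by
#' default; the all-off row is the multi-head-attention-only baseline) and
#' reports mean +/- std metrics per row.
#'
#' @param dataset A `paired_dataset`.
#' @param flag_grid Data frame with logical columns `SAM`, `TAM`, `CAM`;
#'   default: the full 2^3 grid.
#' @param config A [train_config()].
#' @return An `ablation_result` tibble: one row per combination with
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
run_ablation <- function(dataset, flag_grid = NULL,
                         config = train_config()) {
  if (is.null(flag_grid)) {
    flag_grid <- tidyr::crossing(SAM = c(FALSE, TRUE), TAM = c(FALSE, TRUE),
                                 CAM = c(FALSE, TRUE))
  }
  rows <- vector("list", nrow(flag_grid))
  for (r in seq_len(nrow(flag_grid))) {
    cfgr <- config
    cfgr$component_flags <- list(SAM = flag_grid$SAM[r],
                                 TAM = flag_grid$TAM[r],
                                 CAM = flag_grid$CAM[r])
    cv <- cross_validate(dataset, cfgr)
    rep <- cv$report
    wide <- stats::setNames(
      c(rep$mean, rep$sd),
      c(paste0(rep$metric, "_mean"), paste0(rep$metric, "_sd"))
    )
    rows[[r]] <- dplyr::bind_cols(flag_grid[r, ],
                                  tibble::as_tibble_row(wide))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ablation_result", class(out)))
}

#' Accuracy as a function of decoder head count
#'
#' Cross-validates the configuration at each head number; counts that do
#' not divide the channel dimension are reported as skipped rather than
#' evaluated.
#'
#' @param dataset A `paired_dataset`.
#' @param head_numbers Integer vector of head counts (default 1..12).
#' @param config A [train_config()].
#' @return A `head_sweep_result` tibble with `n_heads`, `accuracy_mean`,
#'   `accuracy_sd`, `skipped`, `reason`.
#' @export
head_sweep <- function(dataset, head_numbers = 1:12,
                       config = train_config()) {
  rows <- lapply(head_numbers, function(h) {
    if (config$channels %% h != 0L) {
      return(tibble::tibble(n_heads = h, accuracy_mean = NA_real_,
                            accuracy_sd = NA_real_, skipped = TRUE,
                            reason = sprintf("C = %d not divisible by %d",
                                             config$channels, h)))
    }
    cfgr <- config
    cfgr$n_heads <- as.integer(h)
    cv <- cross_validate(dataset, cfgr)
    acc <- cv$report[cv$report$metric == "accuracy", ]
    tibble::tibble(n_heads = h, accuracy_mean = acc$mean,
                   accuracy_sd = acc$sd, skipped = FALSE, reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("head_sweep_result", class(out)))
}

#' Cross-validated comparison of fusion strategies
#'
#' @param dataset A `paired_dataset`.
#' @param variants Character vector of variant names (see
#'   [build_fusion_variant()]).
#' @param config A [train_config()].
#' @return A `fusion_comparison` tibble: one row per variant with
#'   `<metric>_mean` / `<metric>_sd` columns.
#' @export
compare_fusion_variants <- function(dataset,
                                    variants = fusion_variants(),
                                    config = train_config()) {
  rows <- lapply(variants, function(v) {
    cfgr <- config
    cfgr$fusion_variant <- v
    cv <- cross_validate(dataset, cfgr)
    rep <- cv$report
    wide <- stats::setNames(
      c(rep$mean, rep$sd),
      c(paste0(rep$metric, "_mean"), paste0(rep$metric, "_sd"))
    )
    dplyr::bind_cols(tibble::tibble(variant = v),
                     tibble::as_tibble_row(wide))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fusion_comparison", class(out)))
}
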