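# Full-model assembly. A risk model is a flat named list of parameter
# arrays plus a configuration; the forward pass composes backbone ->
# intra-modal attention -> cross-attention -> compression -> decoder, and
# the backward pass mirrors it exactly. Ablation flags replace inactive
# attention blocks by identity pass-throughs; fusion variants rewire the
# same backbone and record embedding into early/intermediate/late fusion
# baselines or single-modality models.

fusion_variants <- function() {
  c("proposed", "early", "intermediate", "late", "image_only", "ehr_only")
}

sub_params <- function(params, prefix) {
  nms <- names(params)[startsWith(names(params), prefix)]
  out <- params[nms]
  names(out) <- substring(nms, nchar(prefix) + 1L)
  out
}

model_config <- function(K, n_ehr, volume_shape, channels = 12L,
                         n_heads = 6L, flags = list(SAM = TRUE, TAM = TRUE,
                                                    CAM = TRUE),
                         variant = "proposed", backbone_name = "tiny_cnn",
                         scaled_attention = FALSE,
                         cross_mode = "exclude_self", seed = 1L) {
  variant <- match.arg(variant, fusion_variants())
  if (channels %% n_heads != 0L) {
    stop(sprintf("channels = %d is not divisible by n_heads = %d",
                 channels, n_heads), call. = FALSE)
  }
  list(K = as.integer(K), n_ehr = as.integer(n_ehr),
       volume_shape = as.integer(volume_shape),
       C = as.integer(channels), n_heads = as.integer(n_heads),
       flags = lapply(flags, isTRUE), variant = variant,
       backbone_name = backbone_name, scaled_attention = scaled_attention,
       cross_mode = cross_mode, seed = as.integer(seed))
}

init_model_params <- function(cfg) {
  C <- cfg$C; K <- cfg$K; Fn <- cfg$n_ehr
  bb <- backbone(cfg$backbone_name, channels = C, seed = cfg$seed)
  prefix <- function(p, pre) stats::setNames(p, paste0(pre, names(p)))
  params <- list()
  has_image <- cfg$variant != "ehr_only"
  has_ehr <- cfg$variant != "image_only"
  if (has_image) params <- c(params, bb$params)
  withr::with_seed(cfg$seed + 1L, {
    if (has_ehr && cfg$variant != "early" && cfg$variant != "intermediate") {
      params$emb_We <- rnorm_mat(Fn, C, sd = 1 / sqrt(Fn))
      params$emb_be <- rep(0, C)
    }
    if (cfg$variant %in% c("proposed", "image_only", "ehr_only")) {
      if (has_image && isTRUE(cfg$flags$SAM)) {
        params <- c(params,
                    prefix(attention_params(C, seed = cfg$seed + 2L), "sa_"))
      }
      if (has_image && isTRUE(cfg$flags$TAM)) {
        params <- c(params,
                    prefix(attention_params(C, seed = cfg$seed + 3L), "ta_"))
      }
      if (cfg$variant == "proposed" && isTRUE(cfg$flags$CAM)) {
        # symmetric affinity initialization: query and key projections of
        # each cross-attention block start identical (and a factor-2 scale),
        # so the initial affinity is a positive-semidefinite bilinear form;
        # this bootstraps cross-modal alignment, which otherwise has to
        # emerge from second-order gradients
        cm <- attention_params(C, seed = cfg$seed + 4L, out_proj = FALSE)
        cs <- attention_params(C, seed = cfg$seed + 5L, out_proj = FALSE)
        cm$Wq <- 2 * cm$Wq; cm$Wk <- cm$Wq
        cs$Wq <- 2 * cs$Wq; cs$Wk <- cs$Wq
        params <- c(params, prefix(cm, "cm_"), prefix(cs, "cs_"))
      }
      if (has_image) {
        params <- c(params, prefix(mha_params(C, seed = cfg$seed + 6L), "d1_"))
      }
      if (has_ehr) {
        params <- c(params, prefix(mha_params(C, seed = cfg$seed + 7L), "d2_"))
      }
      params$Xd <- class_query(K, C, seed = cfg$seed + 8L)
      params$fc_W <- rnorm_mat(K * C, K, sd = 1 / sqrt(K * C))
      params$fc_b <- rep(0, K)
    } else if (cfg$variant == "early") {
      params$e_W <- rnorm_mat(C + Fn, K, sd = 1 / sqrt(C + Fn))
      params$e_b <- rep(0, K)
    } else if (cfg$variant == "intermediate") {
      params$i_W1 <- rnorm_mat(C, C, sd = 1 / sqrt(C))
      params$i_b1 <- rep(0, C)
      params$i_W2 <- rnorm_mat(Fn, C, sd = 1 / sqrt(Fn))
      params$i_b2 <- rep(0, C)
      params$ifc_W <- rnorm_mat(C, K, sd = 1 / sqrt(C))
      params$ifc_b <- rep(0, K)
    } else if (cfg$variant == "late") {
      params <- c(params, prefix(mha_params(C, seed = cfg$seed + 6L), "l_"))
      params$Xd <- class_query(K, C, seed = cfg$seed + 8L)
      params$fc_W <- rnorm_mat(K * C, K, sd = 1 / sqrt(K * C))
      params$fc_b <- rep(0, K)
    }
  })
  list(params = params, bb = bb)
}

# broadcast a C-vector over the (D', H', W') grid in A4 layout
broadcast_A4 <- function(s, d3) {
  array(rep(s, each = prod(d3)), c(d3, length(s)))
}

# per-slice spatial mean pooling of an A4 map -> (D', C)
pool_slices <- function(A4) {
  d <- dim(A4)
  B <- aperm(array(A4, c(d[1], d[2] * d[3], d[4])), c(2, 1, 3))
  matrix(colMeans(matrix(B, d[2] * d[3], d[1] * d[4])), d[1], d[4])
}

## ---- forward ----

model_fw <- function(vol, x, params, cfg, bb) {
  variant <- cfg$variant
  cache <- list(variant = variant)
  C <- cfg$C
  has_image <- variant != "ehr_only"
  has_ehr <- variant != "image_only"

  if (has_image) {
    bf <- backbone_fw(vol, bb, params)
    A4 <- bf$A4
    d3 <- dim(A4)[1:3]
    P <- prod(d3[2:3])
    cache$bf <- bf
    cache$d3 <- d3
  }
  if (variant == "early") {
    g <- colMeans(matrix(A4, prod(dim(A4)[1:3]), C))
    z <- c(g, x)
    logits <- drop(z %*% params$e_W) + params$e_b
    cache$z <- z
    cache$P_all <- prod(dim(A4)[1:3])
  } else if (variant == "intermediate") {
    g <- colMeans(matrix(A4, prod(dim(A4)[1:3]), C))
    z <- drop(g %*% params$i_W1) + params$i_b1 +
      drop(x %*% params$i_W2) + params$i_b2
    logits <- drop(z %*% params$ifc_W) + params$ifc_b
    cache$g <- g; cache$z <- z; cache$x <- x
    cache$P_all <- prod(dim(A4)[1:3])
  } else if (variant == "late") {
    M0 <- pool_slices(A4)                       # (D', C)
    s <- drop(x %*% params$emb_We) + params$emb_be
    R <- rbind(M0, matrix(s, d3[1], C, byrow = TRUE))
    ml <- mha_fw(params$Xd, R, R, sub_params(params, "l_"), 1L)
    out <- ml$out
    logits <- drop(as.vector(out) %*% params$fc_W) + params$fc_b
    cache$ml <- ml; cache$out <- out; cache$x <- x; cache$Dp <- d3[1]
  } else {
    # proposed / image_only / ehr_only share the attention pipeline
    if (has_image) {
      sam <- isTRUE(cfg$flags$SAM); tam <- isTRUE(cfg$flags$TAM)
      sa <- if (sam) sa_fw2(A4, sub_params(params, "sa_"),
                           scaled = cfg$scaled_attention)
      ta <- if (tam) ta_fw2(A4, sub_params(params, "ta_"),
                           scaled = cfg$scaled_attention)
      Ms <- if (sam) sa$out else A4       # inactive block = identity
      Mt <- if (tam) ta$out else A4
      Mcomb <- Ms + Mt
      cache$sa <- sa; cache$ta <- ta
    }
    if (has_ehr) {
      s <- drop(x %*% params$emb_We) + params$emb_be
      cache$x <- x; cache$s <- s
    }
    use_cam <- variant == "proposed" && isTRUE(cfg$flags$CAM)
    if (variant == "proposed") {
      A4s <- broadcast_A4(s, d3)
      if (use_cam) {
        ca <- ca_fw2(Mcomb, A4s,
                    list(m = sub_params(params, "cm_"),
                         s = sub_params(params, "cs_")),
                    mode = cfg$cross_mode)
        Mp <- ca$out_m; Sp <- ca$out_s
        cache$ca <- ca
      } else {
        Mp <- Mcomb; Sp <- A4s
      }
      M <- pool_slices(Mp)
      S <- pool_slices(Sp)
    } else if (variant == "image_only") {
      M <- pool_slices(Mcomb)
      S <- NULL
    } else { # ehr_only: D' defaults to 1 pseudo-slice of the record
      M <- NULL
      S <- matrix(s, 1L, C)
    }
    cache$use_cam <- use_cam
    out <- matrix(0, cfg$K, C)
    if (!is.null(M)) {
      m1 <- mha_fw(params$Xd, M, M, sub_params(params, "d1_"), cfg$n_heads)
      out <- out + m1$out
      cache$m1 <- m1
    }
    if (!is.null(S)) {
      m2 <- mha_fw(params$Xd, S, S, sub_params(params, "d2_"), cfg$n_heads)
      out <- out + m2$out
      cache$m2 <- m2
    }
    logits <- drop(as.vector(out) %*% params$fc_W) + params$fc_b
    cache$out <- out; cache$M <- M; cache$S <- S
  }
  probs <- drop(softmax_rows(matrix(logits, 1L)))
  list(logits = logits, probs = probs, cache = cache)
}

## ---- backward ----

model_bw <- function(dlogits, fw, params, cfg, bb) {
  cache <- fw$cache
  variant <- cache$variant
  C <- cfg$C
  G <- list()
  dvol <- NULL; dx <- NULL

  if (variant == "early") {
    G$e_W <- outer(cache$z, dlogits)
    G$e_b <- dlogits
    dz <- drop(params$e_W %*% dlogits)
    dg <- dz[seq_len(C)]
    dx <- dz[-seq_len(C)]
    dA4 <- broadcast_A4(dg / cache$P_all, cache$d3)
    bbk <- backbone_bw(dA4, cache$bf$cache, bb, params)
    G <- c(G, bbk$grads); dvol <- bbk$dvol
    return(list(grads = G, dvol = dvol, dx = dx))
  }
  if (variant == "intermediate") {
    G$ifc_W <- outer(cache$z, dlogits)
    G$ifc_b <- dlogits
    dz <- drop(params$ifc_W %*% dlogits)
    G$i_W1 <- outer(cache$g, dz); G$i_b1 <- dz
    G$i_W2 <- outer(cache$x, dz); G$i_b2 <- dz
    dx <- drop(params$i_W2 %*% dz)
    dg <- drop(params$i_W1 %*% dz)
    dA4 <- broadcast_A4(dg / cache$P_all, cache$d3)
    bbk <- backbone_bw(dA4, cache$bf$cache, bb, params)
    G <- c(G, bbk$grads); dvol <- bbk$dvol
    return(list(grads = G, dvol = dvol, dx = dx))
  }
  if (variant == "late") {
    G$fc_W <- outer(as.vector(cache$out), dlogits)
    G$fc_b <- dlogits
    dout <- matrix(drop(params$fc_W %*% dlogits), cfg$K, C)
    gl <- mha_bw(dout, cache$ml, sub_params(params, "l_"))
    G <- grad_merge(G, "l_", gl)
    G$Xd <- gl$dquery
    dR <- gl$dkeys + gl$dvalues
    Dp <- cache$Dp
    dM0 <- dR[seq_len(Dp), , drop = FALSE]
    ds <- colSums(dR[Dp + seq_len(Dp), , drop = FALSE])
    G$emb_We <- outer(cache$x, ds); G$emb_be <- ds
    dx <- drop(params$emb_We %*% ds)
    d3 <- cache$d3
    P <- prod(d3[2:3])
    dA4 <- array((dM0 / P)[, rep(seq_len(C), each = P)], c(d3, C))
    bbk <- backbone_bw(dA4, cache$bf$cache, bb, params)
    G <- c(G, bbk$grads); dvol <- bbk$dvol
    return(list(grads = G, dvol = dvol, dx = dx))
  }

  # attention pipeline variants
  G$fc_W <- outer(as.vector(cache$out), dlogits)
  G$fc_b <- dlogits
  dout <- matrix(drop(params$fc_W %*% dlogits), cfg$K, C)
  dXd <- matrix(0, cfg$K, C)
  dM <- NULL; dS <- NULL
  if (!is.null(cache$m1)) {
    g1 <- mha_bw(dout, cache$m1, sub_params(params, "d1_"))
    G <- grad_merge(G, "d1_", g1)
    dXd <- dXd + g1$dquery
    dM <- g1$dkeys + g1$dvalues
  }
  if (!is.null(cache$m2)) {
    g2 <- mha_bw(dout, cache$m2, sub_params(params, "d2_"))
    G <- grad_merge(G, "d2_", g2)
    dXd <- dXd + g2$dquery
    dS <- g2$dkeys + g2$dvalues
  }
  G$Xd <- dXd

  if (variant == "ehr_only") {
    ds <- drop(dS)   # single pseudo-slice row
    G$emb_We <- outer(cache$x, ds); G$emb_be <- ds
    dx <- drop(params$emb_We %*% ds)
    return(list(grads = G, dvol = NULL, dx = dx))
  }

  d3 <- cache$d3
  P <- prod(d3[2:3])
  expand_pool <- function(dmat) {
    # gradient of per-slice spatial mean pooling: dA[t,h,w,c] = dmat[t,c]/P
    array((dmat / P)[, rep(seq_len(C), each = P)], c(d3, C))
  }
  if (variant == "image_only") {
    dMcomb <- expand_pool(dM)
  } else {
    dMp <- expand_pool(dM)
    dSp <- expand_pool(dS)
    if (cache$use_cam) {
      cab <- ca_bw2(dMp, dSp, cache$ca,
                   list(m = sub_params(params, "cm_"),
                        s = sub_params(params, "cs_")))
      G <- grad_merge(G, "cm_", cab$grads_m)
      G <- grad_merge(G, "cs_", cab$grads_s)
      dMcomb <- cab$dm
      dA4s <- cab$ds
    } else {
      dMcomb <- dMp
      dA4s <- dSp
    }
    ds <- apply(dA4s, 4L, sum)
    G$emb_We <- outer(cache$x, ds); G$emb_be <- ds
    dx <- drop(params$emb_We %*% ds)
  }

  dA4 <- array(0, c(d3, C))
  if (!is.null(cache$sa)) {
    sb <- sa_bw2(dMcomb, cache$sa, sub_params(params, "sa_"))
    G <- grad_merge(G, "sa_", sb$grads)
    dA4 <- dA4 + sb$dx
  } else {
    dA4 <- dA4 + dMcomb
  }
  if (!is.null(cache$ta)) {
    tb <- ta_bw2(dMcomb, cache$ta, sub_params(params, "ta_"))
    G <- grad_merge(G, "ta_", tb$grads)
    dA4 <- dA4 + tb$dx
  } else {
    dA4 <- dA4 + dMcomb
  }
  bbk <- backbone_bw(dA4, cache$bf$cache, bb, params)
  G <- c(G, bbk$grads)
  list(grads = G, dvol = bbk$dvol, dx = dx)
}

## ---- public model object helpers ----

apply_scaler <- function(x, scaler) (x - scaler$mean) / scaler$sd

#' Forward-pass a single subject through a fitted model
#' @param model A `risk_model` from [train_model()] or
#'   [build_fusion_variant()].
#' @param volume Numeric `(D, H, W)` array in `[0, 1]`.
#' @param ehr Numeric clinical feature vector (raw scale; the model's
#'   stored standardization is applied).
#' @return A `prediction` list with `probs` and `logits`.
#' @export
predict_sample <- function(model, volume, ehr) {
  x <- apply_scaler(ehr, model$scaler)
  fw <- model_fw(volume, x, model$params, model$cfg, model$bb)
  structure(list(probs = fw$probs, logits = fw$logits), class = "prediction")
}

#' Predict class probabilities for every subject of a dataset
#' @param object A `risk_model`.
#' @param newdata A `paired_dataset`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `.pred_class`, and one `.pred_<k>`
#'   probability column per class.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  X <- ehr_matrix(newdata)
  n <- nrow(newdata)
  K <- object$cfg$K
  probs <- matrix(0, n, K)
  for (i in seq_len(n)) {
    probs[i, ] <- predict_sample(object, newdata$volume[[i]], X[i, ])$probs
  }
  out <- tibble::tibble(
    subject_id = newdata$subject_id,
    .pred_class = as.integer(max.col(probs) - 1L)
  )
  colnames(probs) <- paste0(".pred_", seq_len(K) - 1L)
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' Gradient of one class logit with respect to the inputs
#'
#' Backpropagates a one-hot logit gradient to the input volume and record
#' vector. Single-modality variants return an exactly zero gradient for the
#' absent modality.
#'
#' @param model A `risk_model`.
#' @param volume,ehr One subject's inputs.
#' @param class_index Class whose logit is differentiated (0-based).
#' @return List with `dvolume` (array, zeros if the model has no image
#'   branch) and `dehr` (vector, zeros if no record branch).
#' @export
input_gradient <- function(model, volume, ehr, class_index = 0L) {
  x <- apply_scaler(ehr, model$scaler)
  fw <- model_fw(volume, x, model$params, model$cfg, model$bb)
  dlogits <- rep(0, model$cfg$K)
  dlogits[class_index + 1L] <- 1
  bw <- model_bw(dlogits, fw, model$params, model$cfg, model$bb)
  list(
    dvolume = if (is.null(bw$dvol)) array(0, dim(volume)) else bw$dvol,
    dehr = if (is.null(bw$dx)) rep(0, length(ehr)) else bw$dx / model$scaler$sd
  )
}
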