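# Shared fixtures: tiny random feature maps and parameter sets built in
# code, plus brute-force loop oracles kept deliberately naive and separate
# from the vectorized implementation they check.

rand_fm <- function(C, Dp, Hp, Wp, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(C * Dp * Hp * Wp, sd = sd), c(C, Dp, Hp, Wp))
}

rand_attn_params <- function(C, seed = 1, out_proj = TRUE) {
  set.seed(seed)
  p <- list(Wq = matrix(rnorm(C * C, sd = 0.5), C), bq = rnorm(C, sd = 0.2),
            Wk = matrix(rnorm(C * C, sd = 0.5), C), bk = rnorm(C, sd = 0.2),
            Wv = matrix(rnorm(C * C, sd = 0.5), C), bv = rnorm(C, sd = 0.2))
  if (out_proj) {
    p$Wo <- matrix(rnorm(C * C, sd = 0.5), C)
    p$bo <- rnorm(C, sd = 0.2)
  }
  p
}

# naive softmax of a numeric vector (loop-free but independent code path)
naive_softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# brute-force spatial attention: explicit loops over slices and positions
oracle_spatial_attention <- function(fm, p, scaled = FALSE) {
  d <- dim(fm)  # (C, Dp, Hp, Wp)
  C <- d[1]; Dp <- d[2]; P <- d[3] * d[4]
  out <- array(0, d)
  for (t in seq_len(Dp)) {
    v <- matrix(fm[, t, , ], C, P)   # columns are positions
    Kmat <- matrix(0, C, P); Qmat <- matrix(0, C, P); Vmat <- matrix(0, C, P)
    for (i in seq_len(P)) {
      Kmat[, i] <- t(p$Wk) %*% v[, i] + p$bk
      Qmat[, i] <- t(p$Wq) %*% v[, i] + p$bq
      Vmat[, i] <- t(p$Wv) %*% v[, i] + p$bv
    }
    O <- matrix(0, C, P)
    for (j in seq_len(P)) {
      logits <- numeric(P)
      for (i in seq_len(P)) logits[i] <- sum(Kmat[, i] * Qmat[, j])
      if (scaled) logits <- logits / sqrt(C)
      w <- naive_softmax(logits)
      acc <- numeric(C)
      for (i in seq_len(P)) acc <- acc + Vmat[, i] * w[i]
      O[, j] <- t(p$Wo) %*% acc + p$bo
    }
    out[, t, , ] <- array(O, c(C, d[3], d[4]))
  }
  out
}

# brute-force temporal attention: loops over spatial positions and depth
oracle_temporal_attention <- function(fm, p, scaled = FALSE) {
  d <- dim(fm)
  C <- d[1]; Dp <- d[2]
  out <- array(0, d)
  for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
    v <- matrix(fm[, , h, w], C, Dp)
    Kmat <- matrix(0, C, Dp); Qmat <- matrix(0, C, Dp); Vmat <- matrix(0, C, Dp)
    for (i in seq_len(Dp)) {
      Kmat[, i] <- t(p$Wk) %*% v[, i] + p$bk
      Qmat[, i] <- t(p$Wq) %*% v[, i] + p$bq
      Vmat[, i] <- t(p$Wv) %*% v[, i] + p$bv
    }
    for (j in seq_len(Dp)) {
      logits <- sapply(seq_len(Dp), function(i) sum(Kmat[, i] * Qmat[, j]))
      if (scaled) logits <- logits / sqrt(C)
      wgt <- naive_softmax(logits)
      acc <- numeric(C)
      for (i in seq_len(Dp)) acc <- acc + Vmat[, i] * wgt[i]
      out[, j, h, w] <- t(p$Wo) %*% acc + p$bo
    }
  }
  out
}

# brute-force affinity + aggregation on (C, Hp, Wp) maps
oracle_affinity <- function(q_map, k_map, include_self = FALSE) {
  d <- dim(q_map)
  P <- d[2] * d[3]
  Q <- matrix(q_map, d[1], P)
  K <- matrix(k_map, d[1], P)
  A <- matrix(0, P, P)
  for (j in seq_len(P)) {
    cand <- if (include_self) seq_len(P) else setdiff(seq_len(P), j)
    logits <- sapply(cand, function(i) sum(Q[, j] * K[, i]))
    A[j, cand] <- naive_softmax(logits)
  }
  A
}

oracle_aggregate <- function(A, v_map, h_map) {
  d <- dim(v_map)
  P <- d[2] * d[3]
  V <- matrix(v_map, d[1], P)
  H <- matrix(h_map, d[1], P)
  out <- matrix(0, d[1], P)
  for (j in seq_len(P)) {
    acc <- H[, j]
    for (i in seq_len(P)) acc <- acc + A[j, i] * V[, i]
    out[, j] <- acc
  }
  array(out, d)
}

# brute-force multi-head attention: slice channels, attend, re-project
oracle_mha <- function(query, keys, values, p, n_heads) {
  C <- ncol(query)
  dh <- C / n_heads
  Q <- query %*% p$Wq + matrix(p$bq, nrow(query), C, byrow = TRUE)
  K <- keys %*% p$Wk + matrix(p$bk, nrow(keys), C, byrow = TRUE)
  V <- values %*% p$Wv + matrix(p$bv, nrow(values), C, byrow = TRUE)
  O <- matrix(0, nrow(query), C)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    for (j in seq_len(nrow(query))) {
      logits <- sapply(seq_len(nrow(keys)), function(i)
        sum(Q[j, idx] * K[i, idx]) / sqrt(dh))
      w <- naive_softmax(logits)
      acc <- numeric(dh)
      for (i in seq_len(nrow(keys))) acc <- acc + w[i] * V[i, idx]
      O[j, idx] <- acc
    }
  }
  O %*% p$Wo + matrix(p$bo, nrow(query), C, byrow = TRUE)
}

# tiny dataset helper
tiny_dataset <- function(n = 12, K = 2, seed = 1, mode = "fusion_xor",
                         shape = c(4L, 8L, 8L), F = 5L) {
  generate_dataset(synth_config(
    n_samples = n, n_classes = K, volume_shape = shape,
    n_ehr_features = F, signal_mode = mode, seed = seed))
}

fast_config <- function(epochs = 2L, batch_size = 4L, channels = 4L,
                        n_heads = 2L, ...) {
  train_config(channels = channels, n_heads = n_heads, epochs = epochs,
               batch_size = batch_size, n_folds = 2L, ...)
}
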