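# Internal numeric core: small dense/conv/attention primitives with explicit
# forward caches and hand-derived backward passes. Everything operates on
# plain numeric matrices/arrays; shapes are tiny (desk scale) so clarity wins
# over micro-optimisation, but all inner products are BLAS calls.

## ---- dense affine ----

add_bias <- function(M, b) M + rep(b, each = nrow(M))

lin_fw <- function(X, W, b) {
  list(out = add_bias(X %*% W, b), X = X)
}

lin_bw <- function(dout, cache, W) {
  list(
    dX = dout %*% t(W),
    dW = crossprod(cache$X, dout),
    db = colSums(dout)
  )
}

## ---- row-wise softmax (stable; supports -Inf masking) ----

softmax_rows <- function(L, masked = TRUE) {
  n <- nrow(L)
  m <- L[seq_len(n) + n * (max.col(L, ties.method = "first") - 1L)]
  E <- exp(L - m)
  if (masked) E[L == -Inf] <- 0
  E / rowSums(E)
}

# dL given dA and A = softmax_rows(L); masked entries get gradient 0 anyway
softmax_rows_bw <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

## ---- generic single-matrix attention block ----
# X: (P, C) rows are positions. Computes
#   Q = X Wq + bq ; K = X Wk + bk ; V = X Wv + bv
#   L[j, i] = <Q_j, K_i> (/ sqrt(C) if scaled); A = softmax rows over i
#   O = A V ; optionally Y = O Wo + bo
# mask: optional logical (P, P); mask[j, i] = FALSE excludes i from row j.

attn_fw <- function(X, p, scaled = FALSE, mask = NULL, out_proj = TRUE,
                    Xkv = NULL) {
  KV <- if (is.null(Xkv)) X else Xkv
  Q <- add_bias(X %*% p$Wq, p$bq)
  K <- add_bias(KV %*% p$Wk, p$bk)
  V <- add_bias(KV %*% p$Wv, p$bv)
  L <- tcrossprod(Q, K)
  if (scaled) L <- L / sqrt(ncol(Q))
  if (!is.null(mask)) L[!mask] <- -Inf
  A <- softmax_rows(L)
  O <- A %*% V
  Y <- if (out_proj) add_bias(O %*% p$Wo, p$bo) else O
  list(out = Y, A = A, Q = Q, K = K, V = V, O = O, X = X, KV = KV,
       scaled = scaled, mask = mask, out_proj = out_proj,
       cross = !is.null(Xkv))
}

# Returns dX (and dKV when a distinct key/value input was used) plus
# parameter gradients named as in p.
attn_bw <- function(dY, cache, p) {
  g <- list()
  if (cache$out_proj) {
    g$Wo <- crossprod(cache$O, dY)
    g$bo <- colSums(dY)
    dO <- dY %*% t(p$Wo)
  } else {
    dO <- dY
  }
  dA <- dO %*% t(cache$V)
  dV <- crossprod(cache$A, dO)
  dL <- softmax_rows_bw(dA, cache$A)
  if (cache$scaled) dL <- dL / sqrt(ncol(cache$Q))
  dQ <- dL %*% cache$K
  dK <- crossprod(dL, cache$Q)
  g$Wq <- crossprod(cache$X, dQ);  g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$KV, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$KV, dV); g$bv <- colSums(dV)
  dX <- dQ %*% t(p$Wq)
  dKV <- dK %*% t(p$Wk) + dV %*% t(p$Wv)
  if (cache$cross) {
    g$dX <- dX
    g$dKV <- dKV
  } else {
    g$dX <- dX + dKV
  }
  g
}

## ---- multi-head attention (transformer-style) ----
# query (K, C), keys/values (T, C); C %% n_heads == 0. Per-head scaled
# dot-product attention on channel slices, concatenated, output-projected.

mha_fw <- function(query, keys, values, p, n_heads) {
  C <- ncol(query)
  if (C %% n_heads != 0L) {
    stop(sprintf(
      "channel count C = %d is not divisible by n_heads = %d", C, n_heads
    ), call. = FALSE)
  }
  dh <- C %/% n_heads
  Q <- add_bias(query %*% p$Wq, p$bq)
  K <- add_bias(keys %*% p$Wk, p$bk)
  V <- add_bias(values %*% p$Wv, p$bv)
  O <- matrix(0, nrow(query), C)
  As <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmax_rows(tcrossprod(Q[, idx, drop = FALSE],
                                 K[, idx, drop = FALSE]) / sqrt(dh),
                      masked = FALSE)
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    As[[h]] <- A
  }
  Y <- add_bias(O %*% p$Wo, p$bo)
  list(out = Y, Q = Q, K = K, V = V, O = O, As = As, n_heads = n_heads,
       query = query, keys = keys, values = values)
}

mha_bw <- function(dY, cache, p) {
  n_heads <- cache$n_heads
  C <- ncol(cache$Q)
  dh <- C %/% n_heads
  g <- list(Wo = crossprod(cache$O, dY), bo = colSums(dY))
  dO <- tcrossprod(dY, p$Wo)
  dQ <- matrix(0, nrow(cache$Q), C)
  dK <- matrix(0, nrow(cache$K), C)
  dV <- matrix(0, nrow(cache$V), C)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$As[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOh)
    dL <- softmax_rows_bw(dA, A) / sqrt(dh)
    dQ[, idx] <- dL %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dL, cache$Q[, idx, drop = FALSE])
  }
  g$Wq <- crossprod(cache$query, dQ);  g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$keys, dK);   g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$values, dV); g$bv <- colSums(dV)
  g$dquery <- tcrossprod(dQ, p$Wq)
  g$dkeys <- tcrossprod(dK, p$Wk)
  g$dvalues <- tcrossprod(dV, p$Wv)
  g
}

## ---- 3D convolution via im2col ----
# Input array (Ci, D, H, W); weights (Ci * kd * kh * kw, Co); 'same'-style
# zero padding of floor(k/2); arbitrary per-axis stride.

conv3d_geom <- function(in_dim, kernel, stride) {
  pad <- kernel %/% 2L
  out <- (in_dim + 2L * pad - kernel) %/% stride + 1L
  list(pad = pad, out = out)
}

# Cache of im2col index matrices keyed by geometry.
.conv_idx_cache <- new.env(parent = emptyenv())

conv3d_indices <- function(Ci, in_dim, kernel, stride) {
  key <- paste(c(Ci, in_dim, kernel, stride), collapse = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- conv3d_geom(in_dim, kernel, stride)
  pad <- g$pad
  pd <- in_dim + 2L * pad
  od <- g$out
  # output voxel coordinates (column-major over D', H', W')
  oc <- as.matrix(expand.grid(d = seq_len(od[1]), h = seq_len(od[2]),
                              w = seq_len(od[3])))
  # kernel offsets x input channel (column order: ci fastest, then kd, kh, kw)
  kc <- as.matrix(expand.grid(ci = seq_len(Ci), kd = seq_len(kernel[1]),
                              kh = seq_len(kernel[2]), kw = seq_len(kernel[3])))
  n_out <- nrow(oc)
  n_k <- nrow(kc)
  idx <- matrix(0L, n_out, n_k)
  base_d <- (oc[, 1] - 1L) * stride[1]
  base_h <- (oc[, 2] - 1L) * stride[2]
  base_w <- (oc[, 3] - 1L) * stride[3]
  for (j in seq_len(n_k)) {
    ci <- kc[j, 1]; kd <- kc[j, 2]; kh <- kc[j, 3]; kw <- kc[j, 4]
    d <- base_d + kd; h <- base_h + kh; w <- base_w + kw  # 1-based in padded
    idx[, j] <- ci + Ci * ((d - 1L) + pd[1] * ((h - 1L) + pd[2] * (w - 1L)))
  }
  res <- list(idx = idx, pad = pad, pd = pd, out = od, Ci = Ci,
              in_dim = in_dim)
  .conv_idx_cache[[key]] <- res
  res
}

conv3d_pad <- function(x, geom) {
  Ci <- geom$Ci; pd <- geom$pd; pad <- geom$pad; ind <- geom$in_dim
  padded <- array(0, c(Ci, pd))
  padded[, pad[1] + seq_len(ind[1]), pad[2] + seq_len(ind[2]),
         pad[3] + seq_len(ind[3])] <- x
  padded
}

conv3d_fw <- function(x, W, b, kernel, stride) {
  Ci <- dim(x)[1]
  geom <- conv3d_indices(Ci, dim(x)[2:4], kernel, stride)
  padded <- conv3d_pad(x, geom)
  Xcol <- matrix(padded[geom$idx], nrow(geom$idx), ncol(geom$idx))
  out <- add_bias(Xcol %*% W, b)   # (n_out, Co)
  list(out = out, Xcol = Xcol, geom = geom)
}

conv3d_bw <- function(dout, cache, W) {
  geom <- cache$geom
  dW <- crossprod(cache$Xcol, dout)
  db <- colSums(dout)
  dXcol <- tcrossprod(dout, W)
  dpad <- numeric(geom$Ci * prod(geom$pd))
  for (j in seq_len(ncol(geom$idx))) {
    ij <- geom$idx[, j]
    dpad[ij] <- dpad[ij] + dXcol[, j]
  }
  dpad <- array(dpad, c(geom$Ci, geom$pd))
  pad <- geom$pad; ind <- geom$in_dim
  dx <- dpad[, pad[1] + seq_len(ind[1]), pad[2] + seq_len(ind[2]),
             pad[3] + seq_len(ind[3]), drop = FALSE]
  list(dx = array(dx, c(geom$Ci, ind)), dW = dW, db = db)
}

relu_fw <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bw <- function(dout, cache) dout * cache$mask

## ---- parameter-list helpers ----

plist_zeros_like <- function(p) lapply(p, function(x) array(0, dim(x) %||% length(x)))

plist_axpy <- function(acc, g, a = 1) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + a * g[[nm]]
  acc
}

plist_scale <- function(p, a) lapply(p, function(x) x * a)


# merge sub-gradients under a prefix into a flat gradient list
grad_merge <- function(G, prefix, g) {
  keep <- setdiff(names(g), c("dX", "dKV", "dquery", "dkeys", "dvalues", "dx"))
  for (nm in keep) {
    key <- paste0(prefix, nm)
    G[[key]] <- if (is.null(G[[key]])) g[[nm]] else G[[key]] + g[[nm]]
  }
  G
}

rnorm_mat <- function(n, m, sd) matrix(stats::rnorm(n * m, sd = sd), n, m)
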