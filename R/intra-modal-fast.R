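# Batched implementations of the intra-modal and cross-modal attention
# passes used by the training engine: the K/Q/V projections of all slices
# (or all spatial positions) are computed in single matrix products, and
# only the softmax-attention core loops over the attended groups. The
# public per-slice operations in intra-modal.R / inter-modal.R share the
# same math; equivalence is exercised by the oracle tests.

# group-batched self-attention: X_all (G*R, C), G groups of R contiguous
# rows; one attention matrix per group
gattn_fw <- function(X_all, p, G, R, scaled = FALSE, mask = NULL,
                     KV_all = NULL, out_proj = TRUE) {
  KV <- if (is.null(KV_all)) X_all else KV_all
  Q <- add_bias(X_all %*% p$Wq, p$bq)
  K <- add_bias(KV %*% p$Wk, p$bk)
  V <- add_bias(KV %*% p$Wv, p$bv)
  N <- nrow(X_all)
  sc <- if (scaled) sqrt(ncol(Q)) else 1
  # stack the per-group logit matrices vertically and softmax once
  Lbig <- matrix(0, N, R)
  for (g in seq_len(G)) {
    rows <- ((g - 1L) * R + 1L):(g * R)
    Lbig[rows, ] <- tcrossprod(Q[rows, , drop = FALSE],
                               K[rows, , drop = FALSE]) / sc
  }
  has_mask <- !is.null(mask)
  if (has_mask) Lbig[!mask[rep(seq_len(R), G), ]] <- -Inf
  Abig <- softmax_rows(Lbig, has_mask)
  O <- matrix(0, N, ncol(X_all))
  for (g in seq_len(G)) {
    rows <- ((g - 1L) * R + 1L):(g * R)
    O[rows, ] <- Abig[rows, , drop = FALSE] %*% V[rows, , drop = FALSE]
  }
  Y <- if (out_proj) add_bias(O %*% p$Wo, p$bo) else O
  list(out = Y, Q = Q, K = K, V = V, O = O, Abig = Abig, G = G, R = R,
       X = X_all, KV = KV, scaled = scaled, out_proj = out_proj,
       cross = !is.null(KV_all))
}

# attention matrix of group g from a grouped-attention cache
gattn_A <- function(cache, g) {
  rows <- ((g - 1L) * cache$R + 1L):(g * cache$R)
  cache$Abig[rows, , drop = FALSE]
}

gattn_bw <- function(dY, cache, p) {
  G <- cache$G; R <- cache$R
  g_out <- list()
  if (cache$out_proj) {
    g_out$Wo <- crossprod(cache$O, dY)
    g_out$bo <- colSums(dY)
    dO <- tcrossprod(dY, p$Wo)
  } else {
    dO <- dY
  }
  N <- nrow(dY)
  dAbig <- matrix(0, N, R)
  dV <- matrix(0, N, ncol(dY))
  for (g in seq_len(G)) {
    rows <- ((g - 1L) * R + 1L):(g * R)
    dOg <- dO[rows, , drop = FALSE]
    dAbig[rows, ] <- tcrossprod(dOg, cache$V[rows, , drop = FALSE])
    dV[rows, ] <- crossprod(gattn_A(cache, g), dOg)
  }
  sc <- if (cache$scaled) sqrt(ncol(dY)) else 1
  dLbig <- softmax_rows_bw(dAbig, cache$Abig) / sc
  dQ <- matrix(0, N, ncol(dY))
  dK <- matrix(0, N, ncol(dY))
  for (g in seq_len(G)) {
    rows <- ((g - 1L) * R + 1L):(g * R)
    dLg <- dLbig[rows, , drop = FALSE]
    dQ[rows, ] <- dLg %*% cache$K[rows, , drop = FALSE]
    dK[rows, ] <- crossprod(dLg, cache$Q[rows, , drop = FALSE])
  }
  g_out$Wq <- crossprod(cache$X, dQ);  g_out$bq <- colSums(dQ)
  g_out$Wk <- crossprod(cache$KV, dK); g_out$bk <- colSums(dK)
  g_out$Wv <- crossprod(cache$KV, dV); g_out$bv <- colSums(dV)
  dX <- tcrossprod(dQ, p$Wq)
  dKV <- tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  if (cache$cross) {
    g_out$dX <- dX
    g_out$dKV <- dKV
  } else {
    g_out$dX <- dX + dKV
  }
  g_out
}

# A4 (Dp, Hp, Wp, C) <-> grouped-row matrices.
# spatial grouping: rows (p within slice t), t-major blocks
A4_to_rows_s <- function(A4) {
  d <- dim(A4)
  matrix(aperm(array(A4, c(d[1], d[2] * d[3], d[4])), c(2, 1, 3)),
         d[1] * d[2] * d[3], d[4])
}
rows_s_to_A4 <- function(X, d) {
  array(aperm(array(X, c(d[2] * d[3], d[1], d[4])), c(2, 1, 3)), d)
}
# temporal grouping: rows (t within position p), p-major blocks
A4_to_rows_t <- function(A4) {
  d <- dim(A4)
  matrix(A4, d[1] * d[2] * d[3], d[4])
}
rows_t_to_A4 <- function(X, d) array(X, d)

sa_fw2 <- function(A4, p, scaled = FALSE) {
  d <- dim(A4)
  X <- A4_to_rows_s(A4)
  cc <- gattn_fw(X, p, G = d[1], R = d[2] * d[3], scaled = scaled)
  list(out = rows_s_to_A4(cc$out, d), cache = cc, d = d)
}

sa_bw2 <- function(dout, fwres, p) {
  g <- gattn_bw(A4_to_rows_s(dout), fwres$cache, p)
  dx <- rows_s_to_A4(g$dX, fwres$d)
  list(dx = dx, grads = g[setdiff(names(g), c("dX", "dKV"))])
}

ta_fw2 <- function(A4, p, scaled = FALSE) {
  d <- dim(A4)
  X <- A4_to_rows_t(A4)
  cc <- gattn_fw(X, p, G = d[2] * d[3], R = d[1], scaled = scaled)
  list(out = rows_t_to_A4(cc$out, d), cache = cc, d = d)
}

ta_bw2 <- function(dout, fwres, p) {
  g <- gattn_bw(A4_to_rows_t(dout), fwres$cache, p)
  list(dx = rows_t_to_A4(g$dX, fwres$d),
       grads = g[setdiff(names(g), c("dX", "dKV"))])
}

ca_fw2 <- function(A4m, A4s, p, mode = "exclude_self") {
  d <- dim(A4m)
  P <- d[2] * d[3]
  mask <- candidate_mask(d[2], d[3],
                         if (P == 1L && mode == "exclude_self")
                           "include_self" else mode)
  Xm <- A4_to_rows_s(A4m)
  Xs <- A4_to_rows_s(A4s)
  am <- gattn_fw(Xm, p$m, G = d[1], R = P, mask = mask, KV_all = Xs,
                 out_proj = FALSE)
  as <- gattn_fw(Xs, p$s, G = d[1], R = P, mask = mask, KV_all = Xm,
                 out_proj = FALSE)
  list(out_m = rows_s_to_A4(am$out + Xm, d),
       out_s = rows_s_to_A4(as$out + Xs, d),
       am = am, as = as, d = d)
}

ca_bw2 <- function(dOm, dOs, fwres, p) {
  d <- fwres$d
  dm_rows <- A4_to_rows_s(dOm)
  ds_rows <- A4_to_rows_s(dOs)
  gm <- gattn_bw(dm_rows, fwres$am, p$m)
  gs <- gattn_bw(ds_rows, fwres$as, p$s)
  dMin <- dm_rows + gm$dX + gs$dKV
  dSin <- ds_rows + gs$dX + gm$dKV
  list(dm = rows_s_to_A4(dMin, d), ds = rows_s_to_A4(dSin, d),
       grads_m = gm[setdiff(names(gm), c("dX", "dKV"))],
       grads_s = gs[setdiff(names(gs), c("dX", "dKV"))])
}
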