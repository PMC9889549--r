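# Inter-modal encoder: per-slice cross-attention between the image and
# clinical-record representations. Each direction scores its own query
# projection against key projections of the opposite modality ("affinity"),
# softmax-normalizes over a candidate set of positions, takes the
# attention-weighted sum of opposite-modality value vectors and adds the
# local representation back as a residual ("aggregation"). The per-slice
# outputs are spatially average-pooled into the (D', C) matrices consumed
# by the decoder.

# candidate-set mask: mask[j, i] = TRUE if position i is attended from j
.mask_cache <- new.env(parent = emptyenv())

candidate_mask <- function(h_prime, w_prime,
                           mode = c("exclude_self", "include_self",
                                    "criss_cross")) {
  mode <- mode[1]
  if (!mode %in% c("exclude_self", "include_self", "criss_cross")) {
    stop("unknown candidate-set mode '", mode, "'", call. = FALSE)
  }
  key <- paste(h_prime, w_prime, mode, sep = "_")
  hit <- .mask_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- local({
  P <- h_prime * w_prime
  if (mode == "include_self") return(matrix(TRUE, P, P))
  if (mode == "exclude_self") {
    if (P == 1L) {
      stop("1x1 grid with self-exclusion leaves an empty candidate set; ",
           "use mode = \"include_self\"", call. = FALSE)
    }
    return(!diag(P) > 0)
  }
  # criss-cross: same image row or same column as j, excluding j itself
  hw <- cbind(rep(seq_len(h_prime), times = w_prime),
              rep(seq_len(w_prime), each = h_prime))
  m <- outer(hw[, 1], hw[, 1], `==`) | outer(hw[, 2], hw[, 2], `==`)
  diag(m) <- FALSE
  if (P == 1L) {
    stop("1x1 grid with self-exclusion leaves an empty candidate set; ",
         "use mode = \"include_self\"", call. = FALSE)
  }
  m
  })
  .mask_cache[[key]] <- res
  res
}

#' Cross-modal affinity map
#'
#' Scores every query position `j` of one modality against the candidate
#' key positions of the other: the logit for candidate `i` is the inner
#' product of the `C`-vectors at `j` and `i`, and a softmax over the
#' candidate set yields one row of nonnegative weights summing to one. By
#' default the candidate set is every position except `j` itself.
#'
#' @param q_map Query feature map, array `(C, H', W')` (already projected).
#' @param k_map Key feature map, same shape, from the opposite modality.
#' @param mode Candidate set: `"exclude_self"` (default, all `H'W' - 1`
#'   other positions), `"include_self"`, or `"criss_cross"` (same row or
#'   column, excluding `j`).
#' @return Matrix `(H'W', H'W')`; excluded candidates hold exact zeros and
#'   every row sums to one. The logical candidate mask is attached as
#'   attribute `"mask"`.
#' @export
affinity <- function(q_map, k_map, mode = "exclude_self") {
  if (!identical(dim(q_map), dim(k_map))) {
    stop("query and key maps must have identical (C, H', W') shapes",
         call. = FALSE)
  }
  d <- dim(q_map)
  P <- d[2] * d[3]
  Q <- t(matrix(q_map, d[1], P))  # (P, C)
  K <- t(matrix(k_map, d[1], P))
  mask <- candidate_mask(d[2], d[3], mode)
  L <- Q %*% t(K)
  L[!mask] <- -Inf
  A <- softmax_rows(L)
  attr(A, "mask") <- mask
  A
}

#' Cross-modal aggregation
#'
#' The output at position `j` is the affinity-weighted sum of the opposite
#' modality's value vectors over the candidate set, plus the local
#' representation at `j` as a residual.
#'
#' @param A Affinity map from [affinity()], or an all-zero matrix (the
#'   pre-softmax bypass, which returns the residual unchanged).
#' @param v_map Value feature map `(C, H', W')` of the opposite modality.
#' @param h_map Local (residual) feature map `(C, H', W')`.
#' @return Array `(C, H', W')`.
#' @export
aggregate <- function(A, v_map, h_map) {
  if (!identical(dim(v_map), dim(h_map))) {
    stop("value and residual maps must share shapes", call. = FALSE)
  }
  d <- dim(v_map)
  P <- d[2] * d[3]
  if (!identical(dim(A), c(P, P))) {
    stop("affinity map is ", paste(dim(A), collapse = "x"),
         " but the grid has ", P, " positions", call. = FALSE)
  }
  rs <- rowSums(A)
  if (!all(abs(rs - 1) < 1e-5 | abs(rs) < 1e-12)) {
    stop("affinity rows must each sum to 1 (or be all-zero for the ",
         "residual bypass)", call. = FALSE)
  }
  V <- t(matrix(v_map, d[1], P))
  H <- t(matrix(h_map, d[1], P))
  out <- A %*% V + H
  array(t(out), d)
}

# internal cached cross-attention over all slices; A4 layout inputs
ca_fw <- function(A4m, A4s, p, mode = "exclude_self") {
  d <- dim(A4m)
  Dp <- d[1]; P <- d[2] * d[3]; C <- d[4]
  mask <- candidate_mask(d[2], d[3],
                         if (P == 1L && mode == "exclude_self")
                           "include_self" else mode)
  Bm <- array(A4m, c(Dp, P, C))
  Bs <- array(A4s, c(Dp, P, C))
  Om <- array(0, c(Dp, P, C))
  Os <- array(0, c(Dp, P, C))
  cm <- vector("list", Dp)
  cs <- vector("list", Dp)
  for (t in seq_len(Dp)) {
    Mt <- matrix(Bm[t, , ], P, C)
    St <- matrix(Bs[t, , ], P, C)
    a_m <- attn_fw(Mt, p$m, mask = mask, out_proj = FALSE, Xkv = St)
    a_s <- attn_fw(St, p$s, mask = mask, out_proj = FALSE, Xkv = Mt)
    Om[t, , ] <- a_m$out + Mt   # residual: local representation added back
    Os[t, , ] <- a_s$out + St
    cm[[t]] <- a_m
    cs[[t]] <- a_s
  }
  list(out_m = array(Om, d), out_s = array(Os, d), cm = cm, cs = cs)
}

ca_bw <- function(dOm, dOs, cache, p) {
  d <- dim(dOm)
  Dp <- d[1]; P <- d[2] * d[3]; C <- d[4]
  dBm <- array(dOm, c(Dp, P, C))
  dBs <- array(dOs, c(Dp, P, C))
  dMin <- array(0, c(Dp, P, C))
  dSin <- array(0, c(Dp, P, C))
  Gm <- NULL; Gs <- NULL
  for (t in seq_len(Dp)) {
    dm <- matrix(dBm[t, , ], P, C)
    ds <- matrix(dBs[t, , ], P, C)
    gm <- attn_bw(dm, cache$cm[[t]], p$m)
    gs <- attn_bw(ds, cache$cs[[t]], p$s)
    # residual paths plus query/key/value paths of both directions
    dMin[t, , ] <- dm + gm$dX + gs$dKV
    dSin[t, , ] <- ds + gs$dX + gm$dKV
    gm <- gm[setdiff(names(gm), c("dX", "dKV"))]
    gs <- gs[setdiff(names(gs), c("dX", "dKV"))]
    Gm <- if (is.null(Gm)) gm else plist_axpy(Gm, gm)
    Gs <- if (is.null(Gs)) gs else plist_axpy(Gs, gs)
  }
  list(dm = array(dMin, d), ds = array(dSin, d), grads_m = Gm, grads_s = Gs)
}

#' One slice of bidirectional cross-attention
#'
#' Runs the two parallel cross-attention directions for slice `t`: the
#' image representation queries the record representation (keys and values
#' from the record) and vice versa, each with its own projection weights,
#' followed by the residual aggregation.
#'
#' @param reps A [slice_representations()] bundle.
#' @param t Slice index in `1..D'`.
#' @param params List with elements `m` and `s`, each an
#'   [attention_params()] list without output projection.
#' @param mode Candidate-set mode passed to [affinity()].
#' @return List with `M_prime` and `S_prime`, arrays `(C, H', W')`.
#' @export
cross_attention_block <- function(reps, t, params, mode = "exclude_self") {
  d <- dim(reps$image_maps)  # (D', C, H', W')
  Mt <- aperm(array(reps$image_maps[t, , , ], d[2:4]), c(2, 3, 1))  # (H,W,C)
  St <- aperm(array(reps$ehr_maps[t, , , ], d[2:4]), c(2, 3, 1))
  P <- d[3] * d[4]
  mask <- candidate_mask(d[3], d[4],
                         if (P == 1L && mode == "exclude_self")
                           "include_self" else mode)
  Mmat <- matrix(Mt, P, d[2])
  Smat <- matrix(St, P, d[2])
  a_m <- attn_fw(Mmat, params$m, mask = mask, out_proj = FALSE, Xkv = Smat)
  a_s <- attn_fw(Smat, params$s, mask = mask, out_proj = FALSE, Xkv = Mmat)
  to_map <- function(mat) array(t(mat), c(d[2], d[3], d[4]))
  list(M_prime = to_map(a_m$out + Mmat), S_prime = to_map(a_s$out + Smat))
}

#' Compress per-slice maps into the decoder's fused representation
#'
#' Each slice map is spatially average-pooled to one `C`-vector; stacking
#' the `D'` vectors gives the `(D', C)` matrices `M` (image) and `S`
#' (record) that enter the decoder.
#'
#' @param m_slices,s_slices Lists of `D'` arrays `(C, H', W')`.
#' @return A `fused_representation` list with matrices `M` and `S`.
#' @export
compress <- function(m_slices, s_slices) {
  if (length(m_slices) == 0L) stop("no slices to compress", call. = FALSE)
  if (length(m_slices) != length(s_slices)) {
    stop("modalities have different slice counts", call. = FALSE)
  }
  pool <- function(x) apply(x, 1L, mean)
  M <- do.call(rbind, lapply(m_slices, pool))
  S <- do.call(rbind, lapply(s_slices, pool))
  structure(list(M = M, S = S), class = "fused_representation")
}
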