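# Intra-modal encoder: self-attention over the spatial positions of each
# slice ("spatial attention") and over the slice/depth axis at each spatial
# position ("temporal attention" -- depth plays the role of time), plus the
# affine embedding of the clinical-record vector into the image channel
# space. Logits are raw inner products K(v_i)' Q(v_j) by default; a
# 1/sqrt(C) scaled mode is available for numerical robustness.

#' Initialize the projection weights of a self-attention block
#'
#' The four 1x1x1 convolutions of one attention block: key, query, value
#' projections and the output projection, each `C x C` with a bias.
#'
#' @param C Channel count.
#' @param seed Seed for the Gaussian initialization.
#' @param sd Weight standard deviation (default `1/sqrt(C)`).
#' @param out_proj Include the output projection (`Wo`, `bo`)?
#' @return Named list of weight matrices and bias vectors.
#' @export
attention_params <- function(C, seed = 1L, sd = 1 / sqrt(C), out_proj = TRUE) {
  withr::with_seed(seed, {
    p <- list(Wq = rnorm_mat(C, C, sd), bq = rep(0, C),
              Wk = rnorm_mat(C, C, sd), bk = rep(0, C),
              Wv = rnorm_mat(C, C, sd), bv = rep(0, C))
    if (out_proj) {
      p$Wo <- rnorm_mat(C, C, sd)
      p$bo <- rep(0, C)
    }
    p
  })
}

# internal: spatial attention on A4 layout, one attention matrix per slice
sa_fw <- function(A4, p, scaled = FALSE) {
  d <- dim(A4)
  Dp <- d[1]; P <- d[2] * d[3]; C <- d[4]
  out <- array(0, d)
  caches <- vector("list", Dp)
  B <- array(A4, c(Dp, P, C))
  Bo <- array(0, c(Dp, P, C))
  for (t in seq_len(Dp)) {
    Xt <- matrix(B[t, , ], P, C)
    cc <- attn_fw(Xt, p, scaled = scaled)
    Bo[t, , ] <- cc$out
    caches[[t]] <- cc
  }
  list(out = array(Bo, d), caches = caches, scaled = scaled)
}

sa_bw <- function(dout, cache, p) {
  d <- dim(dout)
  Dp <- d[1]; P <- d[2] * d[3]; C <- d[4]
  dB <- array(dout, c(Dp, P, C))
  dBin <- array(0, c(Dp, P, C))
  G <- NULL
  for (t in seq_len(Dp)) {
    g <- attn_bw(matrix(dB[t, , ], P, C), cache$caches[[t]], p)
    dBin[t, , ] <- g$dX
    G <- if (is.null(G)) g else plist_axpy(G, g)
  }
  list(dx = array(dBin, d), grads = G[setdiff(names(G), "dX")])
}

# internal: temporal attention, one attention matrix per spatial position
ta_fw <- function(A4, p, scaled = FALSE) {
  d <- dim(A4)
  Dp <- d[1]; P <- d[2] * d[3]; C <- d[4]
  B <- array(A4, c(Dp, P, C))
  Bo <- array(0, c(Dp, P, C))
  caches <- vector("list", P)
  for (j in seq_len(P)) {
    Xp <- matrix(B[, j, ], Dp, C)
    cc <- attn_fw(Xp, p, scaled = scaled)
    Bo[, j, ] <- cc$out
    caches[[j]] <- cc
  }
  list(out = array(Bo, d), caches = caches, scaled = scaled)
}

ta_bw <- function(dout, cache, p) {
  d <- dim(dout)
  Dp <- d[1]; P <- d[2] * d[3]; C <- d[4]
  dB <- array(dout, c(Dp, P, C))
  dBin <- array(0, c(Dp, P, C))
  G <- NULL
  for (j in seq_len(P)) {
    g <- attn_bw(matrix(dB[, j, ], Dp, C), cache$caches[[j]], p)
    dBin[, j, ] <- g$dX
    G <- if (is.null(G)) g else plist_axpy(G, g)
  }
  list(dx = array(dBin, d), grads = G[setdiff(names(G), "dX")])
}

#' Spatial self-attention over the positions of each slice
#'
#' For every slice of the feature map, each position attends over all
#' `H' x W'` positions of the same slice: logits are inner products of the
#' key and query projections, softmax-normalized per query position; the
#' attended values pass through a final 1x1x1 output projection back to
#' `C` channels.
#'
#' @param fm Feature map array `(C, D', H', W')`.
#' @param params An [attention_params()] list with output projection.
#' @param scaled Divide logits by `sqrt(C)`? Default `FALSE` (raw inner
#'   products).
#' @return Feature map of identical shape. The per-slice attention weights
#'   are attached as attribute `"attention"`, an array
#'   `(D', H'W', H'W')` whose rows (third index attended) sum to one.
#' @export
spatial_attention <- function(fm, params, scaled = FALSE) {
  stopifnot(length(dim(fm)) == 4L)
  if (!all(is.finite(fm))) stop("non-finite feature map", call. = FALSE)
  if (ncol(params$Wq) != dim(fm)[1]) {
    stop("projection channel mismatch: params are for C = ",
         ncol(params$Wq), ", feature map has C = ", dim(fm)[1], call. = FALSE)
  }
  A4 <- fm_to_A4(fm)
  r <- sa_fw(A4, params, scaled = scaled)
  out <- A4_to_fm(r$out)
  Dp <- dim(A4)[1]; P <- dim(A4)[2] * dim(A4)[3]
  att <- array(0, c(Dp, P, P))
  for (t in seq_len(Dp)) att[t, , ] <- r$caches[[t]]$A
  attr(out, "attention") <- att
  out
}

#' Temporal self-attention over the slice (depth) axis
#'
#' At every spatial position, each slice attends over all `D'` slices of the
#' volume at that position; the attended values pass through a final 1x1x1
#' output projection. Depth is the "temporal" axis of the volume.
#'
#' @inheritParams spatial_attention
#' @return Feature map of identical shape, with attribute `"attention"`, an
#'   array `(H'W', D', D')` of row-normalized weights.
#' @export
temporal_attention <- function(fm, params, scaled = FALSE) {
  stopifnot(length(dim(fm)) == 4L)
  if (!all(is.finite(fm))) stop("non-finite feature map", call. = FALSE)
  if (ncol(params$Wq) != dim(fm)[1]) {
    stop("projection channel mismatch: params are for C = ",
         ncol(params$Wq), ", feature map has C = ", dim(fm)[1], call. = FALSE)
  }
  A4 <- fm_to_A4(fm)
  r <- ta_fw(A4, params, scaled = scaled)
  out <- A4_to_fm(r$out)
  Dp <- dim(A4)[1]; P <- dim(A4)[2] * dim(A4)[3]
  att <- array(0, c(P, Dp, Dp))
  for (j in seq_len(P)) att[j, , ] <- r$caches[[j]]$A
  attr(out, "attention") <- att
  out
}

#' Sum the spatial- and temporal-attention streams
#'
#' The two intra-modal streams operate on the same feature map in parallel;
#' their outputs with the same slice index are summed elementwise.
#'
#' @param ms,mt Feature maps of identical shape.
#' @return Elementwise sum, attributes dropped.
#' @export
combine_attention_streams <- function(ms, mt) {
  if (!identical(dim(ms), dim(mt))) {
    stop("shape mismatch: ", paste(dim(ms), collapse = "x"), " vs ",
         paste(dim(mt), collapse = "x"), call. = FALSE)
  }
  out <- unclass(ms) + unclass(mt)
  attributes(out) <- list(dim = dim(ms))
  out
}

#' Embed a clinical-record vector into the image channel space
#'
#' A single fully connected layer maps the standardized `F`-vector to one
#' `C`-vector, which is broadcast over every slice and spatial position so
#' the cross-attention encoder can operate on shape-compatible maps. All
#' slices share the same weights (the record is static per subject).
#'
#' @param ehr Numeric vector of length `F`.
#' @param params List with `We` (`F x C`) and `be` (length `C`).
#' @param d_prime,h_prime,w_prime Target feature-map dimensions.
#' @return Array `(D', C, H', W')` of broadcast embeddings.
#' @export
embed_ehr <- function(ehr, params, d_prime, h_prime, w_prime) {
  if (length(ehr) != nrow(params$We)) {
    stop("record has ", length(ehr), " features but weights expect ",
         nrow(params$We), call. = FALSE)
  }
  s <- drop(ehr %*% params$We) + params$be
  C <- length(s)
  out <- array(0, c(d_prime, C, h_prime, w_prime))
  for (c in seq_len(C)) out[, c, , ] <- s[c]
  out
}

#' Bundle per-slice image and record representations
#'
#' @param image_maps,ehr_maps Arrays `(D', C, H', W')` with matching dims.
#' @return A `slice_representations` list.
#' @export
slice_representations <- function(image_maps, ehr_maps) {
  if (!identical(dim(image_maps), dim(ehr_maps))) {
    stop("image and record maps must share (D', C, H', W')", call. = FALSE)
  }
  structure(list(image_maps = image_maps, ehr_maps = ehr_maps),
            class = "slice_representations")
}
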