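# Volumetric feature extraction. A pluggable backbone maps a normalized
# (D, H, W) volume to a channelled feature map on which the attention
# encoders operate. Two desk-scale architectures are registered: a plain
# 3-layer 3D CNN and a residual ("ResNet-shaped") variant. Both reduce
# spatial resolution by 4x and depth by 2x.
#
# Internal feature-map layout: array (D', H', W', C), abbreviated A4. The
# public FeatureMap layout is (C, D', H', W').

backbone_names <- function() c("tiny_cnn", "tiny_resnet")

#' Construct a volumetric backbone
#'
#' @param name Registered architecture: `"tiny_cnn"` (two strided 3x3x3
#'   convolution + ReLU stages) or `"tiny_resnet"` (same trunk with an
#'   additional residual 3x3x3 stage and a projection skip connection).
#' @param channels Output channel count `C`.
#' @param seed Seed for the weight initialization.
#' @return A `backbone` object holding the architecture and its weights.
#' @export
backbone <- function(name = "tiny_cnn", channels = 12L, seed = 1L) {
  if (!name %in% backbone_names()) {
    stop("unknown backbone '", name, "'; registered: ",
         paste(backbone_names(), collapse = ", "), call. = FALSE)
  }
  channels <- as.integer(channels)
  c1 <- max(4L, channels %/% 2L)
  k3 <- 27L
  params <- withr::with_seed(seed, {
    p <- list(
      bb_W1 = rnorm_mat(k3 * 1L, c1, sd = sqrt(2 / k3)),
      bb_b1 = rep(0, c1),
      bb_W2 = rnorm_mat(k3 * c1, channels, sd = sqrt(2 / (k3 * c1))),
      bb_b2 = rep(0, channels)
    )
    if (name == "tiny_resnet") {
      p$bb_W3 <- rnorm_mat(k3 * channels, channels,
                           sd = sqrt(2 / (k3 * channels)))
      p$bb_b3 <- rep(0, channels)
      p$bb_Ws <- rnorm_mat(c1, channels, sd = sqrt(1 / c1))
      p$bb_bs <- rep(0, channels)
    }
    p
  })
  structure(list(name = name, channels = channels, c1 = c1,
                 stride1 = c(2L, 2L, 2L), stride2 = c(1L, 2L, 2L),
                 kernel = c(3L, 3L, 3L), params = params),
            class = "backbone")
}

#' Feature-map shape a backbone will produce for a volume shape
#' @param bb A [backbone()].
#' @param volume_shape Integer `(D, H, W)`.
#' @return Integer `(C, D', H', W')`.
#' @export
backbone_out_shape <- function(bb, volume_shape) {
  g1 <- conv3d_geom(as.integer(volume_shape), bb$kernel, bb$stride1)
  g2 <- conv3d_geom(g1$out, bb$kernel, bb$stride2)
  c(bb$channels, g2$out)
}

# forward to internal A4 layout; keeps caches for backprop
backbone_fw <- function(vol, bb, params = bb$params) {
  x <- array(vol, c(1L, dim(vol)))
  c1f <- conv3d_fw(x, params$bb_W1, params$bb_b1, bb$kernel, bb$stride1)
  r1 <- relu_fw(c1f$out)
  d1 <- c1f$geom$out
  x1 <- aperm(array(r1$out, c(d1, bb$c1)), c(4, 1, 2, 3))
  c2f <- conv3d_fw(x1, params$bb_W2, params$bb_b2, bb$kernel, bb$stride2)
  d2 <- c2f$geom$out
  if (bb$name == "tiny_cnn") {
    r2 <- relu_fw(c2f$out)
    A4 <- array(r2$out, c(d2, bb$channels))
    cache <- list(c1f = c1f, r1 = r1, c2f = c2f, r2 = r2, d1 = d1, d2 = d2)
  } else {
    r2 <- relu_fw(c2f$out)
    x2 <- aperm(array(r2$out, c(d2, bb$channels)), c(4, 1, 2, 3))
    c3f <- conv3d_fw(x2, params$bb_W3, params$bb_b3, bb$kernel, c(1L, 1L, 1L))
    # projection skip from the first stage output, spatially subsampled to d2
    skipin <- array(r1$out, c(d1, bb$c1))
    i1 <- round(seq(1L, d1[1], length.out = d2[1]))
    i2 <- round(seq(1L, d1[2], length.out = d2[2]))
    i3 <- round(seq(1L, d1[3], length.out = d2[3]))
    sub <- skipin[i1, i2, i3, , drop = FALSE]
    submat <- matrix(sub, prod(d2), bb$c1)
    skf <- lin_fw(submat, params$bb_Ws, params$bb_bs)
    r3 <- relu_fw(c3f$out + skf$out)
    A4 <- array(r3$out, c(d2, bb$channels))
    cache <- list(c1f = c1f, r1 = r1, c2f = c2f, r2 = r2, c3f = c3f,
                  skf = skf, r3 = r3, d1 = d1, d2 = d2, sub_dims = dim(sub))
  }
  list(A4 = A4, cache = cache)
}

backbone_bw <- function(dA4, cache, bb, params = bb$params) {
  d2 <- cache$d2; d1 <- cache$d1
  G <- list()
  if (bb$name == "tiny_cnn") {
    dout2 <- relu_bw(matrix(dA4, prod(d2), bb$channels), cache$r2)
    dskip1 <- NULL
  } else {
    dr3 <- relu_bw(matrix(dA4, prod(d2), bb$channels), cache$r3)
    b3 <- conv3d_bw(dr3, cache$c3f, params$bb_W3)
    G$bb_W3 <- b3$dW; G$bb_b3 <- b3$db
    sk <- lin_bw(dr3, cache$skf, params$bb_Ws)
    G$bb_Ws <- sk$dW; G$bb_bs <- sk$db
    # dx of conv3 arrives in (C, d2) layout -> back to matrix rows
    dx2 <- matrix(aperm(b3$dx, c(2, 3, 4, 1)), prod(d2), bb$channels)
    dout2 <- relu_bw(dx2, cache$r2)
    # scatter the skip gradient back into the stage-1 activation grid
    dskip1 <- array(0, c(d1, bb$c1))
    dsub <- array(sk$dX, cache$sub_dims)
    i1 <- round(seq(1L, d1[1], length.out = d2[1]))
    i2 <- round(seq(1L, d1[2], length.out = d2[2]))
    i3 <- round(seq(1L, d1[3], length.out = d2[3]))
    dskip1[i1, i2, i3, ] <- dsub
  }
  b2 <- conv3d_bw(dout2, cache$c2f, params$bb_W2)
  G$bb_W2 <- b2$dW; G$bb_b2 <- b2$db
  dr1mat <- matrix(aperm(b2$dx, c(2, 3, 4, 1)), prod(d1), bb$c1)
  if (!is.null(dskip1)) dr1mat <- dr1mat + matrix(dskip1, prod(d1), bb$c1)
  dr1 <- relu_bw(dr1mat, cache$r1)
  b1 <- conv3d_bw(dr1, cache$c1f, params$bb_W1)
  G$bb_W1 <- b1$dW; G$bb_b1 <- b1$db
  list(dvol = array(b1$dx, dim(b1$dx)[2:4]), grads = G)
}

#' Extract a channelled feature map from a volume
#'
#' Runs the backbone forward pass. The result is the `(C, D', H', W')`
#' feature map on which the spatial and temporal attention encoders operate.
#'
#' @param volume Numeric `(D, H, W)` array with finite values in `[0, 1]`.
#' @param bb A [backbone()].
#' @return Numeric array `(C, D', H', W')` with attribute `"declared_shape"`.
#' @export
extract_feature_maps <- function(volume, bb) {
  if (!all(is.finite(volume))) {
    stop("volume contains non-finite values", call. = FALSE)
  }
  fw <- backbone_fw(volume, bb)
  fm <- aperm(fw$A4, c(4, 1, 2, 3))
  attr(fm, "declared_shape") <- backbone_out_shape(bb, dim(volume))
  fm
}

# conversions between public (C, D', H', W') and internal (D', H', W', C)
fm_to_A4 <- function(fm) aperm(fm, c(2, 3, 4, 1))
A4_to_fm <- function(A4) aperm(A4, c(4, 1, 2, 3))
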