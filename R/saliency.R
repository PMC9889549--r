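# Attention-map export: per-voxel saliency derived from the intra-modal
# attention blocks. Saliency at a feature-map location combines the
# attention mass the location receives (column sums of the attention
# weights) with the magnitude of its value projection -- the mass alone
# says how often a location is attended, the value norm says how much
# signal it contributes when attended; their product localizes salient
# structure robustly where either factor alone does not. Spatial and
# temporal streams are each rescaled to unit mean and summed, then
# trilinearly upsampled to the input resolution and min-max normalized.

# trilinear upsampling of a (d, h, w) array to target dims
upsample_trilinear <- function(x, target) {
  src <- dim(x)
  coord <- function(n_out, n_in) {
    c0 <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(c0, 1), n_in)
  }
  cd <- coord(target[1], src[1])
  ch <- coord(target[2], src[2])
  cw <- coord(target[3], src[3])
  ld <- floor(cd); hd <- pmin(ld + 1, src[1]); wd <- cd - ld
  lh <- floor(ch); hh <- pmin(lh + 1, src[2]); wh <- ch - lh
  lw <- floor(cw); hw <- pmin(lw + 1, src[3]); ww <- cw - lw
  out <- array(0, target)
  for (k in seq_len(target[3])) {
    a <- x[, , lw[k]] * (1 - ww[k]) + x[, , hw[k]] * ww[k]   # (d_src, h_src)
    b <- a[, lh] * rep(1 - wh, each = src[1]) +
      a[, hh] * rep(wh, each = src[1])                       # (d_src, h_out)
    out[, , k] <- b[ld, ] * (1 - wd) + b[hd, ] * wd
  }
  out
}

#' Attention saliency volume of one subject
#'
#' Runs the model forward and scores every feature-map location by the
#' product of the attention mass it receives (column sums of its slice's
#' spatial attention matrix, and of the depth attention at its position)
#' and the magnitude of its value projection in that attention block.
#' The spatial and temporal streams are rescaled to unit mean, summed,
#' upsampled to the input volume's resolution and min-max normalized to
#' `[0, 1]`.
#'
#' @param model A `risk_model` whose configuration has the spatial and/or
#'   temporal attention blocks active.
#' @param volume `(D, H, W)` input volume.
#' @param ehr Clinical feature vector (ignored by image-only models).
#' @return `(D, H, W)` saliency array in `[0, 1]`.
#' @export
attention_saliency <- function(model, volume, ehr = NULL) {
  flags <- model$cfg$flags
  if (model$cfg$variant == "ehr_only") {
    stop("model has no image branch; no attention map to export",
         call. = FALSE)
  }
  if (!isTRUE(flags$SAM) && !isTRUE(flags$TAM)) {
    stop("model has neither spatial nor temporal attention blocks ",
         "(SAM and TAM are both off); no attention weights to export",
         call. = FALSE)
  }
  x <- if (is.null(ehr)) rep(0, model$cfg$n_ehr) else
    apply_scaler(ehr, model$scaler)
  fw <- model_fw(volume, x, model$params, model$cfg, model$bb)
  d3 <- fw$cache$d3
  Dp <- d3[1]; P <- d3[2] * d3[3]
  mass <- matrix(0, Dp, P)
  if (!is.null(fw$cache$sa)) {
    sac <- fw$cache$sa$cache
    sp <- matrix(0, Dp, P)
    for (t in seq_len(Dp)) {
      rows <- ((t - 1L) * P + 1L):(t * P)
      sp[t, ] <- colSums(gattn_A(sac, t)) *
        sqrt(rowSums(sac$V[rows, , drop = FALSE]^2))
    }
    mass <- mass + sp / mean(sp)
  }
  if (!is.null(fw$cache$ta)) {
    tac <- fw$cache$ta$cache
    tp <- matrix(0, Dp, P)
    vn <- matrix(sqrt(rowSums(tac$V^2)), Dp, P)   # rows: t within p blocks
    for (j in seq_len(P)) tp[, j] <- colSums(gattn_A(tac, j)) * vn[, j]
    mass <- mass + tp / mean(tp)
  }
  sal <- upsample_trilinear(array(mass, d3), dim(volume))
  lo <- min(sal); hi <- max(sal)
  if (hi > lo) (sal - lo) / (hi - lo) else array(0.5, dim(volume))
}

# blue -> red colormap on [0, 1], returned as n x 3 RGB
jet_colours <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

write_overlay_png <- function(slice_img, slice_sal, path, alpha = 0.45) {
  v <- (slice_img - min(slice_img)) /
    max(max(slice_img) - min(slice_img), 1e-12)
  col <- jet_colours(as.vector(slice_sal))
  rgb <- array(0, c(dim(v), 3))
  for (ch in 1:3) {
    rgb[, , ch] <- (1 - alpha) * v + alpha * matrix(col[, ch], nrow(v))
  }
  png::writePNG(rgb, path)
  path
}

#' Export an attention map as NIfTI plus orthogonal overlay images
#'
#' Writes the [attention_saliency()] volume of one subject as a gzipped
#' NIfTI file and three PNG overlays (axial, coronal, sagittal mid-slices)
#' in which saliency from 0 to 1 is mapped from blue to red over the
#' grayscale image.
#'
#' @param model A `risk_model` with active attention blocks.
#' @param volume,ehr One subject's inputs.
#' @param out_prefix Path prefix for the outputs
#'   (`<prefix>_saliency.nii.gz`, `<prefix>_axial.png`, ...).
#' @return Invisibly, a character vector of the written paths, with the
#'   saliency array as attribute `"saliency"`.
#' @export
export_attention_map <- function(model, volume, ehr = NULL,
                                 out_prefix = "attention") {
  sal <- attention_saliency(model, volume, ehr)
  d <- dim(volume)
  nii <- paste0(out_prefix, "_saliency.nii.gz")
  RNifti::writeNifti(sal, nii)
  # volume axes are (D, H, W): axial = fixed slice index, coronal = fixed
  # height, sagittal = fixed width
  paths <- c(
    nii,
    write_overlay_png(volume[ceiling(d[1] / 2), , ],
                      sal[ceiling(d[1] / 2), , ],
                      paste0(out_prefix, "_axial.png")),
    write_overlay_png(volume[, ceiling(d[2] / 2), ],
                      sal[, ceiling(d[2] / 2), ],
                      paste0(out_prefix, "_coronal.png")),
    write_overlay_png(volume[, , ceiling(d[3] / 2)],
                      sal[, , ceiling(d[3] / 2)],
                      paste0(out_prefix, "_sagittal.png"))
  )
  attr(paths, "saliency") <- sal
  invisible(paths)
}

#' Plot a saliency mid-slice
#' @param model A `risk_model`.
#' @param volume,ehr One subject's inputs.
#' @param slice Slice index (default middle).
#' @return A ggplot object.
#' @export
plot_saliency <- function(model, volume, ehr = NULL, slice = NULL) {
  sal <- attention_saliency(model, volume, ehr)
  d <- dim(volume)
  t <- slice %||% ceiling(d[1] / 2)
  df <- tidyr::expand_grid(h = seq_len(d[2]), w = seq_len(d[3]))
  df$intensity <- as.vector(volume[t, , ])[
    (df$w - 1L) * d[2] + df$h]
  df$saliency <- as.vector(sal[t, , ])[(df$w - 1L) * d[2] + df$h]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$h)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$saliency), alpha = 0.9) +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Attention saliency, slice %d", t)) +
    ggplot2::theme_minimal()
}
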