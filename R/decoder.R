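# Disease-oriented decoder: a learnable classification query (one row per
# risk class) attends over the fused image matrix M and record matrix S
# through two parallel multi-head attention layers; the two outputs are
# summed, flattened, and mapped by one fully connected layer to K logits.

#' Initialize a classification query
#'
#' One learnable `C`-vector per disease-risk class, refined by the
#' decoder's attention layers. Initialized as small Gaussian noise.
#'
#' @param K Number of classes.
#' @param C Channel count.
#' @param seed Seed.
#' @return Matrix `(K, C)`.
#' @export
class_query <- function(K, C, seed = 1L) {
  withr::with_seed(seed, rnorm_mat(K, C, sd = 0.1))
}

#' Initialize multi-head attention weights
#' @param C Channel count (key/query/value/output projections are `C x C`).
#' @param seed Seed.
#' @return Named list `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @export
mha_params <- function(C, seed = 1L) {
  attention_params(C, seed = seed, sd = 1 / sqrt(C), out_proj = TRUE)
}

#' Multi-head scaled dot-product attention
#'
#' Transformer-style attention: the channel dimension is split into
#' `n_heads` slices; each head attends with logits scaled by the inverse
#' square root of the head dimension, and the concatenated head outputs
#' pass through the output projection.
#'
#' @param query Matrix `(K, C)`.
#' @param keys,values Matrices `(T, C)` (row count may differ from the
#'   query's).
#' @param n_heads Number of heads; must divide `C`.
#' @param params An [mha_params()] list.
#' @return Matrix `(K, C)`.
#' @export
multi_head_attention <- function(query, keys, values, n_heads, params) {
  if (n_heads < 1L) stop("n_heads must be >= 1", call. = FALSE)
  mha_fw(query, keys, values, params, as.integer(n_heads))$out
}

#' Decode a fused representation into class probabilities
#'
#' Computes `MHA(X_d, M, M) + MHA(X_d, S, S)` with two independently
#' parameterized attention layers, flattens the `(K, C)` sum, and applies
#' the fully connected layer. Probabilities are the softmax of the logits.
#'
#' @param fused A `fused_representation` (list with `M` and `S`, each
#'   `(D', C)`) from [compress()].
#' @param X_d Classification query `(K, C)` from [class_query()].
#' @param params List with `d1` and `d2` ([mha_params()] lists), `fc_W`
#'   (`K*C x K`) and `fc_b` (length `K`).
#' @param n_heads Head count (default 6).
#' @return A `prediction` list with `probs` and `logits`, each length `K`.
#' @export
decode <- function(fused, X_d, params, n_heads = 6L) {
  K <- nrow(X_d); C <- ncol(X_d)
  if (nrow(params$fc_W) != K * C || ncol(params$fc_W) != K) {
    stop("fully connected layer expects ", K, " classes x ", C,
         " channels; got ", paste(dim(params$fc_W), collapse = "x"),
         call. = FALSE)
  }
  o1 <- mha_fw(X_d, fused$M, fused$M, params$d1, as.integer(n_heads))$out
  o2 <- mha_fw(X_d, fused$S, fused$S, params$d2, as.integer(n_heads))$out
  out <- o1 + o2
  logits <- drop(as.vector(out) %*% params$fc_W) + params$fc_b
  probs <- drop(softmax_rows(matrix(logits, 1L)))
  structure(list(probs = probs, logits = logits), class = "prediction")
}

#' Cross-entropy loss
#'
#' Negative log-probability of the true class; the training criterion.
#' For a probability matrix and a label vector the mean over samples is
#' returned.
#'
#' @param pred A `prediction` from [decode()], a probability vector, or a
#'   matrix of per-sample probability rows.
#' @param label Integer class label(s) in `[0, K)`.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, label) {
  probs <- if (inherits(pred, "prediction")) pred$probs else pred
  if (is.matrix(probs)) {
    K <- ncol(probs)
    if (any(label < 0L | label >= K)) {
      stop("labels must lie in [0, ", K, ")", call. = FALSE)
    }
    p <- probs[cbind(seq_len(nrow(probs)), label + 1L)]
    return(mean(-log(p)))
  }
  K <- length(probs)
  if (length(label) != 1L || label < 0L || label >= K) {
    stop("label must be a single integer in [0, ", K, ")", call. = FALSE)
  }
  -log(probs[label + 1L])
}
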