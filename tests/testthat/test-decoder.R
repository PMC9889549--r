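test_that("single-head attention over one key returns its value row", {
  C <- 4
  p <- list(Wq = diag(C), bq = rep(0, C), Wk = diag(C), bk = rep(0, C),
            Wv = diag(C), bv = rep(0, C), Wo = diag(C), bo = rep(0, C))
  query <- matrix(rnorm(2 * C), 2, C)
  kv <- matrix(rnorm(C), 1, C)
  out <- multi_head_attention(query, kv, kv, 1, p)
  expect_equal(out, rbind(kv, kv)[1:2, , drop = FALSE], tolerance = 1e-12)
})

test_that("multi-head attention matches the per-head loop oracle", {
  for (case in 1:4) {
    set.seed(400 + case)
    C <- 8; Kq <- 3; Tn <- sample(2:5, 1)
    p <- rand_attn_params(C, seed = 50 + case)
    query <- matrix(rnorm(Kq * C), Kq, C)
    keys <- matrix(rnorm(Tn * C), Tn, C)
    values <- matrix(rnorm(Tn * C), Tn, C)
    for (h in c(1, 2, 4)) {
      expect_lte(max(abs(multi_head_attention(query, keys, values, h, p) -
                           oracle_mha(query, keys, values, p, h))), 1e-5)
    }
  }
})

test_that("duplicating every key/value row leaves the output unchanged", {
  set.seed(51)
  C <- 4
  p <- rand_attn_params(C, seed = 51)
  query <- matrix(rnorm(2 * C), 2, C)
  keys <- matrix(rnorm(3 * C), 3, C)
  values <- matrix(rnorm(3 * C), 3, C)
  a <- multi_head_attention(query, keys, values, 2, p)
  b <- multi_head_attention(query, keys[rep(1:3, 2), ],
                            values[rep(1:3, 2), ], 2, p)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("invalid head counts raise a configuration error naming both", {
  p <- rand_attn_params(6, seed = 52)
  q <- matrix(0, 2, 6)
  expect_error(multi_head_attention(q, q, q, 4, p), "C = 6.*n_heads = 4")
  expect_error(multi_head_attention(q, q, q, 0, p), ">= 1")
})

decode_params <- function(K, C, seed = 1, zero_out = FALSE) {
  set.seed(seed)
  p <- list(d1 = rand_attn_params(C, seed = seed + 1),
            d2 = rand_attn_params(C, seed = seed + 2),
            fc_W = matrix(rnorm(K * C * K, sd = 0.3), K * C, K),
            fc_b = rnorm(K, sd = 0.2))
  if (zero_out) {
    p$d1$Wo[] <- 0; p$d1$bo[] <- 0
    p$d2$Wo[] <- 0; p$d2$bo[] <- 0
  }
  p
}

test_that("zeroed attention output projections reduce decode to the bias", {
  K <- 3; C <- 4
  p <- decode_params(K, C, seed = 60, zero_out = TRUE)
  fused <- list(M = matrix(0, 2, C), S = matrix(0, 2, C))
  pred <- decode(fused, class_query(K, C, seed = 1), p, n_heads = 2)
  expect_equal(pred$logits, p$fc_b, tolerance = 1e-12)
  expect_equal(pred$probs, naive_softmax(p$fc_b), tolerance = 1e-12)
})

test_that("decoded probabilities always sum to one", {
  set.seed(61)
  for (r in 1:5) {
    K <- sample(2:4, 1); C <- 4
    p <- decode_params(K, C, seed = 60 + r)
    fused <- list(M = matrix(rnorm(3 * C), 3, C),
                  S = matrix(rnorm(3 * C), 3, C))
    pred <- decode(fused, class_query(K, C, seed = r), p, n_heads = 2)
    expect_lte(abs(sum(pred$probs) - 1), 1e-6)
    expect_true(all(pred$probs >= 0))
  }
})

test_that("decode is symmetric in the modalities when both layers share weights", {
  K <- 2; C <- 4
  p <- decode_params(K, C, seed = 70)
  p$d2 <- p$d1
  fused <- list(M = matrix(rnorm(3 * C), 3, C),
                S = matrix(rnorm(3 * C), 3, C))
  swapped <- list(M = fused$S, S = fused$M)
  Xd <- class_query(K, C, seed = 2)
  expect_equal(decode(fused, Xd, p, 2)$probs,
               decode(swapped, Xd, p, 2)$probs, tolerance = 1e-12)
})

test_that("decode is permutation-covariant in the class dimension", {
  K <- 3; C <- 4
  p <- decode_params(K, C, seed = 80)
  Xd <- class_query(K, C, seed = 3)
  fused <- list(M = matrix(rnorm(2 * C), 2, C),
                S = matrix(rnorm(2 * C), 2, C))
  perm <- c(3, 1, 2)
  # permute the query rows, the FC input blocks, and the FC output units
  blocks <- rep(perm, C) + K * rep(seq_len(C) - 1, each = K)
  p2 <- p
  p2$fc_W <- p$fc_W[blocks, perm]
  p2$fc_b <- p$fc_b[perm]
  a <- decode(fused, Xd, p, 2)
  b <- decode(fused, Xd[perm, ], p2, 2)
  expect_equal(b$probs, a$probs[perm], tolerance = 1e-10)
})

test_that("cross-entropy agrees with its closed forms and batch reduction", {
  expect_equal(cross_entropy_loss(c(0, 1, 0), 1L), 0)
  expect_equal(cross_entropy_loss(rep(1 / 3, 3), 2L), log(3),
               tolerance = 1e-12)
  set.seed(90)
  P <- t(apply(matrix(runif(15), 5, 3), 1, function(z) z / sum(z)))
  y <- sample(0:2, 5, replace = TRUE)
  manual <- mean(sapply(1:5, function(i) -log(P[i, y[i] + 1])))
  expect_lte(abs(cross_entropy_loss(P, y) - manual), 1e-7)
  expect_error(cross_entropy_loss(c(0.5, 0.5), 2L), "label")
})
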