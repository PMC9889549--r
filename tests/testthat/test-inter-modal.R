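test_that("affinity with orthogonal queries gives uniform candidate weights", {
  q <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  k <- array(0, c(3, 2, 2))   # all inner products zero
  A <- affinity(q, k)
  off <- A[!diag(4) > 0]
  expect_equal(off, rep(1 / 3, 12), tolerance = 1e-12)
  expect_true(all(diag(A) == 0))
})

test_that("affinity matches the per-position loop oracle", {
  for (case in 1:5) {
    set.seed(300 + case)
    hp <- sample(2:3, 1); wp <- sample(2:3, 1)
    q <- array(rnorm(3 * hp * wp), c(3, hp, wp))
    k <- array(rnorm(3 * hp * wp), c(3, hp, wp))
    A <- affinity(q, k)
    expect_lte(max(abs(A - oracle_affinity(q, k))), 1e-5)
    expect_lte(max(abs(rowSums(A) - 1)), 1e-5)
    Ai <- affinity(q, k, mode = "include_self")
    expect_lte(max(abs(Ai - oracle_affinity(q, k, include_self = TRUE))),
               1e-5)
  }
})

test_that("sharpening the keys monotonically concentrates each row", {
  set.seed(31)
  q <- array(rnorm(12), c(3, 2, 2))
  k <- array(rnorm(12), c(3, 2, 2))
  prev <- rep(0, 4)
  for (scale in c(0.5, 1, 2, 4, 8)) {
    A <- affinity(q, k * scale)
    mx <- apply(A, 1, max)
    expect_true(all(mx >= prev - 1e-12))
    prev <- mx
  }
})

test_that("degenerate 1x1 grids demand self-inclusion", {
  q <- array(1, c(2, 1, 1))
  expect_error(affinity(q, q), "include_self")
  A <- affinity(q, q, mode = "include_self")
  expect_equal(A, matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("aggregation is residual plus weighted candidate values", {
  set.seed(32)
  v <- array(rnorm(12), c(3, 2, 2))
  h <- array(rnorm(12), c(3, 2, 2))
  # all-zero pre-softmax bypass returns the residual exactly
  expect_identical(aggregate(matrix(0, 4, 4), v, h), h)
  # one-hot rows select a single candidate value
  A1 <- matrix(0, 4, 4); A1[, 2] <- 1
  out <- aggregate(A1, v, h)
  V <- matrix(v, 3, 4)
  for (j in 1:4) {
    expect_equal(out[, (j - 1) %% 2 + 1, (j - 1) %/% 2 + 1],
                 V[, 2] + matrix(h, 3, 4)[, j])
  }
  # random affinities match the loop oracle
  set.seed(33)
  q <- array(rnorm(12), c(3, 2, 2)); k <- array(rnorm(12), c(3, 2, 2))
  A <- affinity(q, k)
  expect_lte(max(abs(aggregate(A, v, h) - oracle_aggregate(A, v, h))), 1e-5)
  # unnormalized rows are rejected
  expect_error(aggregate(matrix(0.3, 4, 4), v, h), "sum to 1")
})

test_that("cross-attention on broadcast records reduces to uniform pooling", {
  set.seed(34)
  C <- 3; Dp <- 2; Hp <- 2; Wp <- 2
  img <- array(rnorm(Dp * C * Hp * Wp), c(Dp, C, Hp, Wp))
  svec <- rnorm(C)
  ehr <- array(0, c(Dp, C, Hp, Wp))
  for (cc in seq_len(C)) ehr[, cc, , ] <- svec[cc]
  reps <- slice_representations(img, ehr)
  p <- list(m = rand_attn_params(C, seed = 35, out_proj = FALSE),
            s = rand_attn_params(C, seed = 36, out_proj = FALSE))
  out <- cross_attention_block(reps, 1, p)
  # image-query direction: keys are constant across positions, so every
  # candidate weight is uniform and the update is V(s) plus the residual
  vs <- drop(t(p$m$Wv) %*% svec + p$m$bv)
  Mt <- matrix(aperm(array(img[1, , , ], c(C, Hp, Wp)), c(2, 3, 1)),
               Hp * Wp, C)
  expect_equal(matrix(aperm(out$M_prime, c(2, 3, 1)), Hp * Wp, C),
               sweep(Mt, 2, vs, `+`), tolerance = 1e-10)
  # record-query direction agrees with the explicit affinity + aggregation
  q_map <- array(t(t(matrix(ehr[1, , , ], C, Hp * Wp)) %*% p$s$Wq +
                   matrix(p$s$bq, Hp * Wp, C, byrow = TRUE)) , c(C, Hp, Wp))
  k_map <- array(t(t(matrix(img[1, , , ], C, Hp * Wp)) %*% p$s$Wk +
                   matrix(p$s$bk, Hp * Wp, C, byrow = TRUE)), c(C, Hp, Wp))
  v_map <- array(t(t(matrix(img[1, , , ], C, Hp * Wp)) %*% p$s$Wv +
                   matrix(p$s$bv, Hp * Wp, C, byrow = TRUE)), c(C, Hp, Wp))
  h_map <- array(ehr[1, , , ], c(C, Hp, Wp))
  expected_S <- aggregate(affinity(q_map, k_map), v_map, h_map)
  expect_equal(out$S_prime, expected_S, tolerance = 1e-8)
})

test_that("zero value projections make cross-attention residual-only", {
  set.seed(37)
  C <- 3
  img <- array(rnorm(2 * C * 4), c(2, C, 2, 2))
  ehr <- array(rnorm(2 * C * 4), c(2, C, 2, 2))
  p <- list(m = rand_attn_params(C, seed = 38, out_proj = FALSE),
            s = rand_attn_params(C, seed = 39, out_proj = FALSE))
  p$m$Wv[] <- 0; p$m$bv[] <- 0
  p$s$Wv[] <- 0; p$s$bv[] <- 0
  out <- cross_attention_block(slice_representations(img, ehr), 2, p)
  expect_equal(out$M_prime, array(img[2, , , ], c(C, 2, 2)),
               tolerance = 1e-12)
  expect_equal(out$S_prime, array(ehr[2, , , ], c(C, 2, 2)),
               tolerance = 1e-12)
})

test_that("swapping modalities with mirrored weights swaps the outputs", {
  set.seed(40)
  C <- 3
  a <- array(rnorm(1 * C * 4), c(1, C, 2, 2))
  b <- array(rnorm(1 * C * 4), c(1, C, 2, 2))
  pm <- rand_attn_params(C, seed = 41, out_proj = FALSE)
  ps <- rand_attn_params(C, seed = 42, out_proj = FALSE)
  o1 <- cross_attention_block(slice_representations(a, b), 1,
                              list(m = pm, s = ps))
  o2 <- cross_attention_block(slice_representations(b, a), 1,
                              list(m = ps, s = pm))
  expect_equal(o1$M_prime, o2$S_prime, tolerance = 1e-12)
  expect_equal(o1$S_prime, o2$M_prime, tolerance = 1e-12)
})

test_that("compression pools each slice to its spatial mean", {
  m1 <- array(2.5, c(3, 2, 2))
  out <- compress(list(m1), list(m1))
  expect_equal(out$M, matrix(2.5, 1, 3), ignore_attr = TRUE)

  set.seed(43)
  ms <- lapply(1:3, function(i) array(rnorm(4 * 2 * 2), c(4, 2, 2)))
  ss <- lapply(1:3, function(i) array(rnorm(4 * 2 * 2), c(4, 2, 2)))
  fused <- compress(ms, ss)
  expect_identical(dim(fused$M), c(3L, 4L))
  for (t in 1:3) for (cc in 1:4) {
    expect_equal(fused$M[t, cc], mean(ms[[t]][cc, , ]), tolerance = 1e-6)
    expect_equal(fused$S[t, cc], mean(ss[[t]][cc, , ]), tolerance = 1e-6)
  }
  expect_error(compress(list(), list()), "no slices")
})
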