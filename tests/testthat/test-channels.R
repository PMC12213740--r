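# Attention and convolution feature channels against brute-force oracles.

test_that("scaled attention handles degenerate visibility patterns", {
  Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(6), 3, 2)
  V <- matrix(rnorm(6), 3, 2)
  # single visible position: output equals its value row
  out <- scaled_attention(Q, K, V, c(0L, 1L, 0L))
  for (i in 1:3) expect_equal(out[i, ], V[2, ])
  # all scores equal: output is the mean of visible value rows
  out2 <- scaled_attention(matrix(0, 3, 2), K, V, c(1L, 1L, 0L))
  for (i in 1:3) expect_equal(out2[i, ], colMeans(V[1:2, ]))
  expect_error(scaled_attention(Q, K, V, c(0L, 0L, 0L)), "no visible")
})

test_that("scaled attention matches the loop oracle on 200 random instances", {
  set.seed(101)
  worst <- 0
  for (r in 1:200) {
    L <- sample(2:6, 1); dk <- sample(1:4, 1); dv <- sample(1:4, 1)
    Q <- matrix(rnorm(L * dk), L, dk); K <- matrix(rnorm(L * dk), L, dk)
    V <- matrix(rnorm(L * dv), L, dv)
    vis <- integer(L); vis[sample(L, sample(L, 1))] <- 1L
    worst <- max(worst, max(abs(scaled_attention(Q, K, V, vis) -
                                oracle_attention(Q, K, V, vis))))
  }
  expect_lt(worst, 1e-6)
})

test_that("attention weights over visible positions sum to one", {
  set.seed(55)
  for (r in 1:50) {
    L <- sample(2:8, 1)
    Q <- matrix(rnorm(L * 3), L, 3); K <- matrix(rnorm(L * 3), L, 3)
    vis <- integer(L); vis[sample(L, sample(L, 1))] <- 1L
    A <- triagefuse:::attn_fwd(Q, K, matrix(rnorm(L * 2), L, 2), vis)$A
    expect_equal(rowSums(A), rep(1, L), tolerance = 1e-6)
    expect_true(all(A[, vis == 0L] == 0))
  }
})

test_that("multi-head attention equals the per-head oracle", {
  d <- 4L
  p <- init_attention_params(d, 2L, triagefuse:::local_rng(7))
  X <- matrix(rnorm(5 * d), 5, d)
  vis <- c(1L, 1L, 1L, 0L, 1L)
  expect_equal(multi_head(X, p, vis), oracle_multi_head(X, p, vis),
               tolerance = 1e-10)

  # h = 1 with identity output projection degenerates to scaled attention
  p1 <- init_attention_params(d, 1L, triagefuse:::local_rng(8))
  p1$Wo <- diag(d)
  expect_equal(multi_head(X, p1, vis),
               scaled_attention(X %*% p1$Wq, X %*% p1$Wk, X %*% p1$Wv, vis),
               tolerance = 1e-12)
})

test_that("permuting heads with a matching output-row permutation is invariant", {
  d <- 6L; h <- 3L; dh <- d %/% h
  p <- init_attention_params(d, h, triagefuse:::local_rng(9))
  X <- matrix(rnorm(4 * d), 4, d)
  vis <- rep(1L, 4)
  base <- multi_head(X, p, vis)
  perm <- c(3L, 1L, 2L)
  cols <- unlist(lapply(perm, function(i) ((i - 1L) * dh + 1L):(i * dh)))
  p2 <- list(Wq = p$Wq[, cols], Wk = p$Wk[, cols], Wv = p$Wv[, cols],
             Wo = p$Wo[cols, ], h = h)
  expect_equal(multi_head(X, p2, vis), base, tolerance = 1e-12)
})

test_that("the attention channel pools only visible positions", {
  d <- 4L
  p <- init_attention_params(d, 2L, triagefuse:::local_rng(10))
  T1 <- matrix(rnorm(3 * d), 3, d)
  # L = 1 visible: pooled output equals that position's vector
  one <- mha_channel(T1, p, c(1L, 0L, 0L))
  mh <- multi_head(T1, p, c(1L, 0L, 0L))
  expect_equal(drop(one), mh[1, ])
  # identical samples up to pad count pool identically
  T2 <- rbind(T1, matrix(rnorm(2 * d), 2, d))
  a <- mha_channel(T1, p, c(1L, 1L, 1L))
  b <- mha_channel(T2, p, c(1L, 1L, 1L, 0L, 0L))
  expect_equal(a, b, tolerance = 1e-12)
  # pool-by-hand on a toy instance
  full <- multi_head(T1, p, c(1L, 1L, 1L))
  expect_equal(drop(mha_channel(T1, p, c(1L, 1L, 1L))),
               (full[1, ] + full[2, ] + full[3, ]) / 3, tolerance = 1e-12)
})

test_that("the convolutional channel matches the sliding-window oracle", {
  set.seed(77)
  d <- 3L
  params <- init_cnn_params(d, widths = c(2L, 3L), filters = 2L,
                            triagefuse:::local_rng(12), init_sd = 0.5)
  for (r in 1:50) {
    L <- sample(3:7, 1)
    T_mat <- matrix(rnorm(L * d), L, d)
    vis <- integer(L); vis[sample(L, sample(L, 1))] <- 1L
    expect_equal(drop(cnn_channel(T_mat, params, vis)),
                 oracle_cnn(T_mat, params, vis), tolerance = 1e-6)
  }
})

test_that("convolution output width and edge cases follow the construction", {
  d <- 4L
  p <- init_cnn_params(d, widths = c(3L, 4L, 5L), filters = 100L,
                       triagefuse:::local_rng(13))
  T_mat <- matrix(rnorm(8 * d), 8, d)
  expect_length(drop(cnn_channel(T_mat, p, rep(1L, 8))), 300L)

  pz <- init_cnn_params(d, widths = 2L, filters = 3L)
  pz$kernels$w2$K[] <- 0; pz$kernels$w2$b[] <- 0
  expect_equal(drop(cnn_channel(T_mat, pz, rep(1L, 8))), rep(0, 3))

  expect_error(cnn_channel(matrix(0, 2, d), p, rep(1L, 2)), "widest kernel")

  # single width-2 kernel on a 3-token toy: max of two window scores
  p1 <- init_cnn_params(2L, widths = 2L, filters = 1L,
                        triagefuse:::local_rng(14), init_sd = 1)
  T3 <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  Kk <- matrix(p1$kernels$w2$K[, 1], 2, 2, byrow = TRUE)
  s1 <- sum(Kk * T3[1:2, ]); s2 <- sum(Kk * T3[2:3, ])
  expect_equal(drop(cnn_channel(T3, p1, rep(1L, 3))),
               max(max(s1, 0), max(s2, 0)))
})

test_that("fully-masked positions beyond visible windows cannot change the output", {
  d <- 3L
  p <- init_cnn_params(d, widths = 2L, filters = 4L,
                       triagefuse:::local_rng(15))
  T_mat <- matrix(rnorm(6 * d), 6, d)
  vis <- c(1L, 1L, 1L, 0L, 0L, 0L)
  base <- cnn_channel(T_mat, p, vis)
  T_alt <- T_mat
  T_alt[5:6, ] <- rnorm(2 * d) * 10   # beyond any window touching a visible token
  expect_equal(cnn_channel(T_alt, p, vis), base)
})

test_that("channel projection is an exact affine map", {
  pr <- init_projection_params(3L, 4L, 3L, triagefuse:::local_rng(16))
  om <- matrix(rnorm(6), 2, 3); oc <- matrix(rnorm(8), 2, 4)
  ch <- project_channels(om, oc, pr)
  expect_equal(ch$out_mha, om %*% pr$Pm + rep(pr$bm, each = 2))
  expect_equal(ch$out_cnn, oc %*% pr$Pc + rep(pr$bc, each = 2))
  # identity projection passes the attention channel through
  pr2 <- pr; pr2$Pm <- diag(3); pr2$bm <- rep(0, 3)
  expect_equal(project_channels(om, oc, pr2)$out_mha, om)
  # zero projections zero both outputs
  pr3 <- pr; pr3$Pm[] <- 0; pr3$bm[] <- 0; pr3$Pc[] <- 0; pr3$bc[] <- 0
  ch3 <- project_channels(om, oc, pr3)
  expect_true(all(ch3$out_mha == 0) && all(ch3$out_cnn == 0))
})
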