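# Correlation channels, squeeze/fuse/gate recalibration, attention blocks.

block1 <- function(params) ddgatt:::block_params(params, 1L)

test_that("channel biases are functions of the pair descriptors only", {
  cfg <- test_config()
  s <- fixture_samples(1L)[[1]]
  fx <- fixture_feats(s, cfg)
  params <- init_params(cfg, 3L)
  alpha <- channel_biases(fx$feats, block1(params))
  n <- cfg$n_max
  expect_equal(dim(alpha), c(3L, cfg$H, n, n))

  # identical (D, contact, seqsep, pairtype) inputs -> identical entries:
  # craft a bundle where pairs (1,2) and (3,4) share all descriptors
  f2 <- fx$feats
  idx <- function(i, j) (j - 1L) * n + i
  for (fld in c("contact_code", "seqsep_code", "pairtype_code")) {
    f2[[fld]][idx(3, 4)] <- f2[[fld]][idx(1, 2)]
  }
  f2$rbf[idx(3, 4), ] <- f2$rbf[idx(1, 2), ]
  a2 <- channel_biases(f2, block1(params))
  expect_equal(a2[, , 3, 4], a2[, , 1, 2])

  # padding pairs carry zero in every channel
  pad <- which(!fx$feats$mask)
  if (length(pad)) expect_true(all(alpha[, , , pad] == 0))
})

test_that("channel biases permute consistently with residue permutation", {
  cfg <- test_config(n_max = 10L)
  x <- make_toy_complex(toy_spec(n_per_chain = 5L, seed = 31L))
  prov <- mock_embedding_provider(cfg$embed_dim, 0L)
  sel <- select_residues(x, list(fixture_mutation(x, 2L)), 10L)
  f <- ddgatt:::build_features(x, sel, prov, cfg)
  params <- init_params(cfg, 5L)
  alpha <- channel_biases(f, block1(params))

  perm <- sample(10L)
  f2 <- f
  n <- 10L
  pidx <- as.vector(outer(perm, (perm - 1L) * n, "+"))
  f2$rbf <- f$rbf[pidx, , drop = FALSE]
  f2$contact_code <- f$contact_code[pidx]
  f2$seqsep_code <- f$seqsep_code[pidx]
  f2$pairtype_code <- f$pairtype_code[pidx]
  f2$pairvalid <- f$pairvalid[pidx]
  a2 <- channel_biases(f2, block1(params))
  for (c in 1:3) for (h in seq_len(cfg$H))
    expect_equal(a2[c, h, , ], alpha[c, h, perm, perm])
})

test_that("squeeze matches hand arithmetic and brute force", {
  alpha <- array(1, c(3, 2, 4, 4))          # all ones, H = 2, n = 4
  z <- proteo_squeeze(alpha)
  expect_equal(z, matrix(8, 3, 4))          # 4 residues x 2 heads = 8

  expect_equal(proteo_squeeze(array(0, c(3, 2, 5, 5))), matrix(0, 3, 5))

  set.seed(1)
  a <- array(rnorm(3 * 2 * 5 * 5), c(3, 2, 5, 5))
  z2 <- proteo_squeeze(a)
  ref <- matrix(0, 3, 5)
  for (c in 1:3) for (j in 1:5)
    for (i in 1:5) for (h in 1:2) ref[c, j] <- ref[c, j] + a[c, h, i, j]
  expect_lt(max(abs(z2 - ref)), 1e-6)
})

test_that("fusion is row-stochastic and matches a dense reference", {
  set.seed(7)
  n <- 6L; Hz <- 2L; Dkz <- 4L
  bp <- list(Wq = matrix(rnorm(n * Hz * Dkz), n),
             Wk = matrix(rnorm(n * Hz * Dkz), n),
             Wv = matrix(rnorm(n * Hz * Dkz), n))
  z <- matrix(rnorm(3 * n), 3, n)
  fused <- proteo_fuse(z, bp, Hz, Dkz)
  expect_equal(dim(fused), c(3L, Hz * Dkz))

  ref <- matrix(0, 3, 0)
  for (h in seq_len(Hz)) {
    cols <- (h - 1) * Dkz + seq_len(Dkz)
    Q <- z %*% bp$Wq[, cols]; K <- z %*% bp$Wk[, cols]; V <- z %*% bp$Wv[, cols]
    L <- Q %*% t(K) / sqrt(Dkz)
    P <- exp(L - apply(L, 1, max)); P <- P / rowSums(P)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
    ref <- cbind(ref, P %*% V)
  }
  expect_lt(max(abs(fused - ref)), 1e-6)
})

test_that("single-token fusion degenerates to the value projection", {
  set.seed(8)
  n <- 5L; Hz <- 2L; Dkz <- 3L
  bp <- list(Wq = matrix(rnorm(n * Hz * Dkz), n),
             Wk = matrix(rnorm(n * Hz * Dkz), n),
             Wv = matrix(rnorm(n * Hz * Dkz), n))
  z1 <- matrix(rnorm(n), 1, n)
  expect_lt(max(abs(proteo_fuse(z1, bp, Hz, Dkz) - z1 %*% bp$Wv)), 1e-9)
})

test_that("gates are strictly positive with the zero-weight closed form", {
  n <- 8L; Hz <- 2L; Dkz <- 4L
  bp0 <- list(W1 = matrix(0, Hz * Dkz, n), W2 = matrix(0, n, 1))
  s0 <- proteo_gate(matrix(rnorm(3 * Hz * Dkz), 3), bp0)
  expect_equal(s0, rep(log(2), 3), tolerance = 1e-9)

  set.seed(9)
  for (r in 1:200) {
    bp <- list(W1 = matrix(rnorm(Hz * Dkz * n, 0, 2), Hz * Dkz, n),
               W2 = matrix(rnorm(n, 0, 2), n, 1))
    s <- proteo_gate(matrix(rnorm(3 * Hz * Dkz, 0, 3), 3), bp)
    expect_true(all(s > 0))
  }

  # monotone in the pre-softplus scalar: scale W2 upward on a positive path
  fused <- matrix(abs(rnorm(3 * Hz * Dkz)), 3)
  bp_pos <- list(W1 = matrix(abs(rnorm(Hz * Dkz * n)), Hz * Dkz, n),
                 W2 = matrix(abs(rnorm(n)), n, 1))
  s1 <- proteo_gate(fused, bp_pos)
  bp_pos2 <- bp_pos; bp_pos2$W2 <- bp_pos$W2 * 2
  expect_true(all(proteo_gate(fused, bp_pos2) > s1))
})

test_that("recalibration matches hand computation and the baseline limit", {
  alpha <- array(0, c(3, 1, 1, 1))
  alpha[1, 1, 1, 1] <- 2; alpha[2, 1, 1, 1] <- 3; alpha[3, 1, 1, 1] <- 5
  A <- recalibrate_channels(alpha, s = c(2, 0 + 1e-300, 1))
  # sigmoid(~0) = 0.5: 2*2 - 0.5*3 + 1*5 = 7.5
  expect_equal(as.numeric(A), 7.5, tolerance = 1e-9)

  # s2 -> +inf recovers the unweighted a1 - a2 + a3 combination
  A40 <- recalibrate_channels(alpha, s = c(1, 40, 1))
  expect_equal(as.numeric(A40), 2 - 3 + 5, tolerance = 1e-6)

  # coefficient ranges: contact coefficient in (0,1), others positive
  expect_error(recalibrate_channels(alpha, s = c(-1, 1, 1)))
  s2 <- 5
  expect_true(1 / (1 + exp(-s2)) > 0 && 1 / (1 + exp(-s2)) < 1)

  # padding keys receive the additive mask
  alpha2 <- array(rnorm(3 * 2 * 4 * 4), c(3, 2, 4, 4))
  Am <- recalibrate_channels(alpha2, s = c(1, 1, 1),
                             mask = c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(Am[, , 4] == -Inf))
  expect_true(all(is.finite(Am[, , 1:3])))
})

test_that("attention blocks average uniformly under zero bias and mask keys", {
  set.seed(11)
  n <- 4L; d <- 8L; H <- 2L
  bp <- list(Wv_a = matrix(rnorm(d * d, 0, 0.3), d), bv = rnorm(d),
             Wo = matrix(rnorm(d * d, 0, 0.3), d), bo = rnorm(d),
             Wf1 = matrix(rnorm(d * 2 * d, 0, 0.3), d), bf1 = rnorm(2 * d),
             Wf2 = matrix(rnorm(2 * d * d, 0, 0.3), 2 * d), bf2 = rnorm(d))
  nodes <- matrix(rnorm(n * d), n, d)
  A0 <- array(0, c(H, n, n))
  out <- attention_block(nodes, A0, bp)
  # uniform attention: the attended value is the same mean vector per row,
  # so differences between output rows come only from the residual stream
  Va <- nodes %*% bp$Wv_a + rep(bp$bv, each = n)
  meanV <- matrix(colMeans(Va), n, d, byrow = TRUE)
  X2 <- nodes + (meanV %*% bp$Wo + rep(bp$bo, each = n))
  ref <- X2 + (pmax(X2 %*% bp$Wf1 + rep(bp$bf1, each = n), 0) %*% bp$Wf2 +
                 rep(bp$bf2, each = n))
  expect_lt(max(abs(out - ref)), 1e-6)

  # masked keys get zero attention weight from valid queries
  Am <- array(rnorm(H * n * n), c(H, n, n))
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  Am[, , 4] <- -Inf
  out_m <- attention_block(nodes, Am, bp, mask)
  expect_true(all(is.finite(out_m)))
  expect_true(all(out_m[4, ] == 0))
})

test_that("attention block matches a loop-based reference implementation", {
  set.seed(12)
  n <- 5L; d <- 8L; H <- 2L; dh <- d / H
  bp <- list(Wv_a = matrix(rnorm(d * d, 0, 0.4), d), bv = rnorm(d),
             Wo = matrix(rnorm(d * d, 0, 0.4), d), bo = rnorm(d),
             Wf1 = matrix(rnorm(d * 2 * d, 0, 0.4), d), bf1 = rnorm(2 * d),
             Wf2 = matrix(rnorm(2 * d * d, 0, 0.4), 2 * d), bf2 = rnorm(d))
  nodes <- matrix(rnorm(n * d), n, d)
  A <- array(rnorm(H * n * n), c(H, n, n))
  out <- attention_block(nodes, A, bp)

  Va <- nodes %*% bp$Wv_a + rep(bp$bv, each = n)
  att <- matrix(0, n, d)
  for (h in seq_len(H)) {
    L <- A[h, , ]
    P <- exp(L - apply(L, 1, max)); P <- P / rowSums(P)
    att[, (h - 1) * dh + seq_len(dh)] <- P %*% Va[, (h - 1) * dh + seq_len(dh)]
  }
  X2 <- nodes + (att %*% bp$Wo + rep(bp$bo, each = n))
  ref <- X2 + (pmax(X2 %*% bp$Wf1 + rep(bp$bf1, each = n), 0) %*% bp$Wf2 +
                 rep(bp$bf2, each = n))
  expect_lt(max(abs(out - ref)), 1e-5)
})

test_that("encoding returns the hidden width and uses all block weights", {
  cfg <- test_config()
  s <- fixture_samples(1L)[[1]]
  params <- init_params(cfg, 21L)
  enc <- encode_complex(s$wt, s$mutations, params, cfg)
  expect_equal(dim(enc$u), c(cfg$n_max, cfg$d_model))
  expect_equal(dim(enc$attention), c(cfg$H, cfg$n_max, cfg$n_max))

  # full-size hidden width: d_model = 128 as in the reference architecture
  cfg128 <- ddg_config_tiny(d_model = 128L, embed_dim = 8L, pos_enc_dim = 4L,
                            rbf_centers = 8L, n_max = 16L)
  p128 <- init_params(cfg128, 1L)
  enc128 <- encode_complex(s$wt, s$mutations, p128, cfg128)
  expect_equal(dim(enc128$u), c(16L, 128L))

  # no parameter sharing: perturbing only block-2 weights changes the output
  p2 <- params
  p2[["b2.Wf1"]][2, 3] <- p2[["b2.Wf1"]][2, 3] + 0.5
  enc2 <- encode_complex(s$wt, s$mutations, p2, cfg)
  expect_gt(max(abs(enc2$u - enc$u)), 1e-8)
  # ... while the attention maps (channel weights untouched) are identical
  expect_equal(enc2$attention, enc$attention)
})

test_that("encoding is invariant under rigid motions of the complex", {
  cfg <- test_config()
  s <- fixture_samples(2L)[[2]]
  params <- init_params(cfg, 33L)
  enc <- encode_complex(s$wt, s$mutations, params, cfg)
  for (k in 1:3) {
    y <- transform_structure(s$wt, random_rigid_motion(k * 11L))
    ency <- encode_complex(y, s$mutations, params, cfg)
    expect_lt(max(abs(ency$u - enc$u)), 1e-4)
  }
})

test_that("frozen gates reproduce the unweighted channel combination", {
  cfg <- test_config(gate_mode = "frozen")
  s <- fixture_samples(1L)[[1]]
  fx <- fixture_feats(s, cfg)
  params <- init_params(cfg, 44L)
  # one block by hand: alpha -> A = a1 - a2 + a3 -> attention block
  alpha <- channel_biases(fx$feats, block1(params))
  A <- recalibrate_channels(alpha, c(1, 40, 1), mask = fx$feats$mask)
  A_base <- array(alpha[1, , , ] - alpha[2, , , ] + alpha[3, , , ],
                  dim(alpha)[-1])
  A_base[, , !fx$feats$mask] <- -Inf
  # sigmoid(40) = 1 to double precision
  expect_equal(A[is.finite(A)], A_base[is.finite(A_base)], tolerance = 1e-6)
})
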