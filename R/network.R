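# Batched network core: forward pass and analytic backward pass.
#
# Layout conventions (shared with src/kernels.cpp):
#   - per-slot states: matrices (B*n) x d, sample b in rows (b-1)*n + 1..b*n;
#   - pairwise quantities: matrices (B*n^2) x H, rows ordered (i, j, b) with
#     i fastest; cubes (n, n, B*H) with slice (b-1)*H + h, entry (i, j) =
#     query i, key j;
#   - padding slots carry zero features and are excluded from attention by
#     key masking; their states are re-zeroed after every residual update.
#
# The backward pass is hand-derived per sublayer and verified against central
# finite differences in the test suite.

# --- layout helpers --------------------------------------------------------

addb <- function(M, b) M + rep(b, each = nrow(M))   # add bias row-wise

# Row-wise layer normalization with affine parameters.
ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv_sd <- 1 / sqrt(rowMeans(xc^2) + 1e-6)
  xhat <- xc * inv_sd
  list(y = addb(xhat * rep(g, each = nrow(X)), b), xhat = xhat,
       inv_sd = inv_sd)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dX <- cache$inv_sd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dy * xhat), db = colSums(dy))
}

# Stack per-sample feature bundles (equal n) into batch form.
stack_features <- function(fs) {
  B <- length(fs)
  n <- fs[[1]]$n
  list(
    B = B, n = n,
    X0 = do.call(rbind, lapply(fs, `[[`, "X0")),
    rbf = do.call(rbind, lapply(fs, `[[`, "rbf")),
    contact_code = unlist(lapply(fs, `[[`, "contact_code")),
    seqsep_code = unlist(lapply(fs, `[[`, "seqsep_code")),
    pairtype_code = unlist(lapply(fs, `[[`, "pairtype_code")),
    pairvalid = as.integer(unlist(lapply(fs, `[[`, "pairvalid"))),
    mask = matrix(as.numeric(unlist(lapply(fs, `[[`, "mask"))), n, B),
    maskrow = unlist(lapply(fs, `[[`, "mask")),
    anchors = do.call(rbind, lapply(fs, `[[`, "anchors")),
    frames_R = do.call(rbind, lapply(fs, `[[`, "frames_R")),
    origins = do.call(rbind, lapply(fs, `[[`, "origins")),
    row_sample = rep(seq_len(B), each = n)
  )
}

# --- pathway encoder -------------------------------------------------------

encode_forward <- function(sf, params, config, train = FALSE) {
  n <- sf$n; B <- sf$B
  d <- config$d_model; H <- config$H
  Hz <- config$Hz; Dkz <- config$Dkz
  p <- config$dropout
  use_drop <- train && p > 0
  pv <- sf$pairvalid
  mrow <- sf$maskrow

  Hi <- dense_fwd(sf$X0, params$Wi1, params$bi1, TRUE)
  X <- dense_fwd(Hi, params$Wi2, params$bi2, FALSE)
  X[!mrow, ] <- 0
  input_cache <- list(Hi = Hi)

  blocks <- vector("list", config$n_blocks)
  ones3 <- matrix(1, 3, B)

  for (k in seq_len(config$n_blocks)) {
    P <- block_params(params, k)
    cb <- list(X_in = X)

    ch <- channels_forward(sf$rbf, P$Wr, sf$contact_code, P$Wc,
                           sf$seqsep_code, P$Ws, sf$pairtype_code, P$Wp,
                           pv, n, B)
    cb$a1 <- ch$a1; cb$a2 <- ch$a2; cb$a3 <- ch$a3

    if (config$gate_mode == "learned") {
      zarr <- array(0, c(n, 3, B))
      zarr[, 1, ] <- ch$z1; zarr[, 2, ] <- ch$z2; zarr[, 3, ] <- ch$z3
      Z <- t(matrix(zarr, n, 3 * B))              # (3B) x n, channel-major
      Q <- Z %*% P$Wq; K <- Z %*% P$Wk; Vf <- Z %*% P$Wv
      logits <- attn_outer_n(Q, K, Hz, 3L) / sqrt(Dkz)
      Pf <- masked_softmax(logits, ones3, Hz)
      zAtt <- attn_apply(Pf, Vf, Hz)
      G <- relu(zAtt %*% P$W1)
      gpre <- G %*% P$W2
      s <- softplus(as.vector(gpre))
      smat <- matrix(s, 3, B)
      c1 <- smat[1, ]; c2 <- sigmoid(smat[2, ]); c3 <- smat[3, ]
      cb <- c(cb, list(Z = Z, Q = Q, K = K, Vf = Vf, Pf = Pf, zAtt = zAtt,
                       G = G, gpre = gpre, smat = smat))
    } else {
      c1 <- c2 <- c3 <- rep(1, B)
    }
    cb$c1 <- c1; cb$c2 <- c2; cb$c3 <- c3

    Pattn <- recal_softmax(cb$a1, cb$a2, cb$a3, c1, c2, c3, sf$mask, n, H)
    cb$Pattn <- Pattn

    ln1 <- ln_fwd(X, P$ln1_g, P$ln1_b)
    cb$ln1 <- ln1
    Va <- dense_fwd(ln1$y, P$Wv_a, P$bv, FALSE)
    att <- attn_apply(Pattn, Va, H)
    O <- dense_fwd(att, P$Wo, P$bo, FALSE)
    if (use_drop) {
      m_attn <- matrix((stats::runif(length(O)) >= p) / (1 - p), nrow(O))
      O <- O * m_attn
      cb$m_attn <- m_attn
    }
    X2 <- X + O
    X2[!mrow, ] <- 0

    ln2 <- ln_fwd(X2, P$ln2_g, P$ln2_b)
    cb$ln2 <- ln2
    Fh <- dense_fwd(ln2$y, P$Wf1, P$bf1, TRUE)
    F2 <- dense_fwd(Fh, P$Wf2, P$bf2, FALSE)
    if (use_drop) {
      m_ffn <- matrix((stats::runif(length(F2)) >= p) / (1 - p), nrow(F2))
      F2 <- F2 * m_ffn
      cb$m_ffn <- m_ffn
    }
    X <- X2 + F2
    X[!mrow, ] <- 0

    cb$Va <- Va; cb$att <- att; cb$X2 <- X2; cb$Fh <- Fh
    blocks[[k]] <- cb
  }

  # Side-chain geometric codes from the final attention map.
  Plast <- blocks[[config$n_blocks]]$Pattn
  Vanch <- do.call(cbind, rep(list(sf$anchors), H))
  fM <- attn_apply(Plast, Vanch, H)
  G3 <- matrix(0, nrow(fM), 3 * H)
  zeta <- matrix(0, nrow(fM), H)
  inv <- matrix(0, nrow(fM), H)
  bsa <- matrix(0, nrow(fM), 7 * H)
  e1 <- sf$frames_R[, 1:3]; e2 <- sf$frames_R[, 4:6]; e3 <- sf$frames_R[, 7:9]
  for (h in seq_len(H)) {
    ch <- 3 * (h - 1)
    delta <- fM[, ch + (1:3), drop = FALSE] - sf$origins
    g <- cbind(rowSums(delta * e1), rowSums(delta * e2), rowSums(delta * e3))
    zt <- sqrt(rowSums(g^2))
    iv <- ifelse(zt < 1e-8, 0, 1 / zt)
    G3[, ch + (1:3)] <- g
    zeta[, h] <- zt
    inv[, h] <- iv
    bsa[, 7 * (h - 1) + (1:7)] <- cbind(g, zt, g * iv)
  }
  bsa[!mrow, ] <- 0

  lnf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  Xn <- lnf$y
  Xn[!mrow, ] <- 0
  if (config$bsa_mode == "concat") {
    cat_ <- cbind(Xn, bsa)
    u <- dense_fwd(cat_, params$Wb, params$bb, FALSE)
  } else {
    cat_ <- bsa
    u <- Xn + dense_fwd(bsa, params$Wb, params$bb, FALSE)
  }
  u[!mrow, ] <- 0

  list(u = u, Plast = Plast, A_last_pre_mask = NULL,
       cache = list(input = input_cache, blocks = blocks,
                    fM = fM, G3 = G3, zeta = zeta, inv = inv,
                    bsa = bsa, cat_ = cat_, Vanch = Vanch, X_final = X,
                    lnf = lnf))
}

encode_backward <- function(enc, sf, params, config, du, grads) {
  n <- sf$n; B <- sf$B
  d <- config$d_model; H <- config$H
  Hz <- config$Hz; Dkz <- config$Dkz
  pv <- sf$pairvalid
  mrow <- sf$maskrow
  ca <- enc$cache

  add <- function(name, val) grads[[name]] <- grads[[name]] + val

  du[!mrow, ] <- 0
  if (config$bsa_mode == "concat") {
    add("Wb", crossprod(ca$cat_, du))
    add("bb", colSums(du))
    dcat <- du %*% t(params$Wb)
    dXn <- dcat[, seq_len(d), drop = FALSE]
    dbsa <- dcat[, d + seq_len(7 * H), drop = FALSE]
  } else {
    dXn <- du
    add("Wb", crossprod(ca$bsa, du))
    add("bb", colSums(du))
    dbsa <- du %*% t(params$Wb)
  }
  dbsa[!mrow, ] <- 0
  dXn[!mrow, ] <- 0
  lb <- ln_bwd(dXn, ca$lnf, params$lnf_g)
  add("lnf_g", lb$dg); add("lnf_b", lb$db)
  dX <- lb$dX

  e1 <- sf$frames_R[, 1:3]; e2 <- sf$frames_R[, 4:6]; e3 <- sf$frames_R[, 7:9]
  dfM <- matrix(0, nrow(ca$fM), 3 * H)
  for (h in seq_len(H)) {
    ch3 <- 3 * (h - 1); ch7 <- 7 * (h - 1)
    g <- ca$G3[, ch3 + (1:3), drop = FALSE]
    iv <- ca$inv[, h]
    dxi <- dbsa[, ch7 + (1:3), drop = FALSE]
    dzt <- dbsa[, ch7 + 4]
    dpsi <- dbsa[, ch7 + (5:7), drop = FALSE]
    dg <- dxi + g * (dzt * iv) +
      dpsi * iv - g * (rowSums(g * dpsi) * iv^3)
    dfM[, ch3 + (1:3)] <- dg[, 1] * e1 + dg[, 2] * e2 + dg[, 3] * e3
  }
  dPlast_bsa <- attn_outer_n(dfM, ca$Vanch, H, n)

  for (k in rev(seq_len(config$n_blocks))) {
    P <- block_params(params, k)
    pre <- paste0("b", k, ".")
    cb <- ca$blocks[[k]]
    dX[!mrow, ] <- 0

    dF2 <- if (!is.null(cb$m_ffn)) dX * cb$m_ffn else dX
    add(paste0(pre, "Wf2"), crossprod(cb$Fh, dF2))
    add(paste0(pre, "bf2"), colSums(dF2))
    dFh <- (dF2 %*% t(P$Wf2)) * (cb$Fh > 0)
    add(paste0(pre, "Wf1"), crossprod(cb$ln2$y, dFh))
    add(paste0(pre, "bf1"), colSums(dFh))
    lb2 <- ln_bwd(dFh %*% t(P$Wf1), cb$ln2, P$ln2_g)
    add(paste0(pre, "ln2_g"), lb2$dg)
    add(paste0(pre, "ln2_b"), lb2$db)
    dX2 <- dX + lb2$dX
    dX2[!mrow, ] <- 0

    dO <- if (!is.null(cb$m_attn)) dX2 * cb$m_attn else dX2
    add(paste0(pre, "Wo"), crossprod(cb$att, dO))
    add(paste0(pre, "bo"), colSums(dO))
    datt <- dO %*% t(P$Wo)
    dPattn <- attn_outer_n(datt, cb$Va, H, n)
    if (k == config$n_blocks) dPattn <- dPattn + dPlast_bsa
    dVa <- attn_apply(cb$Pattn, datt, H, transpose = TRUE)
    add(paste0(pre, "Wv_a"), crossprod(cb$ln1$y, dVa))
    add(paste0(pre, "bv"), colSums(dVa))
    lb1 <- ln_bwd(dVa %*% t(P$Wv_a), cb$ln1, P$ln1_g)
    add(paste0(pre, "ln1_g"), lb1$dg)
    add(paste0(pre, "ln1_b"), lb1$db)
    dX_in <- dX2 + lb1$dX

    bw <- recal_softmax_bwd(cb$Pattn, dPattn, cb$a1, cb$a2, cb$a3,
                            cb$c1, cb$c2, cb$c3, n, H)

    dz1 <- dz2 <- dz3 <- matrix(0, n, B)
    if (config$gate_mode == "learned") {
      c2v <- cb$c2
      ds <- rbind(as.vector(bw$dc1),
                  as.vector(bw$dc2) * c2v * (1 - c2v),
                  as.vector(bw$dc3))                         # 3 x B
      dgpre <- as.vector(ds) * sigmoid(as.vector(cb$gpre))
      add(paste0(pre, "W2"), crossprod(cb$G, matrix(dgpre, ncol = 1)))
      dG <- matrix(dgpre, ncol = 1) %*% t(P$W2)
      dpre1 <- dG * (cb$G > 0)
      add(paste0(pre, "W1"), crossprod(cb$zAtt, dpre1))
      dzAtt <- dpre1 %*% t(P$W1)
      dPf <- attn_outer_n(dzAtt, cb$Vf, Hz, 3L)
      dVf <- attn_apply(cb$Pf, dzAtt, Hz, transpose = TRUE)
      dlog <- softmax_bwd(cb$Pf, dPf) / sqrt(Dkz)
      dQ <- attn_apply(dlog, cb$K, Hz)
      dK <- attn_apply(dlog, cb$Q, Hz, transpose = TRUE)
      add(paste0(pre, "Wq"), crossprod(cb$Z, dQ))
      add(paste0(pre, "Wk"), crossprod(cb$Z, dK))
      add(paste0(pre, "Wv"), crossprod(cb$Z, dVf))
      dZ <- dQ %*% t(P$Wq) + dK %*% t(P$Wk) + dVf %*% t(P$Wv)
      idx3 <- rep(1:3, B)
      dz1 <- t(dZ[idx3 == 1L, , drop = FALSE])
      dz2 <- t(dZ[idx3 == 2L, , drop = FALSE])
      dz3 <- t(dZ[idx3 == 3L, , drop = FALSE])
    }

    cw <- channels_bwd(bw$da1, bw$da2, bw$da3, dz1, dz2, dz3,
                       sf$rbf, sf$contact_code, sf$seqsep_code,
                       sf$pairtype_code, pv, n, B,
                       nrow(P$Ws), nrow(P$Wp))
    add(paste0(pre, "Wr"), cw$dWr)
    add(paste0(pre, "Wc"), cw$dWc)
    add(paste0(pre, "Ws"), cw$dWs)
    add(paste0(pre, "Wp"), cw$dWp)

    dX <- dX_in
  }

  dX[!mrow, ] <- 0
  add("Wi2", crossprod(ca$input$Hi, dX))
  add("bi2", colSums(dX))
  dHi <- (dX %*% t(params$Wi2)) * (ca$input$Hi > 0)
  add("Wi1", crossprod(sf$X0, dHi))
  add("bi1", colSums(dHi))
  invisible(NULL)
}

# --- antisymmetric head ----------------------------------------------------

head_ffn <- function(pmat, params) {
  a1 <- dense_fwd(pmat, params$Wh1, params$bh1, TRUE)
  a2 <- dense_fwd(a1, params$Wh2, params$bh2, TRUE)
  a3 <- dense_fwd(a2, params$Wh3, params$bh3, TRUE)
  list(a1 = a1, a2 = a2, a3 = a3, input = pmat)
}

head_ffn_backward <- function(hc, params, d3, grads) {
  add <- function(name, val) grads[[name]] <- grads[[name]] + val
  d3 <- d3 * (hc$a3 > 0)
  add("Wh3", crossprod(hc$a2, d3)); add("bh3", colSums(d3))
  d2 <- (d3 %*% t(params$Wh3)) * (hc$a2 > 0)
  add("Wh2", crossprod(hc$a1, d2)); add("bh2", colSums(d2))
  d1 <- (d2 %*% t(params$Wh2)) * (hc$a1 > 0)
  add("Wh1", crossprod(hc$input, d1)); add("bh1", colSums(d1))
  d1 %*% t(params$Wh1)
}

# --- full model ------------------------------------------------------------

# Forward pass over stacked wild-type/mutant features.  Returns per-sample
# predictions, per-slot contributions, and (optionally) caches for backward.
ddg_forward <- function(sfw, sfm, params, config, train = FALSE,
                        want_cache = FALSE) {
  encw <- encode_forward(sfw, params, config, train)
  encm <- encode_forward(sfm, params, config, train)
  cf <- cbind(encw$u, encm$u)
  cr <- cbind(encm$u, encw$u)
  hf <- head_ffn(cf, params)
  hr <- head_ffn(cr, params)
  rvec <- (hf$a3 - hr$a3) %*% params$Wddg
  rvec[!sfw$maskrow] <- 0
  pred <- as.vector(rowsum(rvec, sfw$row_sample))
  out <- list(pred = pred, rvec = as.vector(rvec),
              Plast_wt = encw$Plast, Plast_mut = encm$Plast,
              u_wt = encw$u, u_mut = encm$u)
  if (want_cache) out$cache <- list(encw = encw, encm = encm, hf = hf, hr = hr)
  out
}

zero_like <- function(params) {
  g <- new.env(parent = emptyenv())
  for (nm in names(params)) g[[nm]] <- params[[nm]] * 0
  g
}

# Backward pass: dpred (length B) -> gradient list aligned with params.
ddg_backward <- function(fwd, sfw, sfm, params, config, dpred) {
  d <- config$d_model
  grads <- zero_like(params)
  ca <- fwd$cache
  drvec <- dpred[sfw$row_sample]
  drvec[!sfw$maskrow] <- 0
  grads$Wddg <- grads$Wddg +
    crossprod(ca$hf$a3 - ca$hr$a3, matrix(drvec, ncol = 1))
  dout <- matrix(drvec, ncol = 1) %*% t(params$Wddg)
  dcf <- head_ffn_backward(ca$hf, params, dout, grads)
  dcr <- head_ffn_backward(ca$hr, params, -dout, grads)
  du_wt <- dcf[, seq_len(d), drop = FALSE] + dcr[, d + seq_len(d), drop = FALSE]
  du_mut <- dcf[, d + seq_len(d), drop = FALSE] + dcr[, seq_len(d), drop = FALSE]
  encode_backward(ca$encw, sfw, params, config, du_wt, grads)
  encode_backward(ca$encm, sfm, params, config, du_mut, grads)
  out <- as.list(grads)[names(params)]
  out
}
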