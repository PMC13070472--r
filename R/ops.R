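# Per-sample operations of the encoder, recalibration unit, and side-chain
# attention module.  These are thin single-sample views over the batched
# network core, so the exported surface and the training path share one
# implementation.

#' Build the three pairwise correlation channels
#'
#' Channel 1 encodes 3D structure: a per-head linear map of a Gaussian
#' radial-basis expansion of the C-beta distance (centres 0-20 A).  Channel 2
#' encodes the 2D contact map through a per-head contact embedding.  Channel
#' 3 encodes 1D sequence relationships: per-head maps of the clipped signed
#' sequence separation and of the ordered residue-pair type.  Padding pairs
#' carry 0 in every channel.
#'
#' @param feats per-sample feature bundle from the encoder pipeline (see
#'   [encode_complex()] for the user-level entry point).
#' @param bp block parameter list (Wr, Wc, Ws, Wp).
#' @return array of shape (3, H, n, n): `alpha[c, h, i, j]`.
#' @export
channel_biases <- function(feats, bp) {
  n <- feats$n
  H <- ncol(bp$Wr)
  pv <- feats$pairvalid
  a1 <- feats$rbf %*% bp$Wr
  a2 <- bp$Wc[feats$contact_code, , drop = FALSE]; a2[!pv, ] <- 0
  a3 <- bp$Ws[feats$seqsep_code, , drop = FALSE] +
    bp$Wp[feats$pairtype_code, , drop = FALSE]
  a3[!pv, ] <- 0
  alpha <- array(0, c(3, H, n, n))
  alpha[1, , , ] <- aperm(array(a1, c(n, n, H)), c(3, 1, 2))
  alpha[2, , , ] <- aperm(array(a2, c(n, n, H)), c(3, 1, 2))
  alpha[3, , , ] <- aperm(array(a3, c(n, n, H)), c(3, 1, 2))
  alpha
}

#' Squeeze the correlation channels into residue-wise descriptors
#'
#' z\[c, j\] sums channel c over the first residue axis and all heads,
#' summarizing the global correlation pattern each residue participates in.
#'
#' @param alpha array (3, H, n, n) from [channel_biases()].
#' @return 3 x n matrix.
#' @export
proteo_squeeze <- function(alpha) {
  apply(alpha, c(1, 4), sum)
}

#' Self-attentive fusion of the channel descriptors
#'
#' Multi-head scaled dot-product attention over the three channel tokens
#' (softmax across channels), heads concatenated.
#'
#' @param z 3 x n descriptor matrix from [proteo_squeeze()].
#' @param bp block parameters (Wq, Wk, Wv).
#' @param Hz number of fusion heads.
#' @param Dkz fusion key dimension.
#' @return 3 x (Hz * Dkz) fused descriptor.
#' @export
proteo_fuse <- function(z, bp, Hz, Dkz) {
  C <- nrow(z)
  Q <- z %*% bp$Wq; K <- z %*% bp$Wk; V <- z %*% bp$Wv
  logits <- attn_outer_n(Q, K, Hz, C) / sqrt(Dkz)
  Pf <- masked_softmax(logits, matrix(1, C, 1), Hz)
  attn_apply(Pf, V, Hz)
}

#' Channel gates from the fused descriptor
#'
#' s_c = softplus(relu(fused_c W1) W2); strictly positive for any finite
#' input.
#'
#' @param fused 3 x (Hz * Dkz) matrix from [proteo_fuse()].
#' @param bp block parameters (W1, W2).
#' @return numeric gate vector of length 3.
#' @export
proteo_gate <- function(fused, bp) {
  softplus(as.vector(relu(fused %*% bp$W1) %*% bp$W2))
}

#' Recalibrate the channels into one attention bias
#'
#' A = s1 * a1 - sigmoid(s2) * a2 + s3 * a3.  The sigmoid confines the
#' contact channel's coefficient to (0, 1), preventing uncontrolled
#' amplification of the subtracted channel; padding keys then receive an
#' additive -Inf mask.
#'
#' @param alpha array (3, H, n, n).
#' @param s gate vector (length 3, positive).
#' @param mask logical validity of the n slots (default all valid).
#' @return array (H, n, n) of attention logits.
#' @export
recalibrate_channels <- function(alpha, s, mask = NULL) {
  stopifnot(all(s > 0))
  A <- s[1] * alpha[1, , , , drop = FALSE] -
    sigmoid(s[2]) * alpha[2, , , , drop = FALSE] +
    s[3] * alpha[3, , , , drop = FALSE]
  A <- array(A, dim(alpha)[-1])
  if (!is.null(mask) && any(!mask)) A[, , !mask] <- -Inf
  A
}

#' One biased graph-attention block
#'
#' Attention weights are the softmax (over keys) of the bias `A` itself;
#' values are a linear map of the node states.  Heads are concatenated,
#' projected, added residually, then a two-layer feed-forward block with its
#' own residual is applied.  Rows whose keys are all masked fall back to
#' uniform attention over the valid slots.
#'
#' @param nodes n x d_model state matrix.
#' @param A attention bias (H, n, n), already masked (-Inf on padding keys).
#' @param bp block parameters (Wv_a, bv, Wo, bo, Wf1, bf1, Wf2, bf2; when
#'   pre-normalization parameters ln1_g/ln1_b/ln2_g/ln2_b are present, each
#'   sublayer input is layer-normalized first, as in the full encoder).
#' @param mask logical slot validity (default all valid).
#' @return updated n x d_model matrix.
#' @export
attention_block <- function(nodes, A, bp, mask = NULL) {
  n <- nrow(nodes)
  H <- dim(A)[1]
  if (is.null(mask)) mask <- rep(TRUE, n)
  cu <- aperm(A, c(2, 3, 1))
  Pattn <- masked_softmax(cu, matrix(as.numeric(mask), n, 1), H)
  vin <- if (!is.null(bp$ln1_g)) ln_fwd(nodes, bp$ln1_g, bp$ln1_b)$y else nodes
  Va <- addb(vin %*% bp$Wv_a, bp$bv)
  att <- attn_apply(Pattn, Va, H)
  X2 <- nodes + addb(att %*% bp$Wo, bp$bo)
  X2[!mask, ] <- 0
  fin <- if (!is.null(bp$ln2_g)) ln_fwd(X2, bp$ln2_g, bp$ln2_b)$y else X2
  Fh <- relu(addb(fin %*% bp$Wf1, bp$bf1))
  X3 <- X2 + addb(Fh %*% bp$Wf2, bp$bf2)
  X3[!mask, ] <- 0
  X3
}

#' Attention-weighted projection of side-chain anchors
#'
#' Per head, the row-stochastic softmax (over keys) of the residue attention
#' bias is applied to the C-beta anchor coordinates, giving each residue an
#' attention-weighted anchor point per head.
#'
#' @param A attention bias (H, n, n), masked.
#' @param f n x 3 anchor coordinates (C-beta, virtual for glycine).
#' @param mask logical slot validity.
#' @return array (H, n, 3).
#' @export
project_points <- function(A, f, mask = NULL) {
  H <- dim(A)[1]; n <- dim(A)[2]
  if (is.null(mask)) mask <- rep(TRUE, n)
  cu <- aperm(A, c(2, 3, 1))
  P <- masked_softmax(cu, matrix(as.numeric(mask), n, 1), H)
  fM <- attn_apply(P, do.call(cbind, rep(list(f), H)), H)
  out <- array(0, c(H, n, 3))
  for (h in seq_len(H)) out[h, , ] <- fM[, 3 * (h - 1) + (1:3)]
  out
}

#' Residue-local geometric descriptors of projected points
#'
#' g = R^T (f_proj - origin) per residue and head; positional descriptor
#' xi = g, distance zeta = ||g||, direction psi = g / ||g|| (zero when
#' zeta < 1e-8).  All three are rigid-motion invariant by construction.
#'
#' @param fM array (H, n, 3) from [project_points()].
#' @param frames list of per-residue [build_local_frame()] results.
#' @return list with `xi` (H, n, 3), `zeta` (H, n), `psi` (H, n, 3).
#' @export
local_descriptors <- function(fM, frames) {
  H <- dim(fM)[1]; n <- dim(fM)[2]
  xi <- array(0, c(H, n, 3)); psi <- array(0, c(H, n, 3))
  zeta <- matrix(0, H, n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    for (h in seq_len(H)) {
      g <- as.vector(crossprod(fr$R, fM[h, i, ] - fr$origin))
      xi[h, i, ] <- g
      zt <- l2norm(g)
      zeta[h, i] <- zt
      if (zt >= 1e-8) psi[h, i, ] <- g / zt
    }
  }
  list(xi = xi, zeta = zeta, psi = psi)
}

#' Assemble the side-chain geometric code
#'
#' Concatenates (xi, zeta, psi) across heads into an n x 7H code matrix.
#'
#' @param xi array (H, n, 3).
#' @param zeta matrix (H, n).
#' @param psi array (H, n, 3).
#' @return n x (7 * H) matrix.
#' @export
assemble_bsa <- function(xi, zeta, psi) {
  H <- dim(xi)[1]; n <- dim(xi)[2]
  out <- matrix(0, n, 7 * H)
  for (h in seq_len(H)) {
    out[, 7 * (h - 1) + (1:7)] <- cbind(xi[h, , , drop = TRUE],
                                        zeta[h, ],
                                        psi[h, , , drop = TRUE])
  }
  out
}

#' Per-residue antisymmetric ddG contribution
#'
#' (FFN(u_wt + u_mut concatenated) - FFN(u_mut + u_wt concatenated)) W_ddg:
#' negates exactly under argument swap, for any weights.
#'
#' @param u_wt_i,u_mut_i d_model-vectors for one residue.
#' @param params model parameters (head weights).
#' @return scalar, kcal/mol.
#' @export
residue_ddg <- function(u_wt_i, u_mut_i, params) {
  cf <- matrix(c(u_wt_i, u_mut_i), 1)
  cr <- matrix(c(u_mut_i, u_wt_i), 1)
  as.numeric((head_ffn(cf, params)$a3 - head_ffn(cr, params)$a3) %*%
               params$Wddg)
}
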