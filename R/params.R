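# Parameter initialization and portable checkpointing.
#
# Parameters live in a flat named list of numeric matrices/vectors; block k's
# weights are prefixed "bk." (no sharing across blocks).  Initialization is
# Glorot-style normal for dense maps and small-scale normal for the bias
# embedding tables, all drawn from a preserved seeded stream.

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize model parameters
#'
#' @param config a [ddg_config()].
#' @param seed RNG seed.
#' @return flat named list of parameter arrays (class `ddg_params`).
#' @export
init_params <- function(config, seed = 1L) {
  with_preserved_seed(seed * 17L + 1L, {
    d <- config$d_model; H <- config$H
    Hz <- config$Hz; Dkz <- config$Dkz; n <- config$n_max
    Fin <- node_input_dim(config)
    hh <- config$head_hidden
    fuse_sd <- 1 / (0.3 * n^1.5 * H)
    p <- list(
      Wi1 = glorot(Fin, d), bi1 = numeric(d),
      Wi2 = glorot(d, d), bi2 = numeric(d)
    )
    for (k in seq_len(config$n_blocks)) {
      pre <- paste0("b", k, ".")
      Wc0 <- matrix(stats::rnorm(2 * H, 0, 0.15), 2, H)
      Ws0 <- matrix(stats::rnorm((2 * config$seqsep_clip + 2) * H, 0, 0.05),
                    2 * config$seqsep_clip + 2, H)
      # Structured attention prior: head 1 starts out attending sharply to
      # cross-partner contacts (the contact channel enters the combined
      # logit subtractively, so an attractive contact prior is negative);
      # the random parts of the tables start small so the prior is crisp.
      # Training is free to reshape all of it.
      Wc0[2, 1] <- Wc0[2, 1] - 4
      Ws0[2 * config$seqsep_clip + 2, 1] <-
        Ws0[2 * config$seqsep_clip + 2, 1] + 4
      blk <- list(
        Wr = matrix(stats::rnorm(config$rbf_centers * H, 0, 0.15),
                    config$rbf_centers, H),
        Wc = Wc0,
        Ws = Ws0,
        Wp = matrix(stats::rnorm(400 * H, 0, 0.05), 400, H),
        # The squeezed descriptors z scale with n_max * H * |alpha|
        # (|alpha| ~ 0.3 at init), so the fusion maps start small enough to
        # keep fusion logits O(1); the gate output layer starts at zero so
        # every gate begins at softplus(0) = log 2 and moves smoothly.
        Wq = matrix(stats::rnorm(n * Hz * Dkz, 0, fuse_sd), n, Hz * Dkz),
        Wk = matrix(stats::rnorm(n * Hz * Dkz, 0, fuse_sd), n, Hz * Dkz),
        Wv = matrix(stats::rnorm(n * Hz * Dkz, 0, fuse_sd), n, Hz * Dkz),
        W1 = glorot(Hz * Dkz, n), W2 = matrix(0, n, 1),
        ln1_g = rep(1, d), ln1_b = numeric(d),
        ln2_g = rep(1, d), ln2_b = numeric(d),
        Wv_a = glorot(d, d), bv = numeric(d),
        Wo = glorot(d, d), bo = numeric(d),
        Wf1 = glorot(d, 2 * d), bf1 = numeric(2 * d),
        Wf2 = glorot(2 * d, d), bf2 = numeric(d)
      )
      names(blk) <- paste0(pre, names(blk))
      p <- c(p, blk)
    }
    p$lnf_g <- rep(1, d)
    p$lnf_b <- numeric(d)
    if (config$bsa_mode == "concat") {
      # identity-preserving start: residue states pass through unchanged,
      # side-chain codes enter at small scale
      p$Wb <- rbind(diag(d) + glorot(d, d) * 0.1,
                    glorot(7L * H, d) * 0.1)
    } else {
      p$Wb <- glorot(7L * H, d)
    }
    p$bb <- numeric(d)
    p$Wh1 <- glorot(2 * d, hh[1]); p$bh1 <- numeric(hh[1])
    p$Wh2 <- glorot(hh[1], hh[2]); p$bh2 <- numeric(hh[2])
    p$Wh3 <- glorot(hh[2], hh[3]); p$bh3 <- numeric(hh[3])
    p$Wddg <- glorot(hh[3], 1)
    class(p) <- "ddg_params"
    p
  })
}

block_params <- function(params, k) {
  pre <- paste0("b", k, ".")
  hit <- startsWith(names(params), pre)
  out <- params[hit]
  names(out) <- substring(names(out), nchar(pre) + 1L)
  out
}

#' Save model weights as a portable text checkpoint
#'
#' JSON with a manifest of array shapes, the configuration, and the flattened
#' values; loads back exactly with [load_weights()].
#'
#' @param params a `ddg_params` list.
#' @param config the matching `ddg_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_weights <- function(params, config, path) {
  payload <- list(
    format = "ddgatt-weights-v1",
    config = unclass(config),
    shapes = lapply(params, function(a) if (is.matrix(a)) dim(a) else length(a)),
    values = lapply(params, function(a) as.numeric(a))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load model weights from a checkpoint
#'
#' @param path file written by [save_weights()].
#' @return list with `params` and `config`.
#' @export
load_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ddgatt-weights-v1"))
    stop("not a ddgatt weight checkpoint: ", path)
  cfgl <- payload$config
  config <- ddg_config(n_max = cfgl$n_max, H = cfgl$H, Hz = cfgl$Hz,
                       Dkz = cfgl$Dkz, d_model = cfgl$d_model,
                       n_blocks = cfgl$n_blocks, dropout = cfgl$dropout,
                       rbf_centers = cfgl$rbf_centers,
                       contact_threshold = cfgl$contact_threshold,
                       seqsep_clip = cfgl$seqsep_clip,
                       embed_dim = cfgl$embed_dim,
                       pos_enc_dim = cfgl$pos_enc_dim,
                       head_hidden = cfgl$head_hidden,
                       gate_mode = cfgl$gate_mode, bsa_mode = cfgl$bsa_mode)
  params <- Map(function(v, sh) {
    if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else as.numeric(v)
  }, payload$values, payload$shapes)
  class(params) <- "ddg_params"
  list(params = params, config = config)
}
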