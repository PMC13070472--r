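# Model configuration.

#' Model and feature configuration
#'
#' Defaults follow the reference architecture: hidden width `d_model = 128`,
#' four attention blocks without parameter sharing, subgraph capacity
#' `n_max = 128`.  Head counts, fusion dimensions and feature settings are
#' exposed because they are tunable; the fusion weights tie `n_max` into the
#' parameter shapes, so `n_max` is fixed at model construction.
#'
#' @param n_max residue subgraph capacity (attention cost is O(n_max^2)).
#' @param H residue-attention heads (d_model must be divisible by H).
#' @param Hz fusion heads of the channel-recalibration unit.
#' @param Dkz fusion key dimension.
#' @param d_model hidden width of residue states.
#' @param n_blocks number of attention blocks (each with its own weights).
#' @param dropout dropout rate applied after attention and feed-forward
#'   sublayers during training.
#' @param rbf_centers number of Gaussian radial-basis centres (0-20 A) for
#'   the distance channel.
#' @param contact_threshold C-beta contact cutoff, Angstrom (closed bound).
#' @param seqsep_clip sequence-separation clipping bound.
#' @param embed_dim sequence-embedding width (32 for the built-in mock;
#'   1024 for an external ProtT5-class provider).
#' @param pos_enc_dim sinusoidal positional-encoding width (even).
#' @param head_hidden hidden widths of the antisymmetric head's
#'   three ReLU layers.
#' @param gate_mode "learned" for the recalibration gates, or "frozen" to fix
#'   all channel coefficients at 1 (the baseline a1 - a2 + a3 combination,
#'   used for ablation).
#' @param bsa_mode how side-chain codes enter the final representation:
#'   "concat" (concatenated with residue states, then projected back to
#'   d_model) or "add" (projected and added).
#' @return list of class `ddg_config`.
#' @export
ddg_config <- function(n_max = 128L, H = 8L, Hz = 4L, Dkz = 32L,
                       d_model = 128L, n_blocks = 4L, dropout = 0,
                       rbf_centers = 16L, contact_threshold = 8,
                       seqsep_clip = 32L, embed_dim = 32L, pos_enc_dim = 16L,
                       head_hidden = c(256L, 128L, 64L),
                       gate_mode = c("learned", "frozen"),
                       bsa_mode = c("concat", "add")) {
  gate_mode <- match.arg(gate_mode)
  bsa_mode <- match.arg(bsa_mode)
  stopifnot(d_model %% H == 0, pos_enc_dim %% 2 == 0, length(head_hidden) == 3,
            rbf_centers >= 2, n_blocks >= 1, dropout >= 0, dropout < 1)
  structure(list(n_max = as.integer(n_max), H = as.integer(H),
                 Hz = as.integer(Hz), Dkz = as.integer(Dkz),
                 d_model = as.integer(d_model), n_blocks = as.integer(n_blocks),
                 dropout = dropout, rbf_centers = as.integer(rbf_centers),
                 contact_threshold = contact_threshold,
                 seqsep_clip = as.integer(seqsep_clip),
                 embed_dim = as.integer(embed_dim),
                 pos_enc_dim = as.integer(pos_enc_dim),
                 head_hidden = as.integer(head_hidden),
                 gate_mode = gate_mode, bsa_mode = bsa_mode),
            class = "ddg_config")
}

#' Reduced desk-scale configuration
#'
#' A small variant (n_max = 32, H = 2, Hz = 2, Dkz = 8, d_model = 32, two
#' blocks) that trains in minutes on one CPU while exercising every
#' architectural component; used throughout the package's own experiments.
#'
#' @param ... overrides forwarded to [ddg_config()].
#' @return a `ddg_config`.
#' @export
ddg_config_tiny <- function(...) {
  args <- list(n_max = 32L, H = 2L, Hz = 2L, Dkz = 8L, d_model = 32L,
               n_blocks = 2L, head_hidden = c(64L, 32L, 16L))
  override <- list(...)
  args[names(override)] <- override
  do.call(ddg_config, args)
}

node_input_dim <- function(config) {
  20L + config$pos_enc_dim + 56L + config$embed_dim
}
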