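# Model fitting and prediction: the user-facing S3 surface.

default_provider <- function(config, seed = 0L) {
  mock_embedding_provider(config$embed_dim, seed)
}

# Map a wild-type-derived selection onto an aligned structure by
# (chain, resseq, icode) keys.
translate_selection <- function(sel, from, to) {
  key_from <- paste(from$chain, from$resseq, from$icode, sep = "\r")
  key_to <- paste(to$chain, to$resseq, to$icode, sep = "\r")
  idx <- match(key_from[sel$indices], key_to)
  if (anyNA(idx))
    stop("structures are not residue-aligned: selection cannot be transferred")
  out <- sel
  out$indices <- idx
  out
}

# Per-sample features for both pathways; the subgraph is selected once per
# pair (symmetric in wild type and mutant) and applied to both.
sample_features <- function(s, config, provider) {
  sel <- select_residues_pair(s$wt, s$mut, s$mutations, config$n_max)
  fw <- build_features(s$wt, sel, provider, config)
  fm <- build_features(s$mut, translate_selection(sel, s$wt, s$mut),
                       provider, config)
  list(wt = fw, mut = fm, sel = sel)
}

prepare_batch <- function(samples, config, provider) {
  fs <- lapply(samples, sample_features, config = config, provider = provider)
  list(sfw = stack_features(lapply(fs, `[[`, "wt")),
       sfm = stack_features(lapply(fs, `[[`, "mut")),
       sels = lapply(fs, `[[`, "sel"))
}

#' Encode one complex into per-residue states
#'
#' Runs residue selection, feature construction and the full block stack for
#' a single structure, returning the final encoding `u` (n_max x d_model)
#' and the last block's post-softmax attention for interpretability.
#'
#' @param structure a `complex_structure`.
#' @param mutations mutation list defining the subgraph centre.
#' @param params model parameters ([init_params()] or a fitted model's).
#' @param config the matching `ddg_config`.
#' @param provider embedding provider (default: built-in mock).
#' @return list with `u`, `attention` (array H x n x n, post-softmax),
#'   `selection`, and `features`.
#' @export
encode_complex <- function(structure, mutations, params, config,
                           provider = default_provider(config)) {
  sel <- select_residues(structure, mutations, config$n_max)
  feats <- build_features(structure, sel, provider, config)
  sf <- stack_features(list(feats))
  enc <- encode_forward(sf, params, config, train = FALSE)
  H <- config$H; n <- config$n_max
  attn <- array(0, c(H, n, n))
  for (h in seq_len(H)) attn[h, , ] <- enc$Plast[, , h]
  list(u = enc$u, attention = attn, selection = sel, features = feats)
}

#' Predict ddG for one sample with explicit parameters
#'
#' @param sample a `sample_record`.
#' @param params model parameters.
#' @param config the matching `ddg_config`.
#' @param provider embedding provider.
#' @return predicted ddG, kcal/mol.
#' @export
predict_ddg <- function(sample, params, config,
                        provider = default_provider(config)) {
  b <- prepare_batch(list(sample), config, provider)
  ddg_forward(b$sfw, b$sfm, params, config)$pred
}

#' Per-residue contributions to a ddG prediction
#'
#' The antisymmetric head is additive over residues, so the prediction
#' decomposes exactly; contributions sum to the total and negate under
#' wild-type/mutant exchange.
#'
#' @inheritParams predict_ddg
#' @return list with `contributions` (per valid slot), `indices` (global
#'   residue positions) and `total`.
#' @export
per_residue_contributions <- function(sample, params, config,
                                      provider = default_provider(config)) {
  b <- prepare_batch(list(sample), config, provider)
  fwd <- ddg_forward(b$sfw, b$sfm, params, config)
  nv <- sum(b$sfw$maskrow)
  list(contributions = fwd$rvec[seq_len(nv)],
       indices = b$sels[[1]]$indices,
       total = fwd$pred)
}

# ---------------------------------------------------------------------------
# Fitting

#' Fit the ddG model
#'
#' Trains the full architecture (biased graph attention with channel
#' recalibration, side-chain attention codes, antisymmetric head) on a list
#' of labelled samples with MSE loss and Adam.  Reverse-mutation
#' augmentation (swap structures, negate label) is applied by default, which
#' makes the training label distribution exactly zero-mean.  The learning
#' rate is halved at 100-epoch checkpoints when the best training loss has
#' not improved over the last 10 recorded epochs.
#'
#' @param samples list of `sample_record`.
#' @param config a [ddg_config()] (default: the desk-scale
#'   [ddg_config_tiny()]).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size samples per step, or `NULL` for full-batch.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param augment apply reverse-mutation augmentation.
#' @param validation optional list of `sample_record` monitored each
#'   `val_every` epochs (never trained on, never augmented).
#' @param val_every validation cadence, epochs.
#' @param provider embedding provider (default mock, seed 0).
#' @param lr_halve enable the plateau halving schedule.
#' @param check_every plateau checkpoint cadence, epochs.
#' @param patience plateau window, recorded epochs.
#' @param verbose print progress.
#' @return object of class `ddg_model`.
#' @export
ddg_fit <- function(samples, config = ddg_config_tiny(), epochs = 300L,
                    lr = 1e-3, batch_size = NULL, seed = 1L, augment = TRUE,
                    validation = NULL, val_every = 50L,
                    provider = default_provider(config), lr_halve = TRUE,
                    check_every = 100L, patience = 10L, verbose = FALSE) {
  if (length(samples) == 0L) stop("empty training set")
  cl <- match.call()
  train_set <- if (augment) reverse_augment(samples) else samples
  batch <- prepare_batch(train_set, config, provider)
  y <- vapply(train_set, `[[`, numeric(1), "ddg")
  vbatch <- NULL
  yv <- NULL
  if (!is.null(validation)) {
    vbatch <- prepare_batch(validation, config, provider)
    yv <- vapply(validation, `[[`, numeric(1), "ddg")
  }

  params <- init_params(config, seed)
  run <- ddg_train_core(params, batch$sfw, batch$sfm, y, config,
                        epochs = epochs, lr = lr, batch_size = batch_size,
                        seed = seed, lr_halve = lr_halve,
                        check_every = check_every, patience = patience,
                        vsfw = if (is.null(vbatch)) NULL else vbatch$sfw,
                        vsfm = if (is.null(vbatch)) NULL else vbatch$sfm,
                        yv = yv, val_every = val_every, verbose = verbose)

  fitted_all <- ddg_forward(batch$sfw, batch$sfm, run$params, config)$pred
  keep <- seq_along(samples)          # originals precede their reverses
  structure(list(params = run$params, config = config, history = run$history,
                 fitted = fitted_all[keep],
                 labels = y[keep],
                 provider = provider, seed = seed, augment = augment,
                 n_train = length(samples), call = cl),
            class = "ddg_model")
}

# Core optimization loop over pre-stacked features.
ddg_train_core <- function(params, sfw, sfm, y, config, epochs, lr,
                           batch_size = NULL, seed = 1L, lr_halve = TRUE,
                           check_every = 100L, patience = 10L,
                           vsfw = NULL, vsfm = NULL, yv = NULL,
                           val_every = 50L, verbose = FALSE) {
  B <- sfw$B
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0), val_loss = numeric(0))
  cur_lr <- lr
  full <- is.null(batch_size) || batch_size >= B
  losses <- numeric(epochs)

  with_preserved_seed(seed * 23L + 9L, {
    for (e in seq_len(epochs)) {
      if (full) {
        fwd <- ddg_forward(sfw, sfm, params, config,
                           train = config$dropout > 0, want_cache = TRUE)
        res <- fwd$pred - y
        loss <- mean(res^2)
        grads <- ddg_backward(fwd, sfw, sfm, params, config, 2 * res / B)
        upd <- adam_step(params, grads, state, cur_lr)
        params <- upd$params; state <- upd$state
      } else {
        ord <- sample.int(B)
        tot <- 0
        for (start in seq(1, B, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1, B)]
          bw <- slice_stack(sfw, idx); bm <- slice_stack(sfm, idx)
          fwd <- ddg_forward(bw, bm, params, config,
                             train = config$dropout > 0, want_cache = TRUE)
          res <- fwd$pred - y[idx]
          tot <- tot + sum(res^2)
          grads <- ddg_backward(fwd, bw, bm, params, config,
                                2 * res / length(idx))
          upd <- adam_step(params, grads, state, cur_lr)
          params <- upd$params; state <- upd$state
        }
        loss <- tot / B
      }
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", e,
             "; reduce the learning rate")
      losses[e] <- loss

      vloss <- NA_real_
      if (!is.null(vsfw) && (e %% val_every == 0L || e == epochs)) {
        vloss <- mean((ddg_forward(vsfw, vsfm, params, config)$pred - yv)^2)
      }
      history <- rbind(history,
                       data.frame(epoch = e, loss = loss, lr = cur_lr,
                                  val_loss = vloss))
      if (verbose && (e %% 25L == 0L || e == 1L))
        message(sprintf("epoch %4d  loss %.4f  lr %.2e", e, loss, cur_lr))

      if (lr_halve && e %% check_every == 0L && e > patience) {
        recent <- losses[(e - patience + 1L):e]
        before <- min(losses[seq_len(e - patience)])
        if (min(recent) >= before) cur_lr <- cur_lr / 2
      }
    }
  })
  list(params = params, history = history)
}

# Subset a stacked feature batch.
slice_stack <- function(sf, idx) {
  n <- sf$n
  rows <- as.vector(outer(seq_len(n), (idx - 1) * n, "+"))
  prow <- as.vector(outer(seq_len(n * n), (idx - 1) * n * n, "+"))
  list(B = length(idx), n = n,
       X0 = sf$X0[rows, , drop = FALSE],
       rbf = sf$rbf[prow, , drop = FALSE],
       contact_code = sf$contact_code[prow],
       seqsep_code = sf$seqsep_code[prow],
       pairtype_code = sf$pairtype_code[prow],
       pairvalid = sf$pairvalid[prow],
       mask = sf$mask[, idx, drop = FALSE],
       maskrow = sf$maskrow[rows],
       anchors = sf$anchors[rows, , drop = FALSE],
       frames_R = sf$frames_R[rows, , drop = FALSE],
       origins = sf$origins[rows, , drop = FALSE],
       row_sample = rep(seq_along(idx), each = n))
}

# ---------------------------------------------------------------------------
# S3 methods

#' @export
print.ddg_model <- function(x, ...) {
  cat(sprintf("ddG graph-attention model (%d blocks, d_model = %d, H = %d, n_max = %d)\n",
              x$config$n_blocks, x$config$d_model, x$config$H, x$config$n_max))
  cat(sprintf("trained on %d samples%s, %d epochs; final training loss %.4f\n",
              x$n_train,
              if (x$augment) " (+ reverse augmentation)" else "",
              nrow(x$history), tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.ddg_model <- function(object, ...) {
  m <- compute_metrics(object$fitted, object$labels)
  out <- list(config = object$config, history = object$history,
              train_metrics = m, n_train = object$n_train)
  class(out) <- "summary.ddg_model"
  out
}

#' @export
print.summary.ddg_model <- function(x, ...) {
  cat("Training-set metrics:\n")
  cat(sprintf("  Rp %.3f | RMSE %.3f | MAE %.3f kcal/mol (n = %d)\n",
              x$train_metrics$rp, x$train_metrics$rmse, x$train_metrics$mae,
              x$train_metrics$n))
  cat(sprintf("Final loss %.4f after %d epochs (lr ends at %.2e)\n",
              tail(x$history$loss, 1), nrow(x$history),
              tail(x$history$lr, 1)))
  invisible(x)
}

#' @export
coef.ddg_model <- function(object, ...) object$params

#' @export
residuals.ddg_model <- function(object, ...) object$labels - object$fitted

#' Predict ddG for new samples
#'
#' @param object a fitted `ddg_model`.
#' @param newdata list of `sample_record` (or a single one).
#' @param type `"response"` for ddG values, `"contributions"` for per-residue
#'   decompositions.
#' @param chunk samples encoded per internal batch.
#' @param ... unused.
#' @return numeric vector (response) or list of contribution lists.
#' @export
predict.ddg_model <- function(object, newdata, type = c("response", "contributions"),
                              chunk = 200L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "sample_record")) newdata <- list(newdata)
  if (type == "contributions") {
    return(lapply(newdata, per_residue_contributions, params = object$params,
                  config = object$config, provider = object$provider))
  }
  preds <- numeric(length(newdata))
  for (start in seq(1, length(newdata), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(newdata))
    b <- prepare_batch(newdata[idx], object$config, object$provider)
    preds[idx] <- ddg_forward(b$sfw, b$sfm, object$params, object$config)$pred
  }
  preds
}

#' @export
plot.ddg_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training MSE", log = "y", ...)
  graphics::plot(x$labels, x$fitted, xlab = "observed ddG (kcal/mol)",
                 ylab = "fitted ddG (kcal/mol)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
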