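# Attention interpretability: residue region classification, top-k attention
# extraction, and region-wise summaries.

REGION_LEVELS <- c("MUT_AROUND", "INTERFACE_AROUND", "CLASS_CROSS",
                   "BACKGROUND")

# Minimum heavy-atom distance from each residue in `idx` to any atom in the
# residue set `ref_idx`.
min_atom_dist <- function(x, idx, ref_idx) {
  ref <- do.call(rbind, x$atoms[ref_idx])
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    a <- x$atoms[[idx[k]]]
    d2 <- outer(rowSums(a^2), rowSums(ref^2), "+") - 2 * tcrossprod(a, ref)
    out[k] <- sqrt(max(0, min(d2)))
  }
  out
}

#' Classify residues into four mutually exclusive regions
#'
#' Near-mutation: any heavy atom within `cutoff` of any heavy atom of a
#' mutation-site residue (sites count as near).  Interface: any heavy atom
#' within `cutoff` of the opposite partner (a distance proxy for the
#' solvent-accessibility-based interface definition; labelled as such).
#' Regions: CLASS_CROSS = near and interface; MUT_AROUND = near only;
#' INTERFACE_AROUND = interface only; BACKGROUND = neither.
#'
#' @param structure a `complex_structure` with a two-group partner split.
#' @param mutations list of `mutation_spec` (or codes).
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 5).
#' @param idx residue positions to classify (default all).
#' @return factor of region labels over `idx`.
#' @export
classify_regions <- function(structure, mutations, cutoff = 5, idx = NULL) {
  if (is.character(mutations)) mutations <- lapply(mutations, parse_mutation_code)
  if (inherits(mutations, "mutation_spec")) mutations <- list(mutations)
  if (length(mutations) == 0L) stop("at least one mutation is required")
  validate_complex(structure, strict = TRUE)
  if (is.null(idx)) idx <- seq_len(n_residues(structure))
  sites <- vapply(mutations, function(m) {
    i <- residue_index(structure, m$chain_id, m$resseq)
    if (is.na(i)) stop("cannot resolve mutation site ", format_mutation(m))
    i
  }, integer(1))

  near <- min_atom_dist(structure, idx, sites) <= cutoff
  side <- partner_side(structure)
  interface <- logical(length(idx))
  for (s in c(1L, 2L)) {
    on_s <- which(side[idx] == s)
    opp <- which(side == (3L - s))
    if (length(on_s) && length(opp))
      interface[on_s] <- min_atom_dist(structure, idx[on_s], opp) <= cutoff
  }
  lab <- rep("BACKGROUND", length(idx))
  lab[near & !interface] <- "MUT_AROUND"
  lab[!near & interface] <- "INTERFACE_AROUND"
  lab[near & interface] <- "CLASS_CROSS"
  factor(lab, levels = REGION_LEVELS)
}

#' Top-k residues by received attention
#'
#' Per head, a residue's score is the column sum of post-softmax attention
#' received over valid query rows; the top k by score are returned (ties:
#' lower slot index first).
#'
#' @param attention post-softmax attention, array (H, n, n) (as returned in
#'   [encode_complex()]'s `attention`).
#' @param k list length per head (default 5; truncated if fewer valid
#'   residues).
#' @param mask logical slot validity.
#' @return list per head: data.frame(slot, score), k rows.
#' @export
top_attention_residues <- function(attention, k = 5L, mask = NULL) {
  H <- dim(attention)[1]; n <- dim(attention)[2]
  if (is.null(mask)) mask <- rep(TRUE, n)
  valid <- which(mask)
  lapply(seq_len(H), function(h) {
    M <- attention[h, , ]
    score <- colSums(M[valid, , drop = FALSE])
    score[!mask] <- -Inf
    ord <- order(-score, seq_len(n))
    top <- ord[seq_len(min(k, length(valid)))]
    data.frame(slot = top, score = score[top])
  })
}

#' Region-wise summary of high-attention residues
#'
#' Counts and fractions of top-k residues per region (fractions sum to 1),
#' with mean and quartiles of their attention scores.
#'
#' @param labels factor of region labels per slot (see [classify_regions()]).
#' @param top_lists per-head top-k lists from [top_attention_residues()].
#' @return data.frame, one row per region.
#' @export
region_summary <- function(labels, top_lists) {
  slots <- unlist(lapply(top_lists, `[[`, "slot"))
  scores <- unlist(lapply(top_lists, `[[`, "score"))
  reg <- labels[slots]
  total <- length(slots)
  do.call(rbind, lapply(REGION_LEVELS, function(r) {
    sel <- which(reg == r)
    qs <- if (length(sel)) stats::quantile(scores[sel], c(0.25, 0.5, 0.75))
          else c(NA_real_, NA_real_, NA_real_)
    data.frame(region = r, count = length(sel),
               fraction = length(sel) / total,
               mean_score = if (length(sel)) mean(scores[sel]) else NA_real_,
               q25 = qs[[1]], median = qs[[2]], q75 = qs[[3]])
  }))
}

#' Full interpretability report for one sample
#'
#' Encodes the wild-type complex, classifies the selected residues, ranks
#' top-k attention per head, and summarizes by region.
#'
#' @param sample a `sample_record`.
#' @param params,config model parameters and configuration.
#' @param k top-k per head.
#' @param cutoff region cutoff, Angstrom.
#' @param provider embedding provider.
#' @return list: labels, top (per head), summary, selection.
#' @export
explain_sample <- function(sample, params, config, k = 5L, cutoff = 5,
                           provider = default_provider(config)) {
  enc <- encode_complex(sample$wt, sample$mutations, params, config, provider)
  sel <- enc$selection
  labels <- classify_regions(sample$wt, sample$mutations, cutoff,
                             idx = sel$indices)
  labels <- factor(as.character(labels), levels = REGION_LEVELS)
  # pad labels to slot space (padding slots never rank: mask passed below)
  top <- top_attention_residues(enc$attention, k, mask = sel$mask)
  list(labels = labels, top = top,
       summary = region_summary(labels, top), selection = sel)
}
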