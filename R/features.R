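# SE(3)-invariant node features, pairwise descriptors, and the pluggable
# sequence-embedding provider.
#
# Invariance strategy: all geometric node features are expressed in the
# residue-local frame built from N, CA, C; all pairwise features are
# functions of distances, sequence separation, or residue types only.

#' Build the residue-local orthonormal frame
#'
#' e1 = unit(C - CA); e2 = Gram-Schmidt of (N - CA) against e1; e3 = e1 x e2;
#' R = \[e1 e2 e3\] column-wise, origin = CA.  Under a rigid motion (Q, t)
#' the frame transforms as R' = Q R, origin' = Q origin + t, so coordinates
#' mapped by x -> R^T (x - origin) are invariant.
#'
#' @param residue a residue record (see [get_residue()]).
#' @return list of class `local_frame` with `R` (3 x 3) and `origin`.
#' @export
build_local_frame <- function(residue) {
  a <- residue$atoms
  if (!all(c("N", "CA", "C") %in% rownames(a)))
    stop("incomplete backbone: cannot build local frame")
  ca <- a["CA", ]
  v1 <- a["C", ] - ca
  if (l2norm(v1) < 1e-3) stop("degenerate frame: C and CA coincide")
  e1 <- v1 / l2norm(v1)
  v2 <- a["N", ] - ca
  v2 <- v2 - sum(v2 * e1) * e1
  if (l2norm(v2) < 1e-3) stop("degenerate frame: N, CA, C are collinear")
  e2 <- v2 / l2norm(v2)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  structure(list(R = cbind(e1, e2, e3, deparse.level = 0), origin = ca),
            class = "local_frame")
}

#' Local heavy-atom geometry descriptor
#'
#' Maps up to 14 heavy atoms (canonical name order for the residue type) into
#' the residue-local frame by x -> R^T (x - origin); absent slots are zero
#' with presence flag 0.  Flattened as 42 coordinates (slot-major) followed
#' by 14 flags.
#'
#' @param residue a residue record.
#' @param frame its [build_local_frame()] result.
#' @return numeric vector of length 56.
#' @export
local_atom_geometry <- function(residue, frame) {
  slots <- aa_heavy_atoms(residue$aa)
  coords <- matrix(0, MAX_HEAVY_ATOMS, 3)
  flags <- numeric(MAX_HEAVY_ATOMS)
  a <- residue$atoms
  hit <- match(slots, rownames(a))
  for (s in seq_along(slots)) {
    if (!is.na(hit[s])) {
      coords[s, ] <- crossprod(frame$R, a[hit[s], ] - frame$origin)
      flags[s] <- 1
    }
  }
  c(as.vector(t(coords)), flags)
}

#' Pairwise C-beta distance matrix of a selection
#'
#' @param structure a `complex_structure`.
#' @param selection a `residue_selection`.
#' @param pad sentinel distance written into padding rows/columns.
#' @return n_max x n_max matrix, Angstrom.
#' @export
pairwise_distances <- function(structure, selection, pad = 999) {
  n <- selection$n_max
  nv <- sum(selection$mask)
  cb <- cbeta_matrix(structure, selection$indices)
  D <- matrix(pad, n, n)
  D[seq_len(nv), seq_len(nv)] <- as.matrix(stats::dist(cb))
  D
}

#' Binary contact map from a distance matrix
#'
#' contact\[i, j\] = 1 iff D\[i, j\] <= threshold and i != j.  The threshold is
#' closed (exactly 8.0 A counts as a contact).  Padding entries carry the
#' sentinel distance and therefore never register.
#'
#' @param D distance matrix.
#' @param threshold contact cutoff, Angstrom (default 8).
#' @return binary matrix of the same shape.
#' @export
contact_map <- function(D, threshold = 8) {
  if (threshold <= 0) stop("contact threshold must be positive")
  C <- (D <= threshold) * 1
  diag(C) <- 0
  C
}

#' Signed, clipped sequence separation
#'
#' Within a chain: clamp(resseq_j - resseq_i, -clip, clip); across chains the
#' sentinel value clip + 1.  Padding positions are 0.
#'
#' @param structure a `complex_structure`.
#' @param selection a `residue_selection`.
#' @param clip clipping bound (default 32).
#' @return n_max x n_max integer matrix.
#' @export
sequence_separation <- function(structure, selection, clip = 32L) {
  n <- selection$n_max
  nv <- sum(selection$mask)
  out <- matrix(0L, n, n)
  ch <- structure$chain[selection$indices]
  rs <- structure$resseq[selection$indices]
  sep <- pmin(pmax(outer(rs, rs, function(i, j) j - i), -clip), clip)
  sep[outer(ch, ch, "!=")] <- clip + 1L
  out[seq_len(nv), seq_len(nv)] <- sep
  out
}

# Residue-pair type index (ordered 20 x 20 vocabulary, 1..400).
pair_types <- function(structure, selection) {
  n <- selection$n_max
  nv <- sum(selection$mask)
  ai <- match(structure$aa[selection$indices], AA1)
  out <- matrix(1L, n, n)
  out[seq_len(nv), seq_len(nv)] <- outer(ai, ai, function(i, j) (i - 1L) * 20L + j)
  out
}

#' Sinusoidal positional encoding over within-chain index
#'
#' @param pos integer positions (1-based within chain).
#' @param P encoding dimension (even, default 16).
#' @return length(pos) x P matrix.
#' @export
positional_encoding <- function(pos, P = 16L) {
  stopifnot(P %% 2 == 0)
  k <- seq_len(P / 2)
  freq <- 1 / 10000^(2 * (k - 1) / P)
  ang <- outer(pos, freq)
  out <- matrix(0, length(pos), P)
  out[, 2 * k - 1] <- sin(ang)
  out[, 2 * k] <- cos(ang)
  out
}

# ---------------------------------------------------------------------------
# Embedding provider

#' Deterministic mock sequence-embedding provider
#'
#' Stands in for an external protein-language-model: each residue's E-vector
#' is a deterministic function of (residue type, within-chain index, seed)
#' with unit-variance entries.  Mirroring the structure of real per-residue
#' language-model embeddings -- dominated by residue identity with a weaker
#' positional component -- the vector is a fixed type vector plus a smaller
#' fixed position vector (weights 0.95 and sqrt(1 - 0.95^2)).  A real
#' provider can be attached through the same interface: a list with
#' `embed_dim` and `embed(chains)` returning one (length x E) matrix per
#' chain string.
#'
#' @param embed_dim embedding width E (default 32).
#' @param seed provider seed.
#' @return list of class `embedding_provider`.
#' @export
mock_embedding_provider <- function(embed_dim = 32L, seed = 0L) {
  E <- as.integer(embed_dim)
  w_type <- 0.95
  w_pos <- sqrt(1 - w_type^2)
  type_vec <- function(aa) {
    h <- (seed * 7919 + match(aa, AA1) * 104729) %% 2147483647
    with_preserved_seed(h, stats::rnorm(E))
  }
  pos_vec <- function(i) {
    h <- (seed * 7919 + 2099 + i * 1299709) %% 2147483647
    with_preserved_seed(h, stats::rnorm(E))
  }
  embed_one <- function(seq_string) {
    aas <- strsplit(seq_string, "")[[1]]
    out <- matrix(0, length(aas), E)
    for (i in seq_along(aas)) {
      out[i, ] <- w_type * type_vec(aas[i]) + w_pos * pos_vec(i)
    }
    out
  }
  structure(list(embed_dim = E,
                 embed = function(chains) lapply(chains, embed_one)),
            class = "embedding_provider")
}

#' Mock per-residue embeddings for a set of chains
#'
#' Convenience wrapper over [mock_embedding_provider()].
#'
#' @param chains character vector of per-chain amino-acid strings.
#' @param seed provider seed.
#' @param E embedding width.
#' @return list of (length x E) matrices.
#' @export
mock_embeddings <- function(chains, seed = 0L, E = 32L) {
  mock_embedding_provider(E, seed)$embed(chains)
}

# ---------------------------------------------------------------------------
# Full per-sample feature bundle

rbf_expand <- function(d, centers) {
  sigma <- centers[2] - centers[1]
  exp(-(outer(d, centers, "-"))^2 / (2 * sigma^2))
}

# Assemble everything the encoder needs for one structure + selection.
# Padding slots carry zero node features, sentinel distances, and are flagged
# invalid in `mask` / `pairvalid`.
build_features <- function(structure, selection, provider, config) {
  n <- selection$n_max
  nv <- sum(selection$mask)
  idx <- selection$indices

  aa_idx <- match(structure$aa[idx], AA1)
  onehot <- matrix(0, n, 20)
  onehot[cbind(seq_len(nv), aa_idx)] <- 1

  # True within-chain position (index in the full chain, not the selected
  # subsequence), so encodings of a residue do not depend on which subgraph
  # it was selected into.
  chain_pos <- stats::ave(seq_len(n_residues(structure)), structure$chain,
                          FUN = seq_along)
  pe <- matrix(0, n, config$pos_enc_dim)
  pe[seq_len(nv), ] <- positional_encoding(chain_pos[idx], config$pos_enc_dim)

  geom <- matrix(0, n, 56)
  frames_R <- matrix(0, n, 9)
  origins <- matrix(0, n, 3)
  anchors <- matrix(0, n, 3)
  for (k in seq_len(nv)) {
    res <- get_residue(structure, idx[k])
    fr <- build_local_frame(res)
    geom[k, ] <- local_atom_geometry(res, fr)
    frames_R[k, ] <- as.vector(fr$R)
    origins[k, ] <- fr$origin
    anchors[k, ] <- get_cbeta(res)
  }

  # Embed the full chains (as a language model would see them) and take the
  # selected residues' rows, keyed by true chain position.
  chains <- unique(structure$chain)
  full_seqs <- vapply(chains, function(ch)
    paste(structure$aa[structure$chain == ch], collapse = ""), character(1))
  embs <- provider$embed(full_seqs)
  emb <- matrix(0, n, provider$embed_dim)
  if (nv > 0) {
    chain_of <- structure$chain[idx]
    for (ci in seq_along(chains)) {
      rows <- which(chain_of == chains[ci])
      if (length(rows)) emb[rows, ] <- embs[[ci]][chain_pos[idx][rows], ]
    }
  }

  D <- pairwise_distances(structure, selection)
  cont <- contact_map(D, config$contact_threshold)
  seqsep <- sequence_separation(structure, selection, config$seqsep_clip)
  ptype <- pair_types(structure, selection)

  mask <- selection$mask
  pairvalid <- as.vector(outer(mask, mask, "&"))
  centers <- seq(0, 20, length.out = config$rbf_centers)
  rbf <- rbf_expand(as.vector(D), centers)
  rbf[!pairvalid, ] <- 0

  # Embedding-table codes: seqsep -clip..clip -> 1..2clip+1, cross-chain
  # sentinel -> 2clip+2; padding rows point at code 1 but are masked.
  clip <- config$seqsep_clip
  scode <- as.vector(seqsep) + clip + 1L
  scode[as.vector(seqsep) == clip + 1L] <- 2L * clip + 2L
  scode[!pairvalid] <- 1L

  list(n = n, nv = nv, mask = mask, sel = selection,
       X0 = cbind(onehot, pe, geom, emb),
       D = D,
       pairvalid = pairvalid,
       rbf = rbf,
       contact_code = as.integer(as.vector(cont)) + 1L,
       seqsep_code = as.integer(scode),
       pairtype_code = as.integer(as.vector(ptype)),
       anchors = anchors, frames_R = frames_R, origins = origins)
}
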