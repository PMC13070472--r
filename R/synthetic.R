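# Synthetic two-chain complexes with a known additive contact-energy oracle.
#
# Each chain is an idealized alpha-helix (1.5 A rise, 100 deg twist, 2.3 A
# radius for the C-alpha trace); N, C, O are placed with fixed local-frame
# offsets and C-beta by the idealized tetrahedral construction, so frames and
# virtual-C-beta code paths are exercised with well-conditioned geometry.
# The two helices are antiparallel-adjacent, positioned so that the minimum
# cross-chain C-alpha distance hits a target interface gap, giving a genuine
# interface band.  Labels come from a cross-partner contact energy
# (hydropathy-product weights) plus Gaussian noise.

#' Specification of a synthetic toy complex
#'
#' @param n_per_chain residues per chain (>= 4).
#' @param seed RNG seed controlling residue types.
#' @param interface_gap target minimum cross-chain C-alpha distance, Angstrom
#'   (in \[4, 10\]).
#' @param noise_sigma label noise standard deviation, kcal/mol.
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(n_per_chain = 20L, seed = 1L, interface_gap = 5,
                     noise_sigma = 0.25) {
  stopifnot(n_per_chain >= 4L, interface_gap >= 4, interface_gap <= 10,
            noise_sigma >= 0)
  structure(list(n_per_chain = as.integer(n_per_chain), seed = as.integer(seed),
                 interface_gap = interface_gap, noise_sigma = noise_sigma),
            class = "toy_spec")
}

helix_trace <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  t <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1) * rise)
}

# Backbone + C-beta from a C-alpha trace using per-residue tangent/radial/
# binormal frames; all offsets are fixed in the local frame so the chain has
# uniform idealized geometry.
build_chain_atoms <- function(ca, aa, axis_shift = c(0, 0, 0)) {
  n <- nrow(ca)
  prev <- ca[c(1, seq_len(n - 1)), , drop = FALSE]
  nxt <- ca[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  tg <- nxt - prev
  tg <- tg / sqrt(rowSums(tg^2))
  rad <- ca - matrix(axis_shift, n, 3, byrow = TRUE)
  rad[, 3] <- 0                         # radial direction off the helix axis
  rad <- rad / sqrt(rowSums(rad^2))
  bi <- cbind(tg[, 2] * rad[, 3] - tg[, 3] * rad[, 2],
              tg[, 3] * rad[, 1] - tg[, 1] * rad[, 3],
              tg[, 1] * rad[, 2] - tg[, 2] * rad[, 1])
  bi <- bi / sqrt(rowSums(bi^2))
  uN <- -0.608 * tg + 0.761 * rad - 0.226 * bi
  uN <- uN / sqrt(rowSums(uN^2))
  uC <- 0.608 * tg + 0.761 * rad + 0.226 * bi
  uC <- uC / sqrt(rowSums(uC^2))
  uO <- 0.25 * tg + 0.55 * rad + 0.80 * bi
  uO <- uO / sqrt(rowSums(uO^2))
  N <- ca + 1.458 * uN
  C <- ca + 1.525 * uC
  O <- C + 1.229 * uO
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    m <- rbind(N = N[i, ], CA = ca[i, ], C = C[i, ], O = O[i, ])
    if (aa[i] != "G") {
      m <- rbind(m, CB = virtual_cbeta(N[i, ], ca[i, ], C[i, ]))
    }
    atoms[[i]] <- m
  }
  atoms
}

#' Generate a synthetic two-chain complex
#'
#' Deterministic: the same `toy_spec` always yields an identical structure.
#' Chains are "A" and "B"; partner split is A vs B.
#'
#' @param spec a [toy_spec()].
#' @return a `complex_structure`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_per_chain
  aa_pool <- AA1
  aa <- with_preserved_seed(spec$seed * 2L + 11L, {
    list(a = sample(aa_pool, n, replace = TRUE),
         b = sample(aa_pool, n, replace = TRUE))
  })

  ca_a <- helix_trace(n)
  ca_b0 <- helix_trace(n)
  # Antiparallel copy: rotate 180 deg about x, stagger half a rise.
  ca_b0[, 2] <- -ca_b0[, 2]
  ca_b0[, 3] <- max(ca_a[, 3]) - ca_b0[, 3] + 0.75

  place_b <- function(dx) {
    b <- ca_b0
    b[, 1] <- b[, 1] + dx
    b
  }
  mind <- function(dx) {
    b <- place_b(dx)
    min(sqrt(outer(rowSums(ca_a^2), rowSums(b^2), "+") -
               2 * tcrossprod(ca_a, b)))
  }
  lo <- 4.6; hi <- 40                  # helix diameter keeps lo feasible
  if (mind(hi) < spec$interface_gap) stop("infeasible interface gap")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mind(mid) < spec$interface_gap) lo <- mid else hi <- mid
  }
  dx <- hi
  ca_b <- place_b(dx)

  atoms_a <- build_chain_atoms(ca_a, aa$a, axis_shift = c(0, 0, 0))
  atoms_b <- build_chain_atoms(ca_b, aa$b, axis_shift = c(dx, 0, 0))
  new_complex_structure(chain = rep(c("A", "B"), each = n),
                        resseq = c(seq_len(n), seq_len(n)),
                        icode = character(0),
                        aa = c(aa$a, aa$b),
                        atoms = c(atoms_a, atoms_b),
                        partners = list(g1 = "A", g2 = "B"))
}

#' Build a mutant structure from a wild-type complex
#'
#' The residue type at the site is replaced; the C-beta of the site and of
#' residues whose C-beta lies within 5 A of it are jittered by Gaussian noise
#' (sigma 0.3 A, seeded) to emulate side-chain repacking.  Backbone atoms are
#' untouched.
#'
#' @param complex wild-type `complex_structure`.
#' @param mutation a `mutation_spec` (or code string).
#' @param seed RNG seed for the jitter.
#' @return mutant `complex_structure`.
#' @export
make_mutant <- function(complex, mutation, seed = 1L) {
  if (is.character(mutation)) mutation <- parse_mutation_code(mutation)
  i <- residue_index(complex, mutation$chain_id, mutation$resseq)
  if (is.na(i)) stop("mutation site ", format_mutation(mutation), " not found")
  if (complex$aa[i] != mutation$wt_aa)
    stop("wild-type mismatch at ", format_mutation(mutation),
         ": structure has ", complex$aa[i])
  mut <- complex
  mut$aa[i] <- mutation$mut_aa

  site_a <- mut$atoms[[i]]
  # Ensure the mutant's atom inventory matches its new type for CB presence:
  # G -> X gains a virtual-constructed CB; X -> G loses it.
  if (mutation$mut_aa == "G") {
    site_a <- site_a[setdiff(rownames(site_a), "CB"), , drop = FALSE]
  } else if (!("CB" %in% rownames(site_a))) {
    site_a <- rbind(site_a,
                    CB = virtual_cbeta(site_a["N", ], site_a["CA", ],
                                       site_a["C", ]))
  }
  mut$atoms[[i]] <- site_a

  cb <- cbeta_matrix(mut)
  d_to_site <- sqrt(colSums((t(cb) - cb[i, ])^2))
  near <- which(d_to_site <= 5)
  with_preserved_seed(seed * 3L + 7L, {
    for (j in near) {
      a <- mut$atoms[[j]]
      if ("CB" %in% rownames(a)) {
        a["CB", ] <- a["CB", ] + stats::rnorm(3, 0, 0.3)
        mut$atoms[[j]] <- a
      }
    }
  })
  mut
}

#' Hydropathy-product contact weights for the synthetic oracle
#'
#' Symmetric 20 x 20 table w(a, b) = -0.1 * kd(a) * kd(b) (Kyte-Doolittle);
#' hydrophobic-hydrophobic cross-interface contacts are favourable.
#'
#' @return named 20 x 20 matrix, kcal/mol per contact.
#' @export
oracle_weights <- function() {
  w <- -0.1 * outer(KD_HYDROPATHY, KD_HYDROPATHY)
  dimnames(w) <- list(names(KD_HYDROPATHY), names(KD_HYDROPATHY))
  w
}

oracle_energy <- function(x, weights, cutoff = 8) {
  side <- partner_side(x)
  cb <- cbeta_matrix(x)
  i1 <- which(side == 1L); i2 <- which(side == 2L)
  d <- sqrt(outer(rowSums(cb[i1, , drop = FALSE]^2),
                  rowSums(cb[i2, , drop = FALSE]^2), "+") -
              2 * tcrossprod(cb[i1, , drop = FALSE], cb[i2, , drop = FALSE]))
  pairs <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(0)
  sum(weights[cbind(x$aa[i1[pairs[, 1]]], x$aa[i2[pairs[, 2]]])])
}

#' Ground-truth ddG from the synthetic contact-energy oracle
#'
#' E(S) sums w(a_i, b_j) over cross-partner C-beta pairs closer than 8 A;
#' the label is E(mut) - E(wt) plus Gaussian noise.  With zero noise,
#' reversing the mutation negates the label exactly.
#'
#' @param wt,mut aligned `complex_structure` objects.
#' @param weights contact weight table (default [oracle_weights()]).
#' @param noise_sigma noise SD, kcal/mol.
#' @param seed RNG seed for the noise draw.
#' @return ddG, kcal/mol.
#' @export
oracle_ddg <- function(wt, mut, weights = oracle_weights(), noise_sigma = 0,
                       seed = 1L) {
  if (n_residues(wt) != n_residues(mut) ||
      !all(wt$chain == mut$chain) || !all(wt$resseq == mut$resseq))
    stop("wild-type and mutant structures are not residue-aligned")
  e <- oracle_energy(mut, weights) - oracle_energy(wt, weights)
  if (noise_sigma > 0) {
    e <- e + with_preserved_seed(seed * 5L + 3L,
                                 stats::rnorm(1, 0, noise_sigma))
  }
  e
}

# Residues with at least one cross-chain C-beta neighbour within 10 A --
# the candidate pool for interface-biased mutation placement.
interface_candidates <- function(x) {
  side <- partner_side(x)
  cb <- cbeta_matrix(x)
  d <- as.matrix(stats::dist(cb))
  cross <- outer(side, side, "!=")
  which(apply(d < 10 & cross, 1, any))
}

#' Generate a synthetic labelled dataset
#'
#' Draws `n` independent (complex, mutation, mutant, label) samples.  Mutation
#' sites are interface-biased (probability 0.7 a site with a cross-chain
#' C-beta neighbour within 10 A, else uniform), reflecting the
#' interface-mutation character of curated ddG benchmarks.
#'
#' @param n number of samples.
#' @param spec a [toy_spec()]; its seed is combined with per-sample indices.
#' @param seed master seed.
#' @return list of `sample_record`.
#' @export
make_dataset <- function(n, spec = toy_spec(), seed = 1L) {
  weights <- oracle_weights()
  lapply(seq_len(n), function(k) {
    s <- spec
    s$seed <- seed * 10000L + k
    wt <- make_toy_complex(s)
    cand <- interface_candidates(wt)
    if (length(cand) == 0L) cand <- seq_len(n_residues(wt))
    site <- with_preserved_seed(s$seed * 7L + 1L, {
      pool <- if (stats::runif(1) < 0.7) cand else seq_len(n_residues(wt))
      pool[sample.int(length(pool), 1L)]
    })
    mut_aa <- with_preserved_seed(s$seed * 7L + 2L, {
      sample(setdiff(AA1, wt$aa[site]), 1L)
    })
    mspec <- structure(list(wt_aa = wt$aa[site], chain_id = wt$chain[site],
                            resseq = wt$resseq[site], mut_aa = mut_aa),
                       class = "mutation_spec")
    mut <- make_mutant(wt, mspec, seed = s$seed)
    ddg <- oracle_ddg(wt, mut, weights, noise_sigma = spec$noise_sigma,
                      seed = s$seed)
    sample_record(wt, mut, list(mspec), ddg)
  })
}

#' Write a dataset as PDB files plus a manifest
#'
#' @param dataset list of `sample_record`.
#' @param dir output directory (created if needed).
#' @return path of the written manifest (TSV).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(k) {
    s <- dataset[[k]]
    wtf <- sprintf("sample%04d_wt.pdb", k)
    mtf <- sprintf("sample%04d_mut.pdb", k)
    write_pdb(s$wt, file.path(dir, wtf))
    write_pdb(s$mut, file.path(dir, mtf))
    data.frame(wt_pdb = wtf, mut_pdb = mtf,
               mutations = paste(vapply(s$mutations, format_mutation, ""),
                                 collapse = ";"),
               ddg = s$ddg)
  })
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
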