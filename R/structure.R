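# Domain types for protein complexes, mutations and samples.
#
# A `complex_structure` stores an ordered residue list (sorted by chain,
# author residue number, insertion code) in a column-oriented layout:
#   chain, resseq, icode, aa  -- per-residue vectors
#   atoms                     -- list of k x 3 coordinate matrices (rownames =
#                                atom names, heavy atoms only)
#   complete                  -- has N, CA and C (residues failing this are
#                                flagged and excluded from modelling)
#   partners                  -- list(g1 =, g2 =) partition of chain ids into
#                                the two interacting sides

new_complex_structure <- function(chain, resseq, icode, aa, atoms,
                                  partners = NULL) {
  n <- length(chain)
  stopifnot(length(resseq) == n, length(aa) == n, length(atoms) == n)
  if (length(icode) == 0L) icode <- rep("", n)
  ord <- order(chain, resseq, icode)
  chain <- chain[ord]; resseq <- as.integer(resseq[ord])
  icode <- icode[ord]; aa <- aa[ord]; atoms <- atoms[ord]
  if (!all(aa %in% AA1)) stop("non-canonical amino-acid type: ",
                              paste(setdiff(aa, AA1), collapse = ", "))
  complete <- vapply(atoms, function(a)
    all(c("N", "CA", "C") %in% rownames(a)), logical(1))
  chains <- unique(chain)
  if (is.null(partners)) partners <- list(g1 = chains[1], g2 = chains[-1])
  structure(list(chain = chain, resseq = resseq, icode = icode, aa = aa,
                 atoms = atoms, complete = complete, partners = partners),
            class = "complex_structure")
}

#' Number of residues in a complex
#' @param x a `complex_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(x) length(x$chain)

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure> %d residues, chains %s | partners: {%s} vs {%s}\n",
              n_residues(x), paste(unique(x$chain), collapse = ","),
              paste(x$partners$g1, collapse = ","),
              paste(x$partners$g2, collapse = ",")))
  invisible(x)
}

#' Override the partner grouping of a complex
#'
#' The two groups must be disjoint, non-empty, and jointly cover all chains.
#'
#' @param x a `complex_structure`.
#' @param g1,g2 character vectors of chain ids.
#' @return the modified structure.
#' @export
set_partners <- function(x, g1, g2) {
  chains <- unique(x$chain)
  if (length(intersect(g1, g2)) > 0L) stop("partner groups must be disjoint")
  if (!setequal(union(g1, g2), chains))
    stop("partner groups must cover all chains")
  if (length(g1) == 0L || length(g2) == 0L)
    stop("partner groups must be non-empty")
  x$partners <- list(g1 = g1, g2 = g2)
  x
}

#' Partner side (1 or 2) of every residue
#' @param x a `complex_structure`.
#' @return integer vector in \{1, 2\} (NA if a chain is in neither group).
#' @export
partner_side <- function(x) {
  side <- rep(NA_integer_, n_residues(x))
  side[x$chain %in% x$partners$g1] <- 1L
  side[x$chain %in% x$partners$g2] <- 2L
  side
}

#' Extract a single residue record
#' @param x a `complex_structure`.
#' @param i residue position.
#' @return list with chain_id, resseq, icode, aa, atoms (matrix), complete.
#' @export
get_residue <- function(x, i) {
  list(chain_id = x$chain[i], resseq = x$resseq[i], icode = x$icode[i],
       aa = x$aa[i], atoms = x$atoms[[i]], complete = x$complete[i])
}

#' Locate a residue by chain and author numbering
#' @param x a `complex_structure`.
#' @param chain chain id.
#' @param resseq author residue number.
#' @param icode insertion code ("" for none).
#' @return residue position, or NA if absent.
#' @export
residue_index <- function(x, chain, resseq, icode = "") {
  hit <- which(x$chain == chain & x$resseq == resseq & x$icode == icode)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

validate_complex <- function(x, strict = FALSE) {
  stopifnot(inherits(x, "complex_structure"))
  if (n_residues(x) == 0L) stop("complex has no residues")
  if (strict) {
    if (length(unique(x$chain)) < 2L)
      stop("complex must contain at least two chains")
    if (length(x$partners$g1) == 0L || length(x$partners$g2) == 0L)
      stop("both partner groups must be non-empty")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# C-beta representative

#' C-beta coordinates of a residue (virtual for glycine)
#'
#' Returns the stored CB atom if present; otherwise an idealized virtual
#' C-beta built from N, CA, C with tetrahedral geometry and a 1.522 A CA-CB
#' bond.  The construction uses only backbone difference vectors, so it is
#' exactly rigid-motion equivariant.
#'
#' @param residue a residue record (see [get_residue()]).
#' @return numeric 3-vector, Angstrom.
#' @export
get_cbeta <- function(residue) {
  a <- residue$atoms
  if ("CB" %in% rownames(a)) return(as.numeric(a["CB", ]))
  if (!all(c("N", "CA", "C") %in% rownames(a)))
    stop("incomplete backbone: cannot build virtual C-beta")
  virtual_cbeta(a["N", ], a["CA", ], a["C", ])
}

virtual_cbeta <- function(N, CA, C) {
  n <- N - CA; c <- C - CA
  ln <- sqrt(sum(n^2)); lc <- sqrt(sum(c^2))
  if (ln < 1e-3 || lc < 1e-3) stop("degenerate backbone geometry")
  nn <- n / ln; cc <- c / lc
  perp <- c(nn[2] * cc[3] - nn[3] * cc[2],
            nn[3] * cc[1] - nn[1] * cc[3],
            nn[1] * cc[2] - nn[2] * cc[1])
  lp <- sqrt(sum(perp^2))
  if (lp < 1e-3) stop("collinear N, CA, C: cannot build virtual C-beta")
  perp <- perp / lp
  bis <- nn + cc; bis <- bis / sqrt(sum(bis^2))
  cosb <- sum(bis * nn)                      # cos of half the N-CA-C angle
  cosa <- min(1, max(-1, 0.3502074 / cosb))  # target angle CB-CA-N = 110.5 deg
  sina <- sqrt(1 - cosa^2)
  as.numeric(CA + 1.522 * (-cosa * bis + sina * perp))
}

# Vectorized C-beta for a set of residue positions.
cbeta_matrix <- function(x, idx = seq_len(n_residues(x))) {
  out <- matrix(NA_real_, length(idx), 3)
  for (k in seq_along(idx)) out[k, ] <- get_cbeta(get_residue(x, idx[k]))
  out
}

# ---------------------------------------------------------------------------
# Mutation codes

#' Parse a mutation code
#'
#' Codes have the form `<wtAA><chain><resseq><mutAA>`, e.g. `"AE315C"`:
#' alanine at residue 315 of chain E mutated to cysteine.
#'
#' @param code mutation code string.
#' @return list with wt_aa, chain_id, resseq, mut_aa (class `mutation_spec`).
#' @export
parse_mutation_code <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([A-Za-z])([0-9]+)([A-Z])$", code))[[1]]
  if (length(m) == 0L)
    stop("malformed mutation code: '", code,
         "' (expected <AA><chain><position><AA>)")
  wt <- m[2]; chain <- m[3]; pos <- as.integer(m[4]); mut <- m[5]
  if (!wt %in% AA1) stop("unknown wild-type amino acid '", wt, "' in ", code)
  if (!mut %in% AA1) stop("unknown mutant amino acid '", mut, "' in ", code)
  if (wt == mut) stop("wild-type equals mutant in mutation code ", code)
  structure(list(wt_aa = wt, chain_id = chain, resseq = pos, mut_aa = mut),
            class = "mutation_spec")
}

#' Format a mutation spec back to its code
#' @param spec a `mutation_spec`.
#' @return string code.
#' @export
format_mutation <- function(spec) {
  paste0(spec$wt_aa, spec$chain_id, spec$resseq, spec$mut_aa)
}

#' Invert a mutation (wild type and mutant amino acids swapped)
#' @param spec a `mutation_spec`.
#' @return the reversed `mutation_spec`.
#' @export
invert_mutation <- function(spec) {
  structure(list(wt_aa = spec$mut_aa, chain_id = spec$chain_id,
                 resseq = spec$resseq, mut_aa = spec$wt_aa),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation>", format_mutation(x), "\n"); invisible(x)
}

# ---------------------------------------------------------------------------
# Sample records

#' Assemble a (wild type, mutant, mutations, ddG) sample
#'
#' Validates that every mutation site resolves in both structures, that the
#' wild-type structure carries `wt_aa` and the mutant structure `mut_aa` at
#' each site.  Sign convention, repo-wide: ddG = dG_mut - dG_wt; negative
#' values are affinity-enhancing.
#'
#' @param wt,mut `complex_structure` objects.
#' @param mutations list of `mutation_spec` (or character codes).
#' @param ddg experimental ddG, kcal/mol.
#' @return object of class `sample_record`.
#' @export
sample_record <- function(wt, mut, mutations, ddg) {
  if (is.character(mutations)) mutations <- lapply(mutations, parse_mutation_code)
  if (length(mutations) == 0L) stop("at least one mutation is required")
  for (m in mutations) {
    iw <- residue_index(wt, m$chain_id, m$resseq)
    im <- residue_index(mut, m$chain_id, m$resseq)
    if (is.na(iw) || is.na(im))
      stop("mutation site ", format_mutation(m),
           " not present in both structures")
    if (wt$aa[iw] != m$wt_aa)
      stop("wild-type residue at ", format_mutation(m), " is ", wt$aa[iw],
           ", expected ", m$wt_aa)
    if (mut$aa[im] != m$mut_aa)
      stop("mutant residue at ", format_mutation(m), " is ", mut$aa[im],
           ", expected ", m$mut_aa)
  }
  structure(list(wt = wt, mut = mut, mutations = mutations,
                 ddg = as.numeric(ddg)),
            class = "sample_record")
}

#' Reverse a sample (wild type and mutant exchanged, label negated)
#' @param s a `sample_record`.
#' @return the reversed `sample_record`.
#' @export
reverse_sample <- function(s) {
  sample_record(s$mut, s$wt, lapply(s$mutations, invert_mutation), -s$ddg)
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample> %s | ddG = %.3f kcal/mol\n",
              paste(vapply(x$mutations, format_mutation, ""), collapse = ";"),
              x$ddg))
  invisible(x)
}
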