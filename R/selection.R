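# Mutation-centred dynamic residue selection.  The modelling subgraph is the
# n_max residues closest (minimum C-beta distance) to any mutation site;
# attention cost downstream is O(n_max^2) regardless of complex size.

#' Select the fixed-size modelling subgraph around the mutation sites
#'
#' Ranking key: minimum C-beta--C-beta distance from a residue to any
#' mutation-site residue (sites themselves have key 0), so every site is
#' always included.  Ties break by (chain, resseq, icode); the returned
#' indices are re-sorted to global residue order.  Residues lacking a
#' complete backbone are excluded from consideration.
#'
#' @param structure a `complex_structure`.
#' @param mutations list of `mutation_spec` (or code strings).
#' @param n_max subgraph capacity (default 128).
#' @return object of class `residue_selection`: list with `indices` (global
#'   residue positions, increasing), `n_max`, `mask` (length-`n_max` validity
#'   flags), and `site_slots` (slot numbers of the mutation sites).
#' @export
select_residues <- function(structure, mutations, n_max = 128L) {
  keyed <- selection_keys(structure, mutations)
  finalize_selection(structure, keyed$sites, keyed$eligible, keyed$key,
                     as.integer(n_max))
}

# Ranking keys: minimum C-beta distance from each complete residue to any
# mutation site (sites get 0).
selection_keys <- function(structure, mutations) {
  if (inherits(mutations, "mutation_spec")) mutations <- list(mutations)
  if (is.character(mutations)) mutations <- lapply(mutations, parse_mutation_code)
  sites <- vapply(mutations, function(m) {
    i <- residue_index(structure, m$chain_id, m$resseq)
    if (is.na(i)) stop("cannot resolve mutation site ", format_mutation(m))
    i
  }, integer(1))
  sites <- unique(sites)
  eligible <- which(structure$complete)
  if (!all(sites %in% eligible))
    stop("mutation site residue lacks a complete backbone")
  cb <- cbeta_matrix(structure, eligible)
  cb_sites <- cb[match(sites, eligible), , drop = FALSE]
  key <- rep(Inf, length(eligible))
  for (s in seq_len(nrow(cb_sites))) {
    ds <- sqrt(colSums((t(cb) - cb_sites[s, ])^2))
    key <- pmin(key, ds)
  }
  key[match(sites, eligible)] <- 0
  list(sites = sites, eligible = eligible, key = key)
}

finalize_selection <- function(structure, sites, eligible, key, n_max) {
  if (n_max < length(sites))
    stop("n_max (", n_max, ") smaller than number of mutation sites (",
         length(sites), ")")
  tie <- order(structure$chain[eligible], structure$resseq[eligible],
               structure$icode[eligible])
  rk <- order(key[tie])                     # stable: ties keep (chain,resseq,icode)
  chosen <- eligible[tie][rk][seq_len(min(n_max, length(eligible)))]
  chosen <- sort(chosen)
  mask <- c(rep(TRUE, length(chosen)), rep(FALSE, n_max - length(chosen)))
  structure(list(indices = chosen, n_max = n_max, mask = mask,
                 site_slots = match(sites, chosen)),
            class = "residue_selection")
}

# Pair-symmetric selection for a (wild-type, mutant) pair: the ranking key
# is the minimum over both structures' C-beta distances, so exchanging the
# structures yields the identical subgraph -- a requirement for the exact
# antisymmetry of the prediction head.
select_residues_pair <- function(wt, mut, mutations, n_max = 128L) {
  kw <- selection_keys(wt, mutations)
  km <- selection_keys(mut, mutations)
  if (!identical(kw$eligible, km$eligible) || !identical(kw$sites, km$sites))
    stop("structures are not residue-aligned")
  finalize_selection(wt, kw$sites, kw$eligible, pmin(kw$key, km$key),
                     as.integer(n_max))
}

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("<residue_selection> %d/%d slots valid, %d mutation site(s)\n",
              sum(x$mask), x$n_max, length(x$site_slots)))
  invisible(x)
}

#' Per-chain amino-acid strings of a selection
#'
#' One string per chain of the structure, restricted to selected residues in
#' order; chains with no selected residue give an empty string.  The
#' concatenated lengths equal the number of valid slots.
#'
#' @param structure a `complex_structure`.
#' @param selection a `residue_selection`.
#' @return named character vector (names = chain ids).
#' @export
selection_sequence <- function(structure, selection) {
  chains <- unique(structure$chain)
  out <- vapply(chains, function(ch) {
    idx <- selection$indices[structure$chain[selection$indices] == ch]
    paste(structure$aa[idx], collapse = "")
  }, character(1))
  names(out) <- chains
  out
}
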