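# Cross-validation fold construction with independence certificates.
#
# Three modes: RSCV (random), SSCV (no structural domain shared between
# folds), C3 (no protein partner shared).  SSCV/C3 group samples by
# connected components over shared annotations, then balance fold sizes with
# a largest-group-first greedy rule; a verifier certifies the constraint.

#' Random k-fold assignment
#'
#' Seeded shuffle; fold sizes differ by at most one.
#'
#' @param sample_ids character or integer sample identifiers.
#' @param k fold count (default 10).
#' @param seed shuffle seed.
#' @return a `fold_assignment` (fold indices 0..k-1 named by sample id).
#' @export
rscv_folds <- function(sample_ids, k = 10L, seed = 1L) {
  n <- length(sample_ids)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  ord <- with_preserved_seed(seed * 29L + 3L, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep(seq_len(k) - 1L, length.out = n)
  new_fold_assignment(stats::setNames(fold, sample_ids), k, "RSCV")
}

new_fold_assignment <- function(fold_of, k, mode, certificate = NULL) {
  structure(list(fold_of = fold_of, k = as.integer(k), mode = mode,
                 certificate = certificate),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %s, %d samples in %d folds\n",
              x$mode, length(x$fold_of), x$k))
  print(table(fold = x$fold_of))
  if (!is.null(x$certificate))
    cat(sprintf("certificate: %d violation(s)\n",
                nrow(x$certificate$violations)))
  invisible(x)
}

# Connected components over a bipartite sample/annotation incidence, via the
# annotation co-membership graph.
annotation_components <- function(ids, ann_sets) {
  stopifnot(length(ids) == length(ann_sets))
  ord <- order(ids)                           # canonical input order
  ids <- ids[ord]; ann_sets <- ann_sets[ord]
  all_ann <- unique(unlist(ann_sets))
  edges <- character(0)
  for (i in seq_along(ids)) {
    for (a in ann_sets[[i]]) {
      edges <- c(edges, paste0("s:", ids[i]), paste0("a:", a))
    }
  }
  g <- igraph::make_graph(edges = edges, directed = FALSE)
  g <- igraph::add_vertices(g, 0)
  iso <- setdiff(paste0("s:", ids), igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  comp <- igraph::components(g)$membership
  split(ids, comp[paste0("s:", ids)])
}

greedy_assign <- function(groups, sizes, k) {
  if (length(groups) < k)
    stop("cannot form ", k, " non-empty folds from ", length(groups),
         " independent groups")
  ord <- order(-sizes, vapply(groups, function(g) min(as.character(g)),
                              character(1)))
  load <- numeric(k)
  fold_of <- integer(0)
  names_of <- character(0)
  for (gi in ord) {
    f <- which.min(load)                       # ties: lowest fold index
    load[f] <- load[f] + sizes[gi]
    fold_of <- c(fold_of, rep(f - 1L, length(groups[[gi]])))
    names_of <- c(names_of, as.character(groups[[gi]]))
  }
  stats::setNames(fold_of[order(names_of)], sort(names_of))
}

#' Structure-disjoint (domain-based) k-fold assignment
#'
#' Complexes sharing at least one structural domain are merged into groups
#' (connected components); groups are assigned largest-first to the
#' currently smallest fold, and samples inherit their complex's fold.  No
#' domain ever spans two folds.
#'
#' @param sample_complex named character vector: sample id -> complex id.
#' @param complex_domains named list: complex id -> character vector of
#'   domain ids (possibly empty).
#' @param k fold count.
#' @return a certified `fold_assignment`.
#' @export
sscv_folds <- function(sample_complex, complex_domains, k = 10L) {
  cx <- sort(unique(sample_complex))
  dom <- complex_domains[cx]
  dom[vapply(dom, is.null, logical(1))] <- list(character(0))
  comp_groups <- annotation_components(cx, dom)
  sizes <- vapply(comp_groups, function(g) sum(sample_complex %in% g),
                  numeric(1))
  cx_fold <- greedy_assign(comp_groups, sizes, k)
  fold <- cx_fold[sample_complex]
  names(fold) <- names(sample_complex)
  fa <- new_fold_assignment(fold, k, "SSCV")
  fa$certificate <- verify_independence(fa, list(sample_complex = sample_complex,
                                                 complex_domains = complex_domains))
  fa
}

#' Partner-disjoint (C3) k-fold assignment
#'
#' Samples sharing any partner protein land in the same fold; different
#' variants of the same partner pair are thereby never split across
#' train and test.
#'
#' @param sample_partners named list: sample id -> character vector of
#'   partner protein identifiers.
#' @param k fold count.
#' @return a certified `fold_assignment`.
#' @export
c3_folds <- function(sample_partners, k = 10L) {
  ids <- sort(names(sample_partners))
  groups <- annotation_components(ids, sample_partners[ids])
  sizes <- vapply(groups, length, numeric(1))
  fold <- greedy_assign(groups, sizes, k)
  fa <- new_fold_assignment(fold, k, "C3")
  fa$certificate <- verify_independence(fa, list(sample_partners = sample_partners))
  fa
}

#' Verify fold independence
#'
#' Exhaustive pairwise check of the mode's constraint: SSCV -- no structural
#' domain in two folds; C3 -- no partner in two folds; RSCV -- membership
#' only.  The certificate lists violations (empty for a valid assignment)
#' and the fold-size table.
#'
#' @param assignment a `fold_assignment`.
#' @param annotations list with `sample_complex` + `complex_domains` (SSCV)
#'   or `sample_partners` (C3).
#' @return list with `violations` (data.frame) and `fold_sizes`.
#' @export
verify_independence <- function(assignment, annotations = list()) {
  fold <- assignment$fold_of
  viols <- data.frame(item = character(0), fold_a = integer(0),
                      fold_b = integer(0))
  item_folds <- list()
  if (assignment$mode == "SSCV" && !is.null(annotations$sample_complex)) {
    sc <- annotations$sample_complex
    cd <- annotations$complex_domains
    for (s in names(fold)) {
      doms <- cd[[sc[[s]]]]
      for (d in doms) item_folds[[d]] <- union(item_folds[[d]], fold[[s]])
    }
  } else if (assignment$mode == "C3" && !is.null(annotations$sample_partners)) {
    sp <- annotations$sample_partners
    for (s in names(fold)) {
      for (p in sp[[s]]) item_folds[[p]] <- union(item_folds[[p]], fold[[s]])
    }
  }
  for (it in names(item_folds)) {
    f <- sort(item_folds[[it]])
    if (length(f) > 1L) {
      viols <- rbind(viols, data.frame(item = it, fold_a = f[1],
                                       fold_b = f[length(f)]))
    }
  }
  list(violations = viols,
       fold_sizes = as.integer(table(factor(fold, levels = 0:(assignment$k - 1L)))))
}

#' Train/validation/test split from a fold assignment
#'
#' Unified 8:1:1 handling for k = 10: one fold is the test set, one the
#' validation set, the rest train.
#'
#' @param assignment a `fold_assignment`.
#' @param test_fold fold index used as test.
#' @param val_fold fold index used as validation (default: next fold,
#'   cyclically).
#' @return list of sample-id character vectors: train, val, test.
#' @export
fold_split <- function(assignment, test_fold = 0L,
                       val_fold = (test_fold + 1L) %% assignment$k) {
  if (test_fold == val_fold) stop("test and validation folds must differ")
  f <- assignment$fold_of
  list(train = names(f)[f != test_fold & f != val_fold],
       val = names(f)[f == val_fold],
       test = names(f)[f == test_fold])
}

#' Read split annotation tables
#'
#' TSV tables: `sample_id, complex_id` plus `complex_id, domain_id` for
#' SSCV, or `sample_id, partner_id` for C3.  Identifiers are opaque strings.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
}
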