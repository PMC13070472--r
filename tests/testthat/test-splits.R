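# Cross-validation fold construction and independence certificates.

test_that("random folds balance sizes and respect the seed", {
  fa <- rscv_folds(sprintf("s%03d", 1:100), k = 10L, seed = 4L)
  expect_equal(sort(unname(fa$fold_of[1:5])) >= 0, rep(TRUE, 5))
  expect_equal(as.vector(table(fa$fold_of)), rep(10L, 10))

  fa2 <- rscv_folds(sprintf("s%03d", 1:101), k = 10L, seed = 4L)
  sizes <- sort(as.vector(table(fa2$fold_of)))
  expect_equal(sizes, c(rep(10L, 9), 11L))

  fa3 <- rscv_folds(sprintf("s%03d", 1:100), k = 10L, seed = 4L)
  expect_identical(fa$fold_of, fa3$fold_of)
  fa4 <- rscv_folds(sprintf("s%03d", 1:100), k = 10L, seed = 5L)
  expect_false(identical(fa$fold_of, fa4$fold_of))

  expect_error(rscv_folds(1:5, k = 10L), "fewer")
})

test_that("structure-disjoint folds keep shared-domain complexes together", {
  # ten complexes with pairwise-disjoint domains, equal sample counts
  sc <- stats::setNames(paste0("c", 1:10), paste0("s", 1:10))
  cd <- stats::setNames(lapply(1:10, function(i) paste0("d", i)),
                        paste0("c", 1:10))
  fa <- sscv_folds(sc, cd, k = 10L)
  expect_equal(sort(as.vector(table(fa$fold_of))), rep(1L, 10))
  expect_equal(nrow(fa$certificate$violations), 0L)

  # complexes X and Y share a domain -> always one fold
  sc2 <- stats::setNames(c("X", "X", "Y", "Z", "W"), paste0("s", 1:5))
  cd2 <- list(X = c("d1", "d2"), Y = c("d2"), Z = "d3", W = "d4")
  fa2 <- sscv_folds(sc2, cd2, k = 3L)
  expect_equal(unname(fa2$fold_of["s1"]), unname(fa2$fold_of["s3"]))
  expect_equal(nrow(fa2$certificate$violations), 0L)

  expect_error(sscv_folds(sc2, cd2, k = 5L), "non-empty")
})

test_that("greedy balancing is bounded by the largest independent group", {
  set.seed(16)
  checked <- 0L
  for (r in 1:40) {
    n_complex <- sample(12:30, 1)
    sc <- stats::setNames(paste0("c", sample(n_complex, 60, replace = TRUE)),
                          paste0("s", 1:60))
    doms <- paste0("d", 1:15)
    cd <- stats::setNames(lapply(seq_len(n_complex), function(i)
      sample(doms, sample(1:2, 1))), paste0("c", 1:n_complex))
    fa <- tryCatch(sscv_folds(sc, cd, 3L), error = function(e) NULL)
    if (is.null(fa)) next                       # fewer groups than folds
    checked <- checked + 1L
    expect_equal(nrow(fa$certificate$violations), 0L)
    sizes <- fa$certificate$fold_sizes
    expect_equal(sum(sizes), 60L)
    # largest-first-into-smallest-fold: the spread never exceeds the
    # largest group's sample count
    grp_of <- split(sc, fa$fold_of[names(sc)])
    comp <- ddgatt:::annotation_components(sort(unique(sc)),
                                           cd[sort(unique(sc))])
    comp_sizes <- vapply(comp, function(g) sum(sc %in% g), numeric(1))
    expect_lte(max(sizes) - min(sizes), max(comp_sizes))
  }
  expect_gt(checked, 5L)
})

test_that("partner-disjoint folds group shared partners and certify", {
  sp <- list(s1 = c("pA", "pB"), s2 = c("pB", "pC"), s3 = c("pD", "pE"),
             s4 = c("pF", "pG"), s5 = c("pH", "pI"))
  fa <- c3_folds(sp, k = 3L)
  expect_equal(unname(fa$fold_of["s1"]), unname(fa$fold_of["s2"]))
  expect_equal(nrow(fa$certificate$violations), 0L)

  # all samples sharing one partner cannot split into many folds
  one <- list(s1 = "p", s2 = "p", s3 = "p")
  expect_error(c3_folds(one, k = 3L), "non-empty")
})

test_that("certificates detect seeded violations and conserve counts", {
  sp <- list(s1 = "pA", s2 = "pA", s3 = "pB", s4 = "pC")
  fa <- c3_folds(sp, k = 3L)
  expect_equal(sum(fa$certificate$fold_sizes), 4L)

  broken <- fa
  broken$fold_of["s2"] <- (broken$fold_of["s1"] + 1L) %% broken$k
  cert <- verify_independence(broken, list(sample_partners = sp))
  expect_gt(nrow(cert$violations), 0L)
  expect_true("pA" %in% cert$violations$item)
})

test_that("random annotation instances always certify cleanly", {
  set.seed(17)
  for (r in 1:30) {
    n <- 40L
    sp <- stats::setNames(lapply(seq_len(n), function(i)
      paste0("p", sample(25, sample(1:2, 1)))), paste0("s", 1:n))
    fa <- tryCatch(c3_folds(sp, k = 4L), error = function(e) NULL)
    if (is.null(fa)) next
    expect_equal(nrow(fa$certificate$violations), 0L)
    expect_equal(sum(fa$certificate$fold_sizes), n)
  }
})

test_that("fold splitting yields disjoint exhaustive train/val/test", {
  fa <- rscv_folds(paste0("s", 1:50), k = 10L, seed = 2L)
  sp <- fold_split(fa, test_fold = 3L)
  expect_length(sp$test, 5L)
  expect_length(sp$val, 5L)
  expect_length(sp$train, 40L)
  expect_length(intersect(sp$test, sp$train), 0L)
  expect_length(intersect(sp$test, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), paste0("s", 1:50))
  expect_error(fold_split(fa, 2L, 2L), "differ")
})
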