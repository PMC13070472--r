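# Local frames, invariant geometry, pairwise descriptors, embeddings.

test_that("local frame matches its defining construction", {
  # backbone placed with C-CA along x and N in the xy-plane -> R = I
  res <- list(aa = "G", atoms = rbind(N = c(0.3, 1.4, 0),
                                      CA = c(0, 0, 0),
                                      C = c(1.5, 0, 0)))
  fr <- build_local_frame(res)
  expect_lt(max(abs(fr$R - diag(3))), 1e-6)
  expect_equal(fr$origin, c(0, 0, 0))

  # orthonormal right-handed for a real residue
  x <- fixture_complex()
  fr2 <- build_local_frame(get_residue(x, 4L))
  expect_lt(max(abs(crossprod(fr2$R) - diag(3))), 1e-6)
  expect_equal(det(fr2$R), 1, tolerance = 1e-6)
})

test_that("local frame is rigid-motion equivariant and rejects degeneracy", {
  x <- fixture_complex()
  res <- get_residue(x, 6L)
  fr <- build_local_frame(res)
  mo <- random_rigid_motion(3L)
  res2 <- res
  res2$atoms <- sweep(res$atoms %*% t(mo$Q), 2, mo$t, "+")
  rownames(res2$atoms) <- rownames(res$atoms)
  fr2 <- build_local_frame(res2)
  expect_lt(max(abs(fr2$R - mo$Q %*% fr$R)), 1e-6)
  expect_lt(max(abs(fr2$origin - (mo$Q %*% fr$origin + mo$t))), 1e-6)

  col <- list(aa = "G", atoms = rbind(N = c(-1, 0, 0), CA = c(0, 0, 0),
                                      C = c(1, 0, 0)))
  expect_error(build_local_frame(col), "collinear")
})

test_that("local atom geometry puts CA at the origin with correct flags", {
  x <- fixture_complex()
  i <- which(x$aa != "G")[1]
  res <- get_residue(x, i)
  res$aa <- "A"                                  # alanine atom inventory
  res$atoms <- res$atoms[c("N", "CA", "C", "O", "CB"), ]
  g <- local_atom_geometry(res, build_local_frame(res))
  expect_length(g, 56L)
  coords <- matrix(g[1:42], ncol = 3, byrow = TRUE)
  flags <- g[43:56]
  expect_equal(coords[2, ], c(0, 0, 0))          # CA slot
  expect_equal(sum(flags), 5)                    # alanine: 5 heavy atoms
  expect_equal(flags, c(rep(1, 5), rep(0, 9)))
})

test_that("atom counts per residue type match the canonical inventory", {
  counts <- vapply(c(A = "A", G = "G", W = "W", R = "R", K = "K"),
                   function(a) length(aa_heavy_atoms(a)), integer(1))
  expect_equal(unname(counts), c(5L, 4L, 14L, 11L, 9L))
})

test_that("local geometry is invariant under rigid motions of the complex", {
  x <- fixture_complex()
  res <- get_residue(x, 8L)
  g <- local_atom_geometry(res, build_local_frame(res))
  for (s in 1:5) {
    mo <- random_rigid_motion(s * 7L)
    res2 <- res
    res2$atoms <- sweep(res$atoms %*% t(mo$Q), 2, mo$t, "+")
    rownames(res2$atoms) <- rownames(res$atoms)
    g2 <- local_atom_geometry(res2, build_local_frame(res2))
    expect_lt(max(abs(g2 - g)), 1e-6)
  }
})

test_that("pairwise distances equal a brute-force double loop", {
  x <- make_toy_complex(toy_spec(n_per_chain = 15L, seed = 17L))
  m <- fixture_mutation(x, 5L)
  sel <- select_residues(x, list(m), 32L)
  D <- pairwise_distances(x, sel)
  nv <- sum(sel$mask)
  ref <- matrix(0, nv, nv)
  cb <- t(vapply(sel$indices, function(i) get_cbeta(get_residue(x, i)),
                 numeric(3)))
  for (i in seq_len(nv)) for (j in seq_len(nv))
    ref[i, j] <- sqrt(sum((cb[i, ] - cb[j, ])^2))
  expect_lt(max(abs(D[1:nv, 1:nv] - ref)), 1e-6)
  expect_equal(D, t(D))
  expect_equal(diag(D)[1:nv], rep(0, nv))
  expect_true(all(D[, !sel$mask] > 900))
})

test_that("contact map uses a closed threshold and matches neighbor counts", {
  D <- matrix(c(0, 5, 8, 5, 0, 9, 8, 9, 0), 3, 3)
  C <- contact_map(D, threshold = 8)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], 1)          # exactly 8.0 counts
  expect_equal(C[2, 3], 0)
  expect_equal(diag(C), rep(0, 3))
  expect_error(contact_map(D, threshold = 0), "positive")

  x <- fixture_complex(seed = 19L, n_per_chain = 8L)
  sel <- select_residues(x, list(fixture_mutation(x, 2L)), 16L)
  D2 <- pairwise_distances(x, sel)
  C2 <- contact_map(D2)
  nv <- sum(sel$mask)
  brute <- sapply(seq_len(nv), function(i)
    sum(D2[i, seq_len(nv)] <= 8) - 1)
  expect_equal(rowSums(C2)[seq_len(nv)], brute)
})

test_that("sequence separation signs, clips, and flags cross-chain pairs", {
  x <- fixture_complex(seed = 23L, n_per_chain = 40L)
  m <- fixture_mutation(x, 1L)
  sel <- select_residues(x, list(m), 80L)
  ss <- sequence_separation(x, sel, clip = 32L)
  ch <- x$chain[sel$indices]
  rs <- x$resseq[sel$indices]
  same_a <- which(ch == "A")
  i <- same_a[1]; j <- same_a[2]
  expect_equal(ss[i, j], rs[j] - rs[i])
  expect_equal(ss[j, i], -(rs[j] - rs[i]))
  cross <- which(outer(ch, ch, "!="), arr.ind = TRUE)[1, ]
  expect_equal(ss[cross[1], cross[2]], 33L)
  wide <- which(outer(rs, rs, function(a, b) b - a) > 32 &
                  outer(ch, ch, "=="), arr.ind = TRUE)
  if (nrow(wide) > 0) expect_equal(ss[wide[1, 1], wide[1, 2]], 32L)
  # antisymmetric within chains
  within <- outer(ch, ch, "==")
  expect_equal(ss[within], -t(ss)[within])
})

test_that("mock embeddings are deterministic, local, and well-shaped", {
  a <- mock_embeddings(c(chA = "AAA"), seed = 5L, E = 16L)[[1]]
  b <- mock_embeddings(c(chA = "AAA"), seed = 5L, E = 16L)[[1]]
  expect_identical(a, b)
  expect_equal(dim(a), c(3L, 16L))

  cvar <- mock_embeddings(c(chA = "AAC"), seed = 5L, E = 16L)[[1]]
  expect_identical(a[1:2, ], cvar[1:2, ])
  expect_false(all(a[3, ] == cvar[3, ]))

  other_seed <- mock_embeddings(c(chA = "AAA"), seed = 6L, E = 16L)[[1]]
  expect_false(all(a == other_seed))
})

test_that("the full feature bundle is finite and rigid-motion invariant", {
  cfg <- test_config()
  s <- fixture_samples(1L)[[1]]
  fx <- fixture_feats(s, cfg)
  expect_all_finite(fx$feats$X0)
  expect_all_finite(fx$feats$rbf)
  for (k in 1:5) {
    mo <- random_rigid_motion(k * 3L + 1L)
    y <- transform_structure(s$wt, mo)
    f2 <- ddgatt:::build_features(y, select_residues(y, s$mutations, cfg$n_max),
                                  fx$provider, cfg)
    expect_lt(max(abs(f2$X0 - fx$feats$X0)), 1e-5)
    expect_lt(max(abs(f2$D - fx$feats$D)), 1e-5)
    expect_identical(f2$contact_code, fx$feats$contact_code)
    expect_identical(f2$seqsep_code, fx$feats$seqsep_code)
  }
})

test_that("positional encodings have unit-bounded entries and fixed width", {
  pe <- positional_encoding(1:50, P = 16L)
  expect_equal(dim(pe), c(50L, 16L))
  expect_true(all(abs(pe) <= 1))
  expect_false(any(duplicated(round(pe, 10))))   # distinct positions
})
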