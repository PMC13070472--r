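# Small shared utilities.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.  All deterministic generators in the
# package go through this, so library calls never clobber user randomness.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(expr)
}

relu <- function(x) pmax(x, 0)

softplus <- function(x) {
  # log(1 + exp(x)) computed stably for large |x|
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

l2norm <- function(v) sqrt(sum(v^2))

#' Draw a uniformly random rigid motion
#'
#' @param seed RNG seed.
#' @param t_scale translation scale, Angstrom.
#' @return list with `Q` (3 x 3 rotation, det +1) and `t` (3-vector).
#' @export
random_rigid_motion <- function(seed = 1L, t_scale = 50) {
  with_preserved_seed(seed * 13L + 5L, {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(m)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(Q = Q, t = stats::runif(3, -t_scale, t_scale))
  })
}

#' Apply a rigid motion to every atom of a complex
#'
#' @param x a `complex_structure`.
#' @param motion list(Q, t) as from [random_rigid_motion()].
#' @return the transformed structure.
#' @export
transform_structure <- function(x, motion) {
  x$atoms <- lapply(x$atoms, function(a) {
    out <- a %*% t(motion$Q)
    out <- sweep(out, 2, motion$t, "+")
    rownames(out) <- rownames(a)
    out
  })
  x
}
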