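# Small random problem instances built in code; all randomness is
# locally seeded so tests are reproducible.

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

rand_named <- function(m, n, prefix_r, prefix_c, gen = stats::runif) {
  matrix(gen(m * n), m, n,
         dimnames = list(sprintf("%s%d", prefix_r, seq_len(m)),
                         sprintf("%s%d", prefix_c, seq_len(n))))
}

rand_W <- function(m, k, scale = 10) {
  rand_named(m, k, "g", "ct", gen = function(n) stats::runif(n, 0, scale))
}

rand_H <- function(k, n, prefix = "s") {
  H <- rand_named(k, n, "ct", prefix, gen = function(n) stats::rgamma(n, 2))
  sweep(H, 2L, colSums(H), "/")
}

# consistent noiseless two-group instance: Y_i = W_i %*% H_i
tiny_instance <- function(m = 6, k = 3, n1 = 5, n2 = 5, seed = 1,
                          de_frac = 0) {
  local_seed(seed, {
    W1 <- rand_W(m, k)
    W2 <- W1
    if (de_frac > 0) {
      idx <- sample.int(m * k, max(1, round(de_frac * m * k)))
      W2[idx] <- W2[idx] * 2
    }
    H1 <- rand_H(k, n1, "a")
    H2 <- rand_H(k, n2, "b")
    list(W1 = W1, W2 = W2, H1 = H1, H2 = H2,
         Y1 = W1 %*% H1, Y2 = W2 %*% H2)
  })
}

# objective of the coupled problem for arbitrary candidate solutions
coupled_obj <- function(inst, W1, W2, E, lam) {
  coupled_objective(inst$Y1, inst$Y2, W1, W2, inst$H1, inst$H2, E, lam)
}

# Independent oracle: solve the full coupled W problem (all genes at
# once, 2*m*k variables) as one block-diagonal NNLS with the pure-R
# Lawson-Hanson solver from pracma.
oracle_joint_W <- function(Y1, Y2, H1, H2, E, lam) {
  m <- nrow(Y1); k <- nrow(H1)
  n1 <- ncol(Y1); n2 <- ncol(Y2)
  rows_per <- n1 + n2 + k
  A <- matrix(0, m * rows_per, 2 * k * m)
  b <- numeric(m * rows_per)
  for (j in seq_len(m)) {
    rs <- (j - 1) * rows_per
    cs <- (j - 1) * 2 * k
    D <- diag(sqrt(lam * E[, j]), k)
    A[rs + seq_len(n1), cs + seq_len(k)] <- t(H1)
    A[rs + n1 + seq_len(n2), cs + k + seq_len(k)] <- t(H2)
    A[rs + n1 + n2 + seq_len(k), cs + seq_len(k)] <- D
    A[rs + n1 + n2 + seq_len(k), cs + k + seq_len(k)] <- -D
    b[rs + seq_len(n1)] <- Y1[j, ]
    b[rs + n1 + seq_len(n2)] <- Y2[j, ]
  }
  x <- pracma::lsqnonneg(A, b)$x
  xm <- matrix(x, nrow = 2 * k)
  W1 <- t(xm[seq_len(k), , drop = FALSE])
  W2 <- t(xm[k + seq_len(k), , drop = FALSE])
  dimnames(W1) <- dimnames(W2) <- list(rownames(Y1), rownames(H1))
  list(W1 = W1, W2 = W2)
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
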