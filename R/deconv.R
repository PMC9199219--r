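#' Non-negative least squares
#'
#' Solves `argmin_{x >= 0} ||A x - b||_2^2` with a fast active-set
#' algorithm on the normal equations (compiled).
#'
#' @param A numeric matrix (p x q), finite entries.
#' @param b numeric vector of length p.
#' @return non-negative solution vector of length q.
#' @examples
#' nnls_solve(diag(2), c(-1, 5))  # c(0, 5)
#' @export
nnls_solve <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (!is.numeric(A) || anyNA(A) || any(!is.finite(A)) ||
      anyNA(b) || any(!is.finite(b))) {
    stop_domain("nnls_solve requires finite numeric inputs")
  }
  if (nrow(A) != length(b)) {
    stop_domain("nrow(A) must equal length(b)", "scaddecon_alignment_error")
  }
  drop(cpp_nnls(A, b))
}

#' Estimate cell-type proportions given expression profiles
#'
#' Solves one NNLS problem per bulk sample, `H[, i] = argmin_{h >= 0}
#' ||W h - Y[, i]||^2`, aligning genes by identifier. `W` may be a full
#' cell-type expression matrix or a signature matrix; its genes must all
#' be present in the bulk.
#'
#' @param Y genes x samples bulk matrix.
#' @param W genes x cell-types expression or signature matrix.
#' @param normalize rescale each column of H to sum to 1 (default
#'   `TRUE`). A column estimated as all zero is replaced by the uniform
#'   composition `1/k` with a warning.
#' @return cell-types x samples proportion matrix.
#' @export
estimate_H <- function(Y, W, normalize = TRUE) {
  if (!all(rownames(W) %in% rownames(Y))) {
    stop_domain("genes of W missing from the bulk matrix",
                "scaddecon_alignment_error")
  }
  Ysub <- Y[rownames(W), , drop = FALSE]
  H <- cpp_nnls_multi(W, Ysub)
  dimnames(H) <- list(colnames(W), colnames(Y))
  if (normalize) {
    cs <- colSums(H)
    zero <- cs <= 0
    if (any(zero)) {
      warning(sprintf("estimate_H: %d all-zero column(s) replaced by uniform proportions",
                      sum(zero)), call. = FALSE)
      H[, zero] <- 1 / nrow(H)
      cs[zero] <- 1
    }
    H <- sweep(H, 2L, cs, "/")
  }
  H
}

#' Estimate expression profiles given proportions
#'
#' Solves one NNLS problem per gene, `W[g, ] = argmin_{w >= 0}
#' ||t(H) w - t(Y)[, g]||^2`; requires at least as many samples as cell
#' types.
#'
#' @param Y genes x samples bulk matrix.
#' @param H cell-types x samples proportion matrix (samples must match
#'   `colnames(Y)`).
#' @return genes x cell-types non-negative expression matrix.
#' @export
estimate_W <- function(Y, H) {
  if (!setequal(colnames(Y), colnames(H))) {
    stop_domain("sample identifiers of Y and H differ",
                "scaddecon_alignment_error")
  }
  H <- H[, colnames(Y), drop = FALSE]
  if (nrow(H) > ncol(Y)) {
    stop_domain("more cell types than samples: W is unidentifiable",
                "scaddecon_identifiability_error")
  }
  Wt <- cpp_nnls_multi(t(H), t(Y))
  W <- t(Wt)
  dimnames(W) <- list(rownames(Y), rownames(H))
  W
}

#' Warm-up alternating NNLS and weight derivation
#'
#' Runs `warmup_rounds` rounds of alternating NNLS per group
#' (expression update, then proportions update with renormalization at
#' every round), independently for the two groups, then derives the
#' coupling-weight matrix from the final per-group expression
#' estimates via [compute_weights()].
#'
#' @param Y1,Y2 genes x samples bulk matrices for the two groups
#'   (shared genes).
#' @param H1_0,H2_0 initial proportion matrices.
#' @param params a [scaddecon_params()] object.
#' @return list with `W1`, `W2` (last expression iterates), `H1`, `H2`
#'   (last proportion iterates), and `E` (cell-types x genes weights).
#' @export
warmup <- function(Y1, Y2, H1_0, H2_0, params = scaddecon_params()) {
  stopifnot(inherits(params, "scaddecon_params"))
  H1 <- H1_0; H2 <- H2_0
  W1 <- NULL; W2 <- NULL
  for (r in seq_len(params$warmup_rounds)) {
    W1 <- estimate_W(Y1, H1)
    W2 <- estimate_W(Y2, H2)
    H1 <- estimate_H(Y1, W1, normalize = TRUE)
    H2 <- estimate_H(Y2, W2, normalize = TRUE)
  }
  E <- compute_weights(W1, W2, zeta = params$zeta, a = params$a)
  list(W1 = W1, W2 = W2, H1 = H1, H2 = H2, E = E)
}
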