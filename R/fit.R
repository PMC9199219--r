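#' Jointly update the two expression matrices under the coupling penalty
#'
#' Minimizes
#' \deqn{\tfrac12\|Y_1 - W_1 H_1\|_F^2 + \tfrac12\|Y_2 - W_2 H_2\|_F^2 +
#'       \tfrac{\lambda}{2}\|W_1 - W_2\|_{E,F}^2}
#' over non-negative `W1`, `W2`, where the weighted norm sums
#' `E[j, g] * (W1[g, j] - W2[g, j])^2`. The problem separates across
#' genes: for each gene the stacked `(n1 + n2 + k) x 2k` system with
#' blocks `[t(H1) | 0; 0 | t(H2); sqrt(lam) D | -sqrt(lam) D]`,
#' `D = diag(sqrt(E[, g]))`, is solved by NNLS; the first k coordinates
#' give the gene's row of `W1` and the last k that of `W2`.
#'
#' @param Y1,Y2 genes x samples bulk matrices (shared gene order).
#' @param H1,H2 cell-types x samples proportion matrices.
#' @param E cell-types x genes weight matrix in `[0, 1]`.
#' @param lam coupling strength (>= 0). At `lam = 0` the update equals
#'   independent [estimate_W()] per group.
#' @return list with non-negative `W1` and `W2` (genes x cell types).
#' @export
joint_W_update <- function(Y1, Y2, H1, H2, E, lam = 1) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) {
    stop_domain("lam must be a scalar >= 0", "scaddecon_parameter_error")
  }
  k <- nrow(H1); m <- nrow(Y1)
  if (!identical(rownames(Y1), rownames(Y2))) {
    stop_domain("Y1 and Y2 must share gene identifiers and order",
                "scaddecon_alignment_error")
  }
  if (nrow(H2) != k || !identical(dim(E), c(k, m))) {
    stop_domain("shapes of H1, H2, E are inconsistent",
                "scaddecon_alignment_error")
  }
  if (ncol(Y1) != ncol(H1) || ncol(Y2) != ncol(H2)) {
    stop_domain("sample counts of Y and H differ", "scaddecon_alignment_error")
  }
  X <- cpp_joint_w_update(t(Y1), t(Y2),
                          t(H1[, colnames(Y1), drop = FALSE]),
                          t(H2[, colnames(Y2), drop = FALSE]),
                          E, lam)
  W1 <- t(X[seq_len(k), , drop = FALSE])
  W2 <- t(X[k + seq_len(k), , drop = FALSE])
  dimnames(W1) <- dimnames(W2) <- list(rownames(Y1), rownames(H1))
  list(W1 = W1, W2 = W2)
}

#' Coupled objective value
#'
#' The quantity the main loop monitors: the two halved per-group
#' residual sums of squares plus `lam/2` times the E-weighted squared
#' difference of the expression matrices.
#'
#' @inheritParams joint_W_update
#' @param W1,W2 genes x cell-types expression matrices.
#' @return scalar objective value.
#' @export
coupled_objective <- function(Y1, Y2, W1, W2, H1, H2, E, lam) {
  0.5 * sum((Y1 - W1 %*% H1)^2) +
    0.5 * sum((Y2 - W2 %*% H2)^2) +
    0.5 * lam * sum(E * (t(W1) - t(W2))^2)
}

#' Coupled two-group deconvolution
#'
#' The main estimation procedure. Starting from initial proportions
#' (given directly, or deconvolved per group from a shared signature
#' matrix by NNLS), it (1) runs the alternating-NNLS [warmup()] to
#' obtain per-group expression estimates and the SCAD-derivative weight
#' matrix E, then (2) iterates the joint SCAD-weighted expression
#' update ([joint_W_update()]) and per-group NNLS proportion updates
#' until the relative change of the coupled objective falls below
#' `params$tol` or `params$max_iter` iterations are reached. E is
#' frozen after warm-up unless `params$recompute_weights` is set.
#'
#' @param Y1,Y2 genes x samples bulk matrices; they must contain the
#'   same genes (rows are aligned by identifier).
#' @param H1_0,H2_0 optional initial proportion matrices (both or
#'   neither).
#' @param signature optional shared signature matrix used to deconvolve
#'   initial proportions when `H1_0`/`H2_0` are not given. Exactly one
#'   of the two initialization routes must be supplied.
#' @param params a [scaddecon_params()] object.
#' @return an object of class `scaddecon_fit` with elements `W1`, `W2`
#'   (genes x cell types), `H1`, `H2` (cell types x samples, unit-sum
#'   columns), `E` (cell types x genes), `iterations_run`,
#'   `objective_trace` (objective after warm-up and after each
#'   iteration), `warmup` (the warm-up iterates), `signature_genes`
#'   (or `NULL`), and `params`.
#' @examples
#' truth <- simulate_dataset(simulation_config(m = 120, k = 3,
#'   n_per_group = 8, noise_sd = 0, seed = 1))
#' fit <- scaddecon(truth$Y1, truth$Y2, H1_0 = truth$H1, H2_0 = truth$H2,
#'                  params = scaddecon_params(max_iter = 2))
#' fit
#' @export
scaddecon <- function(Y1, Y2, H1_0 = NULL, H2_0 = NULL, signature = NULL,
                      params = scaddecon_params()) {
  stopifnot(inherits(params, "scaddecon_params"))
  validate_matrix(Y1, "bulk"); validate_matrix(Y2, "bulk")
  have_H <- !is.null(H1_0) || !is.null(H2_0)
  if (have_H && (is.null(H1_0) || is.null(H2_0))) {
    stop_domain("supply both H1_0 and H2_0, or neither",
                "scaddecon_usage_error")
  }
  if (have_H && !is.null(signature)) {
    stop_domain("supply either initial proportions or a signature matrix, not both",
                "scaddecon_usage_error")
  }
  if (!have_H && is.null(signature)) {
    stop_domain("initialization required: H1_0/H2_0 or a signature matrix",
                "scaddecon_usage_error")
  }
  if (!setequal(rownames(Y1), rownames(Y2))) {
    stop_domain("Y1 and Y2 must contain the same genes",
                "scaddecon_alignment_error")
  }
  Y2 <- Y2[rownames(Y1), , drop = FALSE]

  signature_genes <- NULL
  if (!have_H) {
    al <- align_genes(Y1, signature)
    signature_genes <- rownames(al$sig)
    H1_0 <- estimate_H(al$bulk, al$sig, normalize = TRUE)
    H2_0 <- estimate_H(Y2[signature_genes, , drop = FALSE], al$sig,
                       normalize = TRUE)
  } else {
    H1_0 <- validate_matrix(H1_0, "proportions")
    H2_0 <- validate_matrix(H2_0, "proportions")
    if (!setequal(colnames(H1_0), colnames(Y1)) ||
        !setequal(colnames(H2_0), colnames(Y2))) {
      stop_domain("initial proportions must cover the bulk samples",
                  "scaddecon_alignment_error")
    }
    if (!identical(rownames(H1_0), rownames(H2_0))) {
      stop_domain("H1_0 and H2_0 must share cell types",
                  "scaddecon_alignment_error")
    }
    H1_0 <- H1_0[, colnames(Y1), drop = FALSE]
    H2_0 <- H2_0[, colnames(Y2), drop = FALSE]
  }
  if (params$h_update_genes == "signature" && is.null(signature_genes)) {
    stop_domain("h_update_genes = 'signature' requires signature initialization",
                "scaddecon_usage_error")
  }

  wu <- warmup(Y1, Y2, H1_0, H2_0, params)
  W1 <- wu$W1; W2 <- wu$W2; H1 <- wu$H1; H2 <- wu$H2; E <- wu$E

  obj <- coupled_objective(Y1, Y2, W1, W2, H1, H2, E, params$lam)
  trace <- obj
  iters <- 0L
  for (it in seq_len(params$max_iter)) {
    upd <- joint_W_update(Y1, Y2, H1, H2, E, params$lam)
    W1 <- upd$W1; W2 <- upd$W2
    if (params$h_update_genes == "signature") {
      sg <- signature_genes
      H1 <- estimate_H(Y1[sg, , drop = FALSE], W1[sg, , drop = FALSE])
      H2 <- estimate_H(Y2[sg, , drop = FALSE], W2[sg, , drop = FALSE])
    } else {
      H1 <- estimate_H(Y1, W1)
      H2 <- estimate_H(Y2, W2)
    }
    if (params$recompute_weights) {
      E <- compute_weights(W1, W2, zeta = params$zeta, a = params$a)
    }
    obj_new <- coupled_objective(Y1, Y2, W1, W2, H1, H2, E, params$lam)
    trace <- c(trace, obj_new)
    iters <- it
    if (abs(obj_new - obj) / max(obj, 1e-12) < params$tol) break
    obj <- obj_new
  }

  structure(list(W1 = W1, W2 = W2, H1 = H1, H2 = H2, E = E,
                 iterations_run = iters, objective_trace = trace,
                 warmup = wu, signature_genes = signature_genes,
                 params = params),
            class = "scaddecon_fit")
}

#' @export
print.scaddecon_fit <- function(x, ...) {
  cat("Coupled two-group deconvolution fit\n")
  cat(sprintf("  %d genes, %d cell types; %d + %d samples\n",
              nrow(x$W1), ncol(x$W1), ncol(x$H1), ncol(x$H2)))
  cat(sprintf("  %d main-loop iteration(s); objective %.6g -> %.6g\n",
              x$iterations_run, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)]))
  cat(sprintf("  coupling lambda = %g, zeta = %g, a = %g; free entries (E = 0): %.1f%%\n",
              x$params$lam, x$params$zeta, x$params$a,
              100 * mean(x$E == 0)))
  invisible(x)
}
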