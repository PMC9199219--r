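#' Fitting parameters
#'
#' Collects and validates the tuning parameters of the coupled
#' deconvolution procedure.
#'
#' @param a SCAD shape parameter (> 2); default 3.7, the conventional
#'   cross-validated choice.
#' @param zeta SCAD threshold (>= 0); default 4. The coupling weight for
#'   an entry is 1 while the squared warm-up difference stays below
#'   `zeta` and reaches 0 at `a * zeta`; results are robust for `zeta`
#'   roughly in 1-8.
#' @param lam coupling strength lambda (>= 0) multiplying the weighted
#'   Frobenius penalty; default 1, which makes the penalty commensurate
#'   with the two per-group least-squares losses (all three terms carry
#'   a factor 1/2). `lam = 0` reduces the W update to independent
#'   per-group NNLS.
#' @param warmup_rounds number of alternating NNLS warm-up rounds used
#'   to derive the weight matrix; default 5.
#' @param max_iter cap on main-loop iterations; default 10.
#' @param tol relative objective-change stopping tolerance; default 1e-4.
#' @param h_update_genes `"full"` (default) to update proportions with
#'   every gene of the current W, or `"signature"` to restrict the H
#'   update to signature genes (requires signature-based
#'   initialization).
#' @param recompute_weights expert flag: recompute the weight matrix
#'   from the current W estimates at every main-loop iteration instead
#'   of freezing it after warm-up. Default `FALSE` (frozen), the
#'   recommended behaviour.
#' @param seed integer seed used wherever the procedure needs
#'   randomness (jackknife sample pairing); `NULL` leaves the RNG
#'   untouched.
#' @return an object of class `scaddecon_params` (a validated list).
#' @export
scaddecon_params <- function(a = 3.7, zeta = 4, lam = 1,
                             warmup_rounds = 5L, max_iter = 10L,
                             tol = 1e-4,
                             h_update_genes = c("full", "signature"),
                             recompute_weights = FALSE,
                             seed = NULL) {
  h_update_genes <- match.arg(h_update_genes)
  check_scad_pars(zeta, a)
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) {
    stop_domain("lam must be a scalar >= 0", "scaddecon_parameter_error")
  }
  warmup_rounds <- as.integer(warmup_rounds)
  max_iter <- as.integer(max_iter)
  if (is.na(warmup_rounds) || warmup_rounds < 1L) {
    stop_domain("warmup_rounds must be >= 1", "scaddecon_parameter_error")
  }
  if (is.na(max_iter) || max_iter < 1L) {
    stop_domain("max_iter must be >= 1", "scaddecon_parameter_error")
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol < 0) {
    stop_domain("tol must be a scalar >= 0", "scaddecon_parameter_error")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(a = a, zeta = zeta, lam = lam,
                 warmup_rounds = warmup_rounds, max_iter = max_iter,
                 tol = tol, h_update_genes = h_update_genes,
                 recompute_weights = isTRUE(recompute_weights),
                 seed = seed),
            class = "scaddecon_params")
}

#' @export
print.scaddecon_params <- function(x, ...) {
  cat("scaddecon parameters\n")
  cat(sprintf("  SCAD: a = %g, zeta = %g\n", x$a, x$zeta))
  cat(sprintf("  coupling lambda = %g (weights %s after warm-up)\n",
              x$lam, if (x$recompute_weights) "recomputed" else "frozen"))
  cat(sprintf("  warm-up rounds = %d, max iterations = %d, tol = %g\n",
              x$warmup_rounds, x$max_iter, x$tol))
  cat(sprintf("  H update gene set: %s\n", x$h_update_genes))
  invisible(x)
}
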