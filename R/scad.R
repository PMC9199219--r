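#' SCAD penalty
#'
#' The smoothly clipped absolute deviation (SCAD) penalty evaluated on a
#' non-negative argument: linear with slope `zeta` near the origin, a
#' quadratic blend on `(zeta, a*zeta]`, and constant `zeta^2*(a+1)/2`
#' beyond `a*zeta`. It behaves like an L1 penalty for small values but
#' stops growing for large ones, which is what makes the derived
#' coupling weights signal-adaptive.
#'
#' @param x non-negative numeric scalar, vector or matrix (callers pass
#'   `|x|` or `x^2`); evaluated element-wise.
#' @param zeta threshold parameter (>= 0); the penalty is linear up to
#'   `zeta` and flat beyond `a * zeta`.
#' @param a shape parameter (> 2); `a = 3.7` is the conventional choice
#'   from cross-validated empirical studies.
#' @return penalty values, same shape as `x`.
#' @examples
#' scad_penalty(c(0, 4, 16), zeta = 4, a = 3.7)
#' @export
scad_penalty <- function(x, zeta = 4, a = 3.7) {
  check_scad_pars(zeta, a)
  if (any(x < 0, na.rm = TRUE)) stop_domain("scad_penalty expects x >= 0")
  mid <- (2 * a * zeta * x - x^2 - zeta^2) / (2 * (a - 1))
  out <- ifelse(x <= zeta, zeta * x,
                ifelse(x <= a * zeta, mid, zeta^2 * (a + 1) / 2))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Derivative of the SCAD penalty
#'
#' Evaluates `1` for `x <= zeta`, the linearly decaying
#' `(a*zeta - x)_+ / ((a - 1) * zeta)` for `x > zeta`, and exactly `0`
#' for `x >= a*zeta`; the result is non-increasing and always in
#' `[0, 1]`. At `zeta = 0` the limiting convention is used: `1` at
#' `x = 0` and `0` for `x > 0`.
#'
#' @inheritParams scad_penalty
#' @return derivative values in `[0, 1]`, same shape as `x`.
#' @examples
#' scad_derivative(8, zeta = 4, a = 3.7)  # (3.7*4 - 8) / (2.7*4)
#' @export
scad_derivative <- function(x, zeta = 4, a = 3.7) {
  check_scad_pars(zeta, a)
  if (any(x < 0, na.rm = TRUE)) stop_domain("scad_derivative expects x >= 0")
  if (zeta == 0) {
    out <- as.numeric(x <= 0)
  } else {
    out <- ifelse(x <= zeta, 1, pmax(a * zeta - x, 0) / ((a - 1) * zeta))
  }
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

check_scad_pars <- function(zeta, a) {
  if (!is.numeric(a) || length(a) != 1L || a <= 2) {
    stop_domain("SCAD shape parameter a must be a scalar > 2",
                "scaddecon_parameter_error")
  }
  if (!is.numeric(zeta) || length(zeta) != 1L || zeta < 0) {
    stop_domain("SCAD threshold zeta must be a scalar >= 0",
                "scaddecon_parameter_error")
  }
  invisible(TRUE)
}

#' Coupling-weight matrix from warm-up estimates
#'
#' Builds the cell-types x genes weight matrix E with
#' `E[j, g] = P'_zeta((W1[g, j] - W2[g, j])^2)`, the SCAD derivative of
#' the squared entry-wise difference of the two warm-up expression
#' estimates. Entries whose warm-up difference is small get weight 1
#' (held together by the coupling penalty); entries whose squared
#' difference exceeds `a * zeta` get weight 0 (left free).
#'
#' @param W1bar,W2bar genes x cell-types warm-up expression estimates
#'   with identical dimnames.
#' @param zeta,a SCAD parameters, see [scad_derivative()].
#' @return cell-types x genes weight matrix with entries in `[0, 1]`
#'   (the orientation of `t(W)`).
#' @export
compute_weights <- function(W1bar, W2bar, zeta = 4, a = 3.7) {
  if (!identical(dim(W1bar), dim(W2bar)) ||
      !identical(dimnames(W1bar), dimnames(W2bar))) {
    stop_domain("W1bar and W2bar must share shape and identifiers",
                "scaddecon_alignment_error")
  }
  scad_derivative((t(W1bar) - t(W2bar))^2, zeta = zeta, a = a)
}
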