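#' Tidy a coupled deconvolution fit
#'
#' Returns one row per (gene, cell type) with the two group-specific
#' expression estimates, their difference, and the coupling weight that
#' governed the entry during fitting.
#'
#' @param x a `scaddecon_fit`.
#' @param ... unused.
#' @return a tibble with columns `gene`, `cell_type`, `w1`, `w2`,
#'   `diff`, `weight`.
#' @export
tidy.scaddecon_fit <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$W1), times = ncol(x$W1)),
    cell_type = rep(colnames(x$W1), each = nrow(x$W1)),
    w1 = as.numeric(x$W1),
    w2 = as.numeric(x$W2),
    diff = as.numeric(x$W1 - x$W2),
    weight = as.numeric(t(x$E))
  )
}

#' Glance at a coupled deconvolution fit
#'
#' @param x a `scaddecon_fit`.
#' @param ... unused.
#' @return a one-row tibble: problem dimensions, penalty parameters,
#'   iterations run, initial and final objective, and the fraction of
#'   entries left uncoupled (weight zero).
#' @export
glance.scaddecon_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$W1),
    n_cell_types = ncol(x$W1),
    n1 = ncol(x$H1),
    n2 = ncol(x$H2),
    lambda = x$params$lam,
    zeta = x$params$zeta,
    a = x$params$a,
    iterations = x$iterations_run,
    objective_initial = x$objective_trace[1],
    objective_final = x$objective_trace[length(x$objective_trace)],
    frac_uncoupled = mean(x$E == 0)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
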