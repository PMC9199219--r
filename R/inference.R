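#' Jackknife standard error from replicate difference matrices
#'
#' Applies the leave-one-out jackknife scale to a set of replicate
#' difference matrices: `se[i, j] = (n0 - 1) / sqrt(n0) * sd[i, j]`,
#' where `sd` is the entry-wise sample standard deviation (denominator
#' `n0 - 1`) over the `n0` replicates.
#'
#' @param replicate_diffs list of `n0 >= 2` numeric matrices of
#'   identical shape (the per-replicate `W1 - W2` estimates).
#' @return matrix of standard errors, same shape as the replicates.
#' @examples
#' reps <- lapply(c(1, 1, 1, 3), function(v) matrix(v))
#' jackknife_se_from_replicates(reps)  # (4-1)/sqrt(4) * sd = 1.5
#' @export
jackknife_se_from_replicates <- function(replicate_diffs) {
  n0 <- length(replicate_diffs)
  if (n0 < 2L) stop_domain("need at least 2 replicates",
                           "scaddecon_inference_error")
  dm <- dim(replicate_diffs[[1L]])
  arr <- vapply(replicate_diffs, function(d) {
    if (!identical(dim(d), dm)) stop_domain("replicate shapes differ",
                                            "scaddecon_alignment_error")
    as.numeric(d)
  }, numeric(prod(dm)))
  arr <- matrix(arr, nrow = prod(dm), ncol = n0)  # guard 1-entry matrices
  sds <- apply(arr, 1L, stats::sd)
  se <- matrix((n0 - 1) / sqrt(n0) * sds, nrow = dm[1L], ncol = dm[2L],
               dimnames = dimnames(replicate_diffs[[1L]]))
  se
}

#' Leave-one-out jackknife standard errors for the expression difference
#'
#' Reruns the full coupled estimation `n0 = min(n1, n2)` times, each
#' time leaving one sample out of each group (samples are paired by a
#' seeded permutation of each group), and turns the `n0` replicate
#' `W1 - W2` matrices into entry-wise standard errors via
#' [jackknife_se_from_replicates()]. Each replicate is a complete rerun:
#' warm-up, weight derivation, and main loop on the reduced data.
#'
#' @inheritParams scaddecon
#' @param allow_singular proceed when there are more cell types than
#'   `n0 - 1` remaining samples (default `FALSE`, which raises an
#'   error).
#' @return an object of class `jackknife_result`: list with `se`
#'   (genes x cell types), `n0`, and `replicate_diffs` (the `n0`
#'   difference matrices, retained for audit).
#' @details With fewer than 1.5x as many samples per group as cell
#'   types the leave-one-out refits become unstable; a warning is
#'   emitted in that regime but the computation proceeds.
#' @export
jackknife_se <- function(Y1, Y2, H1_0 = NULL, H2_0 = NULL, signature = NULL,
                         params = scaddecon_params(),
                         allow_singular = FALSE) {
  n1 <- ncol(Y1); n2 <- ncol(Y2)
  n0 <- min(n1, n2)
  if (n0 < 2L) stop_domain("jackknife needs at least 2 samples per group",
                           "scaddecon_inference_error")
  k <- if (!is.null(H1_0)) nrow(H1_0) else ncol(signature)
  if (min(n1, n2) < 1.5 * k) {
    warning(sprintf(
      "per-group sample size (%d) is below 1.5x the number of cell types (%d); jackknife SEs may be unstable",
      min(n1, n2), k), call. = FALSE)
  }
  if (k > n0 - 1L) {
    if (!allow_singular) {
      stop_domain(sprintf(
        "leave-one-out fits have %d samples for %d cell types; set allow_singular = TRUE to override",
        n0 - 1L, k), "scaddecon_inference_error")
    }
    warning("leave-one-out fits have more cell types than samples", call. = FALSE)
  }
  # permute sample IDs (sorted first, so the replicate composition does
  # not depend on the column order of Y)
  ids1 <- sort(colnames(Y1)); ids2 <- sort(colnames(Y2))
  if (!is.null(params$seed)) {
    ids1 <- with_seed(params$seed, sample(ids1))
    ids2 <- with_seed(params$seed + 1L, sample(ids2))
  }
  reps <- vector("list", n0)
  for (r in seq_len(n0)) {
    keep1 <- setdiff(colnames(Y1), ids1[r])
    keep2 <- setdiff(colnames(Y2), ids2[r])
    fit <- scaddecon(Y1[, keep1, drop = FALSE], Y2[, keep2, drop = FALSE],
                     H1_0 = if (!is.null(H1_0)) H1_0[, keep1, drop = FALSE],
                     H2_0 = if (!is.null(H2_0)) H2_0[, keep2, drop = FALSE],
                     signature = signature, params = params)
    reps[[r]] <- fit$W1 - fit$W2
  }
  structure(list(se = jackknife_se_from_replicates(reps), n0 = n0,
                 replicate_diffs = reps),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("Jackknife standard errors: %d x %d entries from %d leave-one-out replicates\n",
              nrow(x$se), ncol(x$se), x$n0))
  invisible(x)
}

#' Cell-type-specific differential expression test
#'
#' Entry-wise z-tests of the group expression difference against its
#' jackknife standard error: `z = (W1 - W2) / se`, two-sided normal
#' p-values, and a direction label (`up` means higher expression in
#' group 1) for entries significant at `alpha`.
#'
#' @param W1,W2 genes x cell-types expression estimates (typically from
#'   a [scaddecon()] fit).
#' @param jk a `jackknife_result` from [jackknife_se()], or a bare SE
#'   matrix of matching shape.
#' @param alpha significance level in (0, 1) used for the direction
#'   call; default 0.01.
#' @param adjust `"none"` (default; raw p-values are thresholded) or
#'   `"bh"` for Benjamini-Hochberg adjustment.
#' @return a tibble with one row per (gene, cell type): `gene`,
#'   `cell_type`, `diff`, `se`, `z`, `p`, `direction` (`up`/`down`/
#'   `none`), and `degenerate` (`TRUE` where `se = 0` but `diff != 0`,
#'   reported as `p = 0`). Where `se = 0` and `diff = 0`, `z` is `NA`
#'   and `p = 1`.
#' @export
deg_test <- function(W1, W2, jk, alpha = 0.01, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_domain("alpha must be in (0, 1)", "scaddecon_parameter_error")
  }
  se <- if (inherits(jk, "jackknife_result")) jk$se else jk
  if (!identical(dim(W1), dim(W2)) || !identical(dim(W1), dim(se))) {
    stop_domain("W1, W2 and se must share shape", "scaddecon_alignment_error")
  }
  d <- W1 - W2
  z <- d / se
  degenerate <- se == 0 & d != 0
  z[se == 0 & d == 0] <- NA_real_
  p <- 2 * stats::pnorm(-abs(z))
  p[se == 0 & d == 0] <- 1
  p[degenerate] <- 0
  if (adjust == "bh") p <- matrix(stats::p.adjust(p, "BH"), nrow = nrow(d))
  sig <- !is.na(p) & p < alpha
  direction <- ifelse(sig & d > 0, "up", ifelse(sig & d < 0, "down", "none"))
  tibble::tibble(
    gene = rep(rownames(W1), times = ncol(W1)),
    cell_type = rep(colnames(W1), each = nrow(W1)),
    diff = as.numeric(d),
    se = as.numeric(se),
    z = as.numeric(z),
    p = as.numeric(p),
    direction = as.character(direction),
    degenerate = as.logical(degenerate)
  )
}

#' Write a differential-expression table as TSV
#'
#' @param deg a tibble from [deg_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
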