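#' Kullback-Leibler divergence between proportion vectors
#'
#' Discrete KL(p || q) with both vectors floored at `eps` and
#' renormalized, so zero proportions do not produce infinities.
#'
#' @param p,q non-negative vectors of equal length (compositions).
#' @param eps floor applied before renormalization (default 1e-10,
#'   smaller than any meaningful proportion).
#' @return scalar divergence (>= 0).
#' @export
kl_divergence <- function(p, q, eps = 1e-10) {
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  sum(p * log(p / q))
}

default_p_grid <- function(n = 30L) 10^seq(log10(1e-12), log10(0.5),
                                           length.out = n)

#' Evaluate estimated proportions and DEG calls against ground truth
#'
#' Computes the two proportion-accuracy metrics (per-sample KL
#' divergence of the true composition from the estimate, averaged over
#' samples, and entry-wise RMSE) and, when a differential-expression
#' table and truth mask are supplied, operating characteristics of the
#' DEG calls: TPR and FPR separately for up- and down-calls over a
#' p-value grid, plus sensitivity, specificity and PPV at `alpha`.
#'
#' @param H_est,H_true cell-types x samples proportion matrices with
#'   matching dimnames (columns aligned by identifier).
#' @param deg optional tibble from [deg_test()].
#' @param de_mask optional genes x cell-types character truth mask
#'   (`"up"`/`"down"`/`"none"`), as produced by [simulate_dataset()].
#' @param alpha significance level for the summary operating point
#'   (default 0.01).
#' @param p_grid p-value cutoffs for the TPR/FPR sweep; default 30
#'   log-spaced points from 1e-12 to 0.5.
#' @return list with `kl`, `rmse`, and (when DEG inputs are given)
#'   `roc` (tibble over the grid: `cutoff`, `tpr_up`, `fpr_up`,
#'   `tpr_down`, `fpr_down`), `sensitivity`, `specificity`, `ppv` at
#'   `alpha`. False-positive rates use only truly non-differential
#'   entries in the denominator; a call counts as a true positive only
#'   when its direction matches the truth.
#' @export
evaluate_metrics <- function(H_est, H_true, deg = NULL, de_mask = NULL,
                             alpha = 0.01, p_grid = default_p_grid()) {
  if (!setequal(colnames(H_est), colnames(H_true)) ||
      !setequal(rownames(H_est), rownames(H_true))) {
    stop_domain("H_est and H_true must share cell types and samples",
                "scaddecon_alignment_error")
  }
  H_est <- H_est[rownames(H_true), colnames(H_true), drop = FALSE]
  kl <- mean(vapply(seq_len(ncol(H_true)), function(i) {
    kl_divergence(H_true[, i], H_est[, i])
  }, numeric(1)))
  rmse <- sqrt(mean((H_est - H_true)^2))
  out <- list(kl = kl, rmse = rmse)

  if (!is.null(deg) && !is.null(de_mask)) {
    truth <- de_mask[cbind(match(deg$gene, rownames(de_mask)),
                           match(deg$cell_type, colnames(de_mask)))]
    if (anyNA(truth)) stop_domain("DEG table entries missing from de_mask",
                                  "scaddecon_alignment_error")
    n_up <- sum(truth == "up"); n_down <- sum(truth == "down")
    n_none <- sum(truth == "none")
    roc <- lapply(p_grid, function(cut) {
      up_call <- deg$p < cut & deg$diff > 0
      down_call <- deg$p < cut & deg$diff < 0
      tibble::tibble(
        cutoff = cut,
        tpr_up = if (n_up) sum(up_call & truth == "up") / n_up else NA_real_,
        fpr_up = if (n_none) sum(up_call & truth == "none") / n_none else NA_real_,
        tpr_down = if (n_down) sum(down_call & truth == "down") / n_down else NA_real_,
        fpr_down = if (n_none) sum(down_call & truth == "none") / n_none else NA_real_
      )
    })
    out$roc <- do.call(rbind, roc)

    call <- deg$p < alpha & deg$diff != 0
    correct <- call & ((deg$diff > 0 & truth == "up") |
                         (deg$diff < 0 & truth == "down"))
    tp <- sum(correct); fp <- sum(call & !correct)
    out$sensitivity <- if (n_up + n_down) tp / (n_up + n_down) else NA_real_
    out$specificity <- if (n_none) 1 - sum(call & truth == "none") / n_none else NA_real_
    out$ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  out
}
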