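#' Plot the objective trace of a fit
#'
#' Line plot of the coupled objective after warm-up (iteration 0) and
#' after each main-loop iteration.
#'
#' @param object a `scaddecon_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scaddecon_fit <- function(object, ...) {
  require_ggplot2()
  df <- data.frame(iteration = seq_along(object$objective_trace) - 1L,
                   objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "main-loop iteration (0 = after warm-up)",
                  y = "coupled objective",
                  title = "Objective trace") +
    ggplot2::theme_minimal()
}

#' Plot estimated cell-type proportions by group
#'
#' Boxplots of the per-sample proportion estimates for each cell type,
#' side by side for the two groups.
#'
#' @param fit a `scaddecon_fit`.
#' @return a ggplot object.
#' @export
plot_proportions <- function(fit) {
  require_ggplot2()
  long <- function(H, grp) {
    data.frame(cell_type = rep(rownames(H), times = ncol(H)),
               proportion = as.numeric(H), group = grp)
  }
  df <- rbind(long(fit$H1, "group 1"), long(fit$H2, "group 2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type,
                                   y = .data$proportion,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "estimated proportion") +
    ggplot2::theme_minimal()
}

#' Volcano plot of cell-type-specific differential expression
#'
#' @param deg a tibble from [deg_test()].
#' @param alpha significance level drawn as a horizontal line
#'   (default 0.01).
#' @return a ggplot object, faceted by cell type.
#' @export
plot_volcano <- function(deg, alpha = 0.01) {
  require_ggplot2()
  df <- deg
  df$mlp <- -log10(pmax(df$p, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff, y = .data$mlp,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(~cell_type, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(up = "#d55e00",
                                            down = "#0072b2",
                                            none = "grey60")) +
    ggplot2::labs(x = "expression difference (group 1 - group 2)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

require_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
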