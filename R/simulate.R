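#' Simulation configuration
#'
#' Describes a synthetic two-group deconvolution study: a log-normal
#' base expression matrix shared by both groups, with a small fraction
#' of group 1's entries spiked up or down by fixed fold changes ("up"
#' means higher in group 1, matching the direction labels of
#' [deg_test()]), Dirichlet
#' mixing proportions (a distinct concentration vector per group), and
#' additive Gaussian noise on the mixed bulk with negatives clipped to
#' zero.
#'
#' @param m number of genes (default 5000).
#' @param k number of cell types (default 5).
#' @param n_per_group samples per group (default 20).
#' @param lognorm_mean,lognorm_sd parameters of the log-normal
#'   expression distribution (defaults 8 and 3). By default they are
#'   the mean and sd of the underlying normal on the log scale
#'   (`lognorm_scale = "log"`); set `lognorm_scale = "natural"` to
#'   interpret them as the mean and sd of the log-normal variable
#'   itself.
#' @param lognorm_scale `"log"` (default) or `"natural"`, see above.
#' @param frac_up,frac_down fractions of the `m * k` expression entries
#'   spiked up / down in group 1 (defaults 0.025 each; the two sets are
#'   disjoint, drawn uniformly over all entries).
#' @param up_folds,down_folds candidate fold changes for spiked entries
#'   (defaults `c(1.5, 2)` and `c(0.67, 0.5)`); each spiked entry draws
#'   its fold uniformly from the set.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the bulk (default 4); negative bulk entries after noise are reset
#'   to 0.
#' @param dirichlet_alpha1,dirichlet_alpha2 positive concentration
#'   vectors of length `k` for the two groups' proportion
#'   distributions; defaults `rep(2, k)` and `seq_len(k)`, two visibly
#'   distinct compositions.
#' @param seed integer RNG seed.
#' @return an object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(m = 5000L, k = 5L, n_per_group = 20L,
                              lognorm_mean = 8, lognorm_sd = 3,
                              lognorm_scale = c("log", "natural"),
                              frac_up = 0.025, frac_down = 0.025,
                              up_folds = c(1.5, 2),
                              down_folds = c(0.67, 0.5),
                              noise_sd = 4,
                              dirichlet_alpha1 = rep(2, k),
                              dirichlet_alpha2 = seq_len(k),
                              seed = 1L) {
  lognorm_scale <- match.arg(lognorm_scale)
  m <- as.integer(m); k <- as.integer(k); n_per_group <- as.integer(n_per_group)
  if (m < 1L || k < 2L || n_per_group < 1L) {
    stop_domain("need m >= 1, k >= 2, n_per_group >= 1",
                "scaddecon_parameter_error")
  }
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down >= 1) {
    stop_domain("spike fractions must be non-negative with frac_up + frac_down < 1",
                "scaddecon_parameter_error")
  }
  if (any(up_folds <= 0) || any(down_folds <= 0)) {
    stop_domain("fold changes must be positive", "scaddecon_parameter_error")
  }
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0",
                                "scaddecon_parameter_error")
  if (length(dirichlet_alpha1) != k || length(dirichlet_alpha2) != k ||
      any(dirichlet_alpha1 <= 0) || any(dirichlet_alpha2 <= 0)) {
    stop_domain("Dirichlet concentration vectors must be positive, length k",
                "scaddecon_parameter_error")
  }
  structure(list(m = m, k = k, n_per_group = n_per_group,
                 lognorm_mean = lognorm_mean, lognorm_sd = lognorm_sd,
                 lognorm_scale = lognorm_scale,
                 frac_up = frac_up, frac_down = frac_down,
                 up_folds = up_folds, down_folds = down_folds,
                 noise_sd = noise_sd,
                 dirichlet_alpha1 = dirichlet_alpha1,
                 dirichlet_alpha2 = dirichlet_alpha2,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rdirichlet_cols <- function(n, alpha) {
  g <- matrix(stats::rgamma(length(alpha) * n, shape = alpha), nrow = length(alpha))
  sweep(g, 2L, colSums(g), "/")
}

#' Generate a synthetic two-group deconvolution dataset
#'
#' Draws ground-truth expression, proportions, and noisy bulk matrices
#' according to a [simulation_config()], recording which entries were
#' spiked. Identical configurations (including the seed) produce
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param config a [simulation_config()].
#' @return an object of class `simulated_truth`: list with `W1`, `W2`
#'   (genes x cell types), `H1`, `H2` (cell types x samples), `Y1`,
#'   `Y2` (genes x samples), `de_mask` (genes x cell types character
#'   matrix with entries `"up"`, `"down"`, `"none"`), and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    m <- config$m; k <- config$k; n <- config$n_per_group
    if (config$lognorm_scale == "log") {
      meanlog <- config$lognorm_mean; sdlog <- config$lognorm_sd
    } else {
      sdlog <- sqrt(log(1 + (config$lognorm_sd / config$lognorm_mean)^2))
      meanlog <- log(config$lognorm_mean) - sdlog^2 / 2
    }
    genes <- sprintf("gene_%d", seq_len(m))
    cts <- sprintf("celltype_%d", seq_len(k))
    W1 <- matrix(stats::rlnorm(m * k, meanlog, sdlog), nrow = m,
                 dimnames = list(genes, cts))

    n_up <- round(m * k * config$frac_up)
    n_down <- round(m * k * config$frac_down)
    if (n_up + n_down > m * k) {
      stop_domain("requested spiked entries exceed the m * k grid",
                  "scaddecon_parameter_error")
    }
    spiked <- sample.int(m * k, n_up + n_down)
    up_idx <- spiked[seq_len(n_up)]
    down_idx <- spiked[n_up + seq_len(n_down)]
    # group 1 carries the spikes so that mask labels share the package's
    # group-1-relative direction convention (up = higher in group 1)
    W2 <- W1
    if (n_up > 0) {
      W1[up_idx] <- W2[up_idx] *
        sample(config$up_folds, n_up, replace = TRUE)
    }
    if (n_down > 0) {
      W1[down_idx] <- W2[down_idx] *
        sample(config$down_folds, n_down, replace = TRUE)
    }
    de_mask <- matrix("none", m, k, dimnames = dimnames(W1))
    de_mask[up_idx] <- "up"
    de_mask[down_idx] <- "down"

    H1 <- rdirichlet_cols(n, config$dirichlet_alpha1)
    H2 <- rdirichlet_cols(n, config$dirichlet_alpha2)
    dimnames(H1) <- list(cts, sprintf("g1_s%d", seq_len(n)))
    dimnames(H2) <- list(cts, sprintf("g2_s%d", seq_len(n)))

    Y1 <- W1 %*% H1
    Y2 <- W2 %*% H2
    if (config$noise_sd > 0) {
      Y1 <- Y1 + matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
      Y2 <- Y2 + matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
    }
    Y1[Y1 < 0] <- 0
    Y2[Y2 < 0] <- 0

    structure(list(W1 = W1, W2 = W2, H1 = H1, H2 = H2,
                   Y1 = Y1, Y2 = Y2, de_mask = de_mask, config = config),
              class = "simulated_truth")
  })
}

#' @export
print.simulated_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated two-group dataset: %d genes x %d cell types, %d samples/group\n",
              cfg$m, cfg$k, cfg$n_per_group))
  cat(sprintf("  spiked entries: %d up, %d down; noise sd = %g; seed = %d\n",
              sum(x$de_mask == "up"), sum(x$de_mask == "down"),
              cfg$noise_sd, cfg$seed))
  invisible(x)
}

#' Build a signature matrix from two expression matrices
#'
#' Averages the two matrices, ranks genes by how strongly one cell type
#' dominates (largest entry divided by second-largest entry per row;
#' rows whose second-largest entry is 0 rank first), and returns the top
#' `ceiling(top_frac * m)` rows of the average as the signature. Ties
#' are broken by original row order.
#'
#' @param W1,W2 aligned genes x cell-types expression matrices.
#' @param top_frac fraction of genes to keep (default 0.05).
#' @return signature matrix (selected rows of `(W1 + W2) / 2`, original
#'   row order).
#' @export
build_signature <- function(W1, W2, top_frac = 0.05) {
  if (ncol(W1) < 2L) stop_domain("ratio undefined with fewer than 2 cell types")
  if (!identical(dim(W1), dim(W2))) {
    stop_domain("W1 and W2 must share shape", "scaddecon_alignment_error")
  }
  if (top_frac <= 0 || top_frac > 1) {
    stop_domain("top_frac must be in (0, 1]", "scaddecon_parameter_error")
  }
  Wbar <- (W1 + W2) / 2
  ratio <- apply(Wbar, 1L, function(r) {
    s <- sort(r, decreasing = TRUE)
    if (s[2L] == 0) Inf else s[1L] / s[2L]
  })
  n_sig <- ceiling(top_frac * nrow(Wbar))
  ord <- order(ratio, decreasing = TRUE, method = "radix")
  sel <- sort(ord[seq_len(n_sig)])
  Wbar[sel, , drop = FALSE]
}

#' Write a simulated dataset as a directory of TSV files
#'
#' Writes `W1.tsv`, `W2.tsv`, `H1.tsv`, `H2.tsv`, `Y1.tsv`, `Y2.tsv`,
#' `de_mask.tsv` and a JSON echo of the configuration
#' (`sim_config.json`) for reproducibility audits.
#'
#' @param truth a `simulated_truth` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, dir) {
  stopifnot(inherits(truth, "simulated_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(truth$W1, file.path(dir, "W1.tsv"), "cellexpr")
  write_matrix(truth$W2, file.path(dir, "W2.tsv"), "cellexpr")
  write_matrix(truth$H1, file.path(dir, "H1.tsv"), "proportions")
  write_matrix(truth$H2, file.path(dir, "H2.tsv"), "proportions")
  write_matrix(truth$Y1, file.path(dir, "Y1.tsv"), "bulk")
  write_matrix(truth$Y2, file.path(dir, "Y2.tsv"), "bulk")
  mask <- truth$de_mask
  con <- file(file.path(dir, "de_mask.tsv"), open = "wb")
  writeLines(paste(c("id", colnames(mask)), collapse = "\t"), con)
  writeLines(paste(rownames(mask), apply(mask, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  close(con)
  cfg <- unclass(truth$config)
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
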