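test_that("generator is deterministic and leaves the caller's RNG alone", {
  cfg <- simulation_config(m = 100, k = 4, n_per_group = 6, seed = 5)
  set.seed(99); before <- runif(1)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  set.seed(99)
  expect_identical(runif(1), before)
})

test_that("default configuration reproduces the study dimensions and spike counts", {
  truth <- simulate_dataset(simulation_config(seed = 3))
  expect_equal(dim(truth$W1), c(5000L, 5L))
  expect_equal(ncol(truth$Y1), 20L)
  expect_equal(ncol(truth$Y2), 20L)
  expect_equal(sum(truth$de_mask == "up"), round(0.025 * 25000))   # 625
  expect_equal(sum(truth$de_mask == "down"), 625)

  # spiked entries carry exactly the configured fold changes (group 1
  # relative to group 2)
  ratio <- truth$W1 / truth$W2
  near <- function(x, set) vapply(x, function(v) min(abs(v - set)) < 1e-12,
                                  logical(1))
  expect_true(all(near(ratio[truth$de_mask == "up"], c(1.5, 2))))
  expect_true(all(near(ratio[truth$de_mask == "down"], c(0.67, 0.5))))
  expect_true(all(ratio[truth$de_mask == "none"] == 1))
})

test_that("noiseless, spike-free configuration returns an exact factorization", {
  truth <- simulate_dataset(simulation_config(m = 60, k = 3, n_per_group = 5,
                                              noise_sd = 0, frac_up = 0,
                                              frac_down = 0, seed = 8))
  expect_identical(truth$W1, truth$W2)
  expect_equal(truth$Y1, truth$W1 %*% truth$H1, tolerance = 1e-12)
  expect_equal(colSums(truth$H1), rep(1, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("natural-scale parameterization matches the requested moments", {
  cfg <- simulation_config(m = 20000, k = 2, n_per_group = 1,
                           lognorm_mean = 8, lognorm_sd = 3,
                           lognorm_scale = "natural", seed = 9)
  truth <- simulate_dataset(cfg)
  expect_equal(mean(truth$W2), 8, tolerance = 0.05)
  expect_equal(stats::sd(truth$W2), 3, tolerance = 0.1)
})

test_that("signature builder ranks rows by dominance ratio with stable ties", {
  W <- matrix(2, 10, 3, dimnames = list(sprintf("g%d", 1:10),
                                        sprintf("ct%d", 1:3)))
  W[4, ] <- c(10, 1, 1)
  sig <- build_signature(W, W, top_frac = 0.1)  # one row
  expect_identical(rownames(sig), "g4")
  expect_equal(unname(sig[1, ]), c(10, 1, 1))

  # all rows identical: stable order keeps the first rows
  W2 <- matrix(2, 10, 3, dimnames = dimnames(W))
  sig2 <- build_signature(W2, W2, top_frac = 0.3)
  expect_identical(rownames(sig2), c("g1", "g2", "g3"))

  # rows with a zero runner-up rank first
  W3 <- W2; W3[7, ] <- c(5, 0, 0)
  expect_identical(rownames(build_signature(W3, W3, top_frac = 0.1)), "g7")

  # top 5% of 5000 genes is 250 rows
  big <- simulate_dataset(simulation_config(seed = 2))
  expect_equal(nrow(build_signature(big$W1, big$W2)), 250L)
})

test_that("proportion metrics recover closed-form values", {
  H <- rand_H(4, 5)
  m <- evaluate_metrics(H, H)
  expect_equal(m$kl, 0, tolerance = 1e-9)
  expect_equal(m$rmse, 0)

  # uniform estimate against point-mass truth: KL -> log k
  k <- 4
  Ht <- matrix(c(1, 0, 0, 0), k, 3, dimnames = list(sprintf("ct%d", 1:k),
                                                    sprintf("s%d", 1:3)))
  He <- matrix(1 / k, k, 3, dimnames = dimnames(Ht))
  m2 <- evaluate_metrics(He, Ht)
  expect_equal(m2$kl, log(k), tolerance = 1e-6)
})

test_that("perfect p-values give ideal operating characteristics", {
  truth <- simulate_dataset(simulation_config(m = 80, k = 3, n_per_group = 5,
                                              seed = 11))
  mask <- truth$de_mask
  diff <- matrix(0, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  diff[mask == "up"] <- 1
  diff[mask == "down"] <- -1
  deg <- tibble::tibble(
    gene = rep(rownames(mask), times = ncol(mask)),
    cell_type = rep(colnames(mask), each = nrow(mask)),
    diff = as.numeric(diff),
    p = ifelse(as.numeric(diff) != 0, 0, 1)
  )
  met <- evaluate_metrics(truth$H1, truth$H1, deg = deg, de_mask = mask)
  inner <- met$roc[met$roc$cutoff > 0 & met$roc$cutoff < 1, ]
  expect_true(all(inner$tpr_up == 1))
  expect_true(all(inner$tpr_down == 1))
  expect_true(all(inner$fpr_up == 0))
  expect_true(all(inner$fpr_down == 0))
  expect_equal(met$ppv, 1)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$specificity, 1)
})

test_that("simulation directory export round-trips through the readers", {
  truth <- simulate_dataset(simulation_config(m = 40, k = 3, n_per_group = 4,
                                              seed = 12))
  dir <- withr::local_tempdir()
  write_simulation(truth, dir)
  expect_setequal(list.files(dir),
                  c("W1.tsv", "W2.tsv", "H1.tsv", "H2.tsv", "Y1.tsv",
                    "Y2.tsv", "de_mask.tsv", "sim_config.json"))
  Y1 <- read_matrix(file.path(dir, "Y1.tsv"), "bulk")
  expect_equal(Y1, truth$Y1, tolerance = 1e-12)
  H1 <- read_matrix(file.path(dir, "H1.tsv"), "proportions")
  expect_equal(H1, truth$H1, tolerance = 1e-10)
})

test_that("coupled fitting controls false positives at least as well as uncoupled", {
  # reduced-scale version of the comparative study (3 seeds)
  wins <- 0
  for (s in 1:3) {
    truth <- simulate_dataset(simulation_config(m = 400, k = 4,
                                                n_per_group = 12, seed = s))
    sig <- build_signature(truth$W1, truth$W2)
    ppv <- vapply(c(1, 0), function(lam) {
      p <- scaddecon_params(lam = lam, seed = s)
      fit <- scaddecon(truth$Y1, truth$Y2, signature = sig, params = p)
      jk <- jackknife_se(truth$Y1, truth$Y2, signature = sig, params = p)
      deg <- deg_test(fit$W1, fit$W2, jk, alpha = 0.01)
      evaluate_metrics(fit$H1, truth$H1, deg = deg,
                       de_mask = truth$de_mask)$ppv
    }, numeric(1))
    if (!is.na(ppv[1]) && !is.na(ppv[2]) && ppv[1] >= ppv[2]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
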