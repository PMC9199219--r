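test_that("joint update reduces to independent NNLS when the penalty vanishes", {
  inst <- tiny_instance(m = 7, k = 3, n1 = 5, n2 = 4, seed = 31, de_frac = 0.1)
  E <- local_seed(32, matrix(runif(3 * 7), 3, 7))

  ind <- list(W1 = estimate_W(inst$Y1, inst$H1),
              W2 = estimate_W(inst$Y2, inst$H2))

  # lam = 0
  upd <- joint_W_update(inst$Y1, inst$Y2, inst$H1, inst$H2, E, lam = 0)
  expect_matrix_equal(upd$W1, ind$W1, tol = 1e-8)
  expect_matrix_equal(upd$W2, ind$W2, tol = 1e-8)

  # E all zero, any lam
  upd0 <- joint_W_update(inst$Y1, inst$Y2, inst$H1, inst$H2,
                         matrix(0, 3, 7), lam = 5)
  expect_matrix_equal(upd0$W1, ind$W1, tol = 1e-8)
  expect_matrix_equal(upd0$W2, ind$W2, tol = 1e-8)

  expect_error(joint_W_update(inst$Y1, inst$Y2, inst$H1, inst$H2, E, lam = -1),
               class = "scaddecon_parameter_error")
})

test_that("column-wise solver attains the oracle objective of the coupled problem", {
  skip_if_not_installed("pracma")
  local_seed(33, {
    for (i in 1:10) {
      m <- sample(3:6, 1); k <- sample(2:3, 1)
      inst <- tiny_instance(m = m, k = k, n1 = sample(3:5, 1),
                            n2 = sample(3:5, 1), seed = 330 + i,
                            de_frac = 0.2)
      E <- matrix(runif(k * m), k, m)
      for (lam in c(0.5, 2)) {
        mine <- joint_W_update(inst$Y1, inst$Y2, inst$H1, inst$H2, E, lam)
        orac <- oracle_joint_W(inst$Y1, inst$Y2, inst$H1, inst$H2, E, lam)
        o_mine <- coupled_obj(inst, mine$W1, mine$W2, E, lam)
        o_orac <- coupled_obj(inst, orac$W1, orac$W2, E, lam)
        expect_lt(abs(o_mine - o_orac), 1e-5 * max(1, o_orac))
      }
    }
  })
})

test_that("stronger coupling never increases the weighted divergence of the solution", {
  inst <- tiny_instance(m = 8, k = 3, n1 = 5, n2 = 5, seed = 34, de_frac = 0.2)
  E <- local_seed(35, matrix(runif(3 * 8), 3, 8))
  div <- vapply(c(0, 0.1, 0.5, 1, 2, 5, 20), function(lam) {
    upd <- joint_W_update(inst$Y1, inst$Y2, inst$H1, inst$H2, E, lam)
    sum(E * (t(upd$W1) - t(upd$W2))^2)
  }, numeric(1))
  expect_true(all(diff(div) <= 1e-8))
})

test_that("with unit weights the update solves the ridge-coupled normal equations", {
  # strictly interior solution: large positive profiles, consistent data
  inst <- tiny_instance(m = 6, k = 3, n1 = 6, n2 = 6, seed = 36)
  inst$W1 <- inst$W1 + 5; inst$W2 <- inst$W1
  inst$Y1 <- inst$W1 %*% inst$H1; inst$Y2 <- inst$W2 %*% inst$H2
  E1 <- matrix(1, 3, 6)
  lam <- 0.7
  upd <- joint_W_update(inst$Y1, inst$Y2, inst$H1, inst$H2, E1, lam)

  G1 <- inst$H1 %*% t(inst$H1); G2 <- inst$H2 %*% t(inst$H2)
  I <- diag(3)
  AtA <- rbind(cbind(G1 + lam * I, -lam * I),
               cbind(-lam * I, G2 + lam * I))
  for (j in 1:6) {
    rhs <- c(inst$H1 %*% inst$Y1[j, ], inst$H2 %*% inst$Y2[j, ])
    x <- solve(AtA, rhs)
    expect_true(all(x > 0))  # interior, so NNLS == unconstrained ridge
    expect_equal(unname(c(upd$W1[j, ], upd$W2[j, ])), unname(x),
                 tolerance = 1e-7)
  }
})

test_that("identical groups stay identical through the whole fit", {
  inst <- tiny_instance(m = 10, k = 3, n1 = 6, seed = 37)
  fit <- scaddecon(inst$Y1, inst$Y1, H1_0 = inst$H1, H2_0 = inst$H1,
                   params = scaddecon_params(max_iter = 3))
  # symmetric up to active-set rounding in the stacked solver
  expect_equal(fit$W1, fit$W2, tolerance = 1e-12)
  expect_equal(fit$H1, fit$H2, tolerance = 1e-12)
  expect_true(all(fit$E == 1))
})

test_that("iteration accounting honours max_iter and records the objective trace", {
  inst <- tiny_instance(m = 10, k = 3, n1 = 6, n2 = 6, seed = 38,
                        de_frac = 0.1)
  expect_error(scaddecon_params(max_iter = 0), class = "scaddecon_parameter_error")
  fit <- scaddecon(inst$Y1, inst$Y2, H1_0 = inst$H1, H2_0 = inst$H2,
                   params = scaddecon_params(max_iter = 1, tol = 0))
  expect_identical(fit$iterations_run, 1L)
  expect_length(fit$objective_trace, 2L)  # after warm-up + one iteration
  expect_true(all(fit$W1 >= 0) && all(fit$W2 >= 0))
  expect_equal(colSums(fit$H1), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("initialization contract is enforced", {
  inst <- tiny_instance(m = 10, k = 3, n1 = 5, n2 = 5, seed = 39)
  sig <- inst$W1[1:5, ]
  expect_error(scaddecon(inst$Y1, inst$Y2, H1_0 = inst$H1, H2_0 = inst$H2,
                         signature = sig),
               class = "scaddecon_usage_error")
  expect_error(scaddecon(inst$Y1, inst$Y2, H1_0 = inst$H1),
               class = "scaddecon_usage_error")
  expect_error(scaddecon(inst$Y1, inst$Y2),
               class = "scaddecon_usage_error")

  Ybad <- inst$Y2
  rownames(Ybad) <- paste0("x", rownames(Ybad))
  expect_error(scaddecon(inst$Y1, Ybad, H1_0 = inst$H1, H2_0 = inst$H2),
               class = "scaddecon_alignment_error")

  # gene order differences are resolved by identifier
  fitA <- scaddecon(inst$Y1, inst$Y2, H1_0 = inst$H1, H2_0 = inst$H2,
                    params = scaddecon_params(max_iter = 1))
  fitB <- scaddecon(inst$Y1, inst$Y2[rev(rownames(inst$Y2)), ],
                    H1_0 = inst$H1, H2_0 = inst$H2,
                    params = scaddecon_params(max_iter = 1))
  expect_equal(fitA$W2, fitB$W2, tolerance = 1e-12)
})

test_that("tidy and glance summarise the fit consistently", {
  inst <- tiny_instance(m = 6, k = 3, n1 = 5, n2 = 5, seed = 40, de_frac = 0.1)
  fit <- scaddecon(inst$Y1, inst$Y2, H1_0 = inst$H1, H2_0 = inst$H2,
                   params = scaddecon_params(max_iter = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6 * 3)
  expect_equal(td$w1[1], fit$W1[1, 1])
  expect_equal(td$weight, as.numeric(t(fit$E)))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 6L)
  expect_equal(gl$objective_final,
               fit$objective_trace[length(fit$objective_trace)])
})

test_that("signature-restricted H updates run and require signature initialization", {
  truth <- simulate_dataset(simulation_config(m = 150, k = 3, n_per_group = 8,
                                              noise_sd = 0, frac_up = 0,
                                              frac_down = 0, seed = 51))
  sig <- build_signature(truth$W1, truth$W2, top_frac = 0.2)
  fit <- scaddecon(truth$Y1, truth$Y2, signature = sig,
                   params = scaddecon_params(h_update_genes = "signature",
                                             max_iter = 2))
  expect_identical(fit$signature_genes, rownames(sig))
  expect_lt(max(abs(fit$H1 - truth$H1)), 1e-6)
  expect_equal(colSums(fit$H1), rep(1, 8), ignore_attr = TRUE,
               tolerance = 1e-8)

  expect_error(
    scaddecon(truth$Y1, truth$Y2, H1_0 = truth$H1, H2_0 = truth$H2,
              params = scaddecon_params(h_update_genes = "signature")),
    class = "scaddecon_usage_error")
})

test_that("weight recomputation is available behind the expert flag", {
  inst <- tiny_instance(m = 20, k = 3, n1 = 6, n2 = 6, seed = 52,
                        de_frac = 0.2)
  fit <- scaddecon(inst$Y1, inst$Y2, H1_0 = inst$H1, H2_0 = inst$H2,
                   params = scaddecon_params(recompute_weights = TRUE,
                                             max_iter = 3))
  expect_equal(fit$E,
               compute_weights(fit$W1, fit$W2, zeta = 4, a = 3.7),
               tolerance = 1e-12)
})
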