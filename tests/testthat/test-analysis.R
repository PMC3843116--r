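test_that("squared Pearson correlation handles exact, independent and degenerate cases", {
  x <- 1:50
  expect_equal(pearson_r2(x, 2 * x + 1), 1)
  expect_equal(pearson_r2(x, -x), 1)
  set.seed(17)
  a <- rnorm(883); b <- rnorm(883)
  expect_lt(pearson_r2(a, b), 0.02)
  expect_error(pearson_r2(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_r2(1:2, 1:2), "at least 3")
})

test_that("Tukey comparisons detect large shifts and not identical groups", {
  set.seed(23)
  g <- rep(c("ost", "int", "mix"), each = 100)
  same <- rnorm(300)
  res <- compare_groups(rep(rnorm(100), 3), g)
  expect_true(all(res$p_adj > 0.99))
  shifted <- c(rnorm(100), rnorm(100) + 5, rnorm(100))
  res2 <- compare_groups(shifted, g)
  expect_lt(res2$p_adj[res2$pair == "ost-int"], 0.001)
  expect_error(compare_groups(rnorm(3), c("a", "a", "b")), "degenerate")
  expect_error(compare_groups(rnorm(3), rep("a", 3)), "2 groups")
})

test_that("Tukey type-I error rate is near the nominal level", {
  set.seed(29)
  n_rep <- 600
  rejections <- 0
  for (i in seq_len(n_rep)) {
    v <- rnorm(36)
    g <- rep(c("a", "b", "c"), each = 12)
    rejections <- rejections + any(compare_groups(v, g)$p_adj < 0.05)
  }
  rate <- rejections / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("distribution tests separate shifted samples and not identical ones", {
  set.seed(37)
  a <- rnorm(200, 24, 5)
  p_same <- compare_distributions(a, a)
  expect_gt(p_same["p_wilcoxon"], 0.9)
  p_shift <- compare_distributions(a, a + 5)
  expect_lt(p_shift["p_wilcoxon"], 0.001)
  expect_lt(p_shift["p_t"], 0.001)
  p_paired <- compare_distributions(a, a + rnorm(200, 0, 0.1),
                                    paired = TRUE)
  expect_length(p_paired, 2)
  expect_error(compare_distributions(1, 1:5), "at least 2")
})

test_that("per-site prediction fills both moduli with the axial value as upper bound", {
  s <- indent_sites(1:4, 1:4, 1:4)
  s$phi_avg <- c(0.36, 0.38, 0.40, 0.38)
  s$theta_avg <- c(0, 20, 40, 0)
  out <- predict_sites(s)
  expect_true(all(out$E_pred <= out$E_pred0 + 1e-9))
  expect_equal(out$E_pred[1], out$E_pred0[1])
  expect_equal(out$E_pred[4], out$E_pred[4])
  # theta = 0 for all sites makes the two predictions identical
  s$theta_avg <- rep(0, 4)
  out0 <- predict_sites(s)
  expect_equal(out0$E_pred, out0$E_pred0)
  # interpolator route agrees with the direct route
  ip <- modulus_interpolator(phi_grid = seq(0.34, 0.42, by = 0.01),
                             theta_grid = seq(0, 45, by = 3))
  s$theta_avg <- c(0, 20, 40, 0)
  out_ip <- predict_sites(s, predictor = ip)
  out_dir <- predict_sites(s)
  expect_lt(max(abs(out_ip$E_pred - out_dir$E_pred)), 0.02)
  # infeasible site is flagged NA rather than failing the batch
  s$phi_avg[2] <- NA
  out_na <- predict_sites(s)
  expect_true(is.na(out_na$E_pred[2]))
})

test_that("degenerate sensitivity ranges collapse to the fixed-parameter modulus", {
  cfg <- sensitivity_config(q_range = c(0.25, 0.25),
                            f_fibril_range = c(0.53, 0.53),
                            theta_range = c(0, 0), n_draws = 4, seed = 5)
  mc <- sensitivity_mc(cfg)
  ref <- indentation_modulus(
    fibril_array_stiffness(table1_params(), phi = 0.34), theta = 0)
  expect_equal(unname(mc$values), rep(ref, 4), tolerance = 1e-10)
  expect_equal(mc$min, mc$max)
})

test_that("sensitivity draws reject infeasible corners and the maximum favors axial alignment", {
  cfg <- sensitivity_config(n_draws = 150, seed = 7)
  mc <- sensitivity_mc(cfg)
  expect_length(mc$values, 150)
  expect_true(all(mc$draws$q * 0.34 / mc$draws$f_fibril <= 1))
  fvoid <- 1 - (1 - mc$draws$q) * 0.34 / (1 - mc$draws$f_fibril)
  expect_true(all(fvoid >= 0 & fvoid <= 1))
  # the top decile of moduli comes disproportionately from small theta
  # or near-dense extra-fibrillar foam; check the theta-monotonicity signal:
  # among draws with similar (q, f), larger theta gives smaller modulus
  ord <- order(mc$values)
  expect_gt(mean(mc$draws$theta[head(ord, 15)]),
            mean(mc$draws$theta[tail(ord, 15)]))
  expect_output(print(mc), "draws")
})

test_that("the pipeline is self-consistent on a noiseless registered cohort", {
  cfg <- cohort_config(n_patterns = 3, seed = 41, E_noise_sd = 0,
                       misregistration = rigid_transform())
  sim <- simulate_cohort(cfg)
  rep <- run_pipeline(sim, register = FALSE)
  corr <- rep$correlation_table
  r2_pred <- corr$r2_vs_E_meas[corr$variable == "E_pred"]
  expect_gt(r2_pred, 1 - 1e-6)
  expect_equal(rep$summary$E_meas[["mean"]], rep$summary$E_pred[["mean"]],
               tolerance = 1e-6)
  # softening by fibril angle: axial prediction exceeds the full prediction
  expect_gt(rep$summary$E_pred0[["mean"]], rep$summary$E_pred[["mean"]])
})

test_that("the pipeline recovers covariates through misregistration and registration", {
  cfg <- cohort_config(n_patterns = 3, seed = 43, E_noise_sd = 0)
  sim <- simulate_cohort(cfg)
  rep <- run_pipeline(sim)
  truth <- lamellar:::invert_transform(cfg$misregistration)
  expect_lt(abs(rep$transform$dx - truth$dx), 0.3)
  expect_lt(abs(rep$transform$dy - truth$dy), 0.3)
  corr <- rep$correlation_table
  expect_gt(corr$r2_vs_E_meas[corr$variable == "E_pred"], 0.95)
})

test_that("pipeline reports are deterministic and written to disk on request", {
  cfg <- cohort_config(n_patterns = 2, seed = 47)
  a <- run_pipeline(simulate_cohort(cfg, predictor = function(p, t) 80 * p - 0.05 * t),
                    register = FALSE)
  b <- run_pipeline(simulate_cohort(cfg, predictor = function(p, t) 80 * p - 0.05 * t),
                    register = FALSE)
  expect_identical(a$summary, b$summary)
  d <- withr::local_tempdir()
  r <- run_pipeline(simulate_cohort(cfg, predictor = function(p, t) 80 * p - 0.05 * t),
                    register = FALSE, dir = d)
  expect_true(file.exists(file.path(d, "sites.csv")))
  expect_true(file.exists(file.path(d, "correlation_table.csv")))
  expect_true(file.exists(file.path(d, "summary.yaml")))
  expect_output(print(r), "retained")
  expect_output(summary(r), "Correlation table")
})
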