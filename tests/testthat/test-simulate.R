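test_that("the generator is reproducible and respects its configuration", {
  cfg <- sim_config(n_genes = 60,
                    affected_sets = list(list(name = "A", size = 10, delta = 1),
                                         list(name = "B", size = 5, delta = 0.5)))
  a <- simulate_expression(cfg, seed = 123)
  b <- simulate_expression(cfg, seed = 123)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)

  c <- simulate_expression(cfg, seed = 124)
  expect_false(identical(a$expr, c$expr))

  expect_equal(nrow(a$expr), 60)
  expect_equal(ncol(a$expr), 16)  # feature_id + 6 cases + 9 controls
  expect_false(expr_is_log2(a$expr))
  expect_true(all(as.matrix(a$expr[-1]) > 0))
  expect_equal(sum(a$truth$set_name == "A", na.rm = TRUE), 10)
  expect_equal(sum(a$truth$delta == 0.5), 5)
  expect_equal(sum(table(a$design$group)[c("case", "control")]), 15)
})

test_that("configuration validation rejects impossible studies", {
  expect_error(sim_config(n_genes = 5,
                          affected_sets = list(list(name = "A", size = 10,
                                                    delta = 1))),
               "exceed")
  expect_error(sim_config(correlation_rho = 1), "\\[0, 1\\)")
  expect_error(sim_config(affected_sets = list(list(name = "A", size = 3,
                                                    delta = -1))),
               "non-negative")
  expect_error(run_simulation_study(data.frame(), n_reps = 10), "empty")
})

test_that("an injected coordinated shift is detected by the full pipeline", {
  cfg <- sim_config(n_genes = 100,
                    affected_sets = list(list(name = "hit", size = 10,
                                              delta = 2)))
  sim <- simulate_expression(cfg, seed = 1)
  fit <- set_shift_test(floor_log2(sim$expr), sim$design, sim$sets)
  expect_lt(glance(fit)$p_combined, 1e-4)
})

test_that("a null dataset produces roughly alpha false positives in the screen", {
  sim <- simulate_expression(sim_config(n_genes = 2000, mu_range = c(6, 11)),
                             seed = 77)
  expect_true(all(sim$truth$delta == 0))
  de <- de_screen(de_table(floor_log2(sim$expr), sim$design))
  # p < 0.05 alone should fire on ~5% of null genes; the fold-change
  # floor then cuts most of those away
  expect_lt(mean(de$t_pvalue < 0.05), 0.08)
  expect_gt(mean(de$t_pvalue < 0.05), 0.02)
  expect_lt(mean(de$passes_screen), 0.05)
})

test_that("combined mid-p null p-values are close to uniform", {
  # 10,000 replicates keep the 0.02 bound ~5 sampling SDs above the
  # null expectation of the KS statistic
  set.seed(88)
  n_reps <- 10000
  k <- 10
  p_comb <- replicate(n_reps, {
    vals <- matrix(rnorm(k * 15, 8, 0.5), nrow = k)
    p <- apply(vals, 1, function(v) {
      wilcoxon_one_tailed(v[1:6], v[7:15], mid_p = TRUE)
    })
    combine_pvalues_z(p)$p_combined
  })
  ks <- suppressWarnings(stats::ks.test(p_comb, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the inclusive exact tail makes the combined test conservative", {
  # with only 55 attainable rank sums in a 6v9 design, p-values that
  # include the observed point are stochastically larger than uniform;
  # the combined test then rejects less often than alpha
  res <- run_simulation_study(data.frame(delta = 0, rho = 0, k = 10),
                              n_reps = 1000, alpha = 0.05, seed = 30,
                              mid_p = FALSE, mu_range = c(6, 11))
  expect_lt(res$rejection_rate, 0.05)
})

test_that("power rises with shift size and set size", {
  grid <- data.frame(delta = c(0.25, 0.75, 0.75), rho = 0, k = c(10, 10, 4))
  res <- run_simulation_study(grid, n_reps = 150, seed = 5,
                              mu_range = c(6, 11))
  expect_gt(res$rejection_rate[2], res$rejection_rate[1])   # delta
  expect_gte(res$rejection_rate[2], res$rejection_rate[3])  # set size
})

test_that("simulation summaries report the estimated shift", {
  res <- run_simulation_study(data.frame(delta = 1, rho = 0, k = 8),
                              n_reps = 100, seed = 9, mu_range = c(6, 10))
  expect_named(res, c("delta", "rho", "k", "n_reps", "rejection_rate",
                      "mc_se", "mean_est_log2fc", "bias"))
  expect_equal(res$mean_est_log2fc, 1, tolerance = 0.2)
})
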