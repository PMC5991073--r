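test_that("p-value to chi-squared transform matches the quantile oracle", {
  expect_equal(p_to_chisq(1.0), 0.0)
  expect_equal(p_to_chisq(0.05), 3.8415, tolerance = 1e-4)
  expect_equal(p_to_chisq(0.5), 0.4549, tolerance = 1e-4)
  # round trip: the upper-tail probability of the output is the input
  p <- c(1e-10, 0.001, 0.3, 0.999, 1)
  expect_equal(pchisq(p_to_chisq(p), 1, lower.tail = FALSE), p)
  expect_error(p_to_chisq(0), "\\(0, 1\\]")
  expect_error(p_to_chisq(1.2), "\\(0, 1\\]")
})

test_that("top-fraction statistic selects ceil(f*m) values with a floor of one", {
  expect_equal(top_fraction_stat(3.0, 0.1), list(k = 1L, stat = 3.0))
  ten <- c(9, runif(9, 0, 5))
  expect_equal(top_fraction_stat(ten, 0.1), list(k = 1L, stat = 9))
  set.seed(2)
  x <- runif(25, 0, 10)
  r <- top_fraction_stat(x, 0.1)
  expect_equal(r$k, 3L) # ceiling(2.5)
  expect_equal(r$stat, sum(sort(x, decreasing = TRUE)[1:3]))
  expect_equal(top_fraction_stat(x, 0.1, k_rounding = "floor")$k, 2L)
  expect_equal(top_fraction_stat(x, 1)$stat, sum(x))
  expect_error(top_fraction_stat(numeric(0), 0.1), "non-empty")
})

test_that("empirical p-value uses the add-one estimator with >= ties", {
  sims <- c(rep(10, 3), rep(1, 996)) # 999 sims, 3 at/above the observed value
  expect_equal(empirical_p(5, sims), 4 / 1000)
  expect_equal(empirical_p(11, sims), 1 / 1000)
  expect_equal(empirical_p(0.5, sims), 1.0)
  expect_equal(empirical_p(10, sims), 4 / 1000) # ties count against the observed
  expect_error(empirical_p(1, numeric(0)), "at least one")
})

test_that("simulated null statistics follow the closed-form distributions", {
  s1 <- simulate_null_stats(matrix(1, 1, 1), f = 0.1, nsim = 10000, seed = 5)
  expect_gt(suppressWarnings(ks.test(s1, pchisq, df = 1)$p.value), 0.01)
  s4 <- simulate_null_stats(diag(4), f = 1.0, nsim = 10000, seed = 6)
  expect_gt(suppressWarnings(ks.test(s4, pchisq, df = 4)$p.value), 0.01)
  expect_identical(simulate_null_stats(diag(3), 0.5, 100, seed = 9),
                   simulate_null_stats(diag(3), 0.5, 100, seed = 9))
})

test_that("simulation refuses indefinite correlation matrices", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(simulate_null_stats(bad, 0.1, 10, seed = 1), "positive semidefinite")
})

test_that("fixed-index selection sums the requested components", {
  R <- ar1_cor(5, 0.4)
  s <- simulate_null_stats(R, f = 0.1, nsim = 50, seed = 3, fixed_indices = c(2, 4))
  z <- rmvn(50, R, seed = 3)
  expect_equal(s, unname(z[, 2]^2 + z[, 4]^2))
})

test_that("a single-SNP window reduces to the per-SNP test", {
  ss <- make_sumstats(0.02)
  R <- matrix(1, 1, 1, dimnames = list("s1", "s1"))
  cfg <- set_test_config(sim_stages = 20000, seed = 13)
  res <- test_window("s1", ss, R, cfg)
  expect_lt(abs(res$empirical_p - 0.02), 3 * sqrt(0.02 * 0.98 / 20000))
  expect_equal(res$top_snp_id, "s1")
  expect_equal(res$top_snp_p, 0.02)
  expect_equal(res$n_snps_tested, 1)
})

test_that("empirical p is monotone non-increasing in the observed statistic", {
  sims <- simulate_null_stats(ar1_cor(10, 0.6), 0.1, 2000, seed = 8)
  obs <- seq(0, 30, length.out = 50)
  p <- vapply(obs, empirical_p, numeric(1), simulated_stats = sims)
  expect_true(all(diff(p) <= 0))
})

test_that("simulation stages escalate only for small p-values", {
  ss_small <- make_sumstats(1e-6)
  ss_mid <- make_sumstats(0.5)
  R <- matrix(1, 1, 1, dimnames = list("s1", "s1"))
  cfg <- set_test_config(sim_stages = c(1000, 10000), seed = 17)
  res_small <- test_window("s1", ss_small, R, cfg)
  expect_equal(res_small$n_sims_used, 10000)
  res_mid <- test_window("s1", ss_mid, R, cfg)
  expect_equal(res_mid$n_sims_used, 1000)
  expect_gt(res_small$observed_stat, res_mid$observed_stat)
})

test_that("window orchestration reports the top SNP with deterministic tie-breaks", {
  p <- c(0.4, 0.01, 0.01, 0.2)
  ss <- make_sumstats(p)
  set.seed(30)
  R <- random_corr(4)
  cfg <- set_test_config(sim_stages = 1000, seed = 19)
  snp_set <- list(window = data.frame(name = "w"), snp_ids = paste0("s", 1:4))
  res <- test_window(snp_set, ss, R, cfg)
  expect_equal(res$mirna_name, "w")
  expect_equal(res$top_snp_id, "s2") # tie with s3 broken by position
  expect_equal(res$top_snp_p, 0.01)
  expect_equal(res$n_snps_tested, 4)
  # results keyed by window name are reproducible
  res2 <- test_window(snp_set, ss, R, cfg)
  expect_identical(res, res2)
})

test_that("windows with no SNPs in the LD panel are flagged untestable", {
  ss <- make_sumstats(c(0.1, 0.2))
  R <- matrix(1, 1, 1, dimnames = list("zz", "zz"))
  res <- test_window(c("s1", "s2"), ss, R, set_test_config(sim_stages = 100))
  expect_true(res$untestable)
  expect_equal(res$n_snps_tested, 0)
})

test_that("SNPs absent from the LD matrix are excluded from the test", {
  ss <- make_sumstats(c(0.001, 0.5, 0.9))
  R <- ar1_cor(2, 0.3) # covers s1, s2 only
  res <- test_window(paste0("s", 1:3), ss, R, set_test_config(sim_stages = 500))
  expect_equal(res$n_snps_tested, 2)
  expect_equal(res$top_snp_id, "s1")
})
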