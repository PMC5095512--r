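test_that("objective equals a directly coded double loop", {
  cfg <- fit_config(i_fit = 20)
  set.seed(3)
  k <- 400
  s <- sfs(table(rbinom(800, k, 0.01) + 1L), k)   # arbitrary occupied counts
  h <- random_histogram(3, k = k)
  # brute force: loop over counts and grid points
  F_obs <- sfs_vector(s, 20)
  brute <- 0
  for (i in 1:20) {
    e_i <- 0
    for (j in seq_along(h$grid$points))
      e_i <- e_i + h$mass[j] * dbinom(i, k, h$grid$points[j])
    brute <- brute + (1 / sqrt(1 + F_obs[i])) * abs(e_i - F_obs[i])
  }
  expect_equal(sfs_objective(h, s, cfg), brute, tolerance = 1e-10)

  # exact-match histogram scores zero
  h_exact <- freq_histogram(0.5, 100)
  s_exact <- sfs(c(`1` = 50, `2` = 25), k = 2)
  expect_equal(sfs_objective(h_exact, s_exact, fit_config(i_fit = 2)), 0)

  # zero histogram vs F_1 = 10 under uniform weights
  h0 <- freq_histogram(c(0.1, 0.5), c(0, 0))
  s1 <- sfs(c(`1` = 10), k = 100)
  expect_equal(sfs_objective(h0, s1, fit_config(weights = "uniform")), 10)
})

test_that("degenerate inputs are handled explicitly", {
  expect_warning(f <- unseen_fit(sfs(numeric(0), k = 100)), "empty SFS")
  expect_equal(total_variants(f$histogram), 0)
  expect_equal(f$objective_value, 0)

  expect_warning(f2 <- unseen_fit(sfs(c(`1` = 5), k = 10),
                                  fit_config(i_fit = 50)),
                 "i_fit lowered")
  expect_equal(f2$diagnostics$i_fit, 10)

  # all variants fixed (only F_k > 0): frequent part carries everything
  s_fix <- sfs(c(`60` = 9), k = 60)
  f3 <- unseen_fit(s_fix, fit_config(i_fit = 20))
  expect_equal(sum(f3$histogram$frequent$count), 9)
  expect_equal(expected_unique(f3$histogram, 1), 9)
})

test_that("round-trip recovery: fit on an exact expected SFS recovers the truth", {
  s <- pointmass_sfs(0.01, 10000, k = 1000)
  f <- unseen_fit(s, fit_config(i_fit = 20))
  T_hat <- total_variants(f$histogram)
  expect_lt(abs(T_hat - 10000) / 10000, 0.10)
  # >= 90% of recovered mass within a factor 2 of the true frequency
  g <- f$histogram$grid$points
  near <- g >= 0.005 & g <= 0.02
  expect_gte(sum(f$histogram$mass[near]) / sum(f$histogram$mass), 0.90)
})

test_that("LP optimality certificate: fitted objective never exceeds the truth's", {
  cfg <- fit_config()
  # truths supported on the estimator's own grid, rare enough that no
  # observed count exceeds i_fit
  scenarios <- list(
    sim_scenario("beta", n_variants = 20000, k = 500, seed = 1),
    sim_scenario("beta", n_variants = 20000, k = 500, seed = 2,
                 shape1 = 1, shape2 = 2000))
  for (sc in scenarios) {
    h_true <- make_true_histogram(sc)
    co <- sample_cohort(h_true, sc$k, seed = sc$seed)
    f <- unseen_fit(co$sfs, cfg)
    expect_lte(sfs_objective(f$histogram, co$sfs, cfg),
               sfs_objective(h_true, co$sfs, cfg) * (1 + 1e-8) + 1e-8)
  }
  # mixture truth pinned to exact grid points
  g <- default_grid(500)$points
  pts <- g[c(30, 80, 120)]
  h_mix <- freq_histogram(pts, c(5000, 2000, 500))
  co <- sample_cohort(h_mix, 500, seed = 5)
  f <- unseen_fit(co$sfs, cfg)
  expect_lte(sfs_objective(f$histogram, co$sfs, cfg),
             sfs_objective(h_mix, co$sfs, cfg) * (1 + 1e-8) + 1e-8)
})

test_that("two-component sampled SFS extrapolates within 5%", {
  h_true <- freq_histogram(c(1e-4, 1e-2), c(50000, 5000))
  co <- sample_cohort(h_true, 10000, seed = 11)
  f <- unseen_fit(co$sfs)
  u_hat <- expected_unique(f$histogram, 10000)
  u_true <- expected_unique(h_true, 10000)
  expect_lt(abs(u_hat - u_true) / u_true, 0.05)
})

test_that("self-extrapolation reproduces the observed distinct count", {
  for (seed in c(1, 2)) {
    sc <- sim_scenario("neutral_like", n_variants = 20000, k = 500, seed = seed)
    co <- sample_cohort(make_true_histogram(sc), 500, seed = seed)
    f <- unseen_fit(co$sfs)
    D <- sfs_total(co$sfs)
    expect_lt(abs(expected_unique(f$histogram, 500) - D) / D, 0.05)
  }
})

test_that("20x extrapolation from 5% allele subsamples recovers the cohort", {
  # single 100-allele subsamples carry large realization noise, so the
  # claim is about the mean prediction across the 20 disjoint subsamples
  sc <- sim_scenario("neutral_like", n_variants = 50000, k = 2000, seed = 0)
  co <- sample_cohort(make_true_histogram(sc), 2000, seed = 0)
  D <- sfs_total(co$sfs)
  part <- split_alleles(co, n_groups = 20, seed = 1)
  preds <- vapply(part$sfs_list, function(s)
    expected_unique(unseen_fit(s)$histogram, 2000), numeric(1))
  expect_lt(abs(mean(preds) - D) / D, 0.10)
})

test_that("discovery-curve prediction composes expected_unique", {
  h <- freq_histogram(1.0, 5)
  f <- structure(list(histogram = h), class = "unseen_fit")
  dc <- predict_discovery_curve(f, c(0, 1, 10))
  expect_equal(dc$expected_distinct, c(0, 5, 5))
  expect_equal(dc$alleles, c(0, 2, 20))

  h_r <- random_histogram(8)
  sizes <- c(10, 100, 1000)
  dc_r <- predict_discovery_curve(h_r, sizes, ploidy = 2)
  expect_equal(dc_r$expected_distinct, expected_unique(h_r, 2 * sizes))
  expect_true(all(diff(dc_r$expected_distinct) >= 0))
})

test_that("partition-family fitting reports zero SD for identical partitions", {
  s <- pointmass_sfs(0.02, 2000, k = 300)
  res <- fit_with_uncertainty(list(s, s, s), cohort_sizes = c(100, 1000),
                              config = fit_config(i_fit = 20))
  expect_equal(res$curve$sd, c(0, 0))
  expect_equal(nrow(res$predictions), 3)
})

test_that("partition-family mean tracks the generating histogram", {
  sc <- sim_scenario("neutral_like", n_variants = 30000, k = 1000, seed = 4)
  h_true <- make_true_histogram(sc)
  co <- sample_cohort(h_true, 1000, seed = 4)
  part <- split_alleles(co, n_groups = 5, seed = 4)
  res <- fit_with_uncertainty(part$sfs_list, cohort_sizes = c(250, 500),
                              ploidy = 2)
  for (r in seq_len(nrow(res$curve))) {
    truth <- expected_unique(h_true, res$curve$alleles[r])
    expect_lt(abs(res$curve$mean[r] - truth), 2 * res$curve$sd[r] + 0.1 * truth)
  }
})
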