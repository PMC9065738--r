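test_that("the Antoniak richness distribution is a proper pmf", {
  expect_equal(antoniak_pmf(5, 1), 1)
  expect_equal(antoniak_pmf(1, 2), c(0.5, 0.5)) # s(2,1)=s(2,2)=1
  # P(S=1) = 1/(theta+1), P(S=2) = theta/(theta+1)
  expect_equal(antoniak_pmf(3, 2), c(1 / 4, 3 / 4))
  for (theta in c(0.1, 1, 10, 100)) {
    for (N in c(1, 2, 10, 50)) {
      expect_equal(sum(antoniak_pmf(theta, N)), 1, tolerance = 1e-10)
    }
  }
  expect_error(antoniak_pmf(0, 5), "theta")
  expect_error(antoniak_pmf(1, 0), "N")
})

test_that("richness is stochastically larger under higher theta", {
  for (N in c(10, 30, 50)) {
    cdf_low <- cumsum(antoniak_pmf(0.5, N))
    cdf_high <- cumsum(antoniak_pmf(20, N))
    expect_true(all(cdf_high <= cdf_low + 1e-12))
  }
})

test_that("the Gibbs fit is reproducible given a seed", {
  meta <- simulate_metacommunity("stick_breaking", 25, 300, seed = 51)
  cm <- simulate_treatment(meta, sim_config(J = 400, m = 0.5, n_sites = 4, seed = 52))
  f1 <- fit_msn(cm, n_gibbs = 400, burn_in = 200, seed = 9)
  f2 <- fit_msn(cm, n_gibbs = 400, burn_in = 200, seed = 9)
  expect_identical(f1$traces$theta, f2$traces$theta)
  expect_identical(f1$traces$I, f2$traces$I)
  expect_equal(sum(f1$beta_post), 1, tolerance = 1e-9)
  expect_length(f1$traces$theta, 200)
  expect_equal(f1$m, f1$I / (f1$I + sample_sizes(cm) - 1), ignore_attr = TRUE)
})

test_that("a single site reproduces the single-sample MLE to within a factor of two", {
  meta <- simulate_metacommunity("stick_breaking", 20, 400, seed = 1)
  sad <- simulate_local_neutral(meta, 800, 0.4, seed = 2)
  counts <- attr(sad, "species_counts")
  cm1 <- community_matrix(matrix(counts, ncol = 1,
    dimnames = list(paste0("sp", seq_along(counts)), "s1")))
  fm <- suppressWarnings(fit_msn(cm1, n_gibbs = 1500, burn_in = 750, seed = 3))
  fh <- fit_hnm(sad)
  expect_lt(abs(log(fm$theta / fh$theta)), log(2))
  expect_lt(abs(log(fm$I / fh$I)), log(2))
})

test_that("P_M and P_L are probabilities, stable under site relabeling", {
  meta <- simulate_metacommunity("stick_breaking", 25, 300, seed = 61)
  cm <- simulate_treatment(meta, sim_config(J = 400, m = 0.5, n_sites = 5, seed = 62))
  fit <- fit_msn(cm, n_gibbs = 800, burn_in = 400, seed = 10)
  tst <- msn_neutrality_test(fit, cm, n_sim = 100, seed = 11)
  expect_true(tst$P_M > 0 && tst$P_M <= 1)
  expect_true(all(tst$P_L > 0 & tst$P_L <= 1))
  expect_error(msn_neutrality_test(fit, cm, n_sim = 5), "n_sim")

  # relabel sites: the test statistic permutes, P_M is unchanged up to
  # simulation noise (the simulation stream is consumed in site order)
  perm <- c(3, 1, 5, 2, 4)
  cmp <- community_matrix(unclass(cm)[, perm])
  fitp <- fit
  fitp$I <- fit$I[perm]
  fitp$m <- fit$m[perm]
  fitp$N <- fit$N[perm]
  tstp <- msn_neutrality_test(fitp, cmp, n_sim = 100, seed = 11)
  expect_lt(abs(tstp$P_M - tst$P_M), 0.2)
  expect_equal(names(tstp$P_L), names(tst$P_L)[perm])
})

test_that("datasets simulated from the fitted model pass the metacommunity test", {
  ok <- 0
  for (r in 1:10) {
    meta <- simulate_metacommunity("stick_breaking", 30, 400, seed = 100 + r)
    cmr <- simulate_treatment(meta, sim_config(J = 500, m = 0.5, n_sites = 5, seed = 200 + r))
    fr <- suppressWarnings(fit_msn(cmr, n_gibbs = 1000, burn_in = 500, seed = 300 + r))
    tr <- msn_neutrality_test(fr, cmr, n_sim = 60, seed = 400 + r)
    ok <- ok + (tr$P_M > 0.05)
  }
  expect_gte(ok, 9)
})

test_that("deterministic identical even sites are rejected at the metacommunity level", {
  m <- matrix(100L, 20, 8, dimnames = list(paste0("sp", 1:20), paste0("s", 1:8)))
  cm <- community_matrix(m)
  fit <- suppressWarnings(fit_msn(cm, n_gibbs = 1000, burn_in = 500, seed = 1))
  tst <- msn_neutrality_test(fit, cm, n_sim = 60, seed = 2)
  expect_lte(tst$P_M, 0.05)
})
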