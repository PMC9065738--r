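test_that("metacommunity profiles are valid probability vectors", {
  even <- simulate_metacommunity("even", s_max = 4)
  expect_equal(even$beta, rep(0.25, 4))

  for (s in 1:5) {
    stick <- simulate_metacommunity("stick_breaking", 20, 500, seed = s)
    logs <- simulate_metacommunity("log_series", 0.95, 200)
    expect_equal(sum(stick$beta), 1, tolerance = 1e-12)
    expect_equal(sum(logs$beta), 1, tolerance = 1e-12)
    expect_true(all(stick$beta >= 0) && all(logs$beta >= 0))
  }
  expect_error(simulate_metacommunity("stick_breaking", 0, 10), "param")
  expect_error(simulate_metacommunity("log_series", 1.2, 10), "param")
})

test_that("higher theta yields more diverse stick-breaking pools", {
  simpson <- function(theta, seed) {
    b <- simulate_metacommunity("stick_breaking", theta, 500, seed = seed)$beta
    1 - sum(b^2)
  }
  d20 <- vapply(1:200, function(s) simpson(20, s), numeric(1))
  d2 <- vapply(1:200, function(s) simpson(2, 10000 + s), numeric(1))
  expect_lt(t.test(d20, d2, alternative = "greater")$p.value, 0.01)
})

test_that("every simulated SAD conserves J exactly, for all dynamics", {
  meta <- simulate_metacommunity("stick_breaking", 10, 200, seed = 1)
  grid <- expand.grid(J = c(1, 50, 500), m = c(0.05, 0.5, 1))
  for (r in seq_len(nrow(grid))) {
    J <- grid$J[r]
    m <- grid$m[r]
    expect_equal(simulate_local_neutral(meta, J, m, seed = r)$J, J)
    expect_equal(simulate_local_if(meta, J, m, cv = 2, seed = r)$J, J)
    expect_equal(simulate_local_pc(meta, J, m, epsilon = 0.7, seed = r)$J, J)
  }
})

test_that("fixed seeds give identical output; zero effect reduces to the neutral urn bit for bit", {
  meta <- simulate_metacommunity("stick_breaking", 15, 300, seed = 2)
  a <- simulate_local_neutral(meta, 400, 0.4, seed = 7)
  b <- simulate_local_neutral(meta, 400, 0.4, seed = 7)
  expect_identical(attr(a, "species_counts"), attr(b, "species_counts"))

  if0 <- simulate_local_if(meta, 400, 0.4, cv = 0, seed = 7)
  pc0 <- simulate_local_pc(meta, 400, 0.4, epsilon = 0, seed = 7)
  expect_identical(attr(if0, "species_counts"), attr(a, "species_counts"))
  expect_identical(attr(pc0, "species_counts"), attr(a, "species_counts"))

  expect_error(simulate_local_neutral(meta, 400, 0), "m")
  expect_error(simulate_local_if(meta, 400, 0.4, cv = -1), "cv")
  expect_error(simulate_local_pc(meta, 400, 0.4, epsilon = 1.2), "epsilon")
})

test_that("m = 1 reduces to multinomial sampling from the metacommunity", {
  meta <- simulate_metacommunity("even", s_max = 20)
  expected <- rep(1000 / 20, 20)
  pvals <- vapply(1:500, function(s) {
    counts <- attr(simulate_local_neutral(meta, 1000, 1, seed = s), "species_counts")
    suppressWarnings(stats::chisq.test(counts, p = meta$beta)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.98)
})

test_that("vanishing migration produces monodominance", {
  meta <- simulate_metacommunity("stick_breaking", 20, 300, seed = 4)
  rich <- vapply(1:100, function(s) {
    simulate_local_neutral(meta, 1000, 1e-6, seed = s)$S
  }, numeric(1))
  expect_lt(mean(rich), 2)
})

test_that("fitness variation raises dominance; density dependence raises evenness", {
  meta <- simulate_metacommunity("stick_breaking", 20, 300, seed = 6)
  bp <- function(sad) max(sad$abundances) / sad$J
  bp_if <- vapply(1:200, function(s) bp(simulate_local_if(meta, 2000, 0.3, cv = 2, seed = s)), numeric(1))
  bp_0 <- vapply(1:200, function(s) bp(simulate_local_if(meta, 2000, 0.3, cv = 0, seed = s)), numeric(1))
  expect_gt(mean(bp_if), mean(bp_0))

  ev_pc <- vapply(1:200, function(s) {
    shannon_evenness(simulate_local_pc(meta, 2000, 0.3, epsilon = 0.8, seed = 5000 + s)$abundances)
  }, numeric(1))
  ev_0 <- vapply(1:200, function(s) {
    shannon_evenness(simulate_local_pc(meta, 2000, 0.3, epsilon = 0, seed = 5000 + s)$abundances)
  }, numeric(1))
  expect_gt(mean(ev_pc), mean(ev_0))
})

test_that("treatment simulation yields reproducible multi-site tables", {
  meta <- simulate_metacommunity("stick_breaking", 12, 250, seed = 9)
  cfg <- sim_config(J = 300, m = 0.6, n_sites = 3, seed = 21)
  cm1 <- simulate_treatment(meta, cfg)
  cm2 <- simulate_treatment(meta, cfg)
  expect_identical(unclass(cm1), unclass(cm2))
  expect_equal(unname(sample_sizes(cm1)), rep(300, 3))
  expect_lte(nrow(cm1), 250)

  cmi <- simulate_treatment(meta, sim_config(J = 300, m = 0.6, n_sites = 4,
                                             effect = 2, seed = 3), "IF")
  expect_equal(unname(sample_sizes(cmi)), rep(300, 4))
})
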