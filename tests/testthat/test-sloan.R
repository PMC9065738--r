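test_that("transition probabilities obey the boundary and normalization identities", {
  expect_equal(sloan_transition_probs(0, 10, 0.5, 0.2)$p_down, 0)
  expect_equal(sloan_transition_probs(10, 10, 0.5, 0.2)$p_up, 0)

  # hand evaluation at N_T = 10, N_i = 5, m = 0.5, p_i = 0.2
  tp <- sloan_transition_probs(5, 10, 0.5, 0.2)
  expect_equal(tp$p_up, 0.5 * (0.5 * 0.2 + 0.5 * 5 / 9))
  expect_equal(tp$p_down, 0.5 * (0.5 * 0.8 + 0.5 * 5 / 9))
  expect_equal(tp$p_up + tp$p_down + tp$p_stay, 1)

  grid <- expand.grid(N_i = 0:20, m = c(0, 0.3, 1), p = c(0, 0.4, 1))
  tp <- sloan_transition_probs(grid$N_i, 20, 0.5, grid$p)
  expect_true(all(abs(tp$p_up + tp$p_down + tp$p_stay - 1) <= 1e-12))
  expect_true(all(tp$p_up >= 0 & tp$p_down >= 0 & tp$p_stay >= 0))
  expect_error(sloan_transition_probs(-1, 10, 0.5, 0.2), "N_i")
  expect_error(sloan_transition_probs(5, 10, 1.5, 0.2), "m")
})

sloan_fixture <- function(m, N_T, n_samp, seed, s_pool = 300) {
  untbx:::with_seed(seed, {
    p <- simulate_metacommunity("log_series", 0.99, s_pool)$beta
    x <- matrix(rbeta(s_pool * n_samp, N_T * m * p, N_T * m * (1 - p)),
                s_pool, n_samp)
    cnt <- round(x * N_T)
    dimnames(cnt) <- list(paste0("sp", seq_len(s_pool)), paste0("s", seq_len(n_samp)))
    src <- matrix(round(p * 1e6), s_pool, 6,
                  dimnames = list(paste0("sp", seq_len(s_pool)), paste0("src", 1:6)))
    list(source = community_matrix(src), dest = community_matrix(cnt), p = p)
  })
}

test_that("migration is recovered from data drawn at known m", {
  hits <- 0
  for (r in 1:5) {
    fx <- sloan_fixture(m = 0.3, N_T = 1e4, n_samp = 30, seed = 700 + r)
    m_hat <- fit_sloan(fx$source, fx$dest)$m
    hits <- hits + (m_hat >= 0.2 && m_hat <= 0.45)
  }
  expect_gte(hits, 4)
})

test_that("the fit is invariant to species relabeling and survives degenerate input", {
  fx <- sloan_fixture(m = 0.3, N_T = 1e4, n_samp = 20, seed = 77)
  f1 <- fit_sloan(fx$source, fx$dest)
  perm <- untbx:::with_seed(1, sample(nrow(fx$source)))
  f2 <- fit_sloan(
    community_matrix(unclass(fx$source)[perm, ]),
    community_matrix(unclass(fx$dest)[perm, ])
  )
  expect_equal(f1$m, f2$m)
  expect_equal(f1$r_squared, f2$r_squared)

  # identical deterministic copies: a legal degenerate case, must not crash
  one <- unclass(fx$dest)[, 1]
  cm <- community_matrix(matrix(one, length(one), 6,
    dimnames = list(rownames(fx$dest), paste0("c", 1:6))))
  fd <- suppressMessages(fit_sloan(cm, cm))
  expect_true(is.numeric(fd$m) && fd$m > 0)
  expect_true(is.numeric(fd$r_squared))

  expect_error(fit_sloan(fx$source, community_matrix(unclass(fx$dest)[, 1:3])),
               "5 samples")
})

test_that("classification matches the interval definition and covers ~95% under the true model", {
  mod <- sloan_model(m = 0.3, N_T = 1e4)
  p <- c(0.01, 0.05, 0.2)
  sh_a <- 1e4 * 0.3 * p
  sh_b <- 1e4 * 0.3 * (1 - p)
  at_median <- qbeta(0.5, sh_a, sh_b)
  cls <- classify_species(mod, p = p, x = at_median)
  expect_true(all(cls$label == "neutral"))
  above <- qbeta(0.99, sh_a, sh_b)
  cls2 <- classify_species(mod, p = p, x = above)
  expect_true(all(cls2$label == "above_neutral"))
  below <- qbeta(0.001, sh_a, sh_b)
  expect_true(all(classify_species(mod, p = p, x = below)$label == "below_neutral"))

  # fractions sum to one over classified species
  fr <- classification_fractions(cls2)
  expect_equal(fr$frac_below + fr$frac_neutral + fr$frac_above, 1)

  # p = 0 or 1 excluded with a message
  expect_message(
    cl3 <- classify_species(mod, p = c(0, 0.1, 1), x = c(0, 0.1, 1)),
    "excluded"
  )
  expect_equal(nrow(cl3), 1)

  # empirical coverage of the 95% interval under self-generated data
  fx <- untbx:::with_seed(99, {
    pp <- simulate_metacommunity("log_series", 0.99, 300)$beta
    xx <- rbeta(300, 1e4 * 0.3 * pp, 1e4 * 0.3 * (1 - pp))
    list(p = pp, x = xx)
  })
  cov <- classify_species(mod, p = fx$p, x = fx$x)
  frac_neutral <- mean(cov$label == "neutral")
  expect_gte(frac_neutral, qbinom(0.025, 300, 0.95) / 300)
  expect_lte(frac_neutral, qbinom(0.975, 300, 0.95) / 300)
})

test_that("the same-set scheme classifies more species neutral than a disjoint pair", {
  # destination drawn at m = 0.3 around pool A; source = a different draw
  # (partial overlap through the shared pool), vs source = destination itself
  fx <- sloan_fixture(m = 0.3, N_T = 1e4, n_samp = 20, seed = 311)
  fx2 <- sloan_fixture(m = 0.05, N_T = 1e4, n_samp = 20, seed = 312)
  cross <- classify_species(fit_sloan(fx2$dest, fx$dest))
  same <- classify_species(fit_sloan(fx$dest, fx$dest))
  expect_gte(
    classification_fractions(same)$frac_neutral,
    classification_fractions(cross)$frac_neutral
  )
})
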