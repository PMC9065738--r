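test_that("Ruzicka similarity matches its definition and limiting cases", {
  expect_equal(ruzicka_similarity(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 1 / 3)
  p <- c(0.2, 0.3, 0.5)
  expect_equal(ruzicka_similarity(p, p), 1)
  expect_equal(ruzicka_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(ruzicka_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_error(ruzicka_similarity(c(1, 0), c(1, 0, 0)), "length")

  # symmetry, bounds, Jaccard reduction on binary vectors
  set.seed(2)
  for (r in 1:20) {
    a <- runif(10)
    b <- runif(10) * rbinom(10, 1, 0.6)
    expect_equal(ruzicka_similarity(a, b), ruzicka_similarity(b, a))
    s <- ruzicka_similarity(a, b)
    expect_true(s >= 0 && s <= 1)
    ab <- as.numeric(a > 0.5)
    bb <- as.numeric(b > 0.3)
    if (sum(pmax(ab, bb)) > 0) {
      jac <- sum(ab & bb) / sum(ab | bb)
      expect_equal(ruzicka_similarity(ab, bb), jac)
    }
  }
})

test_that("the identity null reproduces the observed similarities exactly", {
  cm <- random_cm(n_otu = 30, n_samp = 6, seed = 21)
  rel <- to_relative_abundance(cm)
  C <- untbx:::pairwise_ruzicka(rel)
  E <- null_expected_similarity(cm, n_null = 5, null_algorithm = "identity", seed = 1)
  expect_equal(E, C)
  E1 <- null_expected_similarity(cm, n_null = 20, seed = 3)
  E2 <- null_expected_similarity(cm, n_null = 20, seed = 3)
  expect_identical(E1, E2)
  expect_true(all(E1 >= 0 & E1 <= 1))
})

test_that("null randomizations preserve per-sample richness", {
  cm <- random_cm(n_otu = 40, n_samp = 8, lambda = 1, seed = 31)
  rel <- to_relative_abundance(cm)
  for (alg in c("proportional_frequency", "richness_uniform")) {
    rnd <- null_randomize(cm, alg, seed = 5)
    expect_equal(colSums(rnd > 0), colSums(rel > 0), ignore_attr = TRUE)
    expect_equal(unname(colSums(rnd)), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("the stochasticity ratio follows the per-pair definitions", {
  # single pair, observed more similar than null: SR = E / C
  C <- matrix(c(1, 1, 1, 1), 2)
  E <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_equal(stochasticity_ratio(C, E)$SR, 0.2)
  # single pair, observed less similar: SR = (1 - E)/(1 - C)
  C2 <- matrix(c(1, 0.1, 0.1, 1), 2)
  E2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(stochasticity_ratio(C2, E2)$SR, 0.5 / 0.9)
  # ties excluded; all-tie case defined as 1 with a warning
  expect_warning(sr <- stochasticity_ratio(C, C)$SR, "tied")
  expect_equal(suppressWarnings(stochasticity_ratio(C, C)$SR), 1)

  # mixed pairs
  C3 <- matrix(0.5, 3, 3)
  C3[1, 2] <- C3[2, 1] <- 0.8
  C3[1, 3] <- C3[3, 1] <- 0.2
  C3[2, 3] <- C3[3, 2] <- 0.45
  E3 <- matrix(0.4, 3, 3)
  diag(C3) <- diag(E3) <- 1
  out <- stochasticity_ratio(C3, E3)
  expect_equal(out$n_A, 2)
  expect_equal(out$n_B, 1)
  expect_equal(out$SR, mean(c(0.4 / 0.8, 0.4 / 0.45, (1 - 0.4) / (1 - 0.2))))

  # an exact tie contributes to neither pair type
  C3[2, 3] <- C3[3, 2] <- 0.4
  out_tie <- stochasticity_ratio(C3, E3)
  expect_equal(out_tie$n_A + out_tie$n_B, 2)
  expect_equal(out_tie$SR, mean(c(0.4 / 0.8, (1 - 0.4) / (1 - 0.2))))
})

test_that("SR is invariant to sample reordering", {
  cm <- random_cm(n_otu = 50, n_samp = 7, seed = 41)
  res <- nsr(cm, n_null = 50, seed = 13)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  res2 <- nsr(community_matrix(unclass(cm)[, perm]), n_null = 50, seed = 13)
  expect_equal(res2$SR, res$SR, tolerance = 0.1)
  expect_equal(res2$C, res$C[perm, perm], ignore_attr = TRUE)
})

test_that("NSR realizes its anchors and stays in [0, 1]", {
  # null-coincident configuration: SR = 1 and NSR = 1
  C <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(suppressWarnings(normalized_sr(C, C)), 1)
  Ceps <- C
  Ceps[1, 2] <- Ceps[2, 1] <- 0.6 + 1e-9
  expect_equal(normalized_sr(Ceps, C), 1, tolerance = 1e-6)

  # engineered deterministic limit: identical single-species samples with a
  # richness-preserving uniform null over a 1000-species pool
  det <- matrix(0, 1000, 20)
  det[1, ] <- 1000
  rownames(det) <- paste0("sp", 1:1000)
  colnames(det) <- paste0("s", 1:20)
  res <- nsr(det, n_null = 200, null_algorithm = "richness_uniform", seed = 3)
  expect_lt(res$SR, 0.01)
  expect_lt(res$NSR, 0.01)

  # random matrices: clipping contract
  set.seed(77)
  for (r in 1:25) {
    n <- sample(3:8, 1)
    C <- matrix(runif(n * n), n)
    C <- (C + t(C)) / 2
    E <- matrix(runif(n * n), n)
    E <- (E + t(E)) / 2
    diag(C) <- diag(E) <- 1
    v <- suppressWarnings(normalized_sr(C, E))
    expect_true(v >= 0 && v <= 1)
    sr <- suppressWarnings(stochasticity_ratio(C, E)$SR)
    expect_true(sr >= 0 && sr <= 1)
  }
})

test_that("data generated by the null process itself scores as stochastic", {
  srs <- vapply(1:8, function(r) {
    tmpl <- random_cm(n_otu = 200, n_samp = 15, lambda = 2, seed = 500 + r)
    obs <- null_randomize(tmpl, "proportional_frequency", seed = 600 + r)
    nsr(obs, n_null = 100, seed = 700 + r)$SR
  }, numeric(1))
  expect_gte(mean(srs), 0.9)
})
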