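# ---------------------------------------------------------------------------
# Multi-site neutral model as a hierarchical Dirichlet process (HDP):
# Gibbs fit of theta and per-site immigration numbers, and the P_M / P_L
# neutrality tests.
# ---------------------------------------------------------------------------

#' Antoniak distribution of species richness under a Dirichlet process
#'
#' Probability of observing `S` distinct species after `N` draws from a
#' Dirichlet process with concentration theta:
#' `P(S | theta, N) = s(N, S) theta^S Gamma(theta) / Gamma(theta + N)`,
#' with `s(N, S)` the unsigned Stirling numbers of the first kind, computed
#' by recurrence in log space.
#'
#' @param theta Concentration / biodiversity number (> 0).
#' @param N Number of draws (positive integer).
#' @return Probability vector over `S = 1..N` (sums to 1).
#' @examples
#' antoniak_pmf(1, 2) # (1/2, 1/2)
#' @export
antoniak_pmf <- function(theta, N) {
  check_scalar(theta, "theta", lower = 0, open_lower = TRUE)
  check_scalar(N, "N", lower = 1)
  N <- as.integer(N)
  ls <- stirling_log_row_cpp(N)
  logp <- ls + seq_len(N) * log(theta) + lgamma(theta) - lgamma(theta + N)
  exp(logp)
}

# split-half potential scale reduction factor on one chain
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  ch <- cbind(x[seq_len(half)], x[(n - half + 1):n])
  mns <- colMeans(ch)
  vars <- apply(ch, 2, var)
  W <- mean(vars)
  B <- half * var(mns)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit the multi-site neutral model by Gibbs sampling
#'
#' Hierarchical Dirichlet-process representation of Hubbell's model across
#' sites: the metacommunity profile follows a stick-breaking process at rate
#' theta, and each site's composition is a Dirichlet process draw around it
#' at its own immigration number `I_i`. The sampler works in the Chinese
#' restaurant franchise representation: per site and species it samples
#' ancestral-lineage ("table") counts as sums of Bernoulli indicators, then
#' theta given the total table count (auxiliary-variable step, vague
#' Gamma(1, 0.1) prior), each `I_i` by slice sampling on `log I` (log-uniform
#' prior on \[1e-2, 1e6\]), and the metacommunity profile from its Dirichlet
#' conditional.
#'
#' @param cm A [community_matrix()] whose columns are the sites of one
#'   metacommunity (a single site is allowed and reduces to the one-site
#'   model).
#' @param n_gibbs Total Gibbs iterations (default 5000).
#' @param burn_in Burn-in iterations discarded from summaries (default 2500).
#' @param seed Optional integer seed (local to this call).
#' @return An object of class `msn_fit`: posterior means `theta`, `I`, `m`
#'   (via `I_i = m_i / (1 - m_i) (N_i - 1)`), `beta_post` (posterior-mean
#'   metacommunity relative abundances over observed species, summing to 1),
#'   per-parameter `traces`, the split-chain `rhat_log_theta`, and a
#'   `convergence_warning` flag (R-hat > 1.2 warns but never errors).
#' @export
fit_msn <- function(cm, n_gibbs = 5000, burn_in = 2500, seed = NULL) {
  cm <- as_count_matrix(cm)
  check_scalar(n_gibbs, "n_gibbs", lower = 2)
  check_scalar(burn_in, "burn_in", lower = 1)
  if (burn_in >= n_gibbs) abort("`n_gibbs` must exceed `burn_in`.")
  counts <- unclass(cm)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  N <- colSums(counts)
  if (any(N == 0)) abort("every site needs a positive total.")
  res <- with_seed(seed, {
    msn_gibbs_cpp(
      counts, as.integer(n_gibbs), as.integer(burn_in),
      1.0, 0.1, log(1e-2), log(1e6),
      theta0 = 10, I0 = rep(10, ncol(counts))
    )
  })
  theta_chain <- res$theta_chain
  I_chain <- res$I_chain
  colnames(I_chain) <- colnames(counts)
  I_hat <- colMeans(I_chain)
  rhat <- split_rhat(log(theta_chain))
  conv_warn <- is.finite(rhat) && rhat > 1.2
  if (conv_warn) {
    warn(sprintf("Gibbs chain for log(theta) may not have converged (split R-hat = %.3f).", rhat))
  }
  beta_post <- as.numeric(res$beta_post)
  names(beta_post) <- rownames(counts)
  structure(
    list(
      theta = mean(theta_chain),
      I = I_hat,
      m = I_hat / (I_hat + N - 1),
      beta_post = beta_post / sum(beta_post),
      traces = list(theta = theta_chain, I = I_chain),
      n_gibbs = as.integer(n_gibbs),
      burn_in = as.integer(burn_in),
      seed = seed,
      rhat_log_theta = rhat,
      convergence_warning = conv_warn,
      N = N,
      sample_ids = colnames(counts)
    ),
    class = "msn_fit"
  )
}

#' @export
print.msn_fit <- function(x, ...) {
  cat(sprintf(
    "<msn_fit> %d sites, posterior-mean theta = %.4g (R-hat %.3f)%s\n",
    length(x$I), x$theta, x$rhat_log_theta,
    if (x$convergence_warning) " [convergence warning]" else ""
  ))
  cat("per-site immigration numbers I:",
      paste(signif(head(x$I, 8), 4), collapse = " "),
      if (length(x$I) > 8) "..." else "", "\n")
  invisible(x)
}

# joint test statistic: sum over sites of the Etienne log-likelihood at the
# posterior-mean (theta, I_i). Label-free, so observed and simulated
# metacommunities are scored identically.
msn_site_logliks <- function(count_mat, theta, I) {
  vapply(seq_len(ncol(count_mat)), function(i) {
    x <- count_mat[, i]
    neutral_loglik(sad_sample(x[x > 0]), theta, I[i])
  }, numeric(1))
}

#' Metacommunity and local neutrality tests under the multi-site model
#'
#' Simulates `n_sim` complete metacommunity datasets from the fitted model
#' (a stick-breaking profile at the posterior-mean theta truncated at
#' `S_obs + s_extra` classes, then per-site Dirichlet-multinomial draws at
#' the posterior-mean `I_i`) and compares log-likelihoods. The joint
#' statistic is the sum over sites of the Etienne sampling-formula
#' log-likelihood at the posterior means. `P_M` is the smoothed proportion
#' of simulated datasets whose joint likelihood does not exceed the observed
#' one; `P_L` is the per-site analogue. Values above 0.05 mean the
#' metacommunity (resp. site) is consistent with the neutral model.
#'
#' @param fit An [fit_msn()] result.
#' @param cm The [community_matrix()] the model was fitted to.
#' @param n_sim Number of simulated datasets (>= 20; default 500).
#' @param seed Optional integer seed (local to this call).
#' @param s_extra Stick-breaking truncation margin beyond the observed
#'   richness (default 200).
#' @return An object of class `msn_test` with `P_M`, `P_L` (named per-site
#'   vector) and `n_sim`.
#' @export
msn_neutrality_test <- function(fit, cm, n_sim = 500, seed = NULL, s_extra = 200) {
  stopifnot(inherits(fit, "msn_fit"))
  cm <- as_count_matrix(cm)
  check_scalar(n_sim, "n_sim", lower = 20)
  n_sim <- as.integer(n_sim)
  counts <- unclass(cm)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  M <- ncol(counts)
  N <- colSums(counts)
  S_obs <- nrow(counts)
  with_seed(seed, {
    obs_site <- msn_site_logliks(counts, fit$theta, fit$I)
    obs_joint <- sum(obs_site)
    K <- S_obs + as.integer(s_extra)
    sim_site <- matrix(NA_real_, n_sim, M)
    for (r in seq_len(n_sim)) {
      v <- rbeta(K, 1, fit$theta)
      beta_star <- v * cumprod(c(1, 1 - v[-K]))
      beta_star <- beta_star / sum(beta_star)
      for (i in seq_len(M)) {
        g <- rgamma(K, shape = fit$I[i] * beta_star, rate = 1)
        if (sum(g) <= 0) g[which.max(beta_star)] <- 1
        x <- as.integer(rmultinom(1, N[i], g / sum(g)))
        sim_site[r, i] <- neutral_loglik(sad_sample(x[x > 0]), fit$theta, fit$I[i])
      }
    }
    sim_joint <- rowSums(sim_site)
    P_M <- (1 + sum(sim_joint <= obs_joint)) / (1 + n_sim)
    P_L <- vapply(seq_len(M), function(i) {
      (1 + sum(sim_site[, i] <= obs_site[i])) / (1 + n_sim)
    }, numeric(1))
    names(P_L) <- colnames(counts)
    structure(
      list(P_M = P_M, P_L = P_L, n_sim = n_sim,
           observed_joint_loglik = obs_joint),
      class = "msn_test"
    )
  })
}

#' @export
print.msn_test <- function(x, ...) {
  cat(sprintf("<msn_test> P_M = %.4f (n_sim = %d)\n", x$P_M, x$n_sim))
  cat("P_L:", paste(sprintf("%s = %.3f", names(x$P_L), x$P_L), collapse = ", "), "\n")
  invisible(x)
}
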