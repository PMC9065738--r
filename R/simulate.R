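#' Simulate a metacommunity relative-abundance profile
#'
#' Three regional species pools are available: `stick_breaking` draws stick
#' fractions from Beta(1, theta) — the neutral metacommunity at biodiversity
#' number theta, truncated at `s_max` classes and renormalized;
#' `log_series` sets abundances proportional to `x^k / k` over ranks
#' `k = 1..s_max` (shape `param` = x in (0, 1)); `even` gives all species
#' equal abundance 1/s_max.
#'
#' @param model One of `"stick_breaking"`, `"log_series"`, `"even"`.
#' @param param Positive shape parameter: theta for stick breaking, x in
#'   (0, 1) for the log-series. Ignored for `even`.
#' @param s_max Number of species classes in the truncated pool.
#' @param seed Optional integer seed (local to this call).
#' @return An object of class `metacommunity_profile` with fields `beta`
#'   (relative abundances summing to 1), `model`, `param`.
#' @export
simulate_metacommunity <- function(model = c("stick_breaking", "log_series", "even"),
                                   param = NULL, s_max, seed = NULL) {
  model <- match.arg(model)
  check_scalar(s_max, "s_max", lower = 1)
  s_max <- as.integer(s_max)
  beta <- switch(model,
    stick_breaking = {
      check_scalar(param, "param", lower = 0, open_lower = TRUE)
      with_seed(seed, {
        v <- rbeta(s_max, 1, param)
        b <- v * cumprod(c(1, 1 - v[-s_max]))
        b / sum(b)
      })
    },
    log_series = {
      check_scalar(param, "param", lower = 0, upper = 1,
                   open_lower = TRUE, open_upper = TRUE)
      k <- seq_len(s_max)
      b <- exp(k * log(param) - log(k))
      b / sum(b)
    },
    even = rep(1 / s_max, s_max)
  )
  structure(
    list(beta = beta, model = model, param = if (model == "even") NULL else param),
    class = "metacommunity_profile"
  )
}

#' @export
print.metacommunity_profile <- function(x, ...) {
  cat(sprintf(
    "<metacommunity_profile> model = %s, %d species classes%s\n",
    x$model, length(x$beta),
    if (is.null(x$param)) "" else sprintf(", param = %g", x$param)
  ))
  invisible(x)
}

as_meta <- function(meta) {
  if (inherits(meta, "metacommunity_profile")) return(meta)
  if (is.numeric(meta) && all(meta >= 0) && abs(sum(meta) - 1) < 1e-8) {
    return(structure(list(beta = meta, model = "custom", param = NULL),
                     class = "metacommunity_profile"))
  }
  abort("expected a metacommunity_profile or a probability vector.")
}

# shared urn front-end; returns the full per-class count vector
local_counts <- function(meta, J, m, fec = NULL, eps = 0) {
  meta <- as_meta(meta)
  check_scalar(J, "J", lower = 1)
  check_scalar(m, "m", lower = 0, upper = 1, open_lower = TRUE)
  if (is.null(fec)) fec <- rep(1, length(meta$beta))
  urn_sample_cpp(meta$beta, as.integer(J), m, fec, eps)
}

counts_to_sad <- function(counts) {
  sad <- sad_sample(counts[counts > 0])
  attr(sad, "species_counts") <- counts
  sad
}

#' Simulate one local community under neutral assembly
#'
#' Hubbell urn scheme: with immigration number `I = m (J - 1) / (1 - m)`
#' (infinite when `m = 1`), the (n+1)-th individual is an immigrant drawn
#' from the metacommunity with probability `I / (I + n)`, otherwise a copy
#' of a uniformly chosen prior individual.
#'
#' @param meta A [simulate_metacommunity()] profile (or probability vector).
#' @param J Local community size (total individuals).
#' @param m Migration probability in (0, 1].
#' @param seed Optional integer seed (local to this call).
#' @return A [sad_sample()]; the full per-class count vector is attached as
#'   attribute `species_counts`.
#' @export
simulate_local_neutral <- function(meta, J, m, seed = NULL) {
  with_seed(seed, counts_to_sad(local_counts(meta, J, m)))
}

#' Simulate a local community with intrinsic fitness differences (IF model)
#'
#' Non-neutral generator: each species carries a fecundity drawn once from a
#' Gamma distribution with mean 1 and coefficient of variation `cv`.
#' Fecundities multiply both the immigration weights (`beta_k * f_k`,
#' renormalized) and the local reproduction weights (`N_k * f_k`). At
#' `cv = 0` all fecundities are 1 and the generator is bit-identical to
#' [simulate_local_neutral()] for the same seed.
#'
#' @inheritParams simulate_local_neutral
#' @param cv Coefficient of variation of species fecundities (effect size,
#'   >= 0; 0 is exactly neutral).
#' @param fecundity Optional pre-drawn fecundity vector (one value per
#'   species class), used when several sites must share one draw.
#' @return A [sad_sample()].
#' @export
simulate_local_if <- function(meta, J, m, cv, seed = NULL, fecundity = NULL) {
  check_scalar(cv, "cv", lower = 0)
  meta <- as_meta(meta)
  with_seed(seed, {
    fec <- if (cv == 0) {
      NULL
    } else if (!is.null(fecundity)) {
      fecundity
    } else {
      rgamma(length(meta$beta), shape = 1 / cv^2, rate = 1 / cv^2)
    }
    counts_to_sad(local_counts(meta, J, m, fec = fec))
  })
}

#' Simulate a local community with density-dependent dynamics (PC model)
#'
#' Non-neutral generator with rare-species advantage: the local-copy step of
#' the urn picks species `k` with probability proportional to
#' `N_k^(1 - epsilon)`. At `epsilon = 0` the generator is bit-identical to
#' [simulate_local_neutral()] for the same seed.
#'
#' @inheritParams simulate_local_neutral
#' @param epsilon Density-dependence strength in \[0, 1\] (effect size; 0 is
#'   exactly neutral).
#' @return A [sad_sample()].
#' @export
simulate_local_pc <- function(meta, J, m, epsilon, seed = NULL) {
  check_scalar(epsilon, "epsilon", lower = 0, upper = 1)
  with_seed(seed, counts_to_sad(local_counts(meta, J, m, eps = epsilon)))
}

#' Simulation configuration for a multi-site treatment
#'
#' @param J Local community size per site.
#' @param m Migration probability in (0, 1].
#' @param n_sites Number of sites (samples).
#' @param effect Non-neutral control parameter (cv for IF, epsilon for PC);
#'   0 means neutral dynamics.
#' @param seed Optional integer seed; a fixed seed makes
#'   [simulate_treatment()] byte-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(J, m, n_sites = 1, effect = 0, seed = NULL) {
  check_scalar(J, "J", lower = 1)
  check_scalar(m, "m", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(n_sites, "n_sites", lower = 1)
  check_scalar(effect, "effect", lower = 0)
  structure(
    list(J = as.integer(J), m = m, n_sites = as.integer(n_sites),
         effect = effect, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a multi-site OTU table from one metacommunity
#'
#' Runs `n_sites` independent local simulations against a shared
#' metacommunity profile and assembles the resulting counts into a
#' [community_matrix()]. Sites are drawn sequentially from a single RNG
#' stream seeded by `config$seed`, so a fixed seed gives byte-identical
#' output. For the IF model the species fecundities are drawn once per
#' treatment and shared by all sites.
#'
#' @param meta A [simulate_metacommunity()] profile.
#' @param config A [sim_config()].
#' @param model Local dynamics: `"neutral"`, `"IF"` or `"PC"`.
#' @return A [community_matrix()] with `n_sites` columns, each summing to
#'   `config$J`; all-zero OTU rows are dropped.
#' @export
simulate_treatment <- function(meta, config, model = c("neutral", "IF", "PC")) {
  model <- match.arg(model)
  meta <- as_meta(meta)
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fec <- NULL
    if (model == "IF" && config$effect > 0) {
      fec <- rgamma(length(meta$beta),
        shape = 1 / config$effect^2, rate = 1 / config$effect^2
      )
    }
    cols <- lapply(seq_len(config$n_sites), function(i) {
      switch(model,
        neutral = local_counts(meta, config$J, config$m),
        IF = local_counts(meta, config$J, config$m, fec = fec),
        PC = local_counts(meta, config$J, config$m, eps = config$effect)
      )
    })
    mat <- do.call(cbind, cols)
    rownames(mat) <- sprintf("OTU_%04d", seq_len(nrow(mat)))
    colnames(mat) <- sprintf("sample_%03d", seq_len(ncol(mat)))
    mat <- mat[rowSums(mat) > 0, , drop = FALSE]
    community_matrix(mat)
  })
}
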