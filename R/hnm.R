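# ---------------------------------------------------------------------------
# Hubbell standard neutral model: Etienne sampling-formula likelihood,
# maximum-likelihood fit, and the pseudo-P exact neutrality test.
# ---------------------------------------------------------------------------

# combinatorial constant log J! - sum log n_i - sum log Phi_j!
sad_constant <- function(sad) {
  phi <- table(sad$abundances)
  lgamma(sad$J + 1) - sum(log(sad$abundances)) - sum(lgamma(as.numeric(phi) + 1))
}

sad_logK <- function(sad) {
  lk <- attr(sad, "etienne_logK")
  if (is.null(lk)) lk <- etienne_logK_cpp(sad$abundances)
  lk
}

# attach the (expensive) K(D, A) coefficients so repeated evaluations reuse them
with_logK <- function(sad) {
  if (is.null(attr(sad, "etienne_logK"))) {
    attr(sad, "etienne_logK") <- etienne_logK_cpp(sad$abundances)
  }
  sad
}

#' Etienne sampling-formula log-likelihood
#'
#' Log-probability of an observed species abundance configuration under
#' Hubbell's neutral model with biodiversity number `theta` and immigration
#' number `I`, computed entirely in log space via the K(D, A) coefficient
#' recursion (unsigned Stirling numbers of the first kind), so no linear-space
#' overflow is possible.
#'
#' @param sad A [sad_sample()] or positive abundance vector.
#' @param theta Fundamental biodiversity number (> 0).
#' @param I Immigration number (> 0); `I = m (J - 1) / (1 - m)`.
#' @return The log-likelihood (a single non-positive number).
#' @examples
#' neutral_loglik(sad_sample(c(5, 3, 1)), theta = 10, I = 5)
#' @export
neutral_loglik <- function(sad, theta, I) {
  sad <- as_sad(sad)
  check_scalar(theta, "theta", lower = 0, open_lower = TRUE)
  check_scalar(I, "I", lower = 0, open_lower = TRUE)
  etienne_loglik_cpp(sad_logK(sad), sad$S, sad$J, sad_constant(sad), theta, I)
}

hnm_bounds <- list(
  log_theta = log(c(1e-3, 1e5)),
  logit_m = qlogis(c(1e-6, 1 - 1e-6))
)

# Ewens maximum-likelihood theta given richness S and size J: the unique
# root of sum_{i=0}^{J-1} theta/(theta + i) = S. The standard data-driven
# starting point for fitting the full sampling formula.
theta_ewens <- function(S, J) {
  if (S >= J) return(1e5)
  if (S <= 1) return(1e-3)
  f <- function(th) sum(th / (th + 0:(J - 1))) - S
  tryCatch(uniroot(f, c(1e-3, 1e5), tol = 1e-8)$root, error = function(e) 1)
}

# default start: Ewens theta estimate with m = 0.5
hnm_default_starts <- function(sad) {
  matrix(c(log(theta_ewens(sad$S, sad$J)), qlogis(0.5)), 1,
    dimnames = list(NULL, c("log_theta", "logit_m"))
  )
}

# the optional coarse grid of starts for a global search
hnm_start_grid <- function() {
  as.matrix(expand.grid(
    log_theta = log(c(1, 20, 400)),
    logit_m = qlogis(c(0.1, 0.5, 0.9))
  ))
}

#' Fit Hubbell's neutral model to one sample by maximum likelihood
#'
#' Maximizes the Etienne sampling-formula likelihood over
#' `(log theta, logit m)` by bounded quasi-Newton optimization, started from
#' the Ewens estimate of theta (the classic data-driven initial value) with
#' `m = 0.5` — the convention of established neutral-fitting software, and
#' deterministic. The sampling-formula surface is famously ridged, with a
#' second local optimum at high theta and very low m whose likelihood is
#' often within a log-unit of the first; an exhaustive multi-start search
#' (pass `starts = untbx:::hnm_start_grid()`) frequently lands there, so the
#' local Ewens-anchored convention is the default. Degenerate SADs — a
#' single species, or all singletons (`J = S`, where the theta MLE
#' diverges) — are fitted against the box bounds and flagged as boundary
#' fits with a warning; theta is capped at 1e5.
#'
#' @param sad A [sad_sample()] or abundance vector with `S >= 1`.
#' @param starts Optional matrix of starting values (columns `log_theta`,
#'   `logit_m`); one row per start, best optimum returned.
#' @return An object of class `hnm_fit` with fields `theta`, `m`, `I`,
#'   `loglik`, `J`, `S`, `boundary`.
#' @export
fit_hnm <- function(sad, starts = NULL) {
  sad <- with_logK(as_sad(sad))
  degenerate <- sad$S <= 1 || sad$J == sad$S
  if (is.null(starts)) starts <- hnm_default_starts(sad)
  cnst <- sad_constant(sad)
  lk <- sad_logK(sad)
  J <- sad$J
  S <- sad$S
  negll <- function(par) {
    theta <- exp(par[1])
    m <- plogis(par[2])
    I <- m * (J - 1) / (1 - m)
    if (!is.finite(I) || I <= 0) return(1e10)
    v <- -etienne_loglik_cpp(lk, S, J, cnst, theta, I)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(hnm_bounds$log_theta[1], hnm_bounds$logit_m[1])
  upper <- c(hnm_bounds$log_theta[2], hnm_bounds$logit_m[2])
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- suppressWarnings(
      nlminb(starts[r, ], negll, lower = lower, upper = upper,
             control = list(iter.max = 300))
    )
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  theta <- exp(best$par[1])
  m <- plogis(best$par[2])
  boundary <- degenerate ||
    abs(best$par[1] - lower[1]) < 1e-6 || abs(best$par[1] - upper[1]) < 1e-6
  if (degenerate) {
    warn(sprintf(
      "degenerate SAD (S = %d, J = %d): boundary fit, theta capped at 1e5.",
      S, J
    ))
  }
  structure(
    list(
      theta = theta, m = m, I = m * (J - 1) / (1 - m),
      loglik = -best$objective, J = J, S = S, boundary = boundary
    ),
    class = "hnm_fit"
  )
}

#' @export
print.hnm_fit <- function(x, ...) {
  cat(sprintf(
    "<hnm_fit> theta = %.4g, m = %.4g (I = %.4g), logLik = %.3f, J = %d, S = %d%s\n",
    x$theta, x$m, x$I, x$loglik, x$J, x$S,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' Simulate one SAD from the fitted Hubbell model
#'
#' Exact draw at (theta, I) via the nested urn: an individual is an immigrant
#' with probability `I / (I + n)`; immigrants found ancestral lineages whose
#' species follow a Chinese restaurant process at rate theta. This is the
#' distribution the Etienne likelihood describes, with no metacommunity
#' truncation.
#'
#' @param theta Biodiversity number (> 0).
#' @param I Immigration number (> 0).
#' @param J Community size.
#' @param seed Optional integer seed (local to this call).
#' @return A [sad_sample()].
#' @export
simulate_hnm_sad <- function(theta, I, J, seed = NULL) {
  check_scalar(theta, "theta", lower = 0, open_lower = TRUE)
  check_scalar(I, "I", lower = 0, open_lower = TRUE)
  check_scalar(J, "J", lower = 1)
  with_seed(seed, sad_sample(nested_crp_sad_cpp(theta, I, as.integer(J))))
}

#' Exact pseudo-P neutrality test for one sample
#'
#' Fits `(theta, I)` to the observed SAD, simulates `n_sim` neutral SADs of
#' the same size J from the fitted model, and compares log-likelihoods. The
#' pseudo-P value is `(1 + #\{simulated <= observed\}) / (1 + n_sim)`; ties
#' count toward the numerator and the +1 smoothing keeps P in (0, 1\].
#' Neutrality is not rejected when P exceeds `alpha`.
#'
#' By default each simulated SAD is refitted before comparison (full
#' parametric bootstrap of the maximized log-likelihood, warm-started at the
#' observed optimum); `refit = FALSE` compares likelihoods at the fixed
#' observed `(theta, I)` — faster, but only approximately calibrated.
#'
#' Samples larger than 30,000 reads are first subsampled without replacement
#' to 30,000 individuals (flagged in the result) to keep the likelihood
#' recursion tractable.
#'
#' @param sad A [sad_sample()] or abundance vector.
#' @param n_sim Number of neutral replicates (>= 20; default 500).
#' @param seed Optional integer seed (local to this call).
#' @param alpha Rejection threshold (default 0.05).
#' @param refit Refit each replicate (default TRUE)?
#' @param fit Optional precomputed `hnm_fit` for the observed SAD.
#' @return An object of class `hnm_test` with `pseudo_p`, `verdict`
#'   (`"neutral_not_rejected"` or `"rejected"`), `observed_loglik`,
#'   `simulated_logliks`, the fit, and flags.
#' @export
hnm_neutrality_test <- function(sad, n_sim = 500, seed = NULL, alpha = 0.05,
                                refit = TRUE, fit = NULL) {
  sad <- as_sad(sad)
  check_scalar(n_sim, "n_sim", lower = 20)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  n_sim <- as.integer(n_sim)
  with_seed(seed, {
    subsampled <- FALSE
    if (sad$J > 30000) {
      sad <- subsample_sad(sad, 30000)
      subsampled <- TRUE
      inform(sprintf("sample subsampled to 30,000 reads for testing (J was larger)."))
    }
    if (is.null(fit)) {
      fit <- if (sad$S <= 1 || sad$J == sad$S) {
        suppressWarnings(fit_hnm(sad))
      } else {
        fit_hnm(sad)
      }
    }
    warm <- matrix(c(log(fit$theta), qlogis(fit$m)), 1,
      dimnames = list(NULL, c("log_theta", "logit_m"))
    )
    obs <- fit$loglik
    sims <- vapply(seq_len(n_sim), function(r) {
      counts <- nested_crp_sad_cpp(fit$theta, fit$I, sad$J)
      sim <- sad_sample(counts)
      if (refit) {
        suppressWarnings(fit_hnm(sim, starts = warm)$loglik)
      } else {
        neutral_loglik(sim, fit$theta, fit$I)
      }
    }, numeric(1))
    pseudo_p <- (1 + sum(sims <= obs)) / (1 + n_sim)
    structure(
      list(
        pseudo_p = pseudo_p,
        observed_loglik = obs,
        simulated_logliks = sims,
        alpha = alpha,
        verdict = if (pseudo_p > alpha) "neutral_not_rejected" else "rejected",
        fit = fit,
        n_sim = n_sim,
        refit = refit,
        subsampled = subsampled
      ),
      class = "hnm_test"
    )
  })
}

# subsample a SAD without replacement to `size` individuals
subsample_sad <- function(sad, size) {
  ids <- rep.int(seq_len(sad$S), sad$abundances)
  keep <- sample(ids, size)
  counts <- tabulate(keep, nbins = sad$S)
  sad_sample(counts[counts > 0])
}

#' @export
print.hnm_test <- function(x, ...) {
  cat(sprintf(
    "<hnm_test> pseudo-P = %.4f (n_sim = %d, alpha = %.2f): %s\n",
    x$pseudo_p, x$n_sim, x$alpha, x$verdict
  ))
  print(x$fit)
  invisible(x)
}

#' Neutrality passing rate across P-value thresholds
#'
#' The fraction of samples whose pseudo-P exceeds each threshold — the
#' P-threshold sweep used instead of FDR correction, since the neutrality
#' convention (large P favours neutrality) makes FDR adjustment
#' counterproductive. The curve is non-increasing in the threshold.
#'
#' @param pvalues Vector of pseudo-P values in \[0, 1\].
#' @param thresholds Vector of thresholds in \[0, 1\].
#' @return A tibble with columns `threshold` and `passing_rate`.
#' @export
passing_rate_curve <- function(pvalues, thresholds = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9)) {
  if (length(pvalues) == 0) abort("empty p-value vector.")
  if (any(pvalues < 0 | pvalues > 1) || any(thresholds < 0 | thresholds > 1)) {
    abort("p-values and thresholds must lie in [0, 1].")
  }
  tibble::tibble(
    threshold = thresholds,
    passing_rate = vapply(thresholds, function(t) mean(pvalues > t), numeric(1))
  )
}
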