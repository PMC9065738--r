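# ---------------------------------------------------------------------------
# Sloan near-neutral model: birth-death transition probabilities, stationary
# beta fit of the migration parameter, and per-species classification
# against the 95% neutral interval.
# ---------------------------------------------------------------------------

#' Sloan per-step transition probabilities
#'
#' In a saturated local community of `N_T` individuals where a dead
#' individual is replaced by an immigrant (probability `m`) or by local
#' reproduction (probability `1 - m`), the abundance `N_i` of a focal OTU
#' with source frequency `p_i` moves up, down, or stays per step with
#' probabilities
#' \deqn{P_{+} = (1 - N_i/N_T) [m p_i + (1 - m) N_i/(N_T - 1)]}
#' \deqn{P_{-} = (N_i/N_T) [m (1 - p_i) + (1 - m)(N_T - N_i)/(N_T - 1)]}
#' and `P_0 = 1 - P_+ - P_-`.
#'
#' @param N_i Focal OTU abundance(s), in `0..N_T`.
#' @param N_T Local community size (>= 2).
#' @param m Migration probability in \[0, 1\].
#' @param p_i Source-community relative frequency(ies) in \[0, 1\].
#' @return A tibble with columns `p_up`, `p_down`, `p_stay` (rows recycled
#'   over `N_i` and `p_i`); each row sums to 1.
#' @export
sloan_transition_probs <- function(N_i, N_T, m, p_i) {
  check_scalar(N_T, "N_T", lower = 2)
  check_scalar(m, "m", lower = 0, upper = 1)
  if (any(N_i < 0 | N_i > N_T)) abort("`N_i` must lie in [0, N_T].")
  if (any(p_i < 0 | p_i > 1)) abort("`p_i` must lie in [0, 1].")
  frac <- N_i / N_T
  p_up <- (1 - frac) * (m * p_i + (1 - m) * N_i / (N_T - 1))
  p_down <- frac * (m * (1 - p_i) + (1 - m) * (N_T - N_i) / (N_T - 1))
  tibble::tibble(p_up = p_up, p_down = p_down, p_stay = 1 - p_up - p_down)
}

#' Sloan model with known parameters
#'
#' Builds a `sloan_fit` object directly from parameter values, for
#' classifying species against a neutral interval without fitting (e.g. on
#' simulated data with known migration).
#'
#' @param m Migration probability in (0, 1\].
#' @param N_T Local community size.
#' @param detection_threshold Relative-abundance detection limit; defaults
#'   to `1 / N_T`.
#' @return A `sloan_fit` object (with `r_squared = NA`).
#' @export
sloan_model <- function(m, N_T, detection_threshold = 1 / N_T) {
  check_scalar(m, "m", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(N_T, "N_T", lower = 2)
  structure(
    list(m = m, N_T = N_T, r_squared = NA_real_,
         detection_threshold = detection_threshold,
         n_species = NA_integer_, species = NULL, failed = FALSE),
    class = "sloan_fit"
  )
}

# stationary beta parameters for source frequency p
sloan_beta_shapes <- function(m, N_T, p) {
  list(a = N_T * m * p, b = N_T * m * (1 - p))
}

#' Fit the Sloan near-neutral model to a source/destination pair
#'
#' The source ("mainland") community supplies per-OTU mean relative
#' abundances `p_i`; the destination ("island") samples supply observed
#' occurrence frequencies (fraction of samples where the OTU exceeds the
#' detection threshold `d`). Under neutral drift-plus-migration, the local
#' relative abundance of OTU `i` is stationary
#' `Beta(N_T m p_i, N_T m (1 - p_i))` (diffusion approximation of the
#' transition probabilities), so the predicted occurrence frequency is that
#' beta's upper-tail mass beyond `d`. The single parameter `m` is fitted by
#' least squares between observed and predicted occurrence frequencies.
#'
#' A negative R-squared flags a failed fit; it is reported, not raised.
#'
#' @param source,dest [community_matrix()] objects (destination needs >= 5
#'   samples). OTU universes are aligned on the union of row labels; the
#'   same matrix may be passed as both (the "same-set" scheme).
#' @param detection_threshold Relative-abundance detection limit `d`;
#'   defaults to `1 / N_T` with `N_T` the rounded mean destination total.
#' @return An object of class `sloan_fit`: `m`, `N_T`, `r_squared`,
#'   `detection_threshold`, `n_species`, and a `species` tibble (`otu`,
#'   `p`, `obs_freq`, `pred_freq`, `x_mean`).
#' @export
fit_sloan <- function(source, dest, detection_threshold = NULL) {
  source <- as_count_matrix(source)
  dest <- as_count_matrix(dest)
  if (ncol(dest) < 5) abort("destination community needs at least 5 samples.")
  otus <- union(rownames(source), rownames(dest))
  src <- matrix(0, length(otus), ncol(source), dimnames = list(otus, colnames(source)))
  src[rownames(source), ] <- unclass(source)
  dst <- matrix(0, length(otus), ncol(dest), dimnames = list(otus, colnames(dest)))
  dst[rownames(dest), ] <- unclass(dest)
  N_T <- round(mean(colSums(dst)))
  d <- if (is.null(detection_threshold)) 1 / N_T else detection_threshold
  check_scalar(d, "detection_threshold", lower = 0, upper = 1, open_upper = TRUE)
  p <- rowMeans(normalize_columns(src))
  rel_dst <- normalize_columns(dst)
  keep <- p > 0
  if (sum(keep) < 5) abort("fewer than 5 species with nonzero source frequency.")
  p <- p[keep]
  obs_freq <- rowMeans(rel_dst[keep, , drop = FALSE] > d)
  x_mean <- rowMeans(rel_dst[keep, , drop = FALSE])
  pred <- function(m) {
    sh <- sloan_beta_shapes(m, N_T, p)
    1 - pbeta(d, sh$a, sh$b)
  }
  ss <- function(m) sum((obs_freq - pred(m))^2)
  opt <- optimize(ss, interval = c(1e-6, 1))
  m_hat <- opt$minimum
  ss_res <- opt$objective
  ss_tot <- sum((obs_freq - mean(obs_freq))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) {
    if (ss_res <= 1e-12) 1 else -Inf
  } else {
    1 - ss_res / ss_tot
  }
  failed <- is.finite(r2) && r2 < 0
  if (failed) inform(sprintf("Sloan fit has negative R-squared (%.3f): flagged as failed.", r2))
  structure(
    list(
      m = m_hat, N_T = N_T, r_squared = r2, detection_threshold = d,
      n_species = sum(keep),
      species = tibble::tibble(
        otu = names(p), p = unname(p), obs_freq = unname(obs_freq),
        pred_freq = unname(pred(m_hat)), x_mean = unname(x_mean)
      ),
      failed = failed
    ),
    class = "sloan_fit"
  )
}

#' @export
print.sloan_fit <- function(x, ...) {
  cat(sprintf(
    "<sloan_fit> m = %.4g, N_T = %d, R^2 = %.3f, %s species%s\n",
    x$m, as.integer(x$N_T), x$r_squared,
    ifelse(is.na(x$n_species), "?", x$n_species),
    if (isTRUE(x$failed)) " [failed fit]" else ""
  ))
  invisible(x)
}

#' Classify species against the 95% neutral interval
#'
#' Each species' observed mean local frequency `x_i` is compared with the
#' central 95% interval (2.5% and 97.5% quantiles) of its stationary
#' `Beta(N_T m p_i, N_T m (1 - p_i))` distribution. Species above the upper
#' quantile are `above_neutral` (positively selected), below the lower
#' quantile `below_neutral` (negatively selected), otherwise `neutral`.
#' Species with `p_i` of exactly 0 or 1 have a degenerate beta and are
#' excluded with a message. Set `on = "occurrence"` to classify observed
#' occurrence frequencies against an interval of predicted occurrence
#' frequencies instead.
#'
#' @param fit A [fit_sloan()] or [sloan_model()] object.
#' @param p Source frequencies; defaults to the fitted species table.
#' @param x Observed mean local frequencies; defaults likewise.
#' @param level Interval coverage (default 0.95).
#' @param on `"abundance"` (default) classifies `x_i` against the beta
#'   quantiles; `"occurrence"` classifies occurrence frequencies against the
#'   binomial interval implied by the beta tail mass across samples.
#' @param n_samples Number of destination samples (needed for
#'   `on = "occurrence"`).
#' @return A tibble of class `species_classification` with columns `p`, `x`,
#'   `lower`, `upper`, `label`, plus attribute `fractions` (the proportions
#'   below/neutral/above, summing to 1 over classified species).
#' @export
classify_species <- function(fit, p = NULL, x = NULL, level = 0.95,
                             on = c("abundance", "occurrence"),
                             n_samples = NULL) {
  stopifnot(inherits(fit, "sloan_fit"))
  on <- match.arg(on)
  if (is.null(p)) {
    if (is.null(fit$species)) abort("supply `p` and `x` for a parameter-only model.")
    p <- fit$species$p
    x <- if (on == "abundance") fit$species$x_mean else fit$species$obs_freq
    otu <- fit$species$otu
  } else {
    if (is.null(x) || length(x) != length(p)) abort("`p` and `x` must have equal length.")
    otu <- names(p) %||% paste0("species_", seq_along(p))
  }
  degen <- p <= 0 | p >= 1
  if (any(degen)) {
    inform(sprintf("%d species with p in {0, 1} excluded (degenerate beta).", sum(degen)))
  }
  p_use <- p[!degen]
  x_use <- x[!degen]
  sh <- sloan_beta_shapes(fit$m, fit$N_T, p_use)
  tail <- (1 - level) / 2
  if (on == "abundance") {
    lower <- qbeta(tail, sh$a, sh$b)
    upper <- qbeta(1 - tail, sh$a, sh$b)
  } else {
    if (is.null(n_samples)) abort("`n_samples` is required for occurrence-based classification.")
    pr <- 1 - pbeta(fit$detection_threshold, sh$a, sh$b)
    lower <- stats::qbinom(tail, n_samples, pr) / n_samples
    upper <- stats::qbinom(1 - tail, n_samples, pr) / n_samples
  }
  label <- dplyr::case_when(
    x_use < lower ~ "below_neutral",
    x_use > upper ~ "above_neutral",
    .default = "neutral"
  )
  out <- tibble::tibble(
    otu = otu[!degen], p = unname(p_use), x = unname(x_use),
    lower = lower, upper = upper,
    label = factor(label, levels = c("below_neutral", "neutral", "above_neutral"))
  )
  class(out) <- c("species_classification", class(out))
  attr(out, "fractions") <- prop.table(table(out$label))
  attr(out, "model") <- list(m = fit$m, N_T = fit$N_T, level = level, on = on)
  out
}

#' Summary fractions of a species classification
#'
#' @param x A [classify_species()] result.
#' @return A tibble with the fractions of species below, within, and above
#'   the neutral interval (summing to 1).
#' @export
classification_fractions <- function(x) {
  stopifnot(inherits(x, "species_classification"))
  fr <- attr(x, "fractions")
  tibble::tibble(
    n_species = nrow(x),
    frac_below = as.numeric(fr["below_neutral"]),
    frac_neutral = as.numeric(fr["neutral"]),
    frac_above = as.numeric(fr["above_neutral"])
  )
}
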