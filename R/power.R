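# ---------------------------------------------------------------------------
# Power analysis for the neutrality test (PNT): simulate matched non-neutral
# datasets (IF / PC dynamics over a log-series metacommunity), test each, and
# apply the detection and false-negative rules.
# ---------------------------------------------------------------------------

#' Power of the neutrality test against a non-neutral alternative
#'
#' Fits the neutral model to a template sample (or uses a supplied fit),
#' then generates `n_datasets` communities of the same size J from the
#' matched non-neutral generator: a metacommunity pool assembled by IF
#' (Gamma-distributed species fecundities, effect = coefficient of
#' variation) or PC (density dependence, effect = epsilon) local dynamics at
#' the fitted migration probability. It then runs the pseudo-P neutrality
#' test on each. Power is the fraction of non-neutral datasets whose
#' pseudo-P falls at or below `alpha`.
#'
#' With the default `meta_model = "stick_breaking"`, a fresh neutral
#' metacommunity is drawn at `theta_hat` for every dataset, so at effect 0
#' the generator coincides with the fitted neutral model and power estimates
#' the test's type-I error (the calibration anchor). The alternative
#' `meta_model = "log_series"` uses one fixed log-series pool with shape
#' `x = J / (J + theta_hat)` (Fisher's relation); because that pool is fixed
#' across datasets rather than integrated over, its effect-0 pseudo-P values
#' are not uniform and power is not anchored at alpha.
#'
#' @param template A [sad_sample()] (or abundance vector) or an [fit_hnm()]
#'   object.
#' @param model Non-neutral local dynamics: `"IF"` or `"PC"`.
#' @param effect Control parameter (cv for IF, epsilon for PC; >= 0).
#' @param n_datasets Number of simulated datasets (>= 20; default 50).
#' @param n_sim_per_test Neutral replicates inside each test (default 100).
#' @param alpha Rejection threshold (default 0.05).
#' @param seed Optional integer seed (local to this call).
#' @param s_max Species classes in the metacommunity pool (default 500).
#' @param refit Refit each test replicate (see [hnm_neutrality_test()]).
#' @param meta_model `"stick_breaking"` (default; fresh neutral pool per
#'   dataset, calibrated at effect 0) or `"log_series"` (one fixed Fisher
#'   pool).
#' @return An object of class `pnt_power`: `model`, `effect`, `n_datasets`,
#'   `ave_p` (mean pseudo-P over the non-neutral datasets), `power`,
#'   `alpha`, `per_dataset_p`.
#' @export
run_power_analysis <- function(template, model = c("IF", "PC"), effect,
                               n_datasets = 50, n_sim_per_test = 100,
                               alpha = 0.05, seed = NULL, s_max = 500,
                               refit = TRUE,
                               meta_model = c("stick_breaking", "log_series")) {
  model <- match.arg(model)
  meta_model <- match.arg(meta_model)
  check_scalar(effect, "effect", lower = 0)
  check_scalar(n_datasets, "n_datasets", lower = 20)
  if (model == "PC" && effect > 1) abort("PC effect (epsilon) must lie in [0, 1].")
  fit <- if (inherits(template, "hnm_fit")) template else fit_hnm(as_sad(template))
  J <- fit$J
  fixed_meta <- if (meta_model == "log_series") {
    simulate_metacommunity("log_series", param = J / (J + fit$theta), s_max = s_max)
  }
  with_seed(seed, {
    p <- vapply(seq_len(n_datasets), function(d) {
      meta <- fixed_meta %||%
        simulate_metacommunity("stick_breaking", fit$theta, s_max)
      fec <- if (model == "IF" && effect > 0) {
        rgamma(s_max, shape = 1 / effect^2, rate = 1 / effect^2)
      }
      sad_d <- switch(model,
        IF = simulate_local_if(meta, J, fit$m, cv = effect, fecundity = fec),
        PC = simulate_local_pc(meta, J, fit$m, epsilon = effect)
      )
      suppressWarnings(
        hnm_neutrality_test(sad_d, n_sim = n_sim_per_test, alpha = alpha,
                            refit = refit)$pseudo_p
      )
    }, numeric(1))
    structure(
      list(
        model = model, effect = effect, n_datasets = as.integer(n_datasets),
        ave_p = mean(p), power = mean(p <= alpha), alpha = alpha,
        per_dataset_p = p
      ),
      class = "pnt_power"
    )
  })
}

#' @export
print.pnt_power <- function(x, ...) {
  cat(sprintf(
    "<pnt_power> %s model, effect = %g: power = %.3f, mean pseudo-P = %.3f (%d datasets, alpha = %.2f)\n",
    x$model, x$effect, x$power, x$ave_p, x$n_datasets, x$alpha
  ))
  invisible(x)
}

#' Non-neutrality detection rule
#'
#' A non-neutral process is declared detected when the sample's observed
#' pseudo-P falls strictly below the average pseudo-P of the matched
#' non-neutral simulations; a tie resolves toward "not detected"
#' (conservative toward the neutral conclusion).
#'
#' @param p_observed Observed pseudo-P value(s) in \[0, 1\].
#' @param ave_p Average pseudo-P over matched non-neutral datasets.
#' @return Logical vector.
#' @export
detect_non_neutral <- function(p_observed, ave_p) {
  if (any(p_observed < 0 | p_observed > 1) || any(ave_p < 0 | ave_p > 1)) {
    abort("inputs must lie in [0, 1].")
  }
  p_observed < ave_p
}

#' False-negative rule for the neutrality test
#'
#' A sample is a false-negative candidate when the non-neutral process is
#' detected (`p_observed < ave_p`) yet the neutrality test itself still
#' passes (`p_observed > alpha`): the test failed to reject a null that the
#' power analysis contradicts.
#'
#' @inheritParams detect_non_neutral
#' @param alpha Neutrality rejection threshold (default 0.05).
#' @return Logical vector; implies [detect_non_neutral()] for the same
#'   inputs.
#' @export
classify_false_negative <- function(p_observed, ave_p, alpha = 0.05) {
  detect_non_neutral(p_observed, ave_p) & p_observed > alpha
}

#' Build detection verdicts for a set of samples
#'
#' @inheritParams classify_false_negative
#' @return A tibble with columns `p_observed`, `ave_p`,
#'   `non_neutral_detected`, `false_negative`, `alpha`.
#' @export
pnt_verdicts <- function(p_observed, ave_p, alpha = 0.05) {
  tibble::tibble(
    p_observed = p_observed,
    ave_p = ave_p,
    non_neutral_detected = detect_non_neutral(p_observed, ave_p),
    false_negative = classify_false_negative(p_observed, ave_p, alpha),
    alpha = alpha
  )
}

#' Summarize detection verdicts
#'
#' Fractions of samples with a detected non-neutral process and with a
#' false-negative flag — the treatment-level summary rows of a power
#' analysis report.
#'
#' @param verdicts A data frame with logical columns `non_neutral_detected`
#'   and `false_negative` (e.g. from [pnt_verdicts()]).
#' @return A tibble with `n`, `frac_detected`, `frac_false_negative`.
#' @export
summarize_pnt <- function(verdicts) {
  if (is.null(verdicts) || NROW(verdicts) == 0) abort("empty verdict list.")
  if (!all(c("non_neutral_detected", "false_negative") %in% names(verdicts))) {
    abort("verdicts need columns `non_neutral_detected` and `false_negative`.")
  }
  tibble::tibble(
    n = NROW(verdicts),
    frac_detected = mean(verdicts$non_neutral_detected),
    frac_false_negative = mean(verdicts$false_negative)
  )
}
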