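# broom-style tidiers and ggplot2 autoplot methods for the fitted objects

#' @export
tidy.hnm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("theta", "m", "I"),
    estimate = c(x$theta, x$m, x$I)
  )
}

#' @export
glance.hnm_fit <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, m = x$m, I = x$I, logLik = x$loglik,
    J = x$J, S = x$S, boundary = x$boundary
  )
}

#' @export
glance.hnm_test <- function(x, ...) {
  tibble::tibble(
    pseudo_p = x$pseudo_p, verdict = x$verdict, alpha = x$alpha,
    observed_loglik = x$observed_loglik, n_sim = x$n_sim,
    theta = x$fit$theta, m = x$fit$m, J = x$fit$J, S = x$fit$S,
    refit = x$refit, subsampled = x$subsampled
  )
}

#' @export
tidy.msn_fit <- function(x, ...) {
  tibble::tibble(
    sample = x$sample_ids, N = unname(x$N),
    I = unname(x$I), m = unname(x$m)
  )
}

#' @export
glance.msn_fit <- function(x, ...) {
  tibble::tibble(
    theta = x$theta, n_sites = length(x$I),
    n_gibbs = x$n_gibbs, burn_in = x$burn_in,
    rhat_log_theta = x$rhat_log_theta,
    convergence_warning = x$convergence_warning
  )
}

#' @export
tidy.msn_test <- function(x, ...) {
  tibble::tibble(sample = names(x$P_L), P_L = unname(x$P_L), P_M = x$P_M)
}

#' @export
tidy.sloan_fit <- function(x, ...) {
  if (is.null(x$species)) return(tibble::tibble())
  x$species
}

#' @export
glance.sloan_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, N_T = x$N_T, r_squared = x$r_squared,
    detection_threshold = x$detection_threshold,
    n_species = x$n_species, failed = isTRUE(x$failed)
  )
}

#' @export
glance.stochasticity_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    mean_pairwise_similarity = x$mean_pairwise_similarity,
    SR = x$SR, NSR = x$NSR, n_A = x$n_A, n_B = x$n_B,
    n_null = x$n_null, null_algorithm = x$null_algorithm
  )
}

#' @export
tidy.pnt_power <- function(x, ...) {
  tibble::tibble(
    dataset = seq_along(x$per_dataset_p),
    model = x$model, effect = x$effect, pseudo_p = x$per_dataset_p,
    rejected = x$per_dataset_p <= x$alpha
  )
}

#' @export
glance.pnt_power <- function(x, ...) {
  tibble::tibble(
    model = x$model, effect = x$effect, n_datasets = x$n_datasets,
    ave_p = x$ave_p, power = x$power, alpha = x$alpha
  )
}

#' Plot a species classification against the neutral interval
#'
#' Occurrence of each species' observed mean frequency relative to the 95%
#' stationary-beta band, on a log source-frequency axis.
#'
#' @param object A [classify_species()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_classification <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$x, colour = .data$label), size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      below_neutral = "#00A9A5", neutral = "#2E7D32", above_neutral = "#D81B60"
    ), drop = FALSE) +
    ggplot2::labs(
      x = "source frequency p (log scale)", y = "local frequency x",
      colour = NULL, title = "Sloan near-neutral classification"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs null-expected pairwise similarity
#'
#' @param object A [nsr()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stochasticity_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$E_bar, y = .data$C,
                                             colour = .data$type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "null-expected similarity", y = "observed similarity",
      title = sprintf("SR = %.3f, NSR = %.3f", object$SR, object$NSR),
      colour = "pair type"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the simulated likelihood distribution of a neutrality test
#'
#' @param object An [hnm_neutrality_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hnm_test <- function(object, ...) {
  df <- tibble::tibble(loglik = object$simulated_logliks)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loglik)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_loglik,
                        colour = "#D81B60", linewidth = 1) +
    ggplot2::labs(
      x = "simulated log-likelihood", y = "count",
      title = sprintf("pseudo-P = %.3f (%s)", object$pseudo_p, object$verdict)
    ) +
    ggplot2::theme_minimal()
}
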