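# ---------------------------------------------------------------------------
# Stochasticity quantification: Ruzicka similarity, null-model expectations,
# the stochasticity ratio SR, and its min-max normalization NSR.
# ---------------------------------------------------------------------------

#' Ruzicka similarity between two abundance vectors
#'
#' Abundance-weighted generalization of the Jaccard index:
#' `sum_k min(p_k, q_k) / sum_k max(p_k, q_k)`. On 0/1 vectors this reduces
#' to the Jaccard coefficient; it equals 1 iff the vectors are identical.
#'
#' @param p,q Non-negative vectors of equal length, not both all-zero.
#' @return A similarity in \[0, 1\].
#' @export
ruzicka_similarity <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length.")
  if (any(p < 0) || any(q < 0)) abort("entries must be non-negative.")
  den <- sum(pmax(p, q))
  if (den == 0) abort("both vectors are all-zero: similarity undefined.")
  sum(pmin(p, q)) / den
}

# all-pairs Ruzicka similarity of column-normalized profiles; for columns
# summing to 1, sum min = (2 - L1)/2 and sum max = (2 + L1)/2
pairwise_ruzicka <- function(relmat) {
  D <- as.matrix(dist(t(relmat), method = "manhattan"))
  C <- (2 - D) / (2 + D)
  diag(C) <- 1
  C
}

as_relabund <- function(x) {
  if (inherits(x, "community_matrix")) return(to_relative_abundance(x))
  if (is.matrix(x) && is.numeric(x)) {
    if (any(x < 0)) abort("abundance matrix must be non-negative.")
    return(normalize_columns(x))
  }
  abort("expected a community_matrix or a non-negative matrix.")
}

#' Randomize a metacommunity under a null assembly model
#'
#' Produces one randomized relative-abundance matrix with the same dimensions
#' and labels as the input. Algorithms:
#' \describe{
#'   \item{`proportional_frequency`}{per sample, preserve observed richness;
#'     draw that many species without replacement with probability
#'     proportional to their regional occupancy frequency; give the drawn
#'     species relative abundances proportional to their regional mean
#'     relative abundances, renormalized.}
#'   \item{`richness_uniform`}{preserve each sample's abundance values but
#'     reassign them to species drawn uniformly (without replacement) from
#'     the full species pool.}
#'   \item{`identity`}{no randomization (degenerate null, for testing).}
#' }
#'
#' @param x A [community_matrix()] or non-negative matrix (species x samples).
#' @param null_algorithm Null algorithm id.
#' @param seed Optional integer seed (local to this call).
#' @return A relative-abundance matrix (columns sum to 1).
#' @export
null_randomize <- function(x, null_algorithm = c("proportional_frequency",
                                                 "richness_uniform", "identity"),
                           seed = NULL) {
  null_algorithm <- match.arg(null_algorithm)
  rel <- as_relabund(x)
  with_seed(seed, {
    switch(null_algorithm,
      identity = rel,
      proportional_frequency = {
        occ <- rowMeans(rel > 0)
        mean_rel <- rowMeans(rel)
        out <- matrix(0, nrow(rel), ncol(rel), dimnames = dimnames(rel))
        for (j in seq_len(ncol(rel))) {
          s_j <- sum(rel[, j] > 0)
          pick <- sample.int(nrow(rel), s_j, prob = occ)
          w <- mean_rel[pick]
          if (sum(w) == 0) w <- rep(1, s_j)
          out[pick, j] <- w / sum(w)
        }
        out
      },
      richness_uniform = {
        out <- matrix(0, nrow(rel), ncol(rel), dimnames = dimnames(rel))
        for (j in seq_len(ncol(rel))) {
          vals <- rel[rel[, j] > 0, j]
          pick <- sample.int(nrow(rel), length(vals))
          out[pick, j] <- vals
        }
        out
      }
    )
  })
}

#' Null-expected pairwise similarity
#'
#' Mean pairwise Ruzicka similarity over `n_null` randomized metacommunities
#' generated by the chosen null algorithm.
#'
#' @inheritParams null_randomize
#' @param n_null Number of null randomizations (default 1000).
#' @return A symmetric matrix of mean null similarities in \[0, 1\].
#' @export
null_expected_similarity <- function(x, n_null = 1000,
                                     null_algorithm = "proportional_frequency",
                                     seed = NULL) {
  rel <- as_relabund(x)
  if (ncol(rel) < 2) abort("need at least 2 samples.")
  check_scalar(n_null, "n_null", lower = 1)
  null_algorithm <- match.arg(null_algorithm,
    c("proportional_frequency", "richness_uniform", "identity"))
  with_seed(seed, {
    acc <- matrix(0, ncol(rel), ncol(rel))
    for (r in seq_len(n_null)) {
      acc <- acc + pairwise_ruzicka(null_randomize(rel, null_algorithm))
    }
    E <- acc / n_null
    dimnames(E) <- list(colnames(rel), colnames(rel))
    E
  })
}

#' Stochasticity ratio from observed and null-expected similarities
#'
#' For sample pairs driven more similar than the null expectation
#' (`C_ij > E_ij`, "type A": determinism toward similarity) the per-pair
#' ratio is `E_ij / C_ij`; for pairs driven less similar (`C_ij < E_ij`,
#' "type B") it is `(1 - E_ij) / (1 - C_ij)`. SR is the average over both
#' pair types; ties `C_ij = E_ij` are excluded from both counts. SR is 0
#' for fully deterministic assembly and 1 when observed similarity matches
#' the null everywhere.
#'
#' @param C Observed pairwise similarity matrix.
#' @param E_bar Null-expected pairwise similarity matrix (same shape).
#' @return A list with `SR`, `n_A`, `n_B`, and a `pairs` tibble of per-pair
#'   ratios.
#' @export
stochasticity_ratio <- function(C, E_bar) {
  if (!all(dim(C) == dim(E_bar))) abort("`C` and `E_bar` must be conformable.")
  n <- ncol(C)
  if (n < 2) abort("need at least 2 samples.")
  idx <- which(upper.tri(C), arr.ind = TRUE)
  c_ij <- C[idx]
  e_ij <- E_bar[idx]
  typeA <- c_ij > e_ij
  typeB <- c_ij < e_ij
  ratio <- rep(NA_real_, length(c_ij))
  ratio[typeA] <- e_ij[typeA] / c_ij[typeA]
  ratio[typeB] <- (1 - e_ij[typeB]) / (1 - c_ij[typeB])
  n_A <- sum(typeA)
  n_B <- sum(typeB)
  SR <- if (n_A + n_B == 0) {
    warn("all pairs tied with the null expectation: SR defined as 1.")
    1
  } else {
    mean(ratio[typeA | typeB])
  }
  list(
    SR = SR, n_A = n_A, n_B = n_B,
    pairs = tibble::tibble(
      i = idx[, 1], j = idx[, 2], C = c_ij, E_bar = e_ij,
      type = dplyr::case_when(typeA ~ "A", typeB ~ "B", .default = "tie"),
      ratio = ratio
    )
  )
}

#' Normalized stochasticity ratio (NSR)
#'
#' Min-max rescaling of SR so the fully deterministic extreme maps to 0 and
#' the null-coincident extreme to 1: each type-A pair's observed similarity
#' is replaced by its extreme attainable value 1 (and each type-B pair's by
#' 0) to obtain `SR_min`, while `SR_max = 1` by construction; then
#' `NSR = (SR - SR_min) / (1 - SR_min)`, clipped to \[0, 1\].
#'
#' @inheritParams stochasticity_ratio
#' @return NSR in \[0, 1\].
#' @export
normalized_sr <- function(C, E_bar) {
  sr <- stochasticity_ratio(C, E_bar)
  pr <- sr$pairs
  used <- pr$type != "tie"
  if (!any(used)) return(sr$SR)
  lowest <- ifelse(pr$type[used] == "A", pr$E_bar[used], 1 - pr$E_bar[used])
  SR_min <- mean(lowest)
  if (1 - SR_min <= .Machine$double.eps) {
    warn("degenerate normalization (SR_min = SR_max): NSR set to SR.")
    return(sr$SR)
  }
  min(1, max(0, (sr$SR - SR_min) / (1 - SR_min)))
}

#' Stochasticity analysis of a metacommunity
#'
#' End-to-end: observed pairwise Ruzicka similarities, null expectations
#' from `n_null` randomizations, the stochasticity ratio SR and its
#' normalization NSR.
#'
#' @inheritParams null_expected_similarity
#' @return An object of class `stochasticity_result` with fields `C`,
#'   `E_bar`, `n_A`, `n_B`, `SR`, `NSR`, `mean_pairwise_similarity`,
#'   `n_null`, `null_algorithm`, `seed`, `pairs`.
#' @export
nsr <- function(x, n_null = 1000, null_algorithm = "proportional_frequency",
                seed = NULL) {
  rel <- as_relabund(x)
  null_algorithm <- match.arg(null_algorithm,
    c("proportional_frequency", "richness_uniform", "identity"))
  C <- pairwise_ruzicka(rel)
  E_bar <- null_expected_similarity(rel, n_null = n_null,
    null_algorithm = null_algorithm, seed = seed)
  sr <- stochasticity_ratio(C, E_bar)
  structure(
    list(
      C = C, E_bar = E_bar, n_A = sr$n_A, n_B = sr$n_B,
      SR = sr$SR, NSR = normalized_sr(C, E_bar),
      mean_pairwise_similarity = mean(C[upper.tri(C)]),
      n_pairs = sum(upper.tri(C)),
      n_null = n_null, null_algorithm = null_algorithm, seed = seed,
      pairs = sr$pairs
    ),
    class = "stochasticity_result"
  )
}

#' @export
print.stochasticity_result <- function(x, ...) {
  cat(sprintf(
    "<stochasticity_result> %d pairs (null: %s, %d draws)\n",
    x$n_pairs, x$null_algorithm, x$n_null
  ))
  cat(sprintf(
    "mean similarity = %.3f, SR = %.3f, NSR = %.3f (n_A = %d, n_B = %d)\n",
    x$mean_pairwise_similarity, x$SR, x$NSR, x$n_A, x$n_B
  ))
  invisible(x)
}
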