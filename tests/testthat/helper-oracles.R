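# Independent oracles and fixture builders used across the suite.

# --- set partitions -------------------------------------------------------

.partition_memo <- new.env(parent = emptyenv())

# All set partitions of {1..n}; each partition is a list of integer blocks.
all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_memo[[key]])) return(.partition_memo[[key]])
  res <- if (n == 0) {
    list(list())
  } else {
    out <- list()
    for (p in all_set_partitions(n - 1)) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], n)
        out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(n))
    }
    out
  }
  .partition_memo[[key]] <- res
  res
}

# --- brute-force Hubbell/Etienne oracle -----------------------------------
# Probability of every abundance configuration of J individuals under the
# two-level neutral process, by exhaustive enumeration: individuals are
# partitioned into ancestral lineages (CRP at rate I), lineages into species
# (CRP at rate theta). Entirely independent of the sampling-formula
# recursion it is used to check.

.etienne_coeff_memo <- new.env(parent = emptyenv())

# theta/I-independent coefficients: for each abundance key, a table of
# (A = lineages, S = species, w = sum over structures of
#  prod (block size - 1)! * prod (group size - 1)!)
etienne_oracle_coeffs <- function(J) {
  key <- as.character(J)
  if (!is.null(.etienne_coeff_memo[[key]])) return(.etienne_coeff_memo[[key]])
  acc <- new.env(parent = emptyenv())
  for (p in all_set_partitions(J)) {
    A <- length(p)
    sizes <- lengths(p)
    w1 <- prod(factorial(sizes - 1))
    for (g in all_set_partitions(A)) {
      S <- length(g)
      w2 <- prod(factorial(lengths(g) - 1))
      ab <- sort(vapply(g, function(ix) sum(sizes[ix]), numeric(1)),
                 decreasing = TRUE)
      k <- paste0(paste(ab, collapse = ","), "|", A, "|", S)
      prev <- acc[[k]]
      acc[[k]] <- if (is.null(prev)) w1 * w2 else prev + w1 * w2
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tab <- data.frame(
    config = vapply(parts, `[[`, "", 1),
    A = as.integer(vapply(parts, `[[`, "", 2)),
    S = as.integer(vapply(parts, `[[`, "", 3)),
    w = vapply(keys, function(k) acc[[k]], numeric(1))
  )
  .etienne_coeff_memo[[key]] <- tab
  tab
}

rising_factorial <- function(x, n) {
  if (n == 0) return(1)
  prod(x + 0:(n - 1))
}

# named probability vector over all abundance configurations of J
etienne_pmf_oracle <- function(J, theta, I) {
  tab <- etienne_oracle_coeffs(J)
  pr <- tab$w * I^tab$A * theta^tab$S /
    (rising_factorial(I, J) * mapply(rising_factorial, theta, tab$A))
  tapply(pr, tab$config, sum)
}

# --- Ewens sampling formula (closed form) ---------------------------------

ewens_loglik_oracle <- function(abund, theta) {
  J <- sum(abund)
  S <- length(abund)
  phi <- table(abund)
  lgamma(J + 1) + S * log(theta) - (lgamma(theta + J) - lgamma(theta)) -
    sum(log(abund)) - sum(lgamma(as.numeric(phi) + 1))
}

# --- small fixtures -------------------------------------------------------

tiny_cm <- function() {
  community_matrix(matrix(c(3, 1, 0, 2), 2, 2,
    dimnames = list(c("otuA", "otuB"), c("s1", "s2"))
  ))
}

random_cm <- function(n_otu = 12, n_samp = 5, lambda = 4, seed = NULL) {
  untbx:::with_seed(seed, {
    m <- matrix(rpois(n_otu * n_samp, lambda), n_otu, n_samp,
      dimnames = list(paste0("OTU", seq_len(n_otu)), paste0("S", seq_len(n_samp)))
    )
    m[, colSums(m) == 0][1] <- 1
    community_matrix(m)
  })
}

shannon_evenness <- function(ab) {
  p <- ab / sum(ab)
  p <- p[p > 0]
  if (length(p) < 2) return(0)
  -sum(p * log(p)) / log(length(p))
}

local_tsv <- function(env = parent.frame()) {
  path <- tempfile(fileext = ".tsv")
  withr::defer(unlink(path), envir = env)
  path
}
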