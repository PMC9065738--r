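#' Construct a community (OTU) count matrix
#'
#' A `community_matrix` is a labelled non-negative integer matrix with OTUs
#' (species-like units) as rows and community samples as columns — the
#' universal input to the neutrality analyses in this package.
#'
#' @param counts Numeric matrix of non-negative integer counts.
#' @param otu_ids Character vector of unique row labels. Defaults to the
#'   rownames of `counts`.
#' @param sample_ids Character vector of unique column labels. Defaults to
#'   the colnames of `counts`.
#' @return An integer matrix of class `community_matrix`.
#' @examples
#' cm <- community_matrix(matrix(c(3, 1, 0, 2), 2, 2,
#'   dimnames = list(c("otu1", "otu2"), c("s1", "s2"))
#' ))
#' sample_sizes(cm)
#' @export
community_matrix <- function(counts, otu_ids = rownames(counts),
                             sample_ids = colnames(counts)) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix.")
  }
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  if (length(otu_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    abort("label lengths do not match matrix dimensions.")
  }
  if (anyDuplicated(otu_ids)) abort("duplicate OTU ids.")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids.")
  bad <- which(!is_whole(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; offending cell at OTU '%s', sample '%s'.",
      otu_ids[bad[1, 1]], sample_ids[bad[1, 2]]
    ))
  }
  m <- matrix(as.integer(round(counts)), nrow(counts), ncol(counts),
    dimnames = list(as.character(otu_ids), as.character(sample_ids))
  )
  class(m) <- c("community_matrix", class(matrix()))
  m
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf(
    "<community_matrix> %d OTUs x %d samples, %s total reads\n",
    nrow(x), ncol(x), format(sum(as.double(x)), big.mark = ",")
  ))
  k <- min(6L, nrow(x))
  j <- min(6L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

#' Per-sample totals (community sizes J)
#'
#' @param cm A [community_matrix()].
#' @return Named numeric vector of column sums.
#' @export
sample_sizes <- function(cm) {
  colSums(unclass(as_count_matrix(cm)))
}

# Accept a community_matrix or a plain labelled count matrix.
as_count_matrix <- function(cm) {
  if (inherits(cm, "community_matrix")) return(cm)
  if (is.matrix(cm) && is.numeric(cm)) return(community_matrix(cm))
  abort("expected a community_matrix or a numeric count matrix.")
}

#' Read an OTU table from tab-separated text
#'
#' Expects one header row of sample ids and one label column of OTU ids.
#' The `"#OTU ID"` header dialect of BIOM TSV exports is tolerated. The
#' returned matrix is always in canonical OTU-by-sample orientation.
#'
#' @param path Path to a TSV file.
#' @param orientation Orientation of the file: `"otus_as_rows"` (default,
#'   common OTU-table convention) or `"samples_as_rows"` (transposed input).
#' @return A [community_matrix()].
#' @export
read_otu_table <- function(path, orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  tb <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, comment = "", name_repair = "minimal"
  )
  if (ncol(tb) < 2) abort("OTU table needs a label column and at least one data column.")
  row_ids <- as.character(tb[[1]])
  col_ids <- names(tb)[-1]
  vals <- suppressWarnings(vapply(tb[-1], as.numeric, numeric(nrow(tb))))
  vals <- matrix(vals, nrow = nrow(tb), dimnames = list(row_ids, col_ids))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric cell at row '%s', column '%s'.",
      row_ids[bad[1, 1]], col_ids[bad[1, 2]]
    ))
  }
  bad <- which(vals < 0 | !is_whole(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "negative or non-integer cell at row '%s', column '%s'.",
      row_ids[bad[1, 1]], col_ids[bad[1, 2]]
    ))
  }
  if (orientation == "samples_as_rows") vals <- t(vals)
  community_matrix(vals)
}

#' Write an OTU table as tab-separated text
#'
#' Inverse of [read_otu_table()]: writing then reading reproduces the matrix
#' exactly, including label order.
#'
#' @param cm A [community_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(cm, path) {
  cm <- as_count_matrix(cm)
  tb <- tibble::as_tibble(unclass(cm), .name_repair = "minimal")
  tb <- tibble::add_column(tb, `#OTU ID` = rownames(cm), .before = 1)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Drop shallow samples from an OTU table
#'
#' Samples whose total read count falls below `min_reads` are excluded (the
#' conventional quality filter before a neutrality test), and OTUs whose row
#' total then becomes zero are dropped. The ids of dropped samples are
#' reported to standard error and attached as attribute `dropped_samples`.
#'
#' @param cm A [community_matrix()].
#' @param min_reads Minimum per-sample total to retain; default 100.
#' @return A filtered [community_matrix()].
#' @export
filter_min_reads <- function(cm, min_reads = 100) {
  cm <- as_count_matrix(cm)
  check_scalar(min_reads, "min_reads", lower = 1)
  totals <- colSums(unclass(cm))
  keep <- totals >= min_reads
  dropped <- colnames(cm)[!keep]
  if (!any(keep)) {
    abort(sprintf(
      "all %d samples fall below %d reads: empty result.", ncol(cm), min_reads
    ))
  }
  out <- unclass(cm)[, keep, drop = FALSE]
  out <- out[rowSums(out) > 0, , drop = FALSE]
  out <- community_matrix(out)
  if (length(dropped) > 0) {
    inform(sprintf(
      "dropped %d sample(s) below %d reads: %s",
      length(dropped), min_reads, paste(dropped, collapse = ", ")
    ))
  }
  attr(out, "dropped_samples") <- dropped
  out
}

#' Convert counts to relative abundances
#'
#' @param cm A [community_matrix()] (or count matrix); every sample must have
#'   a positive total.
#' @return A numeric matrix of proportions; each column sums to 1.
#' @export
to_relative_abundance <- function(cm) {
  cm <- as_count_matrix(cm)
  totals <- colSums(unclass(cm))
  if (any(totals == 0)) {
    abort(sprintf(
      "sample '%s' has zero total reads.", colnames(cm)[which(totals == 0)[1]]
    ))
  }
  sweep(matrix(as.double(unclass(cm)), nrow(cm), ncol(cm), dimnames = dimnames(cm)),
    2, totals, "/"
  )
}

# column-normalize a plain non-negative matrix (used by the null models)
normalize_columns <- function(mat) {
  totals <- colSums(mat)
  if (any(totals <= 0)) abort("cannot normalize a zero-total column.")
  sweep(mat, 2, totals, "/")
}

#' Species abundance distribution of one sample
#'
#' Extracts the abundance vector of a single sample, dropping zero-count
#' OTUs (all sampling-formula likelihoods condition on observed species).
#'
#' @param cm A [community_matrix()].
#' @param sample_id Sample (column) id.
#' @return A [sad_sample()].
#' @export
extract_sad <- function(cm, sample_id) {
  cm <- as_count_matrix(cm)
  if (!sample_id %in% colnames(cm)) {
    abort(sprintf("unknown sample id '%s'.", sample_id))
  }
  x <- unclass(cm)[, sample_id]
  sad_sample(x[x > 0])
}

#' Construct a species abundance distribution (SAD)
#'
#' @param abundances Vector of positive integer abundances, one per observed
#'   species.
#' @return An object of class `sad_sample` with fields `abundances`, `J`
#'   (total individuals) and `S` (species count).
#' @export
sad_sample <- function(abundances) {
  abundances <- unname(abundances)
  if (length(abundances) == 0) abort("empty abundance vector.")
  if (any(!is_whole(abundances)) || any(abundances < 1)) {
    abort("abundances must be positive integers.")
  }
  structure(
    list(
      abundances = as.integer(round(abundances)),
      J = as.integer(sum(abundances)),
      S = length(abundances)
    ),
    class = "sad_sample"
  )
}

#' @export
print.sad_sample <- function(x, ...) {
  cat(sprintf("<sad_sample> J = %d individuals, S = %d species\n", x$J, x$S))
  ab <- sort(x$abundances, decreasing = TRUE)
  cat("abundances:", paste(head(ab, 15), collapse = " "),
      if (x$S > 15) "..." else "", "\n")
  invisible(x)
}

as_sad <- function(x) {
  if (inherits(x, "sad_sample")) return(x)
  if (is.numeric(x)) return(sad_sample(x[x > 0]))
  abort("expected a sad_sample or an abundance vector.")
}
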