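test_that("TSV round trip preserves counts and label order exactly", {
  cm <- tiny_cm()
  path <- local_tsv()
  write_otu_table(cm, path)
  back <- read_otu_table(path)
  expect_identical(unclass(back), unclass(cm))
  expect_equal(unname(sample_sizes(back)), c(4, 2))

  cm2 <- random_cm(seed = 11)
  write_otu_table(cm2, path)
  expect_identical(unclass(read_otu_table(cm2 |> write_otu_table(path))),
                   unclass(cm2))
})

test_that("transposed input is restored to OTU-by-sample orientation", {
  cm <- random_cm(seed = 3)
  path <- local_tsv()
  tb <- tibble::as_tibble(t(unclass(cm)), .name_repair = "minimal")
  tb <- tibble::add_column(tb, sample = colnames(cm), .before = 1)
  readr::write_tsv(tb, path, progress = FALSE)
  back <- read_otu_table(path, orientation = "samples_as_rows")
  expect_identical(unclass(back), unclass(cm))
})

test_that("malformed tables are rejected with the offending cell named", {
  path <- local_tsv()
  writeLines(c("#OTU ID\ts1\ts2", "otuA\t3\t-1", "otuB\t1\t2"), path)
  expect_error(read_otu_table(path), "otuA.*s2")
  writeLines(c("id\ts1\ts2", "otuA\t3\tx", "otuB\t1\t2"), path)
  expect_error(read_otu_table(path), "non-numeric")
  writeLines(c("id\ts1\ts2", "otuA\t3\t1.5", "otuB\t1\t2"), path)
  expect_error(read_otu_table(path), "non-integer")
  writeLines(c("id\ts1\ts1", "otuA\t3\t1", "otuB\t1\t2"), path)
  expect_error(read_otu_table(path), "duplicate")
  expect_error(
    community_matrix(matrix(1, 2, 1, dimnames = list(c("a", "a"), "s"))),
    "duplicate"
  )
})

test_that("read filter drops shallow samples and is idempotent", {
  m <- cbind(s1 = c(50, 49), s2 = c(60, 40), s3 = c(4000, 1000))
  m[2, 1] <- 49 # totals: 99, 100, 5000
  rownames(m) <- c("a", "b")
  cm <- community_matrix(m)
  expect_message(f <- filter_min_reads(cm, 100), "s1")
  expect_equal(colnames(f), c("s2", "s3"))
  expect_equal(attr(f, "dropped_samples"), "s1")

  strip <- function(x) {
    x <- unclass(x)
    attr(x, "dropped_samples") <- NULL
    x
  }
  # identity when nothing is below threshold
  f2 <- filter_min_reads(f, 100)
  expect_identical(strip(f2), strip(f))

  # idempotence on a random table
  cm3 <- random_cm(n_otu = 20, n_samp = 8, lambda = 8, seed = 5)
  a <- suppressMessages(filter_min_reads(cm3, 120))
  b <- suppressMessages(filter_min_reads(a, 120))
  expect_identical(strip(a), strip(b))

  expect_error(filter_min_reads(cm, 10000), "empty result")
})

test_that("relative abundances are column-normalized proportions", {
  cm <- community_matrix(matrix(c(3, 1), 2, 1,
    dimnames = list(c("a", "b"), "s1")))
  expect_equal(as.numeric(to_relative_abundance(cm)), c(0.75, 0.25))

  cm2 <- community_matrix(matrix(c(5, 0, 0), 3, 1,
    dimnames = list(c("a", "b", "c"), "s1")))
  expect_equal(as.numeric(to_relative_abundance(cm2)), c(1, 0, 0))

  z <- community_matrix(matrix(c(1, 0), 1, 2,
    dimnames = list("a", c("ok", "empty"))))
  expect_error(to_relative_abundance(z), "empty")

  cm3 <- random_cm(seed = 9)
  rel <- to_relative_abundance(cm3)
  expect_true(all(abs(colSums(rel) - 1) <= 1e-12))
  # multiplying back by J recovers the integer counts exactly
  back <- sweep(rel, 2, sample_sizes(cm3), "*")
  expect_equal(round(back), unclass(cm3), ignore_attr = TRUE)
})

test_that("SAD extraction drops zero-count species and keeps J and S consistent", {
  cm <- community_matrix(matrix(c(4, 0, 2), 3, 1,
    dimnames = list(c("a", "b", "c"), "s1")))
  sad <- extract_sad(cm, "s1")
  expect_equal(sort(sad$abundances), c(2, 4))
  expect_equal(sad$J, 6)
  expect_equal(sad$S, 2)

  one <- extract_sad(community_matrix(matrix(1, 1, 1,
    dimnames = list("a", "s"))), "s")
  expect_equal(c(one$J, one$S), c(1, 1))

  expect_error(extract_sad(cm, "nope"), "unknown sample")
  expect_error(sad_sample(c(2, 0)), "positive integers")
  expect_error(sad_sample(c(1.5)), "positive integers")
})
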