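test_that("TPM columns are forced to one million and handle zero samples", {
  m <- matrix(c(10, 20, 0, 0), 2, 2,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  et <- expression_table(m, lengths = c(t1 = 1000, t2 = 2000))
  expect_warning(tpm <- compute_tpm(et), "all-zero")
  # equal length-normalised rates -> equal TPM shares
  expect_equal(unname(tpm$values[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(tpm$values[, "s2"]), c(0, 0))
  expect_equal(tpm$unit, "TPM")

  one <- expression_table(matrix(7, 1, 1, dimnames = list("t", "s")),
                          lengths = c(t = 123))
  expect_equal(unname(compute_tpm(one)$values[1, 1]), 1e6)
})

test_that("TPM column sums equal 1e6 on random count tables", {
  withr::local_seed(7)
  m <- matrix(rpois(200, 50), 20, 10)
  et <- make_et(m, lengths = setNames(sample(500:2000, 20),
                                      paste0("t", 1:20)))
  tpm <- compute_tpm(et)
  expect_equal(unname(colSums(tpm$values)), rep(1e6, 10), tolerance = 1e-9)
})

test_that("RPKM follows its definition and scales as expected", {
  m <- matrix(c(10, 0, 7), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
  lens <- c(t1 = 1000, t2 = 800, t3 = 1500)
  et <- expression_table(m, lengths = lens, lib_sizes = c(s1 = 1e6))
  r <- compute_rpkm(et)
  expect_equal(unname(r$values[, 1]),
               c(10, 0, 7 * 1e9 / (1500 * 1e6)))
  # same counts at library 2.5e6
  et2 <- expression_table(m, lengths = lens, lib_sizes = c(s1 = 2.5e6))
  expect_equal(unname(compute_rpkm(et2)$values[3, 1]),
               7 * 1e9 / (1500 * 2.5e6))
  # linear in counts, inverse in length and library size
  withr::local_seed(8)
  cnt <- matrix(rpois(60, 40), 20, 3)
  lens2 <- setNames(sample(500:3000, 20), paste0("t", 1:20))
  a <- make_et(cnt, lengths = lens2)
  b <- make_et(2 * cnt, lengths = lens2,
               lib_sizes = setNames(colSums(cnt), paste0("s", 1:3)))
  expect_equal(compute_rpkm(b)$values, 2 * compute_rpkm(a)$values)
  c2 <- make_et(cnt, lengths = 2 * lens2,
                lib_sizes = setNames(colSums(cnt), paste0("s", 1:3)))
  expect_equal(compute_rpkm(c2)$values, compute_rpkm(a)$values / 2)
  expect_error(compute_rpkm(make_et(cnt, lengths = lens2,
                                    lib_sizes = rep(0, 3))),
               "positive")
})

test_that("expression filter is inclusive at the boundary and monotone", {
  tpm <- make_et(matrix(c(0.5, 0.9, 0.99,
                          0, 0, 1.0,
                          5, 5, 5), 3, 3, byrow = TRUE), unit = "TPM")
  kept <- filter_expressed(tpm)
  expect_false("t1" %in% kept)  # never reaches 1
  expect_true("t2" %in% kept)   # exactly 1 once is enough
  expect_true("t3" %in% kept)
  expect_equal(filter_expressed(tpm, min_tpm = 0), paste0("t", 1:3))
  withr::local_seed(9)
  rt <- make_et(matrix(runif(300, 0, 4), 30, 10), unit = "TPM")
  thresholds <- sort(runif(5, 0, 4))
  keeps <- lapply(thresholds, function(th) filter_expressed(rt, th))
  for (i in seq_len(length(keeps) - 1L)) {
    expect_true(all(keeps[[i + 1L]] %in% keeps[[i]]))
  }
})

test_that("Spearman sample QC handles duplicates, reversals, ties, constants", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 4, 2))
  rownames(m) <- paste0("t", 1:3)
  rho <- sample_correlation(expression_table(m, unit = "TPM"))
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), c(1, 1, 1))
  expect_equal(rho["s1", "s2"], 1)
  expect_equal(rho["s1", "s3"], -1)  # strictly decreasing transform

  # ties: equals Pearson on average ranks
  x <- c(1, 2, 2, 3, 4)
  y <- c(10, 20, 20, 15, 30)
  m2 <- cbind(s1 = x, s2 = y)
  rownames(m2) <- paste0("t", 1:5)
  rho2 <- sample_correlation(expression_table(m2, unit = "TPM"))
  expect_equal(rho2["s1", "s2"], cor(rank(x), rank(y)))

  m3 <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5))
  rownames(m3) <- paste0("t", 1:3)
  expect_warning(rho3 <- sample_correlation(expression_table(m3, unit = "TPM")),
                 "constant")
  expect_true(is.na(rho3["s1", "s2"]))
  expect_equal(unname(diag(rho3)), c(1, 1))
})

test_that("table readers validate and round-trip", {
  d <- withr::local_tempdir()
  cf <- file.path(d, "counts.tsv")
  writeLines(c("transcript_id\ts1\ts2", "t1\t5\t8", "t2\t0\t3"), cf)
  et <- read_count_matrix(cf)
  expect_equal(et$values, matrix(c(5, 0, 8, 3), 2, 2,
                                 dimnames = list(c("t1", "t2"),
                                                 c("s1", "s2"))))
  expect_equal(unname(et$lib_sizes), c(5, 11))  # column-sum fallback

  lf <- file.path(d, "lengths.tsv")
  writeLines(c("transcript_id\tlength", "t1\t1000", "t2\t500"), lf)
  expect_equal(read_lengths(lf), c(t1 = 1000, t2 = 500))
  fa <- file.path(d, "seqs.fa")
  writeLines(c(">t1 some desc", "ACGTACGT", ">t2", "ACG"), fa)
  skip_if_not_installed("Biostrings")
  expect_equal(read_lengths(fa), c(t1 = 8, t2 = 3))

  sf <- file.path(d, "samples.tsv")
  writeLines(c("sample_id\ttaxon\tcondition\treplicate",
               "x\tP1\t30C\t1", "y\tP1\t30C\t1"), sf)
  expect_error(read_sample_meta(sf), "duplicate")
  writeLines(c("sample_id\ttaxon\tcondition\treplicate",
               "x\tP3\t30C\t1"), sf)
  expect_error(read_sample_meta(sf), "taxon")

  bf <- file.path(d, "libs.tsv")
  writeLines(c("sample_id\tlib_size", "s1\t1000000", "s2\t900000"), bf)
  expect_equal(read_lib_sizes(bf), c(s1 = 1e6, s2 = 9e5))
})
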