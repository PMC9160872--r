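test_that("configuration validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(pattern_frequencies = c(no_change = 1)),
               "six bins")
  bad <- c(no_change = 0.9, additivity = 0.2, ELD_P1 = 0, ELD_P2 = 0,
           transgressive_up = 0, transgressive_down = 0)
  expect_error(sim_config(pattern_frequencies = bad), "sum to 1")
  expect_error(sim_config(dispersion = -1))
  expect_error(sim_config(n_replicates = 1))
})

test_that("the same seed reproduces the experiment exactly", {
  cfg <- sim_config(n_pairs = 30, seed = 123)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts_p1, b$counts_p1)
  expect_identical(a$counts_f1, b$counts_f1)
  expect_identical(a$truth, b$truth)
  expect_identical(a$lib_sizes, b$lib_sizes)
  # and the global RNG stream is untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_experiment(cfg))
  expect_identical(runif(1), before)
  # different seed, different data
  expect_false(identical(
    simulate_experiment(sim_config(n_pairs = 30, seed = 124))$counts_f1,
    a$counts_f1))
})

test_that("planted bias fixes the homeolog count ratio at Poisson scale", {
  cfg <- sim_config(n_pairs = 20, conditions = "30C", baseline_mean = 1e6,
                    dispersion = 0, expr_sd = 0, depth_sd = 0,
                    length_range = c(1000, 1000),
                    pattern_frequencies = c(no_change = 1, additivity = 0,
                                            ELD_P1 = 0, ELD_P2 = 0,
                                            transgressive_up = 0,
                                            transgressive_down = 0),
                    seed = 11)
  sim <- simulate_experiment(cfg, true_bias = 1)
  n <- nrow(sim$pairs)
  spt <- rowSums(sim$counts_f1[seq_len(n), ])
  spc <- rowSums(sim$counts_f1[n + seq_len(n), ])
  expect_true(all(abs(spt / spc - 2) < 0.01))
})

test_that("planted truth is internally consistent and recoverable", {
  cfg <- sim_config(n_pairs = 300, baseline_mean = 800, seed = 12)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$truth), 300 * 3)
  expect_true(all(sim$truth$bin %in% c("no_change", "additivity", "ELD_P1",
                                       "ELD_P2", "transgressive_up",
                                       "transgressive_down")))
  # bias estimate tracks the planted value at high counts
  cfg2 <- sim_config(n_pairs = 800, conditions = "30C", baseline_mean = 1000,
                     dispersion = 0.05, expr_sd = 0,
                     length_range = c(1000, 1000),
                     pattern_frequencies = c(no_change = 1, additivity = 0,
                                             ELD_P1 = 0, ELD_P2 = 0,
                                             transgressive_up = 0,
                                             transgressive_down = 0),
                     seed = 13)
  sim2 <- simulate_experiment(cfg2, true_bias = 1)
  r <- sim_rpkm(sim2)
  bhat <- vapply(seq_len(800), function(i) {
    heb_statistic(r$f1$values[sim2$pairs$p1_id[i], ],
                  r$f1$values[sim2$pairs$p2_id[i], ])
  }, numeric(1))
  expect_lt(abs(mean(bhat) - 1), 0.05)
})

test_that("planted no-change pairs are recovered at the t-test's own size", {
  alpha <- 0.05
  cfg <- sim_config(n_pairs = 400, conditions = "30C", baseline_mean = 1000,
                    dispersion = 0.001,
                    pattern_frequencies = c(no_change = 1, additivity = 0,
                                            ELD_P1 = 0, ELD_P2 = 0,
                                            transgressive_up = 0,
                                            transgressive_down = 0),
                    seed = 14)
  sim <- simulate_experiment(cfg)
  r <- sim_rpkm(sim)
  calls <- classify_patterns(sim$pairs, r$p1, r$p2, r$f1, sim$meta,
                             alpha = alpha)
  rate <- mean(calls$bin == "no_change")
  # two independent hybrid-vs-parent tests each reject at ~alpha
  expect_gte(rate, 1 - 2 * alpha - 3 * sqrt(0.1 * 0.9 / 400))
})

test_that("fixtures round-trip and regenerate bit-identically", {
  cfg <- sim_config(n_pairs = 20, seed = 42)
  sim <- simulate_experiment(cfg)
  d <- withr::local_tempdir()
  files <- write_fixture(sim, d)
  expect_true(all(file.exists(files)))
  back <- read_count_matrix(files[["counts_f1"]],
                            lengths = read_lengths(files[["lengths"]]))
  expect_equal(back$values, sim$counts_f1, ignore_attr = FALSE)
  expect_equal(read_lib_sizes(files[["lib_sizes"]]), sim$lib_sizes)
  truth <- utils::read.delim(files[["truth"]], stringsAsFactors = FALSE)
  expect_equal(nrow(truth), 20 * 3)
  meta <- read_sample_meta(files[["samples"]])
  expect_equal(nrow(meta), 27)

  # the committed fixture is exactly this experiment at its recorded seed
  shipped <- system.file("extdata", "sim20", package = "homeobias")
  skip_if(shipped == "", "installed fixture not found")
  for (nm in names(files)) {
    expect_identical(readLines(files[[nm]]),
                     readLines(file.path(shipped, basename(files[[nm]]))),
                     info = nm)
  }
})
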