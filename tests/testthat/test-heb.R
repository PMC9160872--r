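test_that("bias statistic is the base-2 log ratio of homeolog means", {
  expect_equal(heb_statistic(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(heb_statistic(c(80, 80, 80), c(10, 10, 10)), 3)
  expect_equal(heb_statistic(c(10, 10, 10), c(80, 80, 80)), -3)
  # antisymmetry under parent relabelling
  withr::local_seed(41)
  for (i in 1:30) {
    a <- rgamma(3, 5)
    b <- rgamma(3, 5)
    expect_equal(heb_statistic(a, b), -heb_statistic(b, a))
  }
  expect_error(heb_statistic(c(0, 0, 0), c(1, 2, 3)), "excluded")
})

test_that("fold change reproduces the log identity", {
  expect_equal(fold_change(3), 8)
  expect_equal(fold_change(0), 1)
  expect_equal(round(fold_change(2.21), 1), 4.6)
  expect_equal(fold_change(-2), fold_change(2))
  expect_error(fold_change(Inf), "finite")
})

test_that("bias LRT matches direct binomial log-likelihood evaluation", {
  r <- heb_lrt(50, 50)
  expect_equal(r$lrt_stat, 0)
  expect_equal(r$p_value, 1)

  # hand-evaluated statistic for the 80/20 split under an equal-length null
  r <- heb_lrt(80, 20)
  expect_equal(r$lrt_stat, 2 * (80 * log(80 / 50) + 20 * log(20 / 50)))
  expect_lt(r$p_value, 1e-3)

  # counts proportional to lengths satisfy the length-expected null exactly
  r <- heb_lrt(20, 10, len_spt = 2000, len_spc = 1000)
  expect_equal(r$lrt_stat, 0)

  # replicate vectors are summed
  expect_equal(heb_lrt(c(30, 30, 20), c(5, 10, 5))$lrt_stat,
               heb_lrt(80, 20)$lrt_stat)

  # random pairs against an independent dbinom oracle
  withr::local_seed(42)
  for (i in 1:200) {
    x <- rpois(1, 60)
    y <- rpois(1, 40)
    if (x + y == 0) next
    l1 <- sample(500:3000, 1)
    l2 <- sample(500:3000, 1)
    pi0 <- l1 / (l1 + l2)
    got <- heb_lrt(x, y, l1, l2)
    oracle <- max(0, 2 * (dbinom(x, x + y, x / (x + y), log = TRUE) -
                            dbinom(x, x + y, pi0, log = TRUE)))
    expect_lt(abs(got$lrt_stat - oracle), 1e-9)
    expect_equal(got$p_value, pchisq(oracle, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }

  expect_error(heb_lrt(-1, 5), "non-negative")
  expect_error(heb_lrt(0, 0), "excluded")
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  # hand-computed step-up on an uneven vector:
  # sorted p = (.005, .02, .03, .5); q_(i) = min_{j>=i} p_(j)*4/j
  p <- c(0.03, 0.005, 0.5, 0.02)
  expect_equal(bh_fdr(p), c(0.04, 0.02, 0.5, 0.04))
  # permutation equivariance
  withr::local_seed(43)
  pv <- runif(25)
  perm <- sample(25)
  expect_equal(bh_fdr(pv)[perm], bh_fdr(pv[perm]))
  expect_true(all(bh_fdr(pv) >= pv))
  expect_error(bh_fdr(c(0.2, 1.1)), "\\[0, 1\\]")
})

test_that("delta bias is the exact difference of the two biases", {
  expect_equal(delta_heb(1.3, 1.3), 0)
  expect_equal(delta_heb(-1, 2.55), 3.55)
  expect_equal(round(fold_change(delta_heb(-1, 2.55)), 1), 11.7)
  withr::local_seed(44)
  b <- rnorm(20)
  d <- rnorm(20)
  expect_equal(delta_heb(b, d), -delta_heb(d, b))
})

test_that("bias-change LRT equals the 2x2 G-test of homogeneity", {
  r <- delta_heb_lrt(40, 60, 40, 60)
  expect_equal(r$lrt_stat, 0)
  expect_equal(r$p_value, 1)

  r <- delta_heb_lrt(80, 20, 20, 80)
  expect_equal(r$lrt_stat, oracle_g2x2(80, 20, 20, 80), tolerance = 1e-12)
  expect_lt(r$p_value, 1e-10)

  withr::local_seed(45)
  for (i in 1:150) {
    tb <- rpois(4, sample(c(3, 30, 300), 1))
    if (tb[1] + tb[2] == 0 || tb[3] + tb[4] == 0) next
    got <- delta_heb_lrt(tb[1], tb[2], tb[3], tb[4])
    expect_lt(abs(got$lrt_stat - oracle_g2x2(tb[1], tb[2], tb[3], tb[4])),
              1e-9)
  }
  expect_error(delta_heb_lrt(0, 0, 5, 5), "excluded")
})

test_that("bias-change LRT holds its size under a constant true bias", {
  # constant-bias null with Poisson replicate noise: the chi-square
  # reference should reject at ~alpha
  withr::local_seed(46)
  n <- 10000
  b <- sample(c(-2, -1, 0, 1, 2), n, replace = TRUE)
  pr <- 2^b / (1 + 2^b)
  p <- numeric(n)
  for (i in seq_len(n)) {
    p[i] <- delta_heb_lrt(rpois(3, 600 * pr[i]), rpois(3, 600 * (1 - pr[i])),
                          rpois(3, 600 * pr[i]), rpois(3, 600 * (1 - pr[i])))$p_value
  }
  expect_gt(mean(p < 0.05), 0.04)
  expect_lt(mean(p < 0.05), 0.06)
})

test_that("per-condition tests flip direction when parents are relabelled", {
  sim <- simulate_experiment(sim_config(n_pairs = 40, conditions = "30C",
                                        baseline_mean = 300, seed = 47))
  lens <- sim$lengths
  et <- expression_table(sim$counts_f1, lengths = lens,
                         lib_sizes = sim$lib_sizes[colnames(sim$counts_f1)])
  rpkm <- compute_rpkm(et)
  fwd <- heb_condition_test(sim$pairs, et, rpkm, sim$meta, "30C")
  swapped_pairs <- data.frame(p1_id = sim$pairs$p2_id,
                              p2_id = sim$pairs$p1_id,
                              stringsAsFactors = FALSE)
  rev <- heb_condition_test(swapped_pairs, et, rpkm, sim$meta, "30C")
  tst <- fwd$testable
  expect_equal(rev$testable, tst)
  expect_equal(rev$B[tst], -fwd$B[tst])
  expect_equal(rev$lrt_stat[tst], fwd$lrt_stat[tst], tolerance = 1e-12)
  expect_equal(rev$q_value[tst], fwd$q_value[tst])
  flip <- c(toward_Spt = "toward_Spc", toward_Spc = "toward_Spt",
            none = "none")
  expect_equal(rev$direction[tst], unname(flip[fwd$direction[tst]]))
  expect_true(all(fwd$q_value[tst] >= fwd$p_value[tst]))
})

test_that("bias summaries reduce results to the headline numbers", {
  res <- data.frame(B = c(2, 2, -1, 0.2, -0.1),
                    q_value = c(0.01, 0.02, 0.001, 0.5, 0.9),
                    testable = TRUE)
  s <- summarize_bias(res)
  expect_equal(s$n_toward_spt, 2)
  expect_equal(s$n_toward_spc, 1)
  expect_equal(s$mean_b_spt, 2)
  expect_equal(s$fold_spt, 4)
  expect_equal(s$mean_b_spc, -1)
  expect_equal(s$fold_spc, 2)
  expect_equal(s$pct_biased, 100 * 3 / 5)
  expect_equal(s$mean_b_overall, mean(res$B))

  none <- data.frame(B = c(1, -1), q_value = c(0.5, 0.6), testable = TRUE)
  s0 <- summarize_bias(none)
  expect_equal(s0$n_toward_spt + s0$n_toward_spc, 0)
  expect_true(is.na(s0$mean_b_spt) && is.na(s0$fold_spc))
  expect_error(summarize_bias(none[0, ]), "non-empty")
})
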