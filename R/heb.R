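# Homeolog expression bias: the base-2 log-ratio statistic B, its binomial
# likelihood-ratio test against length-expected equal expression, BH-FDR,
# the between-condition bias change (delta-HEB) and its homogeneity G-test,
# and summary reductions.

#' Homeolog expression bias statistic
#'
#' B is the base-2 log ratio of the mean expression of the two homeologs
#' within the hybrid,
#' `B = log2(mean(spt_rpkm) / mean(spc_rpkm))`, i.e. the replicate-count
#' prefactor times the ratio of RPKM sums; with equal replicate numbers
#' (always the case in one hybrid library set) this equals
#' `log2(sum(spt) / sum(spc))`. B = 0 means no bias; B = 3 an 8-fold bias
#' toward the P1 (Spt) homeolog; negative values favour P2 (Spc).
#'
#' @param spt_rpkm,spc_rpkm Per-replicate RPKM vectors of the P1- and
#'   P2-derived homeologs in the hybrid. Each must have a positive sum;
#'   pairs failing this are excluded upstream.
#' @return The bias `B`, a finite number.
#' @export
heb_statistic <- function(spt_rpkm, spc_rpkm) {
  if (any(spt_rpkm < 0) || any(spc_rpkm < 0)) {
    stop("RPKM values must be non-negative")
  }
  if (sum(spt_rpkm) == 0 || sum(spc_rpkm) == 0) {
    stop("excluded pair: both homeologs need non-zero expression")
  }
  log2(mean(spt_rpkm) / mean(spc_rpkm))
}

#' Fold change implied by a bias value
#'
#' @param B Bias value(s) on the base-2 log scale (HEB or delta-HEB).
#' @return `2^|B|`, always >= 1.
#' @examples
#' fold_change(3)     # 8-fold
#' fold_change(-2.39) # ~5.2-fold
#' @export
fold_change <- function(B) {
  if (any(!is.finite(B))) stop("B must be finite")
  2^abs(B)
}

# x*log(p) with the 0*log(0) = 0 convention.
xlogp <- function(x, p) ifelse(x == 0, 0, x * log(p))

#' Likelihood-ratio test for homeolog expression bias
#'
#' Binomial likelihood-ratio test on the summed read counts of the two
#' homeologs in the hybrid. Under the null of equal underlying expression
#' the P1-homeolog read proportion is the length-expected
#' `pi0 = len_spt / (len_spt + len_spc)` (a longer transcript draws
#' proportionally more reads); under the alternative it is the MLE
#' `x_spt / (x_spt + x_spc)`. The statistic `2 * (l1 - l0)` is referred
#' to a chi-square distribution with 1 df.
#'
#' @param spt_counts,spc_counts Non-negative integer read counts for the
#'   two homeologs (replicate vectors are summed).
#' @param len_spt,len_spc Transcript lengths in bp (default equal).
#' @return List with `lrt_stat` (>= 0) and `p_value`.
#' @export
heb_lrt <- function(spt_counts, spc_counts, len_spt = 1, len_spc = 1) {
  if (any(spt_counts < 0) || any(spc_counts < 0)) {
    stop("read counts must be non-negative")
  }
  if (len_spt <= 0 || len_spc <= 0) stop("lengths must be positive")
  x <- sum(spt_counts)
  y <- sum(spc_counts)
  n <- x + y
  if (n < 1) stop("excluded pair: zero total read count")
  pi0 <- len_spt / (len_spt + len_spc)
  p1 <- x / n
  ll0 <- xlogp(x, pi0) + xlogp(y, 1 - pi0)
  ll1 <- xlogp(x, p1) + xlogp(y, 1 - p1)
  stat <- max(0, 2 * (ll1 - ll0))
  list(lrt_stat = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH q-values, `q_(i) = min_(j>=i) p_(j) * m / j` clipped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Change in homeolog expression bias between two conditions
#'
#' By definition `delta = B2 - B1`: positive values mean the bias moved
#' toward the P1 (Spt) homeolog at condition 2 relative to condition 1.
#'
#' @param b1,b2 Finite bias values at the two conditions.
#' @return `b2 - b1`.
#' @export
delta_heb <- function(b1, b2) {
  if (any(!is.finite(b1)) || any(!is.finite(b2))) stop("biases must be finite")
  b2 - b1
}

#' Likelihood-ratio test for a change in homeolog bias
#'
#' G-test of homogeneity of the homeolog read proportion across two
#' conditions, on the 2x2 table of summed counts
#' (conditions x homeologs). Because both homeologs keep their lengths
#' across conditions, the length offsets cancel: under the null there is
#' one common P1-read proportion, under the alternative one per
#' condition. The statistic is referred to chi-square with 1 df.
#'
#' @param spt1,spc1 Homeolog read counts at condition 1 (vectors summed).
#' @param spt2,spc2 Homeolog read counts at condition 2.
#' @return List with `lrt_stat` (the G statistic, >= 0) and `p_value`.
#' @export
delta_heb_lrt <- function(spt1, spc1, spt2, spc2) {
  if (any(c(spt1, spc1, spt2, spc2) < 0)) {
    stop("read counts must be non-negative")
  }
  x1 <- sum(spt1); y1 <- sum(spc1)
  x2 <- sum(spt2); y2 <- sum(spc2)
  n1 <- x1 + y1
  n2 <- x2 + y2
  if (n1 < 1 || n2 < 1) stop("excluded pair: zero total count in a condition")
  p0 <- (x1 + x2) / (n1 + n2)
  ll <- function(x, y, p) xlogp(x, p) + xlogp(y, 1 - p)
  stat <- 2 * (ll(x1, y1, x1 / n1) + ll(x2, y2, x2 / n2) -
                 ll(x1, y1, p0) - ll(x2, y2, p0))
  stat <- max(0, stat)
  list(lrt_stat = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-condition homeolog bias tests for all pairs
#'
#' For one condition, computes B from hybrid RPKM, the binomial LRT from
#' hybrid read counts with length-expected null, BH q-values across all
#' testable pairs, and direction calls. Pairs with a zero summed count in
#' either homeolog are excluded from testing (`testable = FALSE`, `B`
#' and p-values `NA`).
#'
#' @param pairs Data frame with `p1_id`, `p2_id`.
#' @param counts_f1 Hybrid [expression_table()] with unit `count` and
#'   lengths for both homeologs.
#' @param rpkm_f1 Matching hybrid RPKM table.
#' @param meta Sample metadata.
#' @param condition Condition label to test.
#' @param fdr_threshold BH-FDR significance cutoff, default 0.05.
#' @return Data frame with one row per pair: `pair_id`, `p1_id`,
#'   `p2_id`, `condition`, `testable`, `B`, `lrt_stat`, `p_value`,
#'   `q_value`, `significant`, `direction` (`toward_Spt` / `toward_Spc`
#'   / `none`).
#' @export
heb_condition_test <- function(pairs, counts_f1, rpkm_f1, meta, condition,
                               fdr_threshold = 0.05) {
  stopifnot(inherits(counts_f1, "expression_table"),
            inherits(rpkm_f1, "expression_table"))
  if (counts_f1$unit != "count") stop("counts_f1 must hold counts")
  if (is.null(counts_f1$lengths)) stop("counts_f1 needs transcript lengths")
  samp <- meta$sample_id[meta$taxon == "F1" & meta$condition == condition]
  if (length(samp) == 0L) stop("no hybrid samples for condition ", condition)
  n <- nrow(pairs)
  res <- data.frame(pair_id = paste(pairs$p1_id, pairs$p2_id, sep = "|"),
                    p1_id = pairs$p1_id, p2_id = pairs$p2_id,
                    condition = condition, testable = FALSE,
                    B = NA_real_, lrt_stat = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, significant = FALSE,
                    direction = "none", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    spt_c <- counts_f1$values[pairs$p1_id[i], samp]
    spc_c <- counts_f1$values[pairs$p2_id[i], samp]
    if (sum(spt_c) == 0 || sum(spc_c) == 0) next
    res$testable[i] <- TRUE
    res$B[i] <- heb_statistic(rpkm_f1$values[pairs$p1_id[i], samp],
                              rpkm_f1$values[pairs$p2_id[i], samp])
    lrt <- heb_lrt(spt_c, spc_c,
                   len_spt = counts_f1$lengths[[pairs$p1_id[i]]],
                   len_spc = counts_f1$lengths[[pairs$p2_id[i]]])
    res$lrt_stat[i] <- lrt$lrt_stat
    res$p_value[i] <- lrt$p_value
  }
  testable <- which(res$testable)
  if (length(testable) > 0L) {
    res$q_value[testable] <- bh_fdr(res$p_value[testable])
    sig <- res$q_value[testable] < fdr_threshold
    res$significant[testable] <- sig
    res$direction[testable] <- ifelse(!sig, "none",
                                      ifelse(res$B[testable] > 0,
                                             "toward_Spt", "toward_Spc"))
  }
  res
}

#' Bias-change tests between two conditions for all pairs
#'
#' Tests, for every pair testable at both conditions, whether the
#' homeolog read proportion differs between the conditions
#' ([delta_heb_lrt()]), and reports `delta = B2 - B1`. Significance uses
#' the raw chi-square p-value at `alpha` (no FDR adjustment here).
#'
#' @param pairs Data frame with `p1_id`, `p2_id`.
#' @param counts_f1 Hybrid count [expression_table()].
#' @param meta Sample metadata.
#' @param cond1,cond2 The two condition labels (delta is condition 2
#'   minus condition 1).
#' @param heb1,heb2 Results of [heb_condition_test()] at the two
#'   conditions (for `B` and testability).
#' @param alpha Significance level, default 0.05.
#' @return Data frame with one row per pair testable at both
#'   conditions: `pair_id`, `condition_1`, `condition_2`, `B1`, `B2`,
#'   `delta`, `lrt_stat`, `p_value`, `significant`, `direction` of the
#'   bias increase (`toward_Spt` when delta > 0).
#' @export
delta_heb_condition_test <- function(pairs, counts_f1, meta, cond1, cond2,
                                     heb1, heb2, alpha = 0.05) {
  s1 <- meta$sample_id[meta$taxon == "F1" & meta$condition == cond1]
  s2 <- meta$sample_id[meta$taxon == "F1" & meta$condition == cond2]
  ok <- heb1$testable & heb2$testable
  idx <- which(ok)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lrt <- delta_heb_lrt(counts_f1$values[pairs$p1_id[i], s1],
                         counts_f1$values[pairs$p2_id[i], s1],
                         counts_f1$values[pairs$p1_id[i], s2],
                         counts_f1$values[pairs$p2_id[i], s2])
    d <- delta_heb(heb1$B[i], heb2$B[i])
    sig <- lrt$p_value < alpha
    rows[[k]] <- data.frame(pair_id = heb1$pair_id[i],
                            condition_1 = cond1, condition_2 = cond2,
                            B1 = heb1$B[i], B2 = heb2$B[i], delta = d,
                            lrt_stat = lrt$lrt_stat, p_value = lrt$p_value,
                            significant = sig,
                            direction = if (!sig) "none" else
                              if (d > 0) "toward_Spt" else "toward_Spc",
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pair_id = character(), condition_1 = character(),
               condition_2 = character(), B1 = numeric(), B2 = numeric(),
               delta = numeric(), lrt_stat = numeric(), p_value = numeric(),
               significant = logical(), direction = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise homeolog bias results for one condition
#'
#' Reduces a set of per-pair bias results to the headline numbers:
#' counts of significantly biased pairs toward each parent, the mean B
#' within each significant direction and its fold change, the overall
#' mean B across all testable pairs, and the percentage of biased pairs.
#'
#' @param results Data frame from [heb_condition_test()] (needs `B`,
#'   `q_value`, `testable`); rows from one condition.
#' @param fdr_threshold Significance cutoff on the q-value, default 0.05.
#' @return List with `n_testable`, `n_significant`, `pct_biased`,
#'   `n_toward_spt`, `n_toward_spc`, `mean_b_spt`, `fold_spt`,
#'   `mean_b_spc`, `fold_spc` (direction means `NA` when a direction has
#'   no significant pairs) and `mean_b_overall`.
#' @export
summarize_bias <- function(results, fdr_threshold = 0.05) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("summarize_bias requires a non-empty result set")
  }
  if (!is.null(results$testable)) {
    results <- results[results$testable, , drop = FALSE]
  }
  n <- nrow(results)
  if (n == 0L) stop("no testable pairs to summarise")
  sig <- results$q_value < fdr_threshold
  spt <- sig & results$B > 0
  spc <- sig & results$B < 0
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  mean_b_spt <- mean_or_na(results$B[spt])
  mean_b_spc <- mean_or_na(results$B[spc])
  list(n_testable = n,
       n_significant = sum(sig),
       pct_biased = 100 * sum(sig) / n,
       n_toward_spt = sum(spt),
       n_toward_spc = sum(spc),
       mean_b_spt = mean_b_spt,
       fold_spt = if (is.na(mean_b_spt)) NA_real_ else fold_change(mean_b_spt),
       mean_b_spc = mean_b_spc,
       fold_spc = if (is.na(mean_b_spc)) NA_real_ else fold_change(mean_b_spc),
       mean_b_overall = mean(results$B))
}
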