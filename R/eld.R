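# Expression-level-dominance classification: thirteen expression patterns
# of a hybrid relative to its parents, binned into five categories.

# Roman-numeral pattern -> 5-way bin (no_change folds in as a 6th label).
PATTERN_BINS <- c(I = "additivity", XII = "additivity",
                  IV = "ELD_P1", IX = "ELD_P1",
                  II = "ELD_P2", XI = "ELD_P2",
                  V = "transgressive_up", VI = "transgressive_up",
                  VIII = "transgressive_up",
                  III = "transgressive_down", VII = "transgressive_down",
                  X = "transgressive_down",
                  NO_CHANGE = "no_change")

PATTERN_LEVELS <- names(PATTERN_BINS)
BIN_LEVELS <- c("no_change", "additivity", "ELD_P1", "ELD_P2",
                "transgressive_up", "transgressive_down")

#' Classic two-sample Student's t-test
#'
#' Pooled-variance two-sample t-test with a two-sided p-value on
#' `n_x + n_y - 2` degrees of freedom, plus the direction of the mean
#' difference. Unlike [stats::t.test()], degenerate replicate vectors are
#' handled explicitly: two identical constant vectors give p = 1, and a
#' zero pooled variance with unequal means gives p = 0 with a warning.
#'
#' @param x,y Numeric replicate vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p_value` and
#'   `direction` (`"greater"`, `"less"` or `"equal_means"`, the sign of
#'   `mean(x) - mean(y)`).
#' @export
students_t_test <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs >= 2 replicates")
  if (anyNA(x) || anyNA(y)) stop("replicate values must not be missing")
  mx <- mean(x)
  my <- mean(y)
  df <- nx + ny - 2L
  direction <- if (mx > my) "greater" else if (mx < my) "less" else "equal_means"
  pooled <- (sum((x - mx)^2) + sum((y - my)^2)) / df
  if (pooled == 0) {
    if (mx == my) {
      return(list(statistic = 0, df = df, p_value = 1,
                  direction = "equal_means"))
    }
    warning("zero pooled variance with unequal means; p = 0")
    return(list(statistic = sign(mx - my) * Inf, df = df, p_value = 0,
                direction = direction))
  }
  tstat <- (mx - my) / sqrt(pooled * (1 / nx + 1 / ny))
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df),
       direction = direction)
}

#' Classify one homeolog pair into an expression pattern
#'
#' Compares the hybrid's total expression (sum of both homeologs, per
#' replicate) against each parent with three pooled-variance t-tests
#' (hybrid vs P1, hybrid vs P2, P1 vs P2); groups are called "different"
#' when p < `alpha`. The decision table:
#'
#' * hybrid equivalent to both parents: `NO_CHANGE` (with
#'   `conflict_flag` when the parents nevertheless differ — the
#'   intransitive triple);
#' * equivalent to P1 only: P1 expression level dominance (`IV` when
#'   mean(P1) > mean(P2), else `IX`);
#' * equivalent to P2 only: P2 dominance (`II` when mean(P2) > mean(P1),
#'   else `XI`);
#' * different from both, above both parental means: transgressive
#'   up-regulation (`VI` when the parents are equivalent, else `V`/`VIII`
#'   by parental order);
#' * different from both, below both: transgressive down-regulation
#'   (`VII`/`III`/`X` likewise);
#' * different from both, parents differ, hybrid mean strictly between:
#'   additivity (`XII` when mean(P1) < mean(P2), else `I`);
#' * any residual combination: `NO_CHANGE` with `conflict_flag`.
#'
#' @param hybrid_total Per-replicate hybrid total expression (RPKM).
#' @param p1_expr,p2_expr Per-replicate parental expression (RPKM).
#' @param alpha Significance level for each t-test, default 0.05.
#' @param log2_transform Run the tests on `log2(x + 1)` instead of the
#'   raw scale (off by default).
#' @return One-row data frame: `pattern`, `bin`, `conflict_flag`,
#'   `p_h_vs_p1`, `p_h_vs_p2`, `p_p1_vs_p2`, `mean_hybrid`, `mean_p1`,
#'   `mean_p2`.
#' @export
classify_pattern <- function(hybrid_total, p1_expr, p2_expr, alpha = 0.05,
                             log2_transform = FALSE) {
  if (any(hybrid_total < 0) || any(p1_expr < 0) || any(p2_expr < 0)) {
    stop("expression values must be non-negative")
  }
  h <- hybrid_total
  p1 <- p1_expr
  p2 <- p2_expr
  if (log2_transform) {
    h <- log2(h + 1)
    p1 <- log2(p1 + 1)
    p2 <- log2(p2 + 1)
  }
  t_h1 <- students_t_test(h, p1)
  t_h2 <- students_t_test(h, p2)
  t_12 <- students_t_test(p1, p2)
  diff_h1 <- t_h1$p_value < alpha
  diff_h2 <- t_h2$p_value < alpha
  diff_12 <- t_12$p_value < alpha
  mh <- mean(h)
  m1 <- mean(p1)
  m2 <- mean(p2)

  conflict <- FALSE
  if (!diff_h1 && !diff_h2) {
    pattern <- "NO_CHANGE"
    conflict <- diff_12
  } else if (!diff_h1 && diff_h2) {
    pattern <- if (m1 > m2) "IV" else "IX"
  } else if (diff_h1 && !diff_h2) {
    pattern <- if (m2 > m1) "II" else "XI"
  } else if (mh > m1 && mh > m2) {
    pattern <- if (!diff_12) "VI" else if (m1 < m2) "V" else "VIII"
  } else if (mh < m1 && mh < m2) {
    pattern <- if (!diff_12) "VII" else if (m1 < m2) "III" else "X"
  } else if (diff_12 && mh > min(m1, m2) && mh < max(m1, m2)) {
    pattern <- if (m1 < m2) "XII" else "I"
  } else {
    pattern <- "NO_CHANGE"
    conflict <- TRUE
  }

  data.frame(pattern = pattern,
             bin = unname(PATTERN_BINS[pattern]),
             conflict_flag = conflict,
             p_h_vs_p1 = t_h1$p_value,
             p_h_vs_p2 = t_h2$p_value,
             p_p1_vs_p2 = t_12$p_value,
             mean_hybrid = mh, mean_p1 = m1, mean_p2 = m2,
             stringsAsFactors = FALSE)
}

#' Classify all homeolog pairs, per condition
#'
#' Runs [classify_pattern()] for every homeolog pair in every condition.
#' The hybrid total is the per-replicate sum of the two homeologs' RPKM
#' in the hybrid; parental expression comes from the matching parental
#' RPKM tables.
#'
#' @param pairs Data frame with `p1_id`, `p2_id`.
#' @param rpkm_p1,rpkm_p2,rpkm_f1 [expression_table()]s with unit `RPKM`
#'   for the two parents and the hybrid (the hybrid table contains both
#'   homeologs' rows).
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param conditions Conditions to classify, default all in `meta`.
#' @param alpha Per-test significance level, default 0.05.
#' @param log2_transform Passed to [classify_pattern()].
#' @return Data frame with one row per pair per condition: `pair_id`,
#'   `p1_id`, `p2_id`, `condition` and the [classify_pattern()] columns.
#' @export
classify_patterns <- function(pairs, rpkm_p1, rpkm_p2, rpkm_f1, meta,
                              conditions = NULL, alpha = 0.05,
                              log2_transform = FALSE) {
  stopifnot(inherits(rpkm_p1, "expression_table"),
            inherits(rpkm_p2, "expression_table"),
            inherits(rpkm_f1, "expression_table"))
  if (is.null(conditions)) conditions <- unique(meta$condition)
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    s_p1 <- meta$sample_id[meta$taxon == "P1" & meta$condition == cond]
    s_p2 <- meta$sample_id[meta$taxon == "P2" & meta$condition == cond]
    s_f1 <- meta$sample_id[meta$taxon == "F1" & meta$condition == cond]
    if (length(s_p1) < 2L || length(s_p2) < 2L || length(s_f1) < 2L) {
      stop("condition ", cond, " needs >= 2 replicates per taxon")
    }
    rows <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      spt <- pairs$p1_id[i]
      spc <- pairs$p2_id[i]
      call <- classify_pattern(
        rpkm_f1$values[spt, s_f1] + rpkm_f1$values[spc, s_f1],
        rpkm_p1$values[spt, s_p1],
        rpkm_p2$values[spc, s_p2],
        alpha = alpha, log2_transform = log2_transform)
      rows[[i]] <- cbind(data.frame(pair_id = paste(spt, spc, sep = "|"),
                                    p1_id = spt, p2_id = spc,
                                    condition = cond,
                                    stringsAsFactors = FALSE),
                         call)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate pattern calls into bins and patterns
#'
#' @param calls Data frame of pattern calls (needs columns `pattern` and
#'   `bin`), e.g. from [classify_patterns()].
#' @return List of two data frames, `bins` and `patterns`, each with
#'   `count` and `proportion` columns; proportions sum to 1.
#' @export
bin_patterns <- function(calls) {
  if (!is.data.frame(calls) || nrow(calls) == 0L) {
    stop("bin_patterns requires a non-empty set of pattern calls")
  }
  pat <- factor(calls$pattern, levels = PATTERN_LEVELS)
  bin <- factor(calls$bin, levels = BIN_LEVELS)
  if (anyNA(pat) || anyNA(bin)) stop("unknown pattern or bin label")
  n <- nrow(calls)
  pt <- as.data.frame(table(pattern = pat), responseName = "count")
  pt$proportion <- pt$count / n
  bt <- as.data.frame(table(bin = bin), responseName = "count")
  bt$proportion <- bt$count / n
  list(bins = bt, patterns = pt)
}
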