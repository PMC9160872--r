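# Independent oracles and small fixture builders used across test files.

# Brute-force best hit for one query: explicit max/min comparisons,
# independent of the package's radix-order implementation.
oracle_best_subject <- function(hits, q) {
  h <- hits[hits$query_id == q, , drop = FALSE]
  h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
  h <- h[h$evalue == min(h$evalue), , drop = FALSE]
  sort(h$subject_id)[1L]
}

# Exhaustive mutual-best enumeration over all query-subject combinations.
oracle_rbh <- function(hits_ab, hits_ba) {
  out <- list()
  for (a in sort(unique(hits_ab$query_id))) {
    b <- oracle_best_subject(hits_ab, a)
    if (b %in% hits_ba$query_id && oracle_best_subject(hits_ba, b) == a) {
      out[[a]] <- data.frame(p1_id = a, p2_id = b,
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(p1_id = character(), p2_id = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Random directed hit table with deliberate score ties (few bitscore
# levels) to exercise tie-breaking.
random_hits <- function(queries, subjects, p_edge = 0.7) {
  grid <- expand.grid(query_id = queries, subject_id = subjects,
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < p_edge, , drop = FALSE]
  n <- nrow(grid)
  grid$percent_identity <- round(runif(n, 90, 100), 1)
  grid$evalue <- sample(c(0, 1e-180, 1e-120, 1e-60), n, replace = TRUE)
  grid$bitscore <- sample(c(200, 500, 800), n, replace = TRUE)
  rownames(grid) <- NULL
  grid
}

# G statistic of a 2x2 table from cell expectations under independence,
# 2 * sum O * ln(O / E) -- the textbook form, independent of the
# binomial-likelihood construction in the package.
oracle_g2x2 <- function(x1, y1, x2, y2) {
  obs <- matrix(c(x1, y1, x2, y2), 2L, byrow = TRUE)
  total <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / total
  terms <- ifelse(obs == 0, 0, obs * log(obs / expd))
  2 * sum(terms)
}

# Write a tab-separated alignment file from a data frame of 12 columns.
write_hit_file <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1L), collapse = "\t"), path)
  path
}

# Minimal expression_table around a matrix with auto ids.
make_et <- function(m, lengths = NULL, lib_sizes = NULL, unit = "count") {
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expression_table(m, lengths = lengths, lib_sizes = lib_sizes, unit = unit)
}

# RPKM tables for the three taxa of a sim_experiment, using the
# simulator's reported library sizes.
sim_rpkm <- function(sim) {
  et <- function(m) expression_table(m, lengths = sim$lengths,
                                     lib_sizes = sim$lib_sizes[colnames(m)],
                                     unit = "count")
  list(p1 = compute_rpkm(et(sim$counts_p1)),
       p2 = compute_rpkm(et(sim$counts_p2)),
       f1 = compute_rpkm(et(sim$counts_f1)))
}

# Pipeline config pointing at a fixture directory written by
# write_fixture().
fixture_config <- function(dir, outdir, ...) {
  pipeline_config(counts_p1 = file.path(dir, "counts_p1.tsv"),
                  counts_p2 = file.path(dir, "counts_p2.tsv"),
                  counts_f1 = file.path(dir, "counts_f1.tsv"),
                  lengths = file.path(dir, "lengths.tsv"),
                  samples = file.path(dir, "samples.tsv"),
                  lib_sizes = file.path(dir, "lib_sizes.tsv"),
                  hits_ab = file.path(dir, "hits_p1_vs_p2.tsv"),
                  hits_ba = file.path(dir, "hits_p2_vs_p1.tsv"),
                  outdir = outdir, ...)
}
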