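# Synthetic hybrid-transcriptome experiments with planted expression
# patterns and homeolog bias, for end-to-end validation of the pipeline.

#' Default distribution of true homeolog bias
#'
#' Draws per-pair true B values emulating the bias landscape of an F1
#' hybrid at the unstressed condition: about 24% of pairs carry a real
#' bias, skewed 2:1 toward the maternal (Spc, negative-B) subgenome,
#' with magnitudes around `|B| ~ N(2.2, 0.8)`; the remaining pairs are
#' unbiased (B = 0).
#'
#' @param n Number of pairs.
#' @return Numeric vector of true B values.
#' @export
default_bias_distribution <- function(n) {
  biased <- stats::runif(n) < 0.24
  sgn <- ifelse(stats::runif(n) < 0.66, -1, 1)
  ifelse(biased, sgn * abs(stats::rnorm(n, mean = 2.2, sd = 0.8)), 0)
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic experiment. Defaults mirror a
#' three-taxon chilling design: 3 biological replicates per taxon per
#' condition over the ordered conditions 30C, 16C, 4C, negative-binomial
#' counts, and pattern frequencies matching the unstressed mixture of
#' expression patterns (predominantly no change, expression level
#' dominance skewed toward the P2/maternal parent, little transgression).
#'
#' @param n_pairs Number of homeolog pairs.
#' @param n_replicates Biological replicates per taxon per condition.
#' @param conditions Ordered condition labels.
#' @param baseline_mean Expected read count of a length-1kb transcript at
#'   unit expression (sets overall depth).
#' @param dispersion Negative-binomial dispersion phi
#'   (`variance = mu + phi * mu^2`); 0 degenerates to Poisson.
#' @param pattern_frequencies Named probabilities over the six bins
#'   `no_change`, `additivity`, `ELD_P1`, `ELD_P2`, `transgressive_up`,
#'   `transgressive_down`; must sum to 1.
#' @param bias_distribution Function `n -> numeric` drawing one true B
#'   per pair (held constant across conditions).
#' @param parental_fold Fold separation between parental means for
#'   patterns that require differing parents.
#' @param transgressive_factor Factor by which transgressive hybrid
#'   totals exceed the parental range.
#' @param expr_sd Standard deviation of the log-normal baseline
#'   expression across pairs.
#' @param length_range Transcript length bounds in bp.
#' @param lib_size Nominal mapped-read total per library. The simulated
#'   pairs stand for a small panel out of a full transcriptome, so the
#'   mapped total is dominated by unsimulated transcripts and is
#'   reported explicitly rather than recomputed from panel column sums.
#' @param depth_sd Log-scale standard deviation of the per-sample
#'   sequencing-depth factor (scales both the library size and the
#'   expected counts).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 200L,
                       n_replicates = 3L,
                       conditions = c("30C", "16C", "4C"),
                       baseline_mean = 500,
                       dispersion = 0.05,
                       pattern_frequencies = c(no_change = 0.597,
                                               additivity = 0.040,
                                               ELD_P1 = 0.080,
                                               ELD_P2 = 0.199,
                                               transgressive_up = 0.002,
                                               transgressive_down = 0.082),
                       bias_distribution = default_bias_distribution,
                       parental_fold = 4,
                       transgressive_factor = 2,
                       expr_sd = 0.6,
                       length_range = c(500L, 3000L),
                       lib_size = 1e7,
                       depth_sd = 0.05,
                       seed = 1L) {
  stopifnot(n_pairs >= 1, n_replicates >= 2, length(conditions) >= 1,
            baseline_mean > 0, dispersion >= 0, parental_fold > 1,
            transgressive_factor > 1, expr_sd >= 0,
            length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            lib_size > 0, depth_sd >= 0,
            is.function(bias_distribution))
  if (!setequal(names(pattern_frequencies), BIN_LEVELS)) {
    stop("pattern_frequencies must be named over the six bins: ",
         paste(BIN_LEVELS, collapse = ", "))
  }
  pattern_frequencies <- pattern_frequencies[BIN_LEVELS]
  if (any(pattern_frequencies < 0) ||
      abs(sum(pattern_frequencies) - 1) > 1e-8) {
    stop("pattern_frequencies must be non-negative and sum to 1")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 n_replicates = as.integer(n_replicates),
                 conditions = as.character(conditions),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 pattern_frequencies = pattern_frequencies,
                 bias_distribution = bias_distribution,
                 parental_fold = parental_fold,
                 transgressive_factor = transgressive_factor,
                 expr_sd = expr_sd,
                 length_range = as.integer(length_range),
                 lib_size = lib_size,
                 depth_sd = depth_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d pairs, %d replicates x %d conditions ",
                     "(%s), dispersion %.3g, seed %d\n"),
              x$n_pairs, x$n_replicates, length(x$conditions),
              paste(x$conditions, collapse = ", "), x$dispersion, x$seed))
  invisible(x)
}

nb_draw <- function(mu, phi) {
  if (phi <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
}

#' Simulate a parental/hybrid count experiment with planted truth
#'
#' For each homeolog pair, the generator draws transcript lengths and a
#' log-normal baseline expression, plants per-condition expression
#' patterns (drawn from `pattern_frequencies`) and a per-pair true bias
#' B, then emits negative-binomial read counts for both parents and the
#' hybrid. Parental means follow the planted pattern: equal for
#' `no_change`, separated `parental_fold`-fold where a pattern requires
#' differing parents (which parent is higher is randomised, as is
#' whether transgressive pairs have differing parents). The hybrid total
#' equals the dominant parent (ELD), the parental midpoint (additivity),
#' or exceeds the parental range by `transgressive_factor`
#' (transgression), and is split between the homeologs so that the RPKM
#' ratio is `2^B` — i.e. expected counts in proportion
#' `2^B * len_spt : len_spc`, which exercises the length-adjusted null
#' of [heb_lrt()]. All randomness flows from `cfg$seed`; the global RNG
#' state is left untouched.
#'
#' @param cfg A [sim_config()].
#' @param true_bias Optional numeric vector (length 1 or `n_pairs`)
#'   overriding `cfg$bias_distribution`.
#' @return A list of class `sim_experiment`: `counts_p1`, `counts_p2`
#'   (matrices, pairs x replicates*conditions), `counts_f1` (both
#'   homeologs' rows), `lengths` (named vector), `pairs`, `meta`,
#'   `truth` (one row per pair per condition: planted bin, true B,
#'   parental and hybrid expression levels), and `config`.
#' @export
simulate_experiment <- function(cfg, true_bias = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_experiment_impl(cfg, true_bias))
}

simulate_experiment_impl <- function(cfg, true_bias) {
  n <- cfg$n_pairs
  reps <- cfg$n_replicates
  conds <- cfg$conditions
  ids_spt <- sprintf("SPT_%04d", seq_len(n))
  ids_spc <- sprintf("SPC_%04d", seq_len(n))
  len_pool <- cfg$length_range[1]:cfg$length_range[2]
  len_spt <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
  len_spc <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
  base_expr <- exp(stats::rnorm(n, 0, cfg$expr_sd))
  if (is.null(true_bias)) {
    b_true <- cfg$bias_distribution(n)
  } else {
    b_true <- rep_len(true_bias, n)
  }

  sample_names <- function(taxon) {
    unlist(lapply(conds, function(cc) {
      sprintf("%s_%s_r%d", taxon, cc, seq_len(reps))
    }))
  }
  meta <- data.frame(
    sample_id = c(sample_names("P1"), sample_names("P2"), sample_names("F1")),
    taxon = rep(c("P1", "P2", "F1"), each = reps * length(conds)),
    condition = rep(rep(conds, each = reps), times = 3),
    replicate = rep(rep(seq_len(reps), times = length(conds)), times = 3),
    stringsAsFactors = FALSE)

  counts_p1 <- matrix(0L, n, reps * length(conds),
                      dimnames = list(ids_spt, sample_names("P1")))
  counts_p2 <- matrix(0L, n, reps * length(conds),
                      dimnames = list(ids_spc, sample_names("P2")))
  counts_f1 <- matrix(0L, 2L * n, reps * length(conds),
                      dimnames = list(c(ids_spt, ids_spc),
                                      sample_names("F1")))
  # Per-sample sequencing-depth factor; the mapped total scales with it.
  depth_fac <- stats::setNames(exp(stats::rnorm(nrow(meta), 0, cfg$depth_sd)),
                               meta$sample_id)
  lib_sizes <- round(cfg$lib_size * depth_fac)
  truth <- vector("list", length(conds))
  depth <- cfg$baseline_mean
  for (ci in seq_along(conds)) {
    bins <- sample(BIN_LEVELS, n, replace = TRUE,
                   prob = cfg$pattern_frequencies)
    hi_parent <- sample(c(1L, 2L), n, replace = TRUE)
    trans_diff <- stats::runif(n) < 0.5
    needs_diff <- bins %in% c("additivity", "ELD_P1", "ELD_P2") |
      (bins %in% c("transgressive_up", "transgressive_down") & trans_diff)
    e_p1 <- base_expr
    e_p2 <- base_expr
    e_p1[needs_diff & hi_parent == 1L] <-
      e_p1[needs_diff & hi_parent == 1L] * cfg$parental_fold
    e_p2[needs_diff & hi_parent == 2L] <-
      e_p2[needs_diff & hi_parent == 2L] * cfg$parental_fold
    e_h <- ifelse(bins == "no_change", (e_p1 + e_p2) / 2,
           ifelse(bins == "additivity", (e_p1 + e_p2) / 2,
           ifelse(bins == "ELD_P1", e_p1,
           ifelse(bins == "ELD_P2", e_p2,
           ifelse(bins == "transgressive_up",
                  pmax(e_p1, e_p2) * cfg$transgressive_factor,
                  pmin(e_p1, e_p2) / cfg$transgressive_factor)))))
    w <- 2^b_true
    e_spt <- e_h * w / (1 + w)
    e_spc <- e_h - e_spt
    cols <- (ci - 1L) * reps + seq_len(reps)
    for (r in seq_len(reps)) {
      cc <- cols[r]
      counts_p1[, cc] <- nb_draw(e_p1 * len_spt / 1000 * depth *
                                   depth_fac[colnames(counts_p1)[cc]],
                                 cfg$dispersion)
      counts_p2[, cc] <- nb_draw(e_p2 * len_spc / 1000 * depth *
                                   depth_fac[colnames(counts_p2)[cc]],
                                 cfg$dispersion)
      f1_fac <- depth_fac[colnames(counts_f1)[cc]]
      counts_f1[seq_len(n), cc] <-
        nb_draw(e_spt * len_spt / 1000 * depth * f1_fac, cfg$dispersion)
      counts_f1[n + seq_len(n), cc] <-
        nb_draw(e_spc * len_spc / 1000 * depth * f1_fac, cfg$dispersion)
    }
    truth[[ci]] <- data.frame(pair_id = paste(ids_spt, ids_spc, sep = "|"),
                              p1_id = ids_spt, p2_id = ids_spc,
                              condition = conds[ci], bin = bins,
                              true_b = b_true,
                              expr_p1 = e_p1, expr_p2 = e_p2,
                              expr_hybrid = e_h,
                              len_spt = len_spt, len_spc = len_spc,
                              stringsAsFactors = FALSE)
  }
  lengths <- stats::setNames(c(len_spt, len_spc), c(ids_spt, ids_spc))
  structure(list(counts_p1 = counts_p1, counts_p2 = counts_p2,
                 counts_f1 = counts_f1, lengths = lengths,
                 lib_sizes = lib_sizes,
                 pairs = data.frame(p1_id = ids_spt, p2_id = ids_spc,
                                    stringsAsFactors = FALSE),
                 meta = meta,
                 truth = do.call(rbind, truth),
                 config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d homeolog pairs, %d samples, %d conditions\n",
              nrow(x$pairs), nrow(x$meta), length(x$config$conditions)))
  invisible(x)
}

write_tsv_matrix <- function(m, path, id_col = "transcript_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated experiment as a fixture directory
#'
#' Emits the exact TSV dialects consumed by the pipeline readers: three
#' count matrices, transcript lengths, sample metadata, the planted
#' truth table, a flat record of the generating parameters, and two
#' synthetic 12-column alignment hit tables encoding the 1:1 homeolog
#' relationship (one mutual best hit per pair, deterministic fields), so
#' the orthology stage can be exercised on the fixture too.
#'
#' @param sim A `sim_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- function(name) file.path(dir, name)
  write_tsv_matrix(sim$counts_p1, f("counts_p1.tsv"))
  write_tsv_matrix(sim$counts_p2, f("counts_p2.tsv"))
  write_tsv_matrix(sim$counts_f1, f("counts_f1.tsv"))
  utils::write.table(data.frame(transcript_id = names(sim$lengths),
                                length = unname(sim$lengths)),
                     f("lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(sim$lib_sizes),
                                lib_size = unname(sim$lib_sizes)),
                     f("lib_sizes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$meta, f("samples.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, f("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  params <- data.frame(
    key = c("n_pairs", "n_replicates", "conditions", "baseline_mean",
            "dispersion", "parental_fold", "transgressive_factor",
            "expr_sd", "length_min", "length_max", "lib_size", "depth_sd",
            "seed"),
    value = c(cfg$n_pairs, cfg$n_replicates,
              paste(cfg$conditions, collapse = ","), cfg$baseline_mean,
              cfg$dispersion, cfg$parental_fold, cfg$transgressive_factor,
              cfg$expr_sd, cfg$length_range[1], cfg$length_range[2],
              cfg$lib_size, cfg$depth_sd, cfg$seed),
    stringsAsFactors = FALSE)
  utils::write.table(params, f("sim_params.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # Synthetic mutual-best alignment hits: one per pair, both directions.
  alen <- pmin(sim$lengths[sim$pairs$p1_id], sim$lengths[sim$pairs$p2_id])
  hit_df <- function(q, s) {
    data.frame(qseqid = q, sseqid = s, pident = 97.5, length = alen,
               mismatch = round(alen * 0.025), gapopen = 0L,
               qstart = 1L, qend = alen, sstart = 1L, send = alen,
               evalue = 0, bitscore = round(1.8 * alen),
               stringsAsFactors = FALSE)
  }
  utils::write.table(hit_df(sim$pairs$p1_id, sim$pairs$p2_id),
                     f("hits_p1_vs_p2.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(hit_df(sim$pairs$p2_id, sim$pairs$p1_id),
                     f("hits_p2_vs_p1.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(counts_p1 = f("counts_p1.tsv"), counts_p2 = f("counts_p2.tsv"),
             counts_f1 = f("counts_f1.tsv"), lengths = f("lengths.tsv"),
             lib_sizes = f("lib_sizes.tsv"),
             samples = f("samples.tsv"), truth = f("truth.tsv"),
             sim_params = f("sim_params.tsv"),
             hits_ab = f("hits_p1_vs_p2.tsv"),
             hits_ba = f("hits_p2_vs_p1.tsv"))
  invisible(files)
}
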