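# End-to-end orchestration: orthology -> normalisation/filtering ->
# per-condition pattern classification -> per-condition bias tests ->
# consecutive-condition bias-change tests, with TSV reports.

#' Assemble and validate a pipeline configuration
#'
#' @param counts_p1,counts_p2,counts_f1 Paths to the three count
#'   matrices (TSV; the hybrid was quantified against the concatenated
#'   two-parent reference, so `counts_f1` holds rows for both parental
#'   transcript sets).
#' @param lengths Path to transcript lengths (TSV or FASTA), covering
#'   all transcripts.
#' @param samples Path to sample metadata TSV.
#' @param lib_sizes Optional path to a per-sample mapped-read-total TSV
#'   (see [read_lib_sizes()]); without it, library sizes fall back to
#'   count-matrix column sums.
#' @param hits_ab,hits_ba Paths to the two directional alignment hit
#'   tables (may be `NULL` when `pairs` is given).
#' @param pairs Optional path to a precomputed homeolog-pair TSV,
#'   bypassing the orthology stage.
#' @param outdir Output directory for all stage TSVs.
#' @param conditions Ordered condition labels; consecutive entries are
#'   contrasted in the bias-change stage. Defaults to order of first
#'   appearance in the metadata.
#' @param min_identity,max_evalue Alignment pre-filter thresholds.
#' @param min_tpm,min_samples Expression filter (applied to hybrid TPM;
#'   a pair is kept when both homeologs pass).
#' @param alpha Significance level for pattern t-tests and bias-change
#'   calls.
#' @param fdr_threshold BH-FDR cutoff for per-condition bias calls.
#' @param log2_transform Run pattern t-tests on `log2(x + 1)`.
#' @param all_pairs Contrast all condition pairs instead of consecutive
#'   ones only.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_p1, counts_p2, counts_f1, lengths,
                            samples, lib_sizes = NULL,
                            hits_ab = NULL, hits_ba = NULL,
                            pairs = NULL, outdir = "homeobias_out",
                            conditions = NULL,
                            min_identity = 90, max_evalue = 1e-50,
                            min_tpm = 1, min_samples = 1,
                            alpha = 0.05, fdr_threshold = 0.05,
                            log2_transform = FALSE, all_pairs = FALSE) {
  cfg <- list(counts_p1 = counts_p1, counts_p2 = counts_p2,
              counts_f1 = counts_f1, lengths = lengths, samples = samples,
              lib_sizes = lib_sizes,
              hits_ab = hits_ab, hits_ba = hits_ba, pairs = pairs,
              outdir = outdir, conditions = conditions,
              min_identity = min_identity, max_evalue = max_evalue,
              min_tpm = min_tpm, min_samples = min_samples,
              alpha = alpha, fdr_threshold = fdr_threshold,
              log2_transform = isTRUE(log2_transform),
              all_pairs = isTRUE(all_pairs))
  if (is.null(cfg$pairs) && (is.null(cfg$hits_ab) || is.null(cfg$hits_ba))) {
    stop("either both hit tables or a precomputed pair file is required")
  }
  input_paths <- c(cfg$counts_p1, cfg$counts_p2, cfg$counts_f1,
                   cfg$lengths, cfg$samples, cfg$lib_sizes,
                   cfg$hits_ab, cfg$hits_ba, cfg$pairs)
  missing <- input_paths[!file.exists(input_paths)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` (or `key<TAB>value`) entry per line; `#` comments
#' and blank lines ignored. Keys match the arguments of
#' [pipeline_config()]; relative paths are resolved against the config
#' file's directory. `conditions` is a comma-separated list.
#'
#' @param path Config file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=\t]+)[=\t](.*)$", lines))
  if (any(lengths(kv) != 3L)) {
    stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]])
  }
  keys <- trimws(vapply(kv, `[[`, character(1L), 2L))
  vals <- trimws(vapply(kv, `[[`, character(1L), 3L))
  args <- stats::setNames(as.list(vals), keys)
  path_keys <- c("counts_p1", "counts_p2", "counts_f1", "lengths",
                 "samples", "lib_sizes", "hits_ab", "hits_ba", "pairs",
                 "outdir")
  base <- dirname(normalizePath(path))
  for (k in intersect(names(args), path_keys)) {
    if (!grepl("^/", args[[k]])) args[[k]] <- file.path(base, args[[k]])
  }
  num_keys <- c("min_identity", "max_evalue", "min_tpm", "min_samples",
                "alpha", "fdr_threshold")
  for (k in intersect(names(args), num_keys)) {
    args[[k]] <- as.numeric(args[[k]])
  }
  for (k in intersect(names(args), c("log2_transform", "all_pairs"))) {
    args[[k]] <- toupper(args[[k]]) %in% c("TRUE", "YES", "1")
  }
  if ("conditions" %in% names(args)) {
    args$conditions <- trimws(strsplit(args$conditions, ",")[[1L]])
  }
  unknown <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, args)
}

stage_msg <- function(...) message("[homeobias] ", ...)

write_stage <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full homeolog-bias pipeline
#'
#' Executes, in order: reciprocal best-hit pairing (unless a pair file
#' is supplied), TPM normalisation and the hybrid expression filter,
#' RPKM computation, per-condition pattern classification, per-condition
#' bias tests with BH-FDR, and bias-change tests between consecutive
#' conditions. Every stage writes a TSV under `cfg$outdir`; exclusion
#' tallies are logged so the denominator of every reported percentage is
#' auditable. Outputs are deterministic given fixed inputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the pair table, per-condition pattern
#'   calls and summaries, bias results and summaries, bias-change
#'   results and summary, and the paths of all files written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  out <- function(name) file.path(cfg$outdir, name)
  files <- character()

  # --- orthology ---
  if (!is.null(cfg$pairs)) {
    stage_msg("orthology: reading precomputed pairs from ", cfg$pairs)
    pairs <- read_homeolog_pairs(cfg$pairs)
  } else {
    stage_msg("orthology: reciprocal best hits")
    hits_ab <- filter_hits(parse_hit_table(cfg$hits_ab),
                           cfg$min_identity, cfg$max_evalue)
    hits_ba <- filter_hits(parse_hit_table(cfg$hits_ba),
                           cfg$min_identity, cfg$max_evalue)
    pairs <- reciprocal_best_hits(hits_ab, hits_ba)
  }
  stage_msg("orthology: ", nrow(pairs), " homeolog pairs")
  if (nrow(pairs) == 0L) stop("pipeline aborted at orthology: no pairs")
  files["pairs"] <- write_stage(pairs, out("homeolog_pairs.tsv"))

  # --- quantification ---
  stage_msg("quant: reading counts, lengths and metadata")
  lens <- read_lengths(cfg$lengths)
  meta <- read_sample_meta(cfg$samples)
  libs <- if (!is.null(cfg$lib_sizes)) read_lib_sizes(cfg$lib_sizes)
  counts_p1 <- read_count_matrix(cfg$counts_p1, lengths = lens,
                                 lib_sizes = libs)
  counts_p2 <- read_count_matrix(cfg$counts_p2, lengths = lens,
                                 lib_sizes = libs)
  counts_f1 <- read_count_matrix(cfg$counts_f1, lengths = lens,
                                 lib_sizes = libs)
  known <- pairs$p1_id %in% rownames(counts_f1$values) &
    pairs$p2_id %in% rownames(counts_f1$values) &
    pairs$p1_id %in% rownames(counts_p1$values) &
    pairs$p2_id %in% rownames(counts_p2$values)
  if (any(!known)) {
    stage_msg("quant: dropping ", sum(!known),
              " pair(s) whose transcripts are absent from the matrices")
    pairs <- pairs[known, , drop = FALSE]
  }
  conditions <- cfg$conditions
  if (is.null(conditions)) conditions <- unique(meta$condition)
  if (!all(meta$condition %in% conditions)) {
    stop("condition order must cover all metadata conditions")
  }

  rho <- sample_correlation(counts_f1)
  files["sample_correlation"] <- write_stage(
    data.frame(sample_id = rownames(rho), rho, check.names = FALSE),
    out("sample_correlation_f1.tsv"))

  tpm_f1 <- compute_tpm(counts_f1)
  expressed <- filter_expressed(tpm_f1, cfg$min_tpm, cfg$min_samples)
  detected <- pairs$p1_id %in% expressed & pairs$p2_id %in% expressed
  stage_msg("quant: ", sum(detected), " of ", nrow(pairs),
            " pairs pass the hybrid TPM filter (TPM >= ", cfg$min_tpm,
            " in >= ", cfg$min_samples, " sample(s), both homeologs); ",
            sum(!detected), " excluded")
  pairs <- pairs[detected, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("pipeline aborted at quant: no detected pairs")

  rpkm_p1 <- compute_rpkm(counts_p1)
  rpkm_p2 <- compute_rpkm(counts_p2)
  rpkm_f1 <- compute_rpkm(counts_f1)

  # --- pattern classification ---
  stage_msg("eld: classifying ", nrow(pairs), " pairs in ",
            length(conditions), " condition(s)")
  calls <- classify_patterns(pairs, rpkm_p1, rpkm_p2, rpkm_f1, meta,
                             conditions = conditions, alpha = cfg$alpha,
                             log2_transform = cfg$log2_transform)
  pattern_summary <- do.call(rbind, lapply(conditions, function(cc) {
    bp <- bin_patterns(calls[calls$condition == cc, , drop = FALSE])
    cbind(condition = cc, bp$patterns)
  }))
  bin_summary <- do.call(rbind, lapply(conditions, function(cc) {
    bp <- bin_patterns(calls[calls$condition == cc, , drop = FALSE])
    cbind(condition = cc, bp$bins)
  }))
  for (cc in conditions) {
    files[paste0("eld_", cc)] <- write_stage(
      calls[calls$condition == cc, , drop = FALSE],
      out(paste0("eld_", cc, ".tsv")))
  }
  files["pattern_summary"] <- write_stage(pattern_summary,
                                          out("pattern_proportions.tsv"))
  files["bin_summary"] <- write_stage(bin_summary,
                                      out("bin_proportions.tsv"))

  # --- homeolog bias ---
  heb <- list()
  heb_summaries <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cc <- conditions[ci]
    res <- heb_condition_test(pairs, counts_f1, rpkm_f1, meta, cc,
                              fdr_threshold = cfg$fdr_threshold)
    stage_msg("heb [", cc, "]: ", sum(res$testable), " testable pairs (",
              sum(!res$testable), " excluded for zero counts), ",
              sum(res$significant), " significant at FDR < ",
              cfg$fdr_threshold)
    heb[[cc]] <- res
    s <- summarize_bias(res, cfg$fdr_threshold)
    heb_summaries[[ci]] <- data.frame(condition = cc,
                                      as.data.frame(s),
                                      stringsAsFactors = FALSE)
    files[paste0("heb_", cc)] <- write_stage(res, out(paste0("heb_", cc,
                                                             ".tsv")))
  }
  heb_summary <- do.call(rbind, heb_summaries)
  files["heb_summary"] <- write_stage(heb_summary, out("heb_summary.tsv"))

  # --- bias change between conditions ---
  contrasts <- if (cfg$all_pairs && length(conditions) > 1L) {
    cmb <- utils::combn(conditions, 2L)
    lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  } else if (length(conditions) > 1L) {
    lapply(seq_len(length(conditions) - 1L),
           function(i) conditions[c(i, i + 1L)])
  } else {
    list()
  }
  delta <- list()
  delta_summaries <- list()
  for (ct in contrasts) {
    key <- paste(ct[2L], "vs", ct[1L], sep = "_")
    res <- delta_heb_condition_test(pairs, counts_f1, meta, ct[1L], ct[2L],
                                    heb[[ct[1L]]], heb[[ct[2L]]],
                                    alpha = cfg$alpha)
    stage_msg("delta-heb [", key, "]: ", nrow(res), " pairs tested, ",
              sum(res$significant), " significant at p < ", cfg$alpha)
    delta[[key]] <- res
    sig <- res[res$significant, , drop = FALSE]
    mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
    delta_summaries[[key]] <- data.frame(
      contrast = key, n_tested = nrow(res), n_significant = nrow(sig),
      n_toward_spt = sum(sig$direction == "toward_Spt"),
      n_toward_spc = sum(sig$direction == "toward_Spc"),
      mean_abs_delta_spt = mean_or_na(abs(sig$delta[sig$direction ==
                                                      "toward_Spt"])),
      mean_abs_delta_spc = mean_or_na(abs(sig$delta[sig$direction ==
                                                      "toward_Spc"])),
      stringsAsFactors = FALSE)
    files[paste0("delta_heb_", key)] <- write_stage(
      res, out(paste0("delta_heb_", key, ".tsv")))
  }
  if (length(delta_summaries) > 0L) {
    files["delta_heb_summary"] <- write_stage(
      do.call(rbind, delta_summaries), out("delta_heb_summary.tsv"))
  }

  stage_msg("pipeline complete: ", length(files), " files in ", cfg$outdir)
  invisible(list(pairs = pairs, calls = calls,
                 pattern_summary = pattern_summary,
                 bin_summary = bin_summary,
                 heb = heb, heb_summary = heb_summary,
                 delta = delta,
                 delta_summary = if (length(delta_summaries) > 0L)
                   do.call(rbind, delta_summaries) else NULL,
                 files = files))
}
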