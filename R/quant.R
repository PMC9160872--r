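# Expression containers, TPM/RPKM normalisation, expression filter and
# Spearman sample QC.

#' Construct an expression table
#'
#' A light container for a transcripts-by-samples matrix tagged with its
#' unit (`count`, `TPM` or `RPKM`), together with per-transcript lengths
#' (bp) and per-sample library sizes (mapped reads). Library sizes default
#' to column sums of a count matrix, the standard stand-in when an
#' aligner-reported total is not available.
#'
#' @param values Numeric matrix, transcripts in rows (rownames required),
#'   samples in columns (colnames required). All values must be >= 0.
#' @param lengths Named numeric vector of transcript lengths in bp
#'   covering all rownames, or `NULL`.
#' @param lib_sizes Named numeric vector of per-sample library sizes, or
#'   `NULL` (defaults to column sums when `unit = "count"`).
#' @param unit One of `"count"`, `"TPM"`, `"RPKM"`.
#' @return An object of class `expression_table` with elements `values`,
#'   `lengths`, `lib_sizes`, `unit`.
#' @export
expression_table <- function(values, lengths = NULL, lib_sizes = NULL,
                             unit = c("count", "TPM", "RPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have transcript rownames and sample colnames")
  }
  if (!is.numeric(values) || any(values < 0) || anyNA(values)) {
    stop("expression values must be non-negative and non-missing")
  }
  if (!is.null(lengths)) {
    missing_len <- setdiff(rownames(values), names(lengths))
    if (length(missing_len) > 0L) {
      stop("missing transcript lengths for e.g. ", missing_len[1L])
    }
    lengths <- lengths[rownames(values)]
    if (any(lengths < 1) || anyNA(lengths)) {
      stop("transcript lengths must be >= 1 bp")
    }
  }
  if (is.null(lib_sizes) && unit == "count") {
    lib_sizes <- colSums(values)
  }
  if (!is.null(lib_sizes)) {
    if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(values)
    lib_sizes <- lib_sizes[colnames(values)]
  }
  structure(list(values = values, lengths = lengths,
                 lib_sizes = lib_sizes, unit = unit),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table [%s]: %d transcripts x %d samples\n",
              x$unit, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Transcripts-per-million normalisation
#'
#' Converts a count table to TPM: counts are first divided by transcript
#' length (the full length; no fragment-length correction is applied),
#' then each sample is rescaled so the length-normalised rates sum to one
#' million. Samples with all-zero counts yield an all-zero column with a
#' warning rather than dividing by zero.
#'
#' @param counts An [expression_table()] with unit `count` and lengths.
#' @return An `expression_table` with unit `TPM`.
#' @export
compute_tpm <- function(counts) {
  stopifnot(inherits(counts, "expression_table"))
  if (counts$unit != "count") stop("compute_tpm requires a count table")
  if (is.null(counts$lengths)) stop("compute_tpm requires transcript lengths")
  rate <- counts$values / counts$lengths
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with all-zero counts: ",
            paste(colnames(counts$values)[zero], collapse = ", "))
    totals[zero] <- 1  # column stays zero
  }
  tpm <- sweep(rate, 2L, totals, "/") * 1e6
  expression_table(tpm, lengths = counts$lengths,
                   lib_sizes = counts$lib_sizes, unit = "TPM")
}

#' Reads-per-kilobase-per-million normalisation
#'
#' RPKM for transcript t in sample s is
#' `count * 1e9 / (length_bp * library_size)`, correcting read counts for
#' both transcript length and sequencing depth.
#'
#' @param counts An [expression_table()] with unit `count`, lengths and
#'   positive library sizes.
#' @return An `expression_table` with unit `RPKM`.
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "expression_table"))
  if (counts$unit != "count") stop("compute_rpkm requires a count table")
  if (is.null(counts$lengths)) stop("compute_rpkm requires transcript lengths")
  if (is.null(counts$lib_sizes)) stop("compute_rpkm requires library sizes")
  if (any(counts$lib_sizes <= 0)) {
    stop("library sizes must be positive for RPKM")
  }
  rpkm <- sweep(counts$values / counts$lengths, 2L, counts$lib_sizes, "/") * 1e9
  expression_table(rpkm, lengths = counts$lengths,
                   lib_sizes = counts$lib_sizes, unit = "RPKM")
}

#' Expression filter on TPM
#'
#' Retains transcripts with TPM at or above `min_tpm` in at least
#' `min_samples` samples (the boundary is inclusive).
#'
#' @param tpm An [expression_table()] with unit `TPM`.
#' @param min_tpm Minimum TPM, default 1.
#' @param min_samples Minimum number of samples meeting `min_tpm`,
#'   default 1.
#' @return Character vector of retained transcript ids, in input order.
#' @export
filter_expressed <- function(tpm, min_tpm = 1, min_samples = 1) {
  stopifnot(inherits(tpm, "expression_table"))
  if (tpm$unit != "TPM") stop("filter_expressed requires a TPM table")
  keep <- rowSums(tpm$values >= min_tpm) >= min_samples
  rownames(tpm$values)[keep]
}

#' Pairwise Spearman correlation between samples
#'
#' Computes the symmetric matrix of Spearman's rank correlation
#' coefficients between sample columns (average ranks for ties), the
#' standard reproducibility check before downstream testing. Pairs
#' involving a constant sample are undefined and reported as `NA` with a
#' warning; the diagonal is 1 by convention.
#'
#' @param expr An [expression_table()] with at least 2 samples and at
#'   least 3 transcripts.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
sample_correlation <- function(expr) {
  stopifnot(inherits(expr, "expression_table"))
  v <- expr$values
  if (ncol(v) < 2L) stop("sample_correlation requires >= 2 samples")
  if (nrow(v) < 3L) stop("sample_correlation requires >= 3 transcripts")
  constant <- apply(v, 2L, function(col) length(unique(col)) == 1L)
  if (any(constant)) {
    warning("constant sample(s), correlation undefined: ",
            paste(colnames(v)[constant], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of transcript
#' ids, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @param lengths Optional named length vector passed through to the
#'   table.
#' @param lib_sizes Optional named vector of mapped-read totals; when
#'   omitted, column sums are used.
#' @return An [expression_table()] with unit `count`.
#' @export
read_count_matrix <- function(path, lengths = NULL, lib_sizes = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count matrix needs an id column plus samples: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- as.character(df[[1L]])
  if (!is.null(lib_sizes)) {
    missing_ls <- setdiff(colnames(m), names(lib_sizes))
    if (length(missing_ls) > 0L) {
      stop("missing library size for sample ", missing_ls[1L])
    }
    lib_sizes <- lib_sizes[colnames(m)]
  }
  expression_table(m, lengths = lengths, lib_sizes = lib_sizes,
                   unit = "count")
}

#' Read per-sample library sizes from TSV
#'
#' Two columns with header: `sample_id`, `lib_size` (mapped reads).
#' Supplying aligner-reported totals keeps RPKM comparable across taxa
#' when the count matrices cover only a subset of the transcriptome.
#'
#' @param path TSV file path.
#' @return Named numeric vector of library sizes.
#' @export
read_lib_sizes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("library size table needs two columns: ", path)
  ls <- as.numeric(df[[2L]])
  names(ls) <- as.character(df[[1L]])
  if (anyNA(ls) || any(ls <= 0)) stop("invalid library sizes in ", path)
  ls
}

#' Read transcript lengths from TSV or FASTA
#'
#' A file whose first non-blank character is `>` is read as FASTA
#' (lengths taken from the sequences, via Biostrings); otherwise a
#' two-column TSV (`id`, `length`) with header is expected.
#'
#' @param path File path.
#' @return Named numeric vector of lengths in bp.
#' @export
read_lengths <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && startsWith(trimws(first), ">")) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading lengths from FASTA requires the Biostrings package")
    }
    len <- Biostrings::fasta.seqlengths(path)
    names(len) <- sub("\\s.*$", "", names(len))
    return(len)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("length table needs two columns (id, length): ", path)
  len <- as.numeric(df[[2L]])
  names(len) <- as.character(df[[1L]])
  if (anyNA(len) || any(len < 1)) stop("invalid transcript lengths in ", path)
  len
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `taxon` (one of P1, P2, F1),
#' `condition`, `replicate`; the (taxon, condition, replicate) triples
#' must be unique.
#'
#' @param path TSV file path.
#' @return Data frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "taxon", "condition", "replicate")
  if (!all(required %in% names(meta))) {
    stop("sample metadata must have columns ",
         paste(required, collapse = ", "), ": ", path)
  }
  if (!all(meta$taxon %in% c("P1", "P2", "F1"))) {
    stop("taxon must be one of P1, P2, F1")
  }
  key <- paste(meta$taxon, meta$condition, meta$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (taxon, condition, replicate) in ", path)
  }
  meta$condition <- as.character(meta$condition)
  meta
}
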