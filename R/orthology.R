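# Reciprocal best-hit homeolog pairing from tabular alignment hits.

#' Read a tabular alignment hit file
#'
#' Parses the standard 12-column tab-separated alignment dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). Lines starting with `#` are treated as comments and
#' skipped. Only the columns needed for reciprocal best-hit pairing are
#' retained: query id, subject id, percent identity, E-value and bit score.
#'
#' @param path Path to a tab-separated alignment hit file.
#' @return A data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `evalue`, `bitscore`, one row per hit. An empty
#'   file yields a zero-row data frame with a warning.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(paste("q1", "s1", "97.5", "500", "12", "0", "1", "500",
#'                  "1", "500", "1e-100", "900", sep = "\t"), tf)
#' parse_hit_table(tf)
#' @export
parse_hit_table <- function(path) {
  if (!file.exists(path)) {
    stop("alignment hit table not found: ", path)
  }
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("no alignment hits found in ", path)
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- lineno[which(nf < 12L)[1L]]
    stop("malformed alignment row at line ", bad,
         ": expected at least 12 tab-separated columns, found ",
         nf[which(nf < 12L)[1L]])
  }
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(i, name) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x)) {
      bad <- lineno[which(is.na(x))[1L]]
      stop("non-numeric ", name, " at line ", bad)
    }
    x
  }
  hits <- data.frame(query_id = col(1L),
                     subject_id = col(2L),
                     percent_identity = num(3L, "percent identity"),
                     evalue = num(11L, "E-value"),
                     bitscore = num(12L, "bit score"),
                     stringsAsFactors = FALSE)
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    bad <- lineno[which(hits$percent_identity < 0 |
                          hits$percent_identity > 100)[1L]]
    stop("percent identity outside [0, 100] at line ", bad)
  }
  if (any(hits$evalue < 0)) {
    bad <- lineno[which(hits$evalue < 0)[1L]]
    stop("negative E-value at line ", bad)
  }
  hits
}

#' Filter alignment hits on identity and E-value
#'
#' Applies the stringent pre-filter used before reciprocal best-hit
#' pairing, intended to reduce out-paralog matches between the two
#' parental transcript sets: hits are kept when percent identity is at
#' least `min_identity` and the E-value is at most `max_evalue`. Input
#' order is preserved.
#'
#' @param hits Data frame as returned by [parse_hit_table()].
#' @param min_identity Minimum percent identity, in `[0, 100]`. Default 90.
#' @param max_evalue Maximum E-value. Default `1e-50`.
#' @return The retained rows of `hits` (possibly zero rows).
#' @export
filter_hits <- function(hits, min_identity = 90, max_evalue = 1e-50) {
  stopifnot(is.data.frame(hits))
  if (!is.finite(min_identity) || min_identity < 0 || min_identity > 100) {
    stop("min_identity must be a finite value in [0, 100]")
  }
  if (!is.finite(max_evalue) || max_evalue < 0) {
    stop("max_evalue must be finite and non-negative")
  }
  keep <- hits$percent_identity >= min_identity & hits$evalue <= max_evalue
  hits[keep, , drop = FALSE]
}

# Best hit per query: highest bitscore, ties by lowest evalue, then
# lexicographically smallest subject id (total order => reproducible).
best_hit_per_query <- function(hits) {
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal best-hit homeolog pairs
#'
#' Builds the strict 1:1 set of reciprocal best hits between two parental
#' transcript sets from two (already filtered) directional hit tables.
#' A pair `(a, b)` is emitted iff `b` is `a`'s best hit in `hits_ab` and
#' `a` is `b`'s best hit in `hits_ba`. "Best" means highest bit score,
#' with ties broken by lowest E-value and then by lexicographically
#' smallest subject id, so the result is deterministic regardless of
#' input row order.
#'
#' @param hits_ab Hits with parent-1 transcripts as queries and parent-2
#'   transcripts as subjects.
#' @param hits_ba Hits in the opposite direction.
#' @return Data frame with columns `p1_id`, `p2_id`, one row per pair,
#'   sorted by `p1_id`. Each id appears in at most one pair.
#' @seealso [filter_hits()] for the identity/E-value pre-filter.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  stopifnot(is.data.frame(hits_ab), is.data.frame(hits_ba))
  for (h in list(hits_ab, hits_ba)) {
    if (nrow(h) > 0L && any(h$query_id == h$subject_id)) {
      stop("self-hit found (query equals subject); ",
           "parental transcript namespaces must be disjoint")
    }
  }
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L) {
    return(data.frame(p1_id = character(), p2_id = character(),
                      stringsAsFactors = FALSE))
  }
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  back <- best_ba$subject_id[match(best_ab$subject_id, best_ba$query_id)]
  keep <- !is.na(back) & back == best_ab$query_id
  pairs <- data.frame(p1_id = best_ab$query_id[keep],
                      p2_id = best_ab$subject_id[keep],
                      stringsAsFactors = FALSE)
  pairs[order(pairs$p1_id), , drop = FALSE]
}

#' Write homeolog pairs to a two-column TSV
#'
#' @param pairs Data frame with columns `p1_id`, `p2_id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_homeolog_pairs <- function(pairs, path) {
  stopifnot(is.data.frame(pairs), all(c("p1_id", "p2_id") %in% names(pairs)))
  utils::write.table(pairs[, c("p1_id", "p2_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read homeolog pairs from a two-column TSV
#'
#' @param path Path to a TSV with header columns `p1_id`, `p2_id`.
#' @return Data frame with character columns `p1_id` and `p2_id`.
#' @export
read_homeolog_pairs <- function(path) {
  pairs <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!all(c("p1_id", "p2_id") %in% names(pairs))) {
    stop("homeolog pair file must have columns p1_id and p2_id: ", path)
  }
  if (anyDuplicated(pairs$p1_id) || anyDuplicated(pairs$p2_id)) {
    stop("homeolog pairs must be 1:1; duplicated ids in ", path)
  }
  pairs[, c("p1_id", "p2_id")]
}
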