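#' Four-tier best-hit categorization
#'
#' Hits are ranked by query overlap (`100 * aln_length / q_len`) and percent
#' identity: rank 1 = overlap >= 70 and identity >= 50, rank 2 = overlap
#' only, rank 3 = identity only, rank 4 = neither. Thresholds are applied
#' as `>=`.
#'
#' @param hits a hit data.frame (rows are categorized independently).
#' @param min_overlap,min_identity category thresholds in percent.
#' @return Integer vector of ranks (1-4), one per hit row.
#' @export
categorize_hit <- function(hits, min_overlap = 70, min_identity = 50) {
  stopifnot(all(c("aln_length", "q_len", "pct_identity") %in% names(hits)))
  overlap <- 100 * hits$aln_length / hits$q_len
  overlap_high <- overlap >= min_overlap
  identity_high <- hits$pct_identity >= min_identity
  ifelse(overlap_high & identity_high, 1L,
         ifelse(overlap_high, 2L, ifelse(identity_high, 3L, 4L)))
}

#' Retain only hits of each query's best category
#'
#' Per query, the best (lowest-rank) category present among its hits is
#' determined and exactly the hits of that category are kept, ordered by
#' descending bit score (ties broken by subject id).
#'
#' @param hits a hit data.frame.
#' @inheritParams categorize_hit
#' @return The filtered hit data.frame, with a `category` column appended.
#' @export
best_hits_filter <- function(hits, min_overlap = 70, min_identity = 50) {
  if (nrow(hits) == 0L) {
    out <- hits; out$category <- integer(0); return(out)
  }
  hits$category <- categorize_hit(hits, min_overlap, min_identity)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query_id), function(idx) {
    best <- min(hits$category[idx])
    idx <- idx[hits$category[idx] == best]
    idx[order(-hits$bit_score[idx], hits$subject_id[idx])]
  }), use.names = FALSE)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ortholog Hit Ratio of one transcript
#'
#' The OHR of a transcript against a hit is the ungapped alignment length
#' (alignment columns minus gap columns) divided by the full length of the
#' hit sequence, clamped to at most 1; the hit with the best OHR is kept.
#' An OHR of 1 means the transcript covers the entire hit sequence. For
#' imported tabular hits, whose exact gap column count is unknown, gap
#' columns are approximated by `gap_opens` (single-base gaps assumed).
#'
#' @param hits hit data.frame rows sharing one `query_id` (must carry
#'   `s_len`).
#' @return A one-row data.frame `transcript_id`, `best_subject_id`, `ohr`,
#'   `n_hits_considered`, or `NULL` for an empty hit list (query counted as
#'   "no hit").
#' @export
ortholog_hit_ratio <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  stopifnot(length(unique(hits$query_id)) == 1L, all(!is.na(hits$s_len)))
  gapc <- hits$gap_columns
  if (is.null(gapc)) gapc <- rep(NA_integer_, nrow(hits))
  gapc <- ifelse(is.na(gapc), hits$gap_opens, gapc)
  ohr <- pmin(1, (hits$aln_length - gapc) / hits$s_len)
  best <- which.max(ohr)
  data.frame(transcript_id = hits$query_id[1],
             best_subject_id = hits$subject_id[best],
             ohr = ohr[best], n_hits_considered = nrow(hits),
             stringsAsFactors = FALSE)
}

#' Per-query OHR table
#'
#' Applies [ortholog_hit_ratio()] to every query present in a hit table.
#'
#' @param hits a hit data.frame.
#' @return A data.frame with one row per query that has at least one hit.
#' @export
ohr_table <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(transcript_id = character(), best_subject_id = character(),
                      ohr = numeric(), n_hits_considered = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- lapply(split(hits, hits$query_id), ortholog_hit_ratio)
  out <- do.call(rbind, parts)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assembly summary statistics
#'
#' Sequence count, total bp, mean and median length, and N50: the largest
#' attained length L such that sequences of length >= L together cover at
#' least half of the total bases.
#'
#' @param seqs a non-empty [seq_set].
#' @return A one-row data.frame `n_sequences`, `total_bp`, `mean_length`,
#'   `median_length`, `n50_length`.
#' @examples
#' s <- seq_set("demo", id = letters[1:5],
#'              seq = vapply(c(1000, 800, 600, 400, 200),
#'                           function(n) strrep("A", n), ""))
#' assembly_stats(s)
#' @export
assembly_stats <- function(seqs) {
  stopifnot(inherits(seqs, "seq_set"))
  if (length(seqs$id) == 0L) stop2("empty sequence set")
  len <- sort(nchar(seqs$seq), decreasing = TRUE)
  cum <- cumsum(as.numeric(len))
  n50 <- len[which(cum >= sum(as.numeric(len)) / 2)[1]]
  data.frame(n_sequences = length(len), total_bp = sum(as.numeric(len)),
             mean_length = mean(len), median_length = stats::median(len),
             n50_length = n50)
}
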