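STOP_CODONS <- c("TAA", "TAG", "TGA")

# Candidate ORFs in one reading frame of an oriented sequence.
# Returns rows: start_codon, end_codon (1-based codon indices, stop
# excluded), starts_atg, ends_stop.
frame_candidates <- function(codons) {
  ncod <- length(codons)
  if (ncod == 0L) return(NULL)
  is_stop <- codons %in% STOP_CODONS
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (seg in which(!r$values)) {
    i <- starts[seg]; j <- ends[seg]
    bounded_left <- i > 1L
    bounded_right <- j < ncod
    atg <- which(codons[i:j] == "ATG")
    if (length(atg)) {
      k <- i + atg[1] - 1L
      out[[length(out) + 1L]] <- data.frame(
        start_codon = k, end_codon = j, starts_atg = TRUE,
        ends_stop = bounded_right)
    }
    if (!bounded_left && (!length(atg) || atg[1] > 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        start_codon = i, end_codon = j, starts_atg = FALSE,
        ends_stop = bounded_right)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Classify CDS completeness of a transcript
#'
#' Scans all six reading frames for ORF candidates (stop-to-stop segments,
#' optionally entered at the first ATG) and classifies the longest candidate
#' of at least `min_orf_bp` bp:
#' \itemize{
#'   \item `complete` - ATG-initiated and terminated by a stop codon inside
#'     the transcript;
#'   \item `n_fragment` - ends with a stop, but the upstream end runs off
#'     the transcript without an ATG start (amino end truncated);
#'   \item `c_fragment` - ATG start but no stop before the transcript end;
#'   \item `both_fragment` - neither boundary present;
#'   \item `none` - no qualifying ORF.
#' }
#' Candidates lacking an ATG are only admitted when their segment runs off
#' the 5' end of the frame (a truncation can explain the missing start).
#' Ties in length prefer the more complete class, then frames in the order
#' +1, +2, +3, -1, -2, -3. This is a deliberately simple longest-ORF
#' classifier standing in for a trained CDS predictor; only the class
#' taxonomy is consumed downstream.
#'
#' @param seq a single sequence (length >= 3).
#' @param min_orf_bp minimum ORF length in bp, stop codon excluded
#'   (default 300).
#' @return One-row data.frame: `transcript_id`, `class`, `frame` (1..3 on
#'   the forward strand, -1..-3 on the reverse; `NA` for class `none`),
#'   `orf_start`, `orf_end` (0-based half-open forward-strand coordinates)
#'   and `orf_length_bp`.
#' @export
classify_cds <- function(seq, min_orf_bp = 300L) {
  rec <- as_record(seq)
  L <- nchar(rec$seq)
  if (L < 3L) stop2("sequence shorter than 3 bp: ", rec$id)
  class_rank <- c(complete = 1L, n_fragment = 2L, c_fragment = 3L,
                  both_fragment = 4L)
  best <- NULL
  frame_order <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") rec$seq else revcomp(rec$seq)
    for (off in 0:2) {
      frame_order <- frame_order + 1L
      ncod <- (L - off) %/% 3L
      if (ncod < 1L) next
      pos <- off + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(s, pos, pos + 2L)
      cand <- frame_candidates(codons)
      if (is.null(cand)) next
      cand$len_bp <- (cand$end_codon - cand$start_codon + 1L) * 3L
      cand <- cand[cand$len_bp >= min_orf_bp, , drop = FALSE]
      if (nrow(cand) == 0L) next
      cand$class <- ifelse(cand$starts_atg & cand$ends_stop, "complete",
                    ifelse(cand$ends_stop, "n_fragment",
                    ifelse(cand$starts_atg, "c_fragment", "both_fragment")))
      for (ci in seq_len(nrow(cand))) {
        s0 <- off + (cand$start_codon[ci] - 1L) * 3L   # 0-based on oriented seq
        e0 <- off + cand$end_codon[ci] * 3L
        if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
        entry <- list(class = cand$class[ci],
                      frame = if (strand == "+") off + 1L else -(off + 1L),
                      frame_order = frame_order,
                      orf_start = s0, orf_end = e0,
                      len = cand$len_bp[ci])
        if (is.null(best) ||
            entry$len > best$len ||
            (entry$len == best$len &&
             class_rank[[entry$class]] < class_rank[[best$class]]) ||
            (entry$len == best$len &&
             class_rank[[entry$class]] == class_rank[[best$class]] &&
             entry$frame_order < best$frame_order)) {
          best <- entry
        }
      }
    }
  }
  if (is.null(best)) {
    return(data.frame(transcript_id = rec$id, class = "none",
                      frame = NA_integer_, orf_start = NA_integer_,
                      orf_end = NA_integer_, orf_length_bp = 0L,
                      stringsAsFactors = FALSE))
  }
  data.frame(transcript_id = rec$id, class = best$class, frame = best$frame,
             orf_start = best$orf_start, orf_end = best$orf_end,
             orf_length_bp = best$len, stringsAsFactors = FALSE)
}

#' @rdname classify_cds
#' @param seqs a [seq_set].
#' @return `classify_cds_set()`: a data.frame with one row per sequence plus
#'   an attribute `class_counts`, the named count of each class (the classes
#'   partition the set).
#' @export
classify_cds_set <- function(seqs, min_orf_bp = 300L) {
  stopifnot(inherits(seqs, "seq_set"))
  out <- do.call(rbind, lapply(seq_along(seqs$id), function(i)
    classify_cds(list(id = seqs$id[i], seq = seqs$seq[i]), min_orf_bp)))
  counts <- table(factor(out$class, levels = c("complete", "n_fragment",
                                               "c_fragment", "both_fragment",
                                               "none")))
  attr(out, "class_counts") <- counts
  out
}
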