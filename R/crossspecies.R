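best_hit_per_query <- function(hits, evalue_max, min_overlap_pct) {
  ok <- hits$e_value <= evalue_max &
    100 * hits$aln_length / hits$q_len >= min_overlap_pct
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  keep <- vapply(split(seq_len(nrow(hits)), hits$query_id), function(idx) {
    idx[order(-hits$bit_score[idx], -hits$pct_identity[idx],
              hits$subject_id[idx])][1]
  }, integer(1))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two species
#'
#' In each direction the best hit per query is the qualifying hit (e-value
#' at most `evalue_max`, query-side overlap of at least `min_overlap_pct`
#' percent) with maximal bit score; ties break by higher percent identity,
#' then lexicographic subject id. A pair is emitted iff the best hits are
#' mutual. The reported identity is taken from the a-to-b hit; a warning is
#' raised when the two directions disagree by more than one percentage
#' point.
#'
#' @param hits_ab,hits_ba hit data.frames for the two search directions
#'   (both carrying `q_len`).
#' @param evalue_max e-value threshold (default 1e-10).
#' @param min_overlap_pct minimum query-side alignment overlap in percent
#'   (default 90), enforced in both directions.
#' @return A data.frame of RBH pairs: `id_a`, `id_b`, `pct_identity`,
#'   `overlap_a`, `overlap_b`, `evalue_ab`, `evalue_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-10,
                                 min_overlap_pct = 90) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      pct_identity = numeric(), overlap_a = numeric(),
                      overlap_b = numeric(), evalue_ab = numeric(),
                      evalue_ba = numeric(), stringsAsFactors = FALSE)
  ab <- best_hit_per_query(hits_ab, evalue_max, min_overlap_pct)
  ba <- best_hit_per_query(hits_ba, evalue_max, min_overlap_pct)
  if (nrow(ab) == 0L || nrow(ba) == 0L) return(empty)
  back <- stats::setNames(ba$subject_id, ba$query_id)
  mutual <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  ab <- ab[mutual, , drop = FALSE]
  if (nrow(ab) == 0L) return(empty)
  ba_idx <- match(ab$subject_id, ba$query_id)
  out <- data.frame(id_a = ab$query_id, id_b = ab$subject_id,
                    pct_identity = ab$pct_identity,
                    overlap_a = 100 * ab$aln_length / ab$q_len,
                    overlap_b = 100 * ba$aln_length[ba_idx] / ba$q_len[ba_idx],
                    evalue_ab = ab$e_value,
                    evalue_ba = ba$e_value[ba_idx],
                    stringsAsFactors = FALSE)
  diff <- abs(out$pct_identity - ba$pct_identity[ba_idx])
  if (any(diff > 1)) {
    warning(sum(diff > 1), " RBH pair(s) with identity differing by > 1 ",
            "point between directions", call. = FALSE)
  }
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species-specific (PDEG) transcript set
#'
#' Transcripts of one species with no hit in the sibling species' set at the
#' annotation e-value threshold: candidate Potential Differentially
#' Expressed Genes.
#'
#' @param transcripts_a the species' [seq_set].
#' @param hits_ab hit data.frame of `transcripts_a` against the sibling set.
#' @param evalue_max e-value threshold (default 1e-5).
#' @return Character vector of transcript ids.
#' @export
species_specific <- function(transcripts_a, hits_ab, evalue_max = 1e-5) {
  stopifnot(inherits(transcripts_a, "seq_set"))
  with_hit <- unique(hits_ab$query_id[hits_ab$e_value <= evalue_max])
  setdiff(transcripts_a$id, with_hit)
}

#' Divergence summary over RBH pairs
#'
#' Summary statistics of the pairwise identities and the divergent subset
#' below `divergent_cutoff` percent identity.
#'
#' @param pairs RBH pair data.frame from [reciprocal_best_hits()]
#'   (non-empty).
#' @param divergent_cutoff percent identity below which a pair is listed as
#'   divergent (default 97).
#' @return A list of class `divergence_report` with `n_pairs`,
#'   `mean_identity`, `min_identity`, `max_identity`, `median_identity` and
#'   `divergent_pairs` (a subset of `pairs`).
#' @export
divergence_report <- function(pairs, divergent_cutoff = 97) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop2("empty RBH pair list")
  idt <- pairs$pct_identity
  structure(list(n_pairs = nrow(pairs),
                 mean_identity = mean(idt),
                 min_identity = min(idt), max_identity = max(idt),
                 median_identity = stats::median(idt),
                 divergent_cutoff = divergent_cutoff,
                 divergent_pairs = pairs[idt < divergent_cutoff, , drop = FALSE]),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf("<divergence_report: %d RBH pairs>\n", x$n_pairs))
  cat(sprintf("  identity mean %.2f%%, median %.2f%%, range %.2f-%.2f%%\n",
              x$mean_identity, x$median_identity,
              x$min_identity, x$max_identity))
  cat(sprintf("  %d pair(s) below %.1f%% identity\n",
              nrow(x$divergent_pairs), x$divergent_cutoff))
  invisible(x)
}
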