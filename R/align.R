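#' Alignment scoring scheme
#'
#' Affine-gap nucleotide scoring: a gap of length L costs
#' `|gap_open| + L * |gap_extend|`. `N` scores as a mismatch against
#' everything, including itself. The Karlin-Altschul parameters convert raw
#' scores to bit scores and e-values; `karlin_lambda` defaults to the exact
#' ungapped solution of `sum(p_i p_j exp(lambda * s_ij)) = 1` for the chosen
#' match/mismatch scores under uniform base composition, and `karlin_k` to a
#' constant calibrated once for the default scheme (see the package
#' vignette). Only threshold behaviour of the e-values matters downstream.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open,gap_extend gap penalties (< 0).
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters (> 0);
#'   `karlin_lambda = NULL` solves the ungapped equation numerically.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L,
                           gap_open = -5L, gap_extend = -2L,
                           karlin_lambda = NULL, karlin_k = 0.35) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            karlin_k > 0)
  if (is.null(karlin_lambda)) {
    f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
    karlin_lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  }
  stopifnot(karlin_lambda > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k),
            class = "scoring_scheme")
}

#' Seeded search configuration
#'
#' @param kmer_size seed word size (>= 4).
#' @param min_seed_hits minimum number of distinct shared k-mers (on either
#'   strand) for a query/subject pair to be aligned.
#' @param evalue_cutoff hits with larger e-value are discarded.
#' @param both_strands also search the reverse complement of the subjects.
#' @return A list of class `search_config`.
#' @export
search_config <- function(kmer_size = 11L, min_seed_hits = 2L,
                          evalue_cutoff = 10, both_strands = TRUE) {
  stopifnot(kmer_size >= 4L, min_seed_hits >= 1L, evalue_cutoff > 0)
  structure(list(kmer_size = as.integer(kmer_size),
                 min_seed_hits = as.integer(min_seed_hits),
                 evalue_cutoff = evalue_cutoff,
                 both_strands = isTRUE(both_strands)),
            class = "search_config")
}

align_submat <- function(scheme) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scheme$match
  m["N", "N"] <- scheme$mismatch
  m
}

as_record <- function(x) {
  if (inherits(x, "seq_set")) {
    stopifnot(length(x$id) == 1L)
    return(list(id = x$id, seq = x$seq))
  }
  if (is.character(x) && length(x) == 1L) {
    return(list(id = names(x) %||% "seq", seq = toupper(unname(x))))
  }
  stopifnot(is.list(x), !is.null(x$id), !is.null(x$seq))
  x
}

# Local alignment of several queries against one oriented subject in a
# single vectorized call. Returns a list with one element per query: NULL
# when no alignment scores > 0, else the raw alignment features.
align_batch <- function(qseqs, sseq, scheme) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(qseqs), Biostrings::DNAString(sseq),
    type = "local", substitutionMatrix = align_submat(scheme),
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend))
  scores <- Biostrings::score(al)
  ap <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  qs <- IRanges::start(Biostrings::pattern(al))
  qe <- IRanges::end(Biostrings::pattern(al))
  ss <- IRanges::start(Biostrings::subject(al))
  se <- IRanges::end(Biostrings::subject(al))
  lapply(seq_along(qseqs), function(i) {
    if (scores[i] <= 0) return(NULL)
    p <- strsplit(ap[i], "")[[1]]
    s <- strsplit(as_[i], "")[[1]]
    gaps <- p == "-" | s == "-"
    list(score = scores[i],
         matches = sum(p == s & !gaps),
         mismatches = sum(p != s & !gaps),
         gap_columns = sum(gaps),
         gap_opens = count_gap_runs(p) + count_gap_runs(s),
         columns = length(p),
         q_start = qs[i], q_end = qe[i], s_start = ss[i], s_end = se[i])
  })
}

# Single-pair convenience wrapper around align_batch().
align_core <- function(qseq, sseq, scheme) {
  align_batch(qseq, sseq, scheme)[[1]]
}

count_gap_runs <- function(chars) {
  r <- rle(chars == "-")
  sum(r$values)
}

make_hit <- function(query, subject, core, strand, scheme, db_residues) {
  q_len <- nchar(query$seq); s_len <- nchar(subject$seq)
  if (strand == "-") {
    s_start <- s_len - core$s_start + 1L
    s_end <- s_len - core$s_end + 1L
  } else {
    s_start <- core$s_start; s_end <- core$s_end
  }
  ev <- evalue(core$score, q_len, db_residues, scheme)
  data.frame(query_id = query$id, subject_id = subject$id,
             pct_identity = 100 * core$matches / core$columns,
             aln_length = core$columns, mismatches = core$mismatches,
             gap_opens = core$gap_opens,
             q_start = core$q_start, q_end = core$q_end,
             s_start = s_start, s_end = s_end,
             e_value = ev$e_value, bit_score = ev$bit_score,
             q_len = q_len, s_len = s_len, gap_columns = core$gap_columns,
             stringsAsFactors = FALSE)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under affine-gap scoring, optionally on
#' both strands of the subject (a reverse-strand hit is encoded by
#' `s_start > s_end`, following the tabular convention). Returns `NULL` when
#' no alignment has positive score. `pct_identity` is
#' `100 * matches / alignment columns`; coordinates are 1-based inclusive.
#' The e-value is computed against `db_residues` subject residues
#' (default: the subject length).
#'
#' @param query,subject single sequences: a length-1 [seq_set], a named
#'   character scalar, or a `list(id =, seq =)`.
#' @param scheme a [scoring_scheme()].
#' @param both_strands also try the reverse complement of the subject.
#' @param db_residues effective database size for the e-value.
#' @return A one-row hit data.frame, or `NULL`.
#' @examples
#' local_align(c(q = "ACGTACGT"), c(s = "ACGTACGT"))
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        both_strands = TRUE, db_residues = NULL) {
  query <- as_record(query); subject <- as_record(subject)
  stopifnot(nchar(query$seq) > 0, nchar(subject$seq) > 0)
  db_residues <- db_residues %||% nchar(subject$seq)
  fwd <- align_core(query$seq, subject$seq, scheme)
  rev <- if (both_strands) align_core(query$seq, revcomp(subject$seq), scheme)
         else NULL
  if (is.null(fwd) && is.null(rev)) return(NULL)
  if (is.null(rev) || (!is.null(fwd) && fwd$score >= rev$score)) {
    make_hit(query, subject, fwd, "+", scheme, db_residues)
  } else {
    make_hit(query, subject, rev, "-", scheme, db_residues)
  }
}

#' Bit score and e-value from a raw alignment score
#'
#' Karlin-Altschul conversion: `bit = (lambda * S - ln k) / ln 2`,
#' `e = q_len * db_residues * 2^-bit`, computed in log space.
#'
#' @param score raw alignment score (> 0).
#' @param q_len query length in residues.
#' @param db_residues total subject residues searched.
#' @param scheme a [scoring_scheme()].
#' @return A list with `bit_score` and `e_value`.
#' @export
evalue <- function(score, q_len, db_residues, scheme = scoring_scheme()) {
  if (score <= 0) stop2("raw alignment score must be positive")
  bit <- (scheme$karlin_lambda * score - log(scheme$karlin_k)) / log(2)
  e <- exp(log(q_len) + log(db_residues) - bit * log(2))
  list(bit_score = bit, e_value = e)
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), k:n))
}

#' All-vs-all seeded local alignment search
#'
#' Pairs a query with a subject when they share at least
#' `config$min_seed_hits` distinct k-mers on either strand, aligns each
#' candidate pair with [local_align()] (one best alignment per pair), and
#' discards hits above the e-value cutoff. E-values use the total subject
#' residues as database size. Output is sorted by query id, then ascending
#' e-value, then descending bit score.
#'
#' @param queries,subjects [seq_set]s.
#' @param scheme a [scoring_scheme()].
#' @param config a [search_config()].
#' @return A hit data.frame (possibly with zero rows).
#' @export
all_vs_all <- function(queries, subjects, scheme = scoring_scheme(),
                       config = search_config()) {
  stopifnot(inherits(queries, "seq_set"), inherits(subjects, "seq_set"),
            length(queries$id) > 0L, length(subjects$id) > 0L)
  k <- config$kmer_size
  db_residues <- sum(nchar(subjects$seq))
  skmers <- lapply(subjects$seq, kmer_set, k = k)
  smap <- split(rep(seq_along(subjects$id), lengths(skmers)),
                unlist(skmers, use.names = FALSE))
  # candidate (query, subject, strand) triples from shared k-mers
  cand <- list()
  for (qi in seq_along(queries$id)) {
    cf <- seed_candidates(queries$seq[qi], smap, k, config$min_seed_hits)
    cr <- if (config$both_strands)
      seed_candidates(revcomp(queries$seq[qi]), smap, k, config$min_seed_hits)
    else integer(0)
    if (length(cf) || length(cr)) {
      cand[[length(cand) + 1L]] <- data.frame(
        qi = qi, si = c(cf, cr),
        strand = rep(c("+", "-"), c(length(cf), length(cr))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_hit_table())
  cand <- do.call(rbind, cand)
  # align in batches, one vectorized call per (subject, strand)
  cores <- vector("list", nrow(cand))
  for (grp in split(seq_len(nrow(cand)),
                    paste0(cand$si, cand$strand))) {
    si <- cand$si[grp[1]]
    sseq <- if (cand$strand[grp[1]] == "+") subjects$seq[si]
            else revcomp(subjects$seq[si])
    cores[grp] <- align_batch(queries$seq[cand$qi[grp]], sseq, scheme)
  }
  # keep the better strand per (query, subject) pair
  rows <- list()
  for (grp in split(seq_len(nrow(cand)), list(cand$qi, cand$si), drop = TRUE)) {
    ok <- grp[!vapply(cores[grp], is.null, logical(1))]
    if (!length(ok)) next
    best <- ok[which.max(vapply(cores[ok], `[[`, numeric(1), "score"))]
    rows[[length(rows) + 1L]] <- make_hit(
      list(id = queries$id[cand$qi[best]], seq = queries$seq[cand$qi[best]]),
      list(id = subjects$id[cand$si[best]], seq = subjects$seq[cand$si[best]]),
      cores[[best]], cand$strand[best], scheme, db_residues)
  }
  if (!length(rows)) return(empty_hit_table())
  out <- do.call(rbind, rows)
  out <- out[out$e_value <= config$evalue_cutoff, , drop = FALSE]
  out <- out[order(out$query_id, out$e_value, -out$bit_score,
                   out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Subjects sharing >= min_hits distinct k-mers with the (oriented) query.
seed_candidates <- function(qseq, smap, k, min_hits) {
  qk <- kmer_set(qseq, k)
  if (!length(qk)) return(integer(0))
  found <- smap[qk]
  counts <- table(unlist(found, use.names = FALSE))
  as.integer(names(counts)[counts >= min_hits])
}
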