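#' Longest homopolymer run per nucleotide
#'
#' Returns, for each of A, C, G, T, the length of the longest maximal run of
#' that base in the sequence: 0 when the base is absent, 1 when it only
#' occurs in isolation. N terminates a run and never extends one.
#'
#' @param seq a single sequence (length-1 [seq_set], named character scalar,
#'   or `list(id =, seq =)`).
#' @return Named integer vector `c(A =, C =, G =, T =)`.
#' @examples
#' longest_runs(c(x = "AAACCGTT"))
#' @export
longest_runs <- function(seq) {
  rec <- as_record(seq)
  if (!nzchar(rec$seq)) stop2("empty sequence")
  r <- rle(strsplit(rec$seq, "")[[1]])
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (b in names(out)) {
    runs <- r$lengths[r$values == b]
    if (length(runs)) out[b] <- max(runs)
  }
  out
}

#' Homopolymer profile of a sequence set
#'
#' For every nucleotide, tallies the per-sequence longest run into a
#' histogram of run length vs. number of sequences, counting only runs of at
#' least 2 bp (a homopolymer proper). Mean longest-run lengths are computed
#' over the sequences contributing a qualifying run; the global maximum is
#' over all bases and sequences.
#'
#' @param seqs a non-empty [seq_set].
#' @return A list of class `homopolymer_profile` with `histograms` (named
#'   list of run-length -> count tables per base), `means` (named numeric),
#'   `global_max` and `n_sequences`.
#' @export
homopolymer_profile <- function(seqs) {
  stopifnot(inherits(seqs, "seq_set"))
  if (length(seqs$id) == 0L) stop2("empty sequence set")
  per_seq <- t(vapply(seq_along(seqs$id), function(i)
    longest_runs(list(id = seqs$id[i], seq = seqs$seq[i])),
    integer(4)))
  colnames(per_seq) <- c("A", "C", "G", "T")
  histograms <- list(); means <- c(A = NA_real_, C = NA_real_,
                                   G = NA_real_, T = NA_real_)
  for (b in colnames(per_seq)) {
    v <- per_seq[, b]
    v <- v[v >= 2L]
    histograms[[b]] <- if (length(v)) table(v) else table(integer(0))
    means[b] <- if (length(v)) mean(v) else NA_real_
  }
  structure(list(histograms = histograms, means = means,
                 global_max = max(per_seq),
                 n_sequences = length(seqs$id)),
            class = "homopolymer_profile")
}

#' @export
print.homopolymer_profile <- function(x, ...) {
  cat(sprintf("<homopolymer_profile: %d sequences, global max run %d bp>\n",
              x$n_sequences, x$global_max))
  for (b in names(x$means)) {
    cat(sprintf("  %s: mean longest run %s bp over %d sequences with a run >= 2\n",
                b, ifelse(is.na(x$means[b]), "NA", sprintf("%.2f", x$means[b])),
                sum(x$histograms[[b]])))
  }
  invisible(x)
}

# Flat (nucleotide, run_length, count) rows for write_table().
profile_table <- function(profile) {
  rows <- list()
  for (b in names(profile$histograms)) {
    h <- profile$histograms[[b]]
    for (ln in names(h)) {
      rows[[length(rows) + 1L]] <- data.frame(
        nucleotide = b, run_length = as.integer(ln),
        count = as.integer(h[[ln]]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(nucleotide = character(), run_length = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
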