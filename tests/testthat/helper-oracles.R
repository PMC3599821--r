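# Independent brute-force oracles. These are deliberately naive
# implementations, kept separate from the package code paths they check.

# Full-matrix Smith-Waterman with affine gaps (gap of length L costs
# |open| + L * |extend|). Returns the best local score (>= 0).
oracle_affine_score <- function(q, s, match = 1, mismatch = -2,
                                gap_open = -5, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  Ix <- matrix(neg, n + 1, m + 1)  # gap in subject (query residue vs gap)
  Iy <- matrix(neg, n + 1, m + 1)  # gap in query
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (qc[i] == sc[j] && qc[i] != "N") match else mismatch
      prev <- max(M[i, j], Ix[i, j], Iy[i, j], 0)
      M[i + 1, j + 1] <- prev + sub
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                              Ix[i, j + 1] + gap_extend,
                              Iy[i, j + 1] + gap_open + gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                              Iy[i + 1, j] + gap_extend,
                              Ix[i + 1, j] + gap_open + gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

# Longest homopolymer run per base via regex scan.
oracle_longest_runs <- function(s) {
  vapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    m <- gregexpr(paste0(b, "+"), s)[[1]]
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
}

# N50 by sort-and-accumulate.
oracle_n50 <- function(lengths) {
  l <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(l))
  l[which(cs >= sum(as.numeric(l)) / 2)[1]]
}

# Two-sided Fisher p by full hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  x <- max(0L, k - m2):min(k, m1)
  probs <- stats::dhyper(x, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Best-category filter by explicit min-rank search.
oracle_best_hits_filter <- function(hits, min_overlap = 70, min_identity = 50) {
  rank1 <- function(h) {
    ov <- 100 * h$aln_length / h$q_len >= min_overlap
    idt <- h$pct_identity >= min_identity
    if (ov && idt) 1L else if (ov) 2L else if (idt) 3L else 4L
  }
  ranks <- vapply(seq_len(nrow(hits)), function(i) rank1(hits[i, ]), integer(1))
  keep <- logical(nrow(hits))
  for (q in unique(hits$query_id)) {
    idx <- which(hits$query_id == q)
    keep[idx[ranks[idx] == min(ranks[idx])]] <- TRUE
  }
  hits[keep, , drop = FALSE]
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random tabular-style hit table covering n_q queries.
random_hit_table <- function(n_rows, n_q = 5L, n_s = 5L) {
  q_len <- sample(100:1000, n_q, replace = TRUE)
  data.frame(
    query_id = sprintf("q%02d", sample(n_q, n_rows, replace = TRUE)),
    subject_id = sprintf("s%02d", sample(n_s, n_rows, replace = TRUE)),
    pct_identity = round(stats::runif(n_rows, 20, 100), 2),
    aln_length = sample(50:900, n_rows, replace = TRUE),
    mismatches = sample(0:50, n_rows, replace = TRUE),
    gap_opens = sample(0:5, n_rows, replace = TRUE),
    q_start = 1L, q_end = 50L, s_start = 1L, s_end = 50L,
    e_value = 10^stats::runif(n_rows, -50, 0),
    bit_score = round(stats::runif(n_rows, 30, 500), 1),
    q_len = q_len[sample(n_q, n_rows, replace = TRUE)],
    s_len = sample(100:1000, n_rows, replace = TRUE),
    gap_columns = NA_integer_,
    stringsAsFactors = FALSE)
}

# Mutate a DNA string at a fixed per-site substitution rate.
mutate_str <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}
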