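test_that("identical sequences align end to end at 100% identity", {
  hit <- local_align(c(q = "ACGTACGT"), c(s = "ACGTACGT"))
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$aln_length, 8L)
  expect_equal(c(hit$q_start, hit$q_end, hit$s_start, hit$s_end),
               c(1L, 8L, 1L, 8L))
})

test_that("reverse-strand hits are reported with s_start > s_end", {
  hit <- local_align(c(q = "AAAA"), c(s = "TTTT"))
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$aln_length, 4L)
  expect_gt(hit$s_start, hit$s_end)
  # strand search disabled: no positive-scoring alignment remains
  expect_null(local_align(c(q = "AAAA"), c(s = "TTTT"), both_strands = FALSE))
})

test_that("alignment scores match a full-matrix affine DP oracle", {
  set.seed(201)
  sch <- scoring_scheme()
  for (i in 1:150) {
    q <- random_dna_str(sample(5:60, 1))
    s <- random_dna_str(sample(5:60, 1))
    if (i %% 3 == 0) s <- paste0(substr(q, 1, sample(5:30, 1)),
                                 random_dna_str(10))
    core <- twintx:::align_core(q, s, sch)
    impl <- if (is.null(core)) 0 else core$score
    expect_equal(impl, oracle_affine_score(q, s))
  }
})

test_that("alignment score is symmetric under symmetric scoring", {
  set.seed(202)
  for (i in 1:25) {
    q <- random_dna_str(40); s <- random_dna_str(40)
    h1 <- local_align(c(a = q), c(b = s))
    h2 <- local_align(c(b = s), c(a = q))
    expect_equal(is.null(h1), is.null(h2))
    if (!is.null(h1)) expect_equal(h1$bit_score, h2$bit_score)
  }
})

test_that("a fragment aligns to its source at full identity and length", {
  set.seed(203)
  src <- random_dna_str(500)
  frag <- substr(src, 101, 250)
  hit <- local_align(c(f = frag), c(s = src))
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$aln_length, nchar(frag))
  expect_equal(hit$s_start, 101L)
})

test_that("e-values follow the Karlin-Altschul relations", {
  sch <- scoring_scheme()
  e1 <- evalue(50, 100, 1000, sch)
  e2 <- evalue(50, 100, 2000, sch)
  expect_equal(e2$e_value / e1$e_value, 2)
  # log-space and direct formula agree
  direct <- 100 * 1000 * 2^(-e1$bit_score)
  expect_equal(e1$e_value, direct, tolerance = 1e-12)
  # monotone decreasing in score
  scores <- seq(10, 200, by = 10)
  es <- vapply(scores, function(s) evalue(s, 100, 1000, sch)$e_value,
               numeric(1))
  expect_true(all(diff(es) < 0))
  # algebraic anchor: e = q_len * db * 2^-bit, so at bit = 0 the e-value is
  # the search-space size (checked with k > 1 so a positive score attains it)
  sch2 <- scoring_scheme(karlin_k = exp(sch$karlin_lambda))
  expect_equal(evalue(1, 7, 13, sch2)$e_value, 7 * 13, tolerance = 1e-9)
  expect_error(evalue(0, 100, 1000, sch), "positive")
})

test_that("the default lambda solves the ungapped score equation", {
  sch <- scoring_scheme()
  expect_equal(0.25 * exp(sch$karlin_lambda * sch$match) +
                 0.75 * exp(sch$karlin_lambda * sch$mismatch), 1,
               tolerance = 1e-9)
})

test_that("unrelated sets with no shared k-mers yield no hits", {
  q <- seq_set("q", id = "q1", seq = strrep("AC", 50))
  s <- seq_set("s", id = "s1", seq = strrep("GT", 50))  # revcomp of AC-repeat
  cfg <- search_config(both_strands = FALSE)
  expect_equal(nrow(all_vs_all(q, s, config = cfg)), 0L)
})

test_that("seeded search equals the exhaustive search on small related sets", {
  set.seed(204)
  n <- 12L
  ancestors <- replicate(n, random_dna_str(300))
  qs <- seq_set("q", id = sprintf("q%02d", 1:n),
                seq = vapply(ancestors, mutate_str, "", rate = 0.02))
  ss <- seq_set("s", id = sprintf("s%02d", 1:n),
                seq = vapply(ancestors, mutate_str, "", rate = 0.02))
  cfg <- search_config(evalue_cutoff = 1e-5)
  seeded <- all_vs_all(qs, ss, config = cfg)
  # exhaustive: align every pair, apply the same cutoff
  db <- sum(nchar(ss$seq))
  exhaustive <- list()
  for (i in 1:n) for (j in 1:n) {
    h <- local_align(qs[i], ss[j], db_residues = db)
    if (!is.null(h) && h$e_value <= cfg$evalue_cutoff) {
      exhaustive[[length(exhaustive) + 1L]] <- h
    }
  }
  exhaustive <- do.call(rbind, exhaustive)
  key <- function(h) paste(h$query_id, h$subject_id)
  expect_setequal(key(seeded), key(exhaustive))
  m <- match(key(seeded), key(exhaustive))
  expect_equal(seeded$bit_score, exhaustive$bit_score[m])
  expect_equal(seeded$pct_identity, exhaustive$pct_identity[m])
  # and no seeded hit is missing from the exhaustive set by construction
  expect_true(all(!is.na(m)))
})

test_that("seeded search recovers diverged partners at high recall", {
  sim <- generate_twin_transcriptomes(
    sim_config(n_orthologs = 40L, n_specific_a = 0L, n_specific_b = 0L,
               divergence = 0.05, indel_rate = 0,
               length_range = c(300L, 600L), seed = 44L))
  hits <- all_vs_all(sim$a, sim$b)
  found <- mapply(function(a, b) any(hits$query_id == a & hits$subject_id == b),
                  sim$truth$ortholog_pairs$id_a, sim$truth$ortholog_pairs$id_b)
  expect_gte(mean(found), 0.99)
})
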