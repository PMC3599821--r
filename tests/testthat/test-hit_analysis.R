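mk_hit <- function(query_id = "q", subject_id = "s", pct_identity = 99,
                   aln_length = 100L, q_len = 100L, s_len = 100L,
                   bit_score = 100, e_value = 1e-20, gap_opens = 0L,
                   gap_columns = 0L) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_length = aln_length,
             mismatches = 0L, gap_opens = gap_opens, q_start = 1L,
             q_end = aln_length, s_start = 1L, s_end = aln_length,
             e_value = e_value, bit_score = bit_score, q_len = q_len,
             s_len = s_len, gap_columns = gap_columns,
             stringsAsFactors = FALSE)
}

test_that("hit categories follow the overlap/identity thresholds", {
  expect_equal(categorize_hit(mk_hit(pct_identity = 60, aln_length = 80L)), 1L)
  expect_equal(categorize_hit(mk_hit(pct_identity = 49.99, aln_length = 70L)), 2L)
  expect_equal(categorize_hit(mk_hit(pct_identity = 50, aln_length = 69L)), 3L)
  expect_equal(categorize_hit(mk_hit(pct_identity = 10, aln_length = 10L)), 4L)
  # thresholds are inclusive
  expect_equal(categorize_hit(mk_hit(pct_identity = 50, aln_length = 70L)), 1L)
})

test_that("categorization is total and assigns exactly one rank", {
  set.seed(301)
  hits <- random_hit_table(200)
  hits$aln_length <- pmin(hits$aln_length, hits$q_len)
  ranks <- categorize_hit(hits)
  expect_true(all(ranks %in% 1:4))
  expect_length(ranks, nrow(hits))
})

test_that("best-category filtering keeps exactly the best rank per query", {
  h <- rbind(mk_hit(subject_id = "s1", pct_identity = 60, aln_length = 80L,
                    bit_score = 50),
             mk_hit(subject_id = "s2", pct_identity = 55, aln_length = 90L,
                    bit_score = 80),
             mk_hit(subject_id = "s3", pct_identity = 60, aln_length = 30L,
                    bit_score = 90))
  out <- best_hits_filter(h)
  expect_equal(out$subject_id, c("s2", "s1"))  # both rank 1, bit desc
  expect_true(all(out$category == 1L))

  only4 <- mk_hit(pct_identity = 10, aln_length = 10L)
  expect_equal(best_hits_filter(only4)$category, 4L)
})

test_that("best-category filtering matches the brute-force oracle", {
  set.seed(302)
  for (rep in 1:40) {
    hits <- random_hit_table(sample(5:40, 1))
    hits$aln_length <- pmin(hits$aln_length, round(1.2 * hits$q_len))
    out <- best_hits_filter(hits)
    orc <- oracle_best_hits_filter(hits)
    key <- function(h) paste(h$query_id, h$subject_id, h$bit_score)
    expect_setequal(key(out), key(orc))
  }
})

test_that("the OHR is the ungapped alignment share of the hit length", {
  h <- mk_hit(aln_length = 120L, s_len = 200L, gap_columns = 20L)
  expect_equal(ortholog_hit_ratio(h)$ohr, 0.5)
  # a transcript identical to its reference covers it fully
  full <- mk_hit(aln_length = 300L, s_len = 300L, q_len = 300L)
  expect_equal(ortholog_hit_ratio(full)$ohr, 1.0)
  # no hit: none-result
  expect_null(ortholog_hit_ratio(mk_hit()[0, ]))
  # imported hits fall back to gap_opens as the gap-column estimate
  imp <- mk_hit(aln_length = 100L, s_len = 100L, gap_opens = 4L,
                gap_columns = NA_integer_)
  expect_equal(ortholog_hit_ratio(imp)$ohr, 0.96)
})

test_that("the best OHR among multiple hits is kept", {
  h <- rbind(mk_hit(subject_id = "s1", aln_length = 100L, s_len = 400L),
             mk_hit(subject_id = "s2", aln_length = 100L, s_len = 125L),
             mk_hit(subject_id = "s3", aln_length = 100L, s_len = 200L))
  rec <- ortholog_hit_ratio(h)
  expect_equal(rec$best_subject_id, "s2")
  expect_equal(rec$ohr, 0.8)
  expect_equal(rec$n_hits_considered, 3L)
})

test_that("planted coverage fractions are recovered as OHR values", {
  cfg <- sim_config(n_orthologs = 12L, n_specific_a = 0L, n_specific_b = 0L,
                    divergence = 0, indel_rate = 0,
                    fragment_fractions = c(0.25, 0.5, 0.7, 1.0),
                    length_range = c(300L, 600L), seed = 71L)
  sim <- generate_twin_transcriptomes(cfg)
  hits <- all_vs_all(sim$a, sim$references)
  tab <- ohr_table(hits)
  frac <- sim$truth$coverage_fraction
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$ohr[i], frac[[tab$transcript_id[i]]])
  }
})

test_that("extending a fragment never decreases its OHR", {
  set.seed(303)
  src <- random_dna_str(400)
  ref <- seq_set("ref", id = "r1", seq = src)
  last <- 0
  for (len in c(100, 200, 300, 400)) {
    frag <- seq_set("q", id = "f", seq = substr(src, 1, len))
    ohr <- ohr_table(all_vs_all(frag, ref))$ohr
    expect_gte(ohr, last)
    last <- ohr
  }
  expect_equal(last, 1.0)
})

test_that("assembly statistics match hand-computed values", {
  s <- seq_set("x", id = letters[1:5],
               seq = vapply(c(1000L, 800L, 600L, 400L, 200L),
                            function(n) strrep("A", n), ""))
  st <- assembly_stats(s)
  expect_equal(st$n50_length, 800L)
  expect_equal(st$median_length, 600L)
  expect_equal(st$mean_length, 600)
  expect_equal(st$total_bp, 3000)

  one <- assembly_stats(seq_set("x", id = "a", seq = strrep("C", 500)))
  expect_true(all(unlist(one[c("mean_length", "median_length",
                               "n50_length")]) == 500))
  expect_error(assembly_stats(seq_set("x")), "empty")
})

test_that("N50 matches the sort-and-accumulate oracle and bounds the median", {
  set.seed(304)
  for (rep in 1:200) {
    lens <- sample(100:5000, sample(1:60, 1), replace = TRUE)
    s <- seq_set("x", id = sprintf("s%03d", seq_along(lens)),
                 seq = vapply(lens, function(n) strrep("A", n), ""))
    st <- assembly_stats(s)
    expect_equal(st$n50_length, oracle_n50(lens))
    expect_gte(st$n50_length, st$median_length)
  }
})
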