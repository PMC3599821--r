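small_cfg <- function(...) {
  sim_config(n_orthologs = 10L, n_specific_a = 3L, n_specific_b = 3L,
             length_range = c(150L, 300L), seed = 5L, ...)
}

test_that("zero mutation rates give identical ortholog copies", {
  sim <- generate_twin_transcriptomes(
    small_cfg(divergence = 0, indel_rate = 0, fragment_fractions = 1.0))
  expect_true(all(sim$truth$ortholog_pairs$realized_identity == 100))
  expect_equal(sim$a$seq[1:10], sim$b$seq[1:10], ignore_attr = TRUE)
})

test_that("degenerate set sizes are honoured", {
  sim <- generate_twin_transcriptomes(
    sim_config(n_orthologs = 0L, n_specific_a = 5L, n_specific_b = 0L,
               length_range = c(100L, 150L), seed = 2L))
  expect_equal(n_seq(sim$a), 5L)
  expect_equal(n_seq(sim$b), 0L)
  expect_equal(nrow(sim$truth$ortholog_pairs), 0L)
})

test_that("every transcript is either ortholog or species-specific", {
  sim <- generate_twin_transcriptomes(small_cfg())
  tr <- sim$truth
  expect_setequal(sim$a$id, c(tr$ortholog_pairs$id_a, tr$specific_a))
  expect_setequal(sim$b$id, c(tr$ortholog_pairs$id_b, tr$specific_b))
  expect_length(intersect(tr$ortholog_pairs$id_a, tr$specific_a), 0L)
})

test_that("same seed reproduces all outputs exactly", {
  cfg <- small_cfg()
  s1 <- generate_twin_transcriptomes(cfg)
  s2 <- generate_twin_transcriptomes(cfg)
  expect_identical(s1$a$seq, s2$a$seq)
  expect_identical(s1$truth$ortholog_pairs, s2$truth$ortholog_pairs)
  r1 <- generate_reads(s1$a, "ATCAGC", cfg)
  r2 <- generate_reads(s2$a, "ATCAGC", cfg)
  expect_identical(r1$reads$seq, r2$reads$seq)
  expect_identical(r1$read_origin, r2$read_origin)
})

test_that("mean realized identity matches the divergence model", {
  # divergence is defined as expected pairwise divergence, so with no indels
  # the identity of each site is Bernoulli(1 - d): check the realized mean
  # against the exact binomial 99% interval.
  cfg <- sim_config(n_orthologs = 200L, n_specific_a = 0L, n_specific_b = 0L,
                    divergence = 0.02, indel_rate = 0,
                    length_range = c(300L, 1000L), seed = 31L)
  sim <- generate_twin_transcriptomes(cfg)
  lens <- nchar(sim$references$seq)
  total_sites <- sum(lens)
  half99 <- 2.576 * sqrt(0.98 * 0.02 / total_sites) * 100
  weighted_mean <- sum(sim$truth$ortholog_pairs$realized_identity * lens) /
    sum(lens)
  expect_lt(abs(weighted_mean - 98.0), half99 + 1e-9)
})

test_that("realized identity agrees with the alignment engine", {
  sim <- generate_twin_transcriptomes(small_cfg(indel_rate = 0.004))
  for (i in seq_len(5)) {
    p <- sim$truth$ortholog_pairs[i, ]
    hit <- local_align(sim$a[p$id_a], sim$b[p$id_b])
    expect_lt(abs(hit$pct_identity - p$realized_identity), 0.5)
  }
})

test_that("reads carry the printed adapter and barcode structure", {
  sim <- generate_twin_transcriptomes(small_cfg())
  rd <- generate_reads(sim$a, "ATCAGC", small_cfg(homopolymer_error_rate = 0))
  expect_gt(n_seq(rd$reads), 0L)
  expect_true(all(startsWith(rd$reads$seq,
                             "CCATCTCATCCCTGCGTGTCTCCGACTCAG")))
  expect_true(all(substr(rd$reads$seq, 31, 36) == "ATCAGC"))
  expect_true(all(endsWith(rd$reads$seq, "CTGAGACTGCCAAGGCACACAGGGGATAGG")))
  # with no planted error, each insert is an exact substring of its origin
  for (i in seq_len(n_seq(rd$reads))) {
    insert <- strip_known_structure(rd$reads$seq[i], "ATCAGC")
    origin <- sim$a$seq[sim$a$id == rd$read_origin$transcript_id[i]]
    expect_true(grepl(insert, origin, fixed = TRUE))
  }
})

test_that("planted homopolymer errors lengthen exactly one run", {
  sim <- generate_twin_transcriptomes(small_cfg())
  rd <- generate_reads(sim$a, "ATCAGC", small_cfg(homopolymer_error_rate = 1))
  checked <- 0L
  for (i in which(rd$read_origin$planted_error)) {
    insert <- strip_known_structure(rd$reads$seq[i], "ATCAGC")
    origin <- sim$a$seq[sim$a$id == rd$read_origin$transcript_id[i]]
    expect_false(grepl(insert, origin, fixed = TRUE))
    expect_true(shrinks_to_substring(insert, origin))
    checked <- checked + 1L
  }
  expect_gt(checked, 10L)
})

test_that("short transcripts are skipped with a warning", {
  short <- seq_set("a", id = "t1", seq = strrep("ACGT", 10))  # 40 bp
  cfg <- sim_config(read_length_range = c(150L, 400L), seed = 1L)
  expect_warning(rd <- generate_reads(short, "ATCAGC", cfg), "skipped")
  expect_equal(n_seq(rd$reads), 0L)
})

test_that("reads_per_transcript = 0 yields an empty read set", {
  sim <- generate_twin_transcriptomes(small_cfg())
  rd <- generate_reads(sim$a, "ATCAGC", small_cfg(reads_per_transcript = 0L))
  expect_equal(n_seq(rd$reads), 0L)
})

test_that("GO annotation respects vocabulary size and planted enrichment", {
  sim <- generate_twin_transcriptomes(
    sim_config(n_orthologs = 40L, n_specific_a = 40L, n_specific_b = 10L,
               length_range = c(100L, 150L), divergence = 0, seed = 8L))
  ann0 <- generate_go_annotations(sim$a, sim$b, sim$truth, n_terms = 0L)
  expect_length(ann0$go, 0L)

  planted <- data.frame(term = "GO:0000007", species = "a", multiplier = 50)
  ann <- generate_go_annotations(sim$a, sim$b, sim$truth, n_terms = 20L,
                                 enriched_terms = planted, seed = 9L)
  has_term <- vapply(sim$a$id, function(id)
    "GO:0000007" %in% ann$go[[id]], logical(1))
  freq_specific <- mean(has_term[sim$truth$specific_a])
  freq_all <- mean(has_term)
  expect_gt(freq_specific, freq_all)
  expect_equal(ann$go_truth$enriched_in[ann$go_truth$term == "GO:0000007"], "a")

  expect_error(generate_go_annotations(sim$a, sim$b, sim$truth, 20L,
    data.frame(term = "GO:0000001", species = "a", multiplier = 0)),
    "multiplier")
})

test_that("fragment truncation records the realized coverage fraction", {
  cfg <- sim_config(n_orthologs = 20L, n_specific_a = 0L, n_specific_b = 0L,
                    divergence = 0, indel_rate = 0,
                    fragment_fractions = c(0.25, 0.5, 0.7, 1.0),
                    length_range = c(300L, 600L), seed = 13L)
  sim <- generate_twin_transcriptomes(cfg)
  tr <- sim$truth
  for (i in seq_len(20)) {
    p <- tr$ortholog_pairs[i, ]
    ref <- sim$references$seq[sim$references$id == p$ref_id]
    frag <- sim$a$seq[sim$a$id == p$id_a]
    expect_equal(tr$coverage_fraction[[p$id_a]], nchar(frag) / nchar(ref))
    expect_true(grepl(frag, ref, fixed = TRUE))  # divergence 0: exact piece
  }
})
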