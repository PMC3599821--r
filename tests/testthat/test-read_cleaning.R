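test_that("a structured read demultiplexes to its barcode species", {
  read <- paste0("CCATCTCATCCCTGCGTGTCTCCGACTCAG", "ATCAGC",
                 "GACCTTGGCTGTCACTC", "ACGTACGT",
                 "TCGCAGTGAGTGACAGGCCA", "CTGAGACTGCCAAGGCACACAGGGGATAGG")
  out <- demultiplex_and_trim(seq_set("raw", id = "r1", seq = read))
  expect_equal(out$species$nubilalis$seq, "ACGTACGT")
  expect_equal(n_seq(out$species$scapulalis), 0L)
  expect_equal(n_seq(out$unassigned), 0L)
})

test_that("unknown barcodes go to the unassigned bin", {
  read <- paste0("CCATCTCATCCCTGCGTGTCTCCGACTCAG", "TTTTTT",
                 "GACCTTGGCTGTCACTC", strrep("ACGT", 30),
                 "TCGCAGTGAGTGACAGGCCA", "CTGAGACTGCCAAGGCACACAGGGGATAGG")
  out <- demultiplex_and_trim(seq_set("raw", id = "r1", seq = read))
  expect_equal(n_seq(out$unassigned), 1L)
  expect_equal(out$report$removed$unassigned_barcode, 1L)
})

test_that("adapter matching tolerates the configured mismatch budget", {
  adapt <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
  substr(adapt, 3, 3) <- "G"; substr(adapt, 10, 10) <- "A"  # 2 mismatches
  read <- paste0(adapt, "CACACG", "GACCTTGGCTGTCACTC", strrep("TGCA", 30),
                 "TCGCAGTGAGTGACAGGCCA", "CTGAGACTGCCAAGGCACACAGGGGATAGG")
  out <- demultiplex_and_trim(seq_set("raw", id = "r1", seq = read))
  expect_equal(out$species$scapulalis$seq, strrep("TGCA", 30))
})

test_that("simulated batches demultiplex to the correct species", {
  cfg <- sim_config(n_orthologs = 8L, n_specific_a = 2L, n_specific_b = 2L,
                    length_range = c(200L, 400L), seed = 21L,
                    homopolymer_error_rate = 0)
  sim <- generate_twin_transcriptomes(cfg)
  ra <- generate_reads(sim$a, "ATCAGC", cfg)
  rb <- generate_reads(sim$b, "CACACG", cfg)
  all_reads <- seq_set("raw", id = c(ra$reads$id, rb$reads$id),
                       seq = c(ra$reads$seq, rb$reads$seq))
  origin <- rbind(ra$read_origin, rb$read_origin)
  out <- demultiplex_and_trim(all_reads)
  expect_equal(n_seq(out$unassigned), 0L)
  for (sp in c("nubilalis", "scapulalis")) {
    bc <- names(which(c(ATCAGC = "nubilalis", CACACG = "scapulalis") == sp))
    expect_setequal(out$species[[sp]]$id, origin$read_id[origin$barcode == bc])
  }
  # recovered inserts are exact substrings of their origin transcripts
  transcripts <- c(stats::setNames(sim$a$seq, sim$a$id),
                   stats::setNames(sim$b$seq, sim$b$id))
  for (sp in names(out$species)) {
    s <- out$species[[sp]]
    for (i in seq_len(n_seq(s))) {
      tid <- origin$transcript_id[origin$read_id == s$id[i]]
      expect_true(grepl(s$seq[i], transcripts[[tid]], fixed = TRUE))
    }
  }
})

test_that("length and N filters remove the documented classes", {
  reads <- seq_set("r", id = c("ok", "highn", "short"),
                   seq = c(strrep("ACGT", 30),
                           paste0(strrep("N", 10), strrep("ACGT", 28), "AC"),
                           strrep("A", 99)))
  out <- filter_reads(reads, cleaning_config(min_length = 100))
  expect_equal(out$reads$id, "ok")
  expect_equal(out$report$removed$short, 1L)
  expect_equal(out$report$removed$high_n, 1L)
  expect_equal(out$report$input_count,
               out$report$removed$short + out$report$removed$high_n +
                 out$report$output_counts$kept)
})

test_that("filtering is idempotent and preserves order", {
  set.seed(4)
  reads <- seq_set("r", id = sprintf("r%02d", 1:20),
                   seq = replicate(20, random_dna_str(sample(50:200, 1))))
  once <- filter_reads(reads)
  twice <- filter_reads(once$reads)
  expect_identical(twice$reads$id, once$reads$id)
  expect_identical(twice$reads$seq, once$reads$seq)
  expect_equal(twice$report$removed$short + twice$report$removed$high_n, 0L)
  expect_true(!is.unsorted(match(once$reads$id, reads$id)))
})

test_that("rRNA screening removes self-matches and keeps unrelated reads", {
  set.seed(12)
  rrna <- seq_set("rrna", id = "rr1", seq = random_dna_str(150))
  cfg <- cleaning_config(rrna_reference = rrna)
  reads <- seq_set("r", id = c("contam", "clean"),
                   seq = c(rrna$seq[1], random_dna_str(150)))
  out <- screen_rrna(reads, cfg)
  expect_equal(out$reads$id, "clean")
  expect_equal(out$report$removed$rrna, 1L)
  # no reference configured: identity pass-through
  out2 <- screen_rrna(reads, cleaning_config())
  expect_identical(out2$reads$id, reads$id)
})

test_that("demultiplex report conserves read counts", {
  set.seed(9)
  good <- paste0("CCATCTCATCCCTGCGTGTCTCCGACTCAG", "ATCAGC",
                 "GACCTTGGCTGTCACTC", random_dna_str(120),
                 "TCGCAGTGAGTGACAGGCCA", "CTGAGACTGCCAAGGCACACAGGGGATAGG")
  junk <- random_dna_str(150)
  empty_insert <- paste0("CCATCTCATCCCTGCGTGTCTCCGACTCAG", "CACACG",
                         "GACCTTGGCTGTCACTC", "TCGCAGTGAGTGACAGGCCA",
                         "CTGAGACTGCCAAGGCACACAGGGGATAGG")
  out <- demultiplex_and_trim(seq_set("raw", id = c("a", "b", "c"),
                                      seq = c(good, junk, empty_insert)))
  rep <- out$report
  total_out <- sum(unlist(rep$output_counts))
  expect_equal(rep$input_count, total_out + rep$removed$adapter_only +
                 rep$removed$unassigned_barcode)
  expect_equal(rep$removed$adapter_only, 1L)
})
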