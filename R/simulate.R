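# Library structure of the simulated 454 reads: 5'-adapter A, a 6 bp species
# barcode, an inner 5' adapter, the insert, an inner 3' adapter, adapter B.
ADAPTER_A  <- "CCATCTCATCCCTGCGTGTCTCCGACTCAG"
ADAPTER_B  <- "CTGAGACTGCCAAGGCACACAGGGGATAGG"
ADAPTER_5P <- "GACCTTGGCTGTCACTC"
ADAPTER_3P <- "TCGCAGTGAGTGACAGGCCA"
DEFAULT_BARCODES <- c(ATCAGC = "nubilalis", CACACG = "scapulalis")

#' Simulation configuration
#'
#' Parameters of the twin-transcriptome generator. `divergence` is the
#' expected per-site *pairwise* divergence between the two descendant copies
#' of an ancestor: each copy is mutated independently at the per-copy rate
#' `h` solving `(1-h)^2 + h^2/3 = 1 - divergence`, so the expected pairwise
#' identity is exactly `1 - divergence` (the `h^2/3` term accounts for
#' coincident mutations to the same base). Indels are single-base, insertion
#' and deletion equally likely, at per-copy rate `indel_rate / 2`.
#'
#' @param n_orthologs number of ancestor sequences with one descendant copy
#'   in each species.
#' @param n_specific_a,n_specific_b numbers of planted species-specific
#'   transcripts (unrelated random sequences).
#' @param length_range integer `(min, max)` transcript length in bp.
#' @param divergence expected pairwise per-site substitution divergence in
#'   `[0, 1)`.
#' @param indel_rate expected pairwise per-site indel probability in `[0, 1)`.
#' @param fragment_fractions coverage fractions in `(0, 1]`; each descendant
#'   transcript draws one uniformly and is truncated to that fraction of its
#'   ancestor (from a random end). The realized fraction is recorded in the
#'   truth table.
#' @param reads_per_transcript reads sampled per transcript by
#'   [generate_reads()].
#' @param read_length_range integer `(min, max)` insert length in bp.
#' @param homopolymer_error_rate probability that a read carries one planted
#'   run-lengthening error (an existing homopolymer extended by 1-3 bp).
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_orthologs = 200L, n_specific_a = 25L, n_specific_b = 25L,
                       length_range = c(300L, 1000L), divergence = 0.02,
                       indel_rate = 0.002, fragment_fractions = 1.0,
                       reads_per_transcript = 3L,
                       read_length_range = c(150L, 400L),
                       homopolymer_error_rate = 0.2, seed = 1L) {
  stopifnot(is_count(n_orthologs), is_count(n_specific_a), is_count(n_specific_b),
            length(length_range) == 2L, length_range[1] <= length_range[2],
            divergence >= 0, divergence < 1,
            indel_rate >= 0, indel_rate < 1,
            all(fragment_fractions > 0), all(fragment_fractions <= 1),
            is_count(reads_per_transcript),
            length(read_length_range) == 2L,
            read_length_range[1] <= read_length_range[2],
            homopolymer_error_rate >= 0, homopolymer_error_rate <= 1)
  structure(list(n_orthologs = as.integer(n_orthologs),
                 n_specific_a = as.integer(n_specific_a),
                 n_specific_b = as.integer(n_specific_b),
                 length_range = as.integer(length_range),
                 divergence = divergence, indel_rate = indel_rate,
                 fragment_fractions = fragment_fractions,
                 reads_per_transcript = as.integer(reads_per_transcript),
                 read_length_range = as.integer(read_length_range),
                 homopolymer_error_rate = homopolymer_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-copy substitution rate h so that two copies mutated independently at h
# have expected pairwise divergence d: (1-h)^2 + h^2/3 = 1 - d.
per_copy_rate <- function(d) {
  if (d == 0) return(0)
  (3 - sqrt(9 - 12 * d)) / 4
}

# Apply substitutions (rate sub) and single-base indels (rate ind) to a
# character-vector representation of a sequence.
mutate_seq <- function(chars, sub, ind) {
  n <- length(chars)
  if (sub > 0) {
    hit <- which(stats::runif(n) < sub)
    if (length(hit)) {
      alts <- c("A", "C", "G", "T")
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(alts, b), 1L), character(1))
    }
  }
  if (ind > 0) {
    hit <- which(stats::runif(length(chars)) < ind)
    if (length(hit)) {
      for (i in rev(hit)) {
        if (stats::runif(1) < 0.5 && length(chars) > 1L) {
          chars <- chars[-i]                       # deletion
        } else {
          chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = i)
        }
      }
    }
  }
  chars
}

# Truncate an ancestor character vector to fraction f from a random end.
# Returns list(chars, fraction) with the realized fraction keep/len.
truncate_frac <- function(chars, f) {
  n <- length(chars)
  keep <- max(1L, min(n, as.integer(round(f * n))))
  if (keep < n) {
    if (stats::runif(1) < 0.5) chars <- chars[seq_len(keep)]         # keep 5'
    else chars <- chars[(n - keep + 1L):n]                           # keep 3'
  }
  list(chars = chars, fraction = keep / n)
}

global_identity <- function(a, b) {
  mat <- align_submat(scoring_scheme())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(p == s) / length(p)
}

#' Generate twin transcript sets with known truth
#'
#' Draws `n_orthologs` random ancestor sequences and derives one descendant
#' copy per species by independent substitution/indel mutation (see
#' [sim_config()] for the rate model), plus unrelated species-specific
#' transcripts. Each descendant may be truncated to a drawn coverage fraction
#' of its ancestor. The realized pairwise identity of every ortholog pair is
#' computed once by optimal global alignment and recorded in the truth table.
#'
#' @param config a [sim_config()].
#' @return A list with elements `a`, `b` (descendant [seq_set]s),
#'   `references` (full-length ancestors), and `truth`, a list with
#'   `ortholog_pairs` (data.frame `id_a`, `id_b`, `ref_id`,
#'   `realized_identity`), `specific_a`/`specific_b` id vectors,
#'   `coverage_fraction` (named numeric, realized fraction per transcript),
#'   `read_origin` (filled by [generate_reads()]) and `go_truth` (filled by
#'   [generate_go_annotations()]).
#' @examples
#' sim <- generate_twin_transcriptomes(sim_config(n_orthologs = 5,
#'   n_specific_a = 2, n_specific_b = 2, length_range = c(100, 200)))
#' sim$truth$ortholog_pairs
#' @export
generate_twin_transcriptomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    h <- per_copy_rate(config$divergence)
    hi <- config$indel_rate / 2
    n <- config$n_orthologs
    lens <- if (n > 0) draw_range(config$length_range[1],
                                  config$length_range[2], n) else integer()
    ids_a <- sprintf("A_ortho_%04d", seq_len(n))
    ids_b <- sprintf("B_ortho_%04d", seq_len(n))
    ref_ids <- sprintf("ref_%04d", seq_len(n))
    refs <- character(n); seqs_a <- character(n); seqs_b <- character(n)
    frac <- numeric(0)
    for (i in seq_len(n)) {
      anc <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
      refs[i] <- paste(anc, collapse = "")
      for (side in c("a", "b")) {
        f <- if (length(config$fragment_fractions) == 1L) config$fragment_fractions
             else sample(config$fragment_fractions, 1L)
        tr <- truncate_frac(anc, f)
        mut <- mutate_seq(tr$chars, h, hi)
        id <- if (side == "a") ids_a[i] else ids_b[i]
        if (side == "a") seqs_a[i] <- paste(mut, collapse = "")
        else seqs_b[i] <- paste(mut, collapse = "")
        frac[id] <- tr$fraction
      }
    }
    spec_a <- character(config$n_specific_a)
    ids_sa <- sprintf("A_spec_%04d", seq_len(config$n_specific_a))
    for (i in seq_len(config$n_specific_a)) {
      spec_a[i] <- random_dna(draw_range(config$length_range[1],
                                         config$length_range[2]))
    }
    spec_b <- character(config$n_specific_b)
    ids_sb <- sprintf("B_spec_%04d", seq_len(config$n_specific_b))
    for (i in seq_len(config$n_specific_b)) {
      spec_b[i] <- random_dna(draw_range(config$length_range[1],
                                         config$length_range[2]))
    }
    a <- seq_set("a", id = c(ids_a, ids_sa), seq = c(seqs_a, spec_a))
    b <- seq_set("b", id = c(ids_b, ids_sb), seq = c(seqs_b, spec_b))
    references <- seq_set("references", id = ref_ids, seq = refs)
    realized <- vapply(seq_len(n), function(i)
      global_identity(seqs_a[i], seqs_b[i]), numeric(1))
    truth <- list(
      ortholog_pairs = data.frame(id_a = ids_a, id_b = ids_b, ref_id = ref_ids,
                                  realized_identity = realized,
                                  stringsAsFactors = FALSE),
      specific_a = ids_sa, specific_b = ids_sb,
      coverage_fraction = frac,
      read_origin = NULL, go_truth = NULL)
    list(a = a, b = b, references = references, truth = truth)
  })
}

#' Generate reads with the 454 library structure
#'
#' Each read is `adapter A + barcode + inner 5' adapter + insert + inner 3'
#' adapter + adapter B`, the insert being a random subsequence of a
#' transcript. With probability `homopolymer_error_rate` one existing
#' homopolymer run (>= 2 bp) inside the insert is lengthened by 1-3 bp,
#' emulating the dominant 454 error mode; the planting is recorded.
#' Transcripts shorter than the minimum insert length are skipped with a
#' warning.
#'
#' @param transcripts a [seq_set] to sample inserts from.
#' @param species_barcode 6 bp species barcode string.
#' @param config a [sim_config()]; uses `reads_per_transcript`,
#'   `read_length_range`, `homopolymer_error_rate` and `seed`.
#' @return A list with `reads` (a [seq_set]) and `read_origin`, a data.frame
#'   with columns `read_id`, `transcript_id`, `species`, `barcode`,
#'   `planted_error`.
#' @export
generate_reads <- function(transcripts, species_barcode, config) {
  stopifnot(inherits(transcripts, "seq_set"), nchar(species_barcode) == 6L,
            inherits(config, "sim_config"))
  with_seed(config$seed + sum(utf8ToInt(species_barcode)), {
    rows <- list(); seqs <- character(); ids <- character()
    k <- 0L
    min_len <- config$read_length_range[1]
    for (i in seq_along(transcripts$id)) {
      tlen <- nchar(transcripts$seq[i])
      if (config$reads_per_transcript > 0L && tlen < min_len) {
        warning("transcript ", transcripts$id[i], " shorter than minimum ",
                "insert length; skipped", call. = FALSE)
        next
      }
      for (r in seq_len(config$reads_per_transcript)) {
        ilen <- draw_range(min_len, min(tlen, config$read_length_range[2]))
        start <- sample.int(tlen - ilen + 1L, 1L)
        insert <- substr(transcripts$seq[i], start, start + ilen - 1L)
        planted <- FALSE
        if (stats::runif(1) < config$homopolymer_error_rate) {
          ext <- lengthen_run(insert)
          if (!is.null(ext)) { insert <- ext; planted <- TRUE }
        }
        k <- k + 1L
        ids[k] <- sprintf("%s_read_%05d", transcripts$label, k)
        seqs[k] <- paste0(ADAPTER_A, species_barcode, ADAPTER_5P, insert,
                          ADAPTER_3P, ADAPTER_B)
        rows[[k]] <- data.frame(read_id = ids[k],
                                transcript_id = transcripts$id[i],
                                species = transcripts$label,
                                barcode = species_barcode,
                                planted_error = planted,
                                stringsAsFactors = FALSE)
      }
    }
    reads <- seq_set(paste0(transcripts$label, "_reads"), id = ids, seq = seqs)
    origin <- if (k > 0L) do.call(rbind, rows) else
      data.frame(read_id = character(), transcript_id = character(),
                 species = character(), barcode = character(),
                 planted_error = logical(), stringsAsFactors = FALSE)
    list(reads = reads, read_origin = origin)
  })
}

# Lengthen one uniformly chosen homopolymer run (>= 2 bp) by 1-3 bp.
# Returns NULL when the insert has no qualifying run.
lengthen_run <- function(insert) {
  r <- rle(strsplit(insert, "")[[1]])
  runs <- which(r$lengths >= 2L)
  if (!length(runs)) return(NULL)
  pick <- if (length(runs) == 1L) runs else sample(runs, 1L)
  r$lengths[pick] <- r$lengths[pick] + sample(3L, 1L)
  paste(inverse.rle(r), collapse = "")
}

#' Generate GO annotations with optional planted enrichment
#'
#' Background terms are assigned to every transcript independently at a
#' uniform per-term probability. Each enriched term is assigned to the
#' designated species' planted-specific transcripts at `multiplier` times the
#' background odds.
#'
#' @param a,b the two [seq_set]s from [generate_twin_transcriptomes()].
#' @param truth the matching truth list (uses `specific_a`/`specific_b`).
#' @param n_terms number of GO terms in the vocabulary.
#' @param enriched_terms `NULL`, or a data.frame with columns `term`,
#'   `species` (`"a"` or `"b"`) and `multiplier` (> 0).
#' @param seed integer RNG seed.
#' @param background_prob per-term background annotation probability.
#' @return A list with `go` (a `go_table`: named list transcript -> GO ids)
#'   and `go_truth`, a data.frame `term`, `enriched_in` (`"none"`, `"a"` or
#'   `"b"`).
#' @export
generate_go_annotations <- function(a, b, truth, n_terms,
                                    enriched_terms = NULL, seed = 1L,
                                    background_prob = 0.15) {
  stopifnot(is_count(n_terms))
  if (!is.null(enriched_terms)) {
    stopifnot(all(c("term", "species", "multiplier") %in% names(enriched_terms)),
              all(enriched_terms$species %in% c("a", "b")))
    if (any(enriched_terms$multiplier <= 0)) stop2("multiplier must be > 0")
  }
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  go_truth <- data.frame(term = terms, enriched_in = rep("none", n_terms),
                         stringsAsFactors = FALSE)
  if (n_terms == 0L) {
    return(list(go = structure(list(), class = "go_table"), go_truth = go_truth))
  }
  with_seed(seed, {
    ids <- c(a$id, b$id)
    boosted <- matrix(FALSE, nrow = length(ids), ncol = n_terms,
                      dimnames = list(ids, terms))
    if (!is.null(enriched_terms)) {
      for (j in seq_len(nrow(enriched_terms))) {
        tm <- enriched_terms$term[j]
        if (!tm %in% terms) stop2("enriched term ", tm, " not in vocabulary")
        tgt <- if (enriched_terms$species[j] == "a") truth$specific_a
               else truth$specific_b
        boosted[tgt, tm] <- TRUE
        go_truth$enriched_in[go_truth$term == tm] <- enriched_terms$species[j]
      }
    }
    o0 <- background_prob / (1 - background_prob)
    prob <- matrix(background_prob, nrow = length(ids), ncol = n_terms)
    if (!is.null(enriched_terms)) {
      for (j in seq_len(nrow(enriched_terms))) {
        tm <- enriched_terms$term[j]
        o1 <- o0 * enriched_terms$multiplier[j]
        prob[boosted[, tm], which(terms == tm)] <- o1 / (1 + o1)
      }
    }
    draw <- matrix(stats::runif(length(ids) * n_terms), nrow = length(ids)) < prob
    go <- lapply(seq_along(ids), function(i) terms[draw[i, ]])
    names(go) <- ids
    go <- go[lengths(go) > 0L]
    list(go = structure(go, class = "go_table"), go_truth = go_truth)
  })
}

# Sense codons usable as neutral CDS filler: no stop, no ATG.
FILLER_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c(STOP_CODONS, "ATG"))

# Longest stop-free codon run (in bp) for each of the six reading frames.
max_open_runs <- function(s) {
  out <- numeric(0)
  for (seq_or in c(s, revcomp(s))) {
    L <- nchar(seq_or)
    for (off in 0:2) {
      ncod <- (L - off) %/% 3L
      if (ncod < 1L) { out <- c(out, 0); next }
      pos <- off + 3L * (seq_len(ncod) - 1L) + 1L
      is_stop <- substring(seq_or, pos, pos + 2L) %in% STOP_CODONS
      r <- rle(is_stop)
      open <- r$lengths[!r$values]
      out <- c(out, if (length(open)) 3 * max(open) else 0)
    }
  }
  out
}

#' Generate transcripts with planted CDS completeness classes
#'
#' Builds synthetic transcripts whose CDS completeness class is known by
#' construction: `complete` transcripts carry an in-frame stop directly
#' upstream of an ATG-initiated ORF terminated by a stop codon inside the
#' transcript; `n_fragment`/`c_fragment`/`both_fragment` transcripts are
#' the corresponding truncations (ATG lost, stop lost, or both); `none`
#' transcripts contain no ORF of the requested minimum length. Filler
#' codons are drawn from the 60 sense codons that are neither a stop nor
#' ATG, so no spurious in-frame starts are planted, and each transcript is
#' resampled until the planted open segment is strictly longer than the
#' longest stop-free segment of every other reading frame, so the planted
#' ORF is unambiguously the longest-ORF call.
#'
#' @param n_per_class named integer vector with any of the classes
#'   `complete`, `n_fragment`, `c_fragment`, `both_fragment`, `none`.
#' @param n_codons_range `(min, max)` CDS filler length in codons.
#' @param utr_range `(min, max)` UTR length in bp.
#' @param seed integer RNG seed.
#' @return A list with `seqs` (a [seq_set]) and `truth`, a data.frame
#'   `transcript_id`, `class`.
#' @export
generate_cds_transcripts <- function(n_per_class = c(complete = 5L,
                                                     n_fragment = 5L,
                                                     c_fragment = 5L,
                                                     both_fragment = 5L,
                                                     none = 5L),
                                     n_codons_range = c(120L, 180L),
                                     utr_range = c(9L, 45L), seed = 1L) {
  classes <- c("complete", "n_fragment", "c_fragment", "both_fragment", "none")
  stopifnot(all(names(n_per_class) %in% classes))
  with_seed(seed, {
    ids <- character(); seqs <- character(); truth_class <- character()
    filler <- function(n) paste(sample(FILLER_CODONS, n, replace = TRUE),
                                collapse = "")
    utr <- function() random_dna(3L * (draw_range(utr_range[1], utr_range[2]) %/% 3L))
    k <- 0L
    for (cl in names(n_per_class)) {
      for (i in seq_len(n_per_class[[cl]])) {
        ncod <- draw_range(n_codons_range[1], n_codons_range[2])
        stop_codon <- sample(STOP_CODONS, 1L)
        for (try in 1:500) {
          s <- switch(cl,
            complete = paste0(utr(), "TAA", "ATG", filler(ncod), stop_codon, utr()),
            # 5' truncation inside the CDS: ATG lost, stop retained
            n_fragment = paste0(filler(ncod), stop_codon, utr()),
            # 3' truncation: ATG retained, stop lost
            c_fragment = paste0(utr(), "TAA", "ATG", filler(ncod)),
            both_fragment = filler(ncod),
            none = random_dna(60L))
          if (cl == "none") break
          # planted segment length (frame +1, stop codon excluded)
          planted <- switch(cl, complete = 3 * (ncod + 1),
                            n_fragment = 3 * ncod,
                            c_fragment = 3 * (ncod + 1),
                            both_fragment = 3 * ncod)
          runs <- max_open_runs(s)
          if (max(runs[-1]) < planted) break
        }
        k <- k + 1L
        ids[k] <- sprintf("cds_%s_%03d", cl, i)
        seqs[k] <- s
        truth_class[k] <- cl
      }
    }
    list(seqs = seq_set("cds_truth", id = ids, seq = seqs),
         truth = data.frame(transcript_id = ids, class = truth_class,
                            stringsAsFactors = FALSE))
  })
}
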