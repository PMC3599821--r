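PIPELINE_STAGES <- c("simulate", "clean", "hpoly", "align", "ohr", "cds",
                     "rbh", "pdeg", "enrich", "stats")

#' Pipeline configuration
#'
#' Bundles every stage's configuration, the output directory and the master
#' seed. The seed propagates to all stochastic stages, so two runs with the
#' same configuration produce byte-identical artifacts.
#'
#' @param outdir output directory (created if missing).
#' @param seed master RNG seed.
#' @param stages character vector of enabled stages, a subset of
#'   `simulate, clean, hpoly, align, ohr, cds, rbh, pdeg, enrich, stats`.
#'   Stages whose inputs are unavailable are skipped with a log line.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param cleaning a [cleaning_config()].
#' @param scheme a [scoring_scheme()].
#' @param search a [search_config()].
#' @param min_orf_bp ORF classifier threshold, bp.
#' @param rbh_evalue,rbh_overlap RBH thresholds (e-value, percent overlap).
#' @param pdeg_evalue PDEG e-value threshold.
#' @param go_n_terms GO vocabulary size for the simulated annotation.
#' @param go_enriched optional data.frame `term`, `species`, `multiplier`
#'   of planted enrichments.
#' @param verbose print one log line per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("twintx_run_"), seed = 1L,
                            stages = PIPELINE_STAGES,
                            sim = sim_config(seed = seed),
                            cleaning = cleaning_config(),
                            scheme = scoring_scheme(),
                            search = search_config(),
                            min_orf_bp = 300L,
                            rbh_evalue = 1e-10, rbh_overlap = 90,
                            pdeg_evalue = 1e-5,
                            go_n_terms = 50L, go_enriched = NULL,
                            verbose = TRUE) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  sim$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 sim = sim, cleaning = cleaning, scheme = scheme,
                 search = search, min_orf_bp = min_orf_bp,
                 rbh_evalue = rbh_evalue, rbh_overlap = rbh_overlap,
                 pdeg_evalue = pdeg_evalue, go_n_terms = go_n_terms,
                 go_enriched = go_enriched, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full twin-transcriptome comparison
#'
#' Executes the enabled stages in dependency order: simulate the twin
#' transcript sets and reads, demultiplex and clean the reads, profile
#' homopolymers, run the all-vs-all searches, compute OHR completeness, CDS
#' classes, reciprocal best hits with the divergence summary, the
#' species-specific (PDEG) sets and their GO enrichment, and assembly
#' statistics. Every stage writes a plain TSV/FASTA artifact into
#' `config$outdir` and logs one line with its input/output counts. A
#' failing stage aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `comparison_report` collecting each stage's
#'   summary (see the vignette for the field list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log1 <- function(stage, fmt, ...) {
    if (config$verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }
  enabled <- function(s) s %in% config$stages
  art <- function(name) file.path(config$outdir, name)
  rep <- list(seed = config$seed, outdir = config$outdir)
  sim <- NULL; cleaned <- NULL

  if (enabled("simulate")) on_stage("simulate", {
    sim <- generate_twin_transcriptomes(config$sim)
    write_fasta(sim$a, art("transcripts_a.fasta"))
    write_fasta(sim$b, art("transcripts_b.fasta"))
    write_fasta(sim$references, art("references.fasta"))
    write_table(sim$truth$ortholog_pairs, art("truth_ortholog_pairs.tsv"))
    bc <- names(DEFAULT_BARCODES)
    ra <- generate_reads(sim$a, bc[1], config$sim)
    rb <- generate_reads(sim$b, bc[2], config$sim)
    sim$reads <- concat_seq_sets(list(ra$reads, rb$reads), label = "reads")
    sim$truth$read_origin <- rbind(ra$read_origin, rb$read_origin)
    write_fasta(sim$reads, art("reads.fasta"))
    write_table(sim$truth$read_origin, art("truth_read_origin.tsv"))
    log1("simulate", "%d + %d transcripts, %d reads",
         length(sim$a$id), length(sim$b$id), length(sim$reads$id))
    rep$simulate <- list(n_a = length(sim$a$id), n_b = length(sim$b$id),
                         n_reads = length(sim$reads$id))
  })

  if (enabled("clean")) {
    if (is.null(sim)) {
      log1("clean", "skipped: no reads available")
    } else on_stage("clean", {
      dm <- demultiplex_and_trim(sim$reads, config$cleaning)
      cleaned <- list()
      removed <- dm$report$removed
      for (sp in names(dm$species)) {
        fl <- filter_reads(dm$species[[sp]], config$cleaning)
        sc <- screen_rrna(fl$reads, config$cleaning, config$scheme)
        cleaned[[sp]] <- sc$reads
        removed$short <- (removed$short %||% 0L) + fl$report$removed$short
        removed$high_n <- (removed$high_n %||% 0L) + fl$report$removed$high_n
        removed$rrna <- (removed$rrna %||% 0L) + sc$report$removed$rrna
        write_fasta(sc$reads, art(paste0("cleaned_", sp, ".fasta")))
      }
      write_fasta(dm$unassigned, art("unassigned.fasta"))
      report <- cleaning_report(dm$report$input_count, removed,
                                lapply(cleaned, function(s) length(s$id)))
      write_table(data.frame(metric = c("input",
                                        paste0("removed_", names(removed)),
                                        paste0("output_", names(cleaned))),
                             count = c(report$input_count,
                                       unlist(removed, use.names = FALSE),
                                       vapply(cleaned, function(s)
                                         length(s$id), integer(1)))),
                  art("cleaning_report.tsv"))
      log1("clean", "%d reads in, %s out",
           report$input_count,
           paste(sprintf("%s=%d", names(cleaned),
                         vapply(cleaned, function(s) length(s$id), integer(1))),
                 collapse = " "))
      rep$clean <- report
    })
  }

  if (enabled("hpoly")) on_stage("hpoly", {
    targets <- c(if (!is.null(cleaned))
                   stats::setNames(cleaned, paste0("reads_", names(cleaned))),
                 if (!is.null(sim)) list(transcripts_a = sim$a,
                                         transcripts_b = sim$b))
    if (!length(targets)) {
      log1("hpoly", "skipped: no sequence sets available")
    } else {
      rep$hpoly <- lapply(targets, homopolymer_profile)
      for (nm in names(targets)) {
        write_table(profile_table(rep$hpoly[[nm]]),
                    art(paste0("hpoly_", nm, ".tsv")),
                    header = c("nucleotide", "run_length", "count"))
      }
      log1("hpoly", "profiled %s", paste(names(targets), collapse = ", "))
    }
  })

  hits <- list()
  if (enabled("align")) {
    if (is.null(sim)) {
      log1("align", "skipped: no transcript sets available")
    } else on_stage("align", {
      hits$ab <- all_vs_all(sim$a, sim$b, config$scheme, config$search)
      hits$ba <- all_vs_all(sim$b, sim$a, config$scheme, config$search)
      hits$a_ref <- all_vs_all(sim$a, sim$references, config$scheme, config$search)
      hits$b_ref <- all_vs_all(sim$b, sim$references, config$scheme, config$search)
      for (nm in names(hits)) {
        write_tabular_hits(hits[[nm]], art(paste0("hits_", nm, ".tsv")))
      }
      log1("align", "hits: ab=%d ba=%d a_ref=%d b_ref=%d",
           nrow(hits$ab), nrow(hits$ba), nrow(hits$a_ref), nrow(hits$b_ref))
    })
  }

  if (enabled("ohr")) {
    if (is.null(hits$a_ref)) {
      log1("ohr", "skipped: no reference hits available")
    } else on_stage("ohr", {
      rep$ohr <- lapply(list(a = hits$a_ref, b = hits$b_ref), function(h) {
        tab <- ohr_table(best_hits_filter(h))
        list(table = tab, mean_ohr = mean(tab$ohr),
             frac_ge_0.7 = mean(tab$ohr >= 0.7),
             n_full_length = sum(tab$ohr == 1.0))
      })
      write_table(rep$ohr$a$table, art("ohr_a.tsv"))
      write_table(rep$ohr$b$table, art("ohr_b.tsv"))
      log1("ohr", "mean OHR a=%.3f b=%.3f",
           rep$ohr$a$mean_ohr, rep$ohr$b$mean_ohr)
    })
  }

  if (enabled("cds")) {
    if (is.null(sim)) {
      log1("cds", "skipped: no transcript sets available")
    } else on_stage("cds", {
      rep$cds <- lapply(list(a = sim$a, b = sim$b), classify_cds_set,
                        min_orf_bp = config$min_orf_bp)
      write_table(rep$cds$a, art("cds_a.tsv"))
      write_table(rep$cds$b, art("cds_b.tsv"))
      log1("cds", "a: %s", paste(names(attr(rep$cds$a, "class_counts")),
                                 attr(rep$cds$a, "class_counts"),
                                 sep = "=", collapse = " "))
    })
  }

  if (enabled("rbh")) {
    if (is.null(hits$ab)) {
      log1("rbh", "skipped: no cross-species hits available")
    } else on_stage("rbh", {
      pairs <- reciprocal_best_hits(hits$ab, hits$ba,
                                    config$rbh_evalue, config$rbh_overlap)
      write_table(pairs, art("rbh_pairs.tsv"),
                  header = c("id_a", "id_b", "pct_identity", "overlap_a",
                             "overlap_b", "evalue_ab", "evalue_ba"))
      rep$rbh <- list(pairs = pairs)
      if (nrow(pairs) > 0L) {
        rep$rbh$divergence <- divergence_report(pairs)
        write_table(rep$rbh$divergence$divergent_pairs,
                    art("divergent_pairs.tsv"),
                    header = names(pairs))
        log1("rbh", "%d pairs, mean identity %.2f%%, %d divergent",
             nrow(pairs), rep$rbh$divergence$mean_identity,
             nrow(rep$rbh$divergence$divergent_pairs))
      } else log1("rbh", "no pairs")
    })
  }

  if (enabled("pdeg")) {
    if (is.null(hits$ab) || is.null(sim)) {
      log1("pdeg", "skipped: no cross-species hits available")
    } else on_stage("pdeg", {
      rep$pdeg <- list(a = species_specific(sim$a, hits$ab, config$pdeg_evalue),
                       b = species_specific(sim$b, hits$ba, config$pdeg_evalue))
      writeLines(rep$pdeg$a, art("pdeg_a.txt"))
      writeLines(rep$pdeg$b, art("pdeg_b.txt"))
      log1("pdeg", "a=%d b=%d", length(rep$pdeg$a), length(rep$pdeg$b))
    })
  }

  if (enabled("enrich")) {
    if (is.null(rep$pdeg) || is.null(sim)) {
      log1("enrich", "skipped: no PDEG sets available")
    } else on_stage("enrich", {
      ann <- generate_go_annotations(sim$a, sim$b, sim$truth,
                                     n_terms = config$go_n_terms,
                                     enriched_terms = config$go_enriched,
                                     seed = config$seed)
      write_go_table(ann$go, art("go_annotations.tsv"))
      rep$enrich <- lapply(list(a = list(test = rep$pdeg$a, ref = sim$a$id),
                                b = list(test = rep$pdeg$b, ref = sim$b$id)),
                           function(x) {
        if (!length(x$test)) return(NULL)
        go_enrich(x$test, x$ref, ann$go)
      })
      for (sp in c("a", "b")) {
        if (!is.null(rep$enrich[[sp]])) {
          write_table(rep$enrich[[sp]], art(paste0("enrich_", sp, ".tsv")))
        }
      }
      nsig <- vapply(rep$enrich, function(e)
        if (is.null(e)) 0L else sum(e$significant), integer(1))
      log1("enrich", "significant terms: a=%d b=%d", nsig[["a"]], nsig[["b"]])
    })
  }

  if (enabled("stats")) {
    if (is.null(sim)) {
      log1("stats", "skipped: no transcript sets available")
    } else on_stage("stats", {
      rep$stats <- list(a = assembly_stats(sim$a), b = assembly_stats(sim$b))
      write_table(rbind(cbind(species = "a", rep$stats$a),
                        cbind(species = "b", rep$stats$b)),
                  art("assembly_stats.tsv"))
      log1("stats", "a: N50=%d, b: N50=%d",
           rep$stats$a$n50_length, rep$stats$b$n50_length)
    })
  }

  rep$truth <- if (!is.null(sim)) sim$truth else NULL
  out <- structure(rep, class = "comparison_report")
  write_report_text(out, art("report.txt"))
  out
}

write_report_text <- function(rep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("twin-transcriptome comparison report (seed %d)", rep$seed)
  if (!is.null(rep$stats)) {
    for (sp in c("a", "b")) {
      s <- rep$stats[[sp]]
      w("assembly %s: n=%d total=%.0f mean=%.1f median=%.1f N50=%d", sp,
        s$n_sequences, s$total_bp, s$mean_length, s$median_length,
        s$n50_length)
    }
  }
  if (!is.null(rep$ohr)) {
    for (sp in c("a", "b")) {
      o <- rep$ohr[[sp]]
      w("OHR %s: mean=%.4f frac>=0.7=%.4f full-length=%d", sp,
        o$mean_ohr, o$frac_ge_0.7, o$n_full_length)
    }
  }
  if (!is.null(rep$cds)) {
    for (sp in c("a", "b")) {
      cc <- attr(rep$cds[[sp]], "class_counts")
      w("CDS %s: %s", sp, paste(names(cc), cc, sep = "=", collapse = " "))
    }
  }
  if (!is.null(rep$rbh) && nrow(rep$rbh$pairs) > 0L) {
    d <- rep$rbh$divergence
    w("RBH: n=%d identity mean=%.2f min=%.2f max=%.2f divergent(<%g%%)=%d",
      d$n_pairs, d$mean_identity, d$min_identity, d$max_identity,
      d$divergent_cutoff, nrow(d$divergent_pairs))
  }
  if (!is.null(rep$pdeg)) {
    w("PDEG: a=%d b=%d", length(rep$pdeg$a), length(rep$pdeg$b))
  }
  if (!is.null(rep$enrich)) {
    for (sp in c("a", "b")) {
      e <- rep$enrich[[sp]]
      if (!is.null(e)) w("enrichment %s: %d/%d terms significant", sp,
                         sum(e$significant), nrow(e))
    }
  }
  invisible(path)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(readLines(file.path(x$outdir, "report.txt")), sep = "\n")
  invisible(x)
}
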