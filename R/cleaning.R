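#' Read-cleaning configuration
#'
#' Defaults follow the simulated 454 library layout: reads begin with
#' adapter A, then a 6 bp species barcode, an inner 5' adapter, the insert,
#' an inner 3' adapter and adapter B. Adapter A must match at position 0
#' within `max_adapter_mismatches`; the 3'-side adapters are stripped by
#' anchored suffix matching within the same budget, or by an exact partial
#' suffix overlap of at least 8 bp (adapters running off the read end).
#'
#' @param adapter_a,adapter_b outer 454 adapters.
#' @param adapter_5p,adapter_3p inner library adapters flanking the insert.
#' @param barcodes named character vector: barcode -> species label. All
#'   barcodes must share one length.
#' @param max_adapter_mismatches mismatch budget per adapter match.
#' @param min_length minimum insert length kept by [filter_reads()], bp.
#' @param max_n_fraction maximum tolerated fraction of N residues.
#' @param rrna_reference optional [seq_set] of rRNA sequences screened
#'   against by [screen_rrna()] (`NULL` disables the screen).
#' @param rrna_min_identity,rrna_min_overlap a read is discarded as rRNA when
#'   some local alignment to the reference reaches at least this percent
#'   identity over at least this many aligned bp.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(adapter_a = ADAPTER_A, adapter_b = ADAPTER_B,
                            adapter_5p = ADAPTER_5P, adapter_3p = ADAPTER_3P,
                            barcodes = DEFAULT_BARCODES,
                            max_adapter_mismatches = 2L,
                            min_length = 100L, max_n_fraction = 0.02,
                            rrna_reference = NULL,
                            rrna_min_identity = 90, rrna_min_overlap = 100L) {
  stopifnot(length(barcodes) >= 1L, !is.null(names(barcodes)),
            length(unique(nchar(names(barcodes)))) == 1L,
            max_adapter_mismatches >= 0L, min_length >= 0L,
            max_n_fraction >= 0, max_n_fraction <= 1,
            rrna_min_identity > 0, rrna_min_identity <= 100,
            rrna_min_overlap >= 1L)
  structure(list(adapter_a = toupper(adapter_a), adapter_b = toupper(adapter_b),
                 adapter_5p = toupper(adapter_5p),
                 adapter_3p = toupper(adapter_3p),
                 barcodes = barcodes,
                 max_adapter_mismatches = as.integer(max_adapter_mismatches),
                 min_length = as.integer(min_length),
                 max_n_fraction = max_n_fraction,
                 rrna_reference = rrna_reference,
                 rrna_min_identity = rrna_min_identity,
                 rrna_min_overlap = as.integer(rrna_min_overlap)),
            class = "cleaning_config")
}

cleaning_report <- function(input_count, removed, output_counts) {
  structure(list(input_count = input_count, removed = removed,
                 output_counts = output_counts),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat("  input:", x$input_count, "\n")
  for (nm in names(x$removed)) cat(sprintf("  removed %s: %d\n", nm, x$removed[[nm]]))
  for (nm in names(x$output_counts))
    cat(sprintf("  output %s: %d\n", nm, x$output_counts[[nm]]))
  invisible(x)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Strip `adapter` from the 3' end of `s`: anchored suffix within `mm`
# mismatches, else exact partial prefix-of-adapter overlap >= min_partial bp.
strip_3p <- function(s, adapter, mm, min_partial = 8L) {
  n <- nchar(s); na <- nchar(adapter)
  if (n >= na && hamming(substr(s, n - na + 1L, n), adapter) <= mm) {
    return(substr(s, 1L, n - na))
  }
  for (l in seq(min(na - 1L, n), min_partial)) {
    if (substr(s, n - l + 1L, n) == substr(adapter, 1L, l)) {
      return(substr(s, 1L, n - l))
    }
  }
  s
}

#' Demultiplex and trim raw reads
#'
#' For each read, adapter A is matched at position 0 within the mismatch
#' budget; the following barcode assigns the read to a species. The inner
#' 5' adapter is then stripped from the 5' side, and adapter B plus the
#' inner 3' adapter from the 3' side. Reads without a recognizable adapter A
#' or with an unknown barcode go to the `"unassigned"` bin; reads whose
#' insert is empty after trimming are counted under `adapter_only`.
#'
#' @param reads a [seq_set] of raw reads.
#' @param config a [cleaning_config()].
#' @return A list with `species` (named list of [seq_set]s, one per species
#'   label present in `config$barcodes`), `unassigned` (a [seq_set]) and
#'   `report` (a `cleaning_report`).
#' @export
demultiplex_and_trim <- function(reads, config = cleaning_config()) {
  stopifnot(inherits(reads, "seq_set"), inherits(config, "cleaning_config"))
  blen <- nchar(names(config$barcodes)[1])
  na <- nchar(config$adapter_a)
  mm <- config$max_adapter_mismatches
  species <- unique(unname(config$barcodes))
  bins <- stats::setNames(lapply(species, function(s) list(id = character(), seq = character())),
                          species)
  unassigned <- list(id = character(), seq = character())
  n_adapter_only <- 0L; n_unassigned <- 0L
  for (i in seq_along(reads$id)) {
    s <- reads$seq[i]
    if (nchar(s) < na + blen ||
        hamming(substr(s, 1L, na), config$adapter_a) > mm) {
      n_unassigned <- n_unassigned + 1L
      unassigned$id <- c(unassigned$id, reads$id[i])
      unassigned$seq <- c(unassigned$seq, s)
      next
    }
    bc <- substr(s, na + 1L, na + blen)
    sp <- config$barcodes[bc]
    if (is.na(sp)) {
      n_unassigned <- n_unassigned + 1L
      unassigned$id <- c(unassigned$id, reads$id[i])
      unassigned$seq <- c(unassigned$seq, s)
      next
    }
    body <- substr(s, na + blen + 1L, nchar(s))
    n5 <- nchar(config$adapter_5p)
    if (nchar(body) >= n5 &&
        hamming(substr(body, 1L, n5), config$adapter_5p) <= mm) {
      body <- substr(body, n5 + 1L, nchar(body))
    }
    body <- strip_3p(body, config$adapter_b, mm)
    body <- strip_3p(body, config$adapter_3p, mm)
    if (!nzchar(body)) {
      n_adapter_only <- n_adapter_only + 1L
      next
    }
    bins[[sp]]$id <- c(bins[[sp]]$id, reads$id[i])
    bins[[sp]]$seq <- c(bins[[sp]]$seq, body)
  }
  out <- lapply(species, function(sp)
    seq_set(sp, id = bins[[sp]]$id, seq = bins[[sp]]$seq))
  names(out) <- species
  report <- cleaning_report(
    length(reads$id),
    removed = list(adapter_only = n_adapter_only,
                   unassigned_barcode = n_unassigned),
    output_counts = lapply(out, function(s) length(s$id)))
  list(species = out,
       unassigned = seq_set("unassigned", id = unassigned$id,
                            seq = unassigned$seq, qual = NULL),
       report = report)
}

#' Length and N-content filters
#'
#' Removes reads shorter than `min_length` bp (counted under `short`) and
#' reads whose fraction of N residues exceeds `max_n_fraction` (counted
#' under `high_n`; a read failing both is counted under `short`). Survivor
#' order is preserved; the filter is idempotent.
#'
#' @param reads a trimmed [seq_set].
#' @param config a [cleaning_config()].
#' @return A list with `reads` (survivors) and `report`.
#' @export
filter_reads <- function(reads, config = cleaning_config()) {
  stopifnot(inherits(reads, "seq_set"))
  len <- nchar(reads$seq)
  nfrac <- vapply(reads$seq, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
    numeric(1), USE.NAMES = FALSE)
  short <- len < config$min_length
  high_n <- !short & nfrac > config$max_n_fraction
  keep <- !short & !high_n
  report <- cleaning_report(
    length(reads$id),
    removed = list(short = sum(short), high_n = sum(high_n)),
    output_counts = list(kept = sum(keep)))
  list(reads = reads[keep], report = report)
}

#' Screen reads against an rRNA reference
#'
#' A read is discarded when any local alignment to a reference sequence
#' reaches at least `rrna_min_identity` percent identity over at least
#' `rrna_min_overlap` aligned bp (both strands). With no reference
#' configured the screen is a pass-through.
#'
#' @param reads a [seq_set].
#' @param config a [cleaning_config()]; uses `rrna_reference`,
#'   `rrna_min_identity`, `rrna_min_overlap`.
#' @param scheme a [scoring_scheme()] for the alignments.
#' @return A list with `reads` (survivors) and `report`.
#' @export
screen_rrna <- function(reads, config = cleaning_config(),
                        scheme = scoring_scheme()) {
  stopifnot(inherits(reads, "seq_set"))
  ref <- config$rrna_reference
  if (is.null(ref) || length(ref$id) == 0L) {
    return(list(reads = reads,
                report = cleaning_report(length(reads$id),
                                         removed = list(rrna = 0L),
                                         output_counts = list(kept = length(reads$id)))))
  }
  is_rrna <- vapply(seq_along(reads$id), function(i) {
    for (j in seq_along(ref$id)) {
      hit <- local_align(list(id = reads$id[i], seq = reads$seq[i]),
                         list(id = ref$id[j], seq = ref$seq[j]),
                         scheme = scheme, both_strands = TRUE)
      if (!is.null(hit) && hit$pct_identity >= config$rrna_min_identity &&
          hit$aln_length >= config$rrna_min_overlap) return(TRUE)
    }
    FALSE
  }, logical(1))
  report <- cleaning_report(
    length(reads$id),
    removed = list(rrna = sum(is_rrna)),
    output_counts = list(kept = sum(!is_rrna)))
  list(reads = reads[!is_rrna], report = report)
}
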