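# Standard columns of the tabular hit format (BLAST outfmt-6 order), plus the
# full sequence lengths carried alongside and, for hits produced by the
# internal aligner, the exact number of gap columns.
HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "e_value", "bit_score")

empty_hit_table <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   pct_identity = numeric(), aln_length = integer(),
                   mismatches = integer(), gap_opens = integer(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   e_value = numeric(), bit_score = numeric(),
                   q_len = integer(), s_len = integer(),
                   gap_columns = integer(), stringsAsFactors = FALSE)
  df
}

#' Read sequences from FASTA or FASTQ
#'
#' The dialect is auto-detected from the first character of the file
#' (`>` for FASTA, `@` for FASTQ). Residues are uppercased and `U` is mapped
#' to `T`; any character outside A, C, G, T, N is an error. FASTQ qualities
#' are decoded as phred+33 integers. The id is the header up to the first
#' whitespace; the remainder is kept as the description.
#'
#' @param path path to a FASTA or FASTQ file.
#' @param label set label; defaults to the file name without extension.
#' @return A [seq_set].
#' @export
read_fasta <- function(path, label = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop2("file not found: ", path)
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)[1] %||% ""), 1, 1)
  if (!nzchar(first) || is.na(first)) stop2("no records in ", path)
  if (first == ">") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- NULL
  } else if (first == "@") {
    ss <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qraw <- as.character(S4Vectors::mcols(ss)$qualities)
    qual <- lapply(qraw, function(q) utf8ToInt(q) - 33L)
  } else {
    stop2("cannot detect FASTA/FASTQ dialect in ", path,
          " (first character '", first, "')")
  }
  if (length(ss) == 0L) stop2("no records in ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  seq_set(label, id = ids, seq = seqs, desc = desc, qual = qual)
}

#' Write a sequence set to FASTA (or FASTQ)
#'
#' @param x a [seq_set].
#' @param path output file path.
#' @param width line width for FASTA wrapping (one line per sequence when 0).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "seq_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$id)) {
    header <- if (nzchar(x$desc[i])) paste(x$id[i], x$desc[i]) else x$id[i]
    writeLines(paste0(">", header), con)
    s <- x$seq[i]
    if (width > 0L && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x$id)) {
    q <- if (!is.null(x$qual)) x$qual[[i]] else NULL
    if (is.null(q)) q <- rep(40L, nchar(x$seq[i]))
    writeLines(c(paste0("@", x$id[i]), x$seq[i], "+",
                 intToUtf8(q + 33L)), con)
  }
  invisible(path)
}

#' Read 12-column tabular alignment hits
#'
#' Parses the standard tab-separated hit format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). The format does
#' not carry full sequence lengths, so these are supplied as named integer
#' vectors and attached as `q_len`/`s_len`; lines referring to unknown ids
#' are an error.
#'
#' @param path hit file path.
#' @param query_lengths,subject_lengths named integer vectors mapping sequence
#'   id to full sequence length (e.g. `seq_lengths(set)`).
#' @return A hit data.frame (one row per hit) with the 12 standard columns
#'   plus `q_len`, `s_len` and `gap_columns` (`NA` for imported hits, whose
#'   gap column count is unknown).
#' @export
read_tabular_hits <- function(path, query_lengths, subject_lengths) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop2("malformed hit line ", which(nf < 12L)[1], ": expected >= 12 fields, got ",
          nf[nf < 12L][1])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  bad <- which(is.na(hits$pct_identity) | is.na(hits$aln_length) |
                 is.na(hits$q_start) | is.na(hits$q_end) |
                 is.na(hits$e_value) | is.na(hits$bit_score))
  if (length(bad)) stop2("malformed hit line ", bad[1], ": non-numeric field")
  mq <- match(hits$query_id, names(query_lengths))
  if (anyNA(mq)) stop2("unknown query id: ", hits$query_id[is.na(mq)][1])
  ms <- match(hits$subject_id, names(subject_lengths))
  if (anyNA(ms)) stop2("unknown subject id: ", hits$subject_id[is.na(ms)][1])
  hits$q_len <- as.integer(query_lengths[mq])
  hits$s_len <- as.integer(subject_lengths[ms])
  hits$gap_columns <- NA_integer_
  hits
}

#' @rdname read_tabular_hits
#' @param hits a hit data.frame as produced by [all_vs_all()] or
#'   [read_tabular_hits()].
#' @export
write_tabular_hits <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_length, hits$mismatches, hits$gap_opens,
                   hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                   format_evalue(hits$e_value), hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

format_evalue <- function(e) {
  out <- formatC(e, format = "e", digits = 2)
  out[e == 0] <- "0.0"
  out
}

#' Write a flat table of records as TSV
#'
#' All rows must share the same field names; floating point values are
#' rendered with 4 decimal places, integers without decimals. A header line
#' is always written, taken from the first row (or from `header` when the
#' row list is empty).
#'
#' @param rows a data.frame, or a list of named lists/vectors with identical
#'   names.
#' @param path output path.
#' @param header column names to use for an empty `rows`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, header = NULL) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (length(rows) == 0L) {
    if (is.null(header)) stop2("empty row list needs an explicit header")
    writeLines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  } else {
    nm <- names(rows[[1]])
    same <- vapply(rows, function(r) identical(names(r), nm), logical(1))
    if (!all(same)) stop2("heterogeneous rows: field names differ at row ",
                          which(!same)[1])
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(as.list(r), stringsAsFactors = FALSE)))
  }
  cols <- vapply(names(df), function(cn) {
    col <- df[[cn]]
    if (is.double(col)) fmt_num(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L, dimnames = list(NULL, names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a transcript-to-GO annotation table
#'
#' Two tab-separated columns (transcript id, GO term id), one pair per line;
#' a header line is detected and skipped if its second field is not a GO id.
#'
#' @param path TSV path.
#' @return A named list mapping transcript id to a character vector of GO
#'   term ids (class `go_table`).
#' @export
read_go_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), class = "go_table"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop2("malformed GO table line ", which(lengths(fields) < 2L)[1])
  }
  tid <- vapply(fields, `[`, character(1), 1L)
  term <- vapply(fields, `[`, character(1), 2L)
  if (!grepl("^GO:\\d{7}$", term[1])) { # header line
    tid <- tid[-1]; term <- term[-1]
  }
  bad <- !grepl("^GO:\\d{7}$", term)
  if (any(bad)) stop2("invalid GO term id '", term[bad][1], "'")
  structure(split(term, tid), class = "go_table")
}

#' @rdname read_go_table
#' @param go a `go_table` (named list transcript -> GO ids).
#' @export
write_go_table <- function(go, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("transcript_id\tgo_id", con)
  for (tid in names(go)) {
    if (length(go[[tid]]))
      writeLines(paste(tid, sort(go[[tid]]), sep = "\t"), con)
  }
  invisible(path)
}
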