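#' Sequence sets
#'
#' A `seq_set` is the package's container for a collection of nucleotide
#' sequences (reads or transcripts): parallel vectors of ids, descriptions
#' and residue strings, plus optional per-record phred quality vectors.
#' Residues are uppercase over the alphabet A, C, G, T, N.
#'
#' @param label single string naming the set (species or sample).
#' @param id character vector of unique, non-empty record ids.
#' @param seq character vector of residue strings, same length as `id`.
#' @param desc optional character vector of descriptions (default empty).
#' @param qual optional list of integer phred vectors, one per record, each
#'   the same length as its sequence, or `NULL` when qualities are absent.
#' @return An object of class `seq_set`.
#' @examples
#' s <- seq_set("demo", id = c("a", "b"), seq = c("ACGT", "TTTT"))
#' n_seq(s)
#' seq_lengths(s)
#' @export
seq_set <- function(label, id = character(), seq = character(),
                    desc = NULL, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop2("id and seq must have the same length")
  desc <- if (is.null(desc)) rep("", length(id)) else as.character(desc)
  if (length(desc) != length(id)) stop2("desc must match the number of records")
  x <- structure(list(label = as.character(label)[1], id = id, desc = desc,
                      seq = seq, qual = qual),
                 class = "seq_set")
  validate_seq_set(x)
  x
}

validate_seq_set <- function(x) {
  if (anyDuplicated(x$id)) {
    stop2("duplicate sequence id: ", x$id[duplicated(x$id)][1])
  }
  if (any(!nzchar(x$id))) stop2("empty sequence id")
  if (any(nchar(x$seq) < 1L)) {
    stop2("zero-length sequence for id: ", x$id[nchar(x$seq) < 1L][1])
  }
  bad <- grepl("[^ACGTN]", x$seq)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr("[^ACGTN]", x$seq[i])
    stop2("non-IUPAC character '", substr(x$seq[i], pos, pos),
          "' in record '", x$id[i], "' at position ", as.integer(pos))
  }
  if (!is.null(x$qual)) {
    if (length(x$qual) != length(x$id)) stop2("qual must match the number of records")
    ok <- vapply(seq_along(x$qual), function(i) {
      is.null(x$qual[[i]]) || length(x$qual[[i]]) == nchar(x$seq[i])
    }, logical(1))
    if (!all(ok)) stop2("quality length differs from sequence length for id: ",
                        x$id[!ok][1])
  }
  invisible(x)
}

#' @rdname seq_set
#' @param x a `seq_set`.
#' @export
n_seq <- function(x) length(x$id)

#' @rdname seq_set
#' @export
seq_lengths <- function(x) stats::setNames(nchar(x$seq), x$id)

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
`[.seq_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(label = x$label, id = x$id[i], desc = x$desc[i],
                 seq = x$seq[i],
                 qual = if (is.null(x$qual)) NULL else x$qual[i]),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set '%s': %d sequences, %s bp total>\n",
              x$label, length(x$id),
              format(sum(nchar(x$seq)), big.mark = ",")))
  show <- utils::head(seq_along(x$id), 6L)
  for (i in show) {
    s <- x$seq[i]
    cat(sprintf("  %s (%d bp) %s%s\n", x$id[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x$id) > 6L) cat(sprintf("  ... and %d more\n", length(x$id) - 6L))
  invisible(x)
}

# Bind several seq_sets (ids must stay unique).
concat_seq_sets <- function(sets, label = sets[[1]]$label) {
  qual <- NULL
  if (any(vapply(sets, function(s) !is.null(s$qual), logical(1)))) {
    qual <- do.call(c, lapply(sets, function(s) {
      s$qual %||% rep(list(NULL), length(s$id))
    }))
  }
  seq_set(label,
          id = unlist(lapply(sets, `[[`, "id"), use.names = FALSE),
          seq = unlist(lapply(sets, `[[`, "seq"), use.names = FALSE),
          desc = unlist(lapply(sets, `[[`, "desc"), use.names = FALSE),
          qual = qual)
}
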