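#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Table layout `(a, b; c, d)`: the two-sided p-value sums the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. The odds
#' ratio reported is the sample odds ratio `a*d / (b*c)` (`Inf` when
#' `b*c == 0` and `a*d > 0`). A degenerate margin gives p = 1 with a
#' message.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return A list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(5, 5, 5, 5)
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    message("degenerate 2x2 margin; p = 1")
    or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else a * d / (b * c)
    return(list(odds_ratio = or, p_value = 1))
  }
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                          alternative = "two.sided")$p.value
  or <- if (b * c == 0) Inf else a * d / (b * c)
  list(odds_ratio = or, p_value = min(1, p))
}

#' GO-term enrichment of a transcript subset
#'
#' Tests every GO term annotated in the reference set for over- or
#' under-representation in the test subset with a two-sided Fisher exact
#' test. The 2x2 table compares the test set against the reference set
#' *minus* the test set, so the two columns are disjoint and the test's
#' independence assumption holds. P-values are corrected across all tested
#' terms (Benjamini-Hochberg by default).
#'
#' @param test_ids transcript ids of the test subset (non-empty, must be a
#'   subset of `reference_ids`).
#' @param reference_ids transcript ids of the full reference set.
#' @param go a `go_table` (named list transcript -> GO ids, see
#'   [read_go_table()]).
#' @param alpha significance level applied to adjusted p-values.
#' @param method multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return A data.frame sorted by adjusted p-value with columns `term`,
#'   `a_count`, `b_count` (term carriers in test / reference-only),
#'   `a_total`, `b_total`, `odds_ratio`, `direction` (`"over"` or
#'   `"under"`), `p_value`, `p_adjusted`, `significant`.
#' @export
go_enrich <- function(test_ids, reference_ids, go, alpha = 0.05,
                      method = "BH") {
  if (length(test_ids) == 0L) stop2("empty test set")
  if (!all(test_ids %in% reference_ids)) {
    stop2("test set must be a subset of the reference set")
  }
  test_ids <- unique(test_ids)
  reference_ids <- unique(reference_ids)
  rest_ids <- setdiff(reference_ids, test_ids)
  ann <- go[names(go) %in% reference_ids]
  terms <- sort(unique(unlist(ann, use.names = FALSE)))
  if (!length(terms)) {
    return(data.frame(term = character(), a_count = integer(),
                      b_count = integer(), a_total = integer(),
                      b_total = integer(), odds_ratio = numeric(),
                      direction = character(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  carriers <- lapply(stats::setNames(terms, terms), function(tm)
    names(ann)[vapply(ann, function(v) tm %in% v, logical(1))])
  a_total <- length(test_ids); b_total <- length(rest_ids)
  rows <- lapply(terms, function(tm) {
    a <- sum(carriers[[tm]] %in% test_ids)
    c_ <- length(carriers[[tm]]) - a
    ft <- suppressMessages(fisher_exact(a, a_total - a, c_, b_total - c_))
    prop_a <- a / a_total
    prop_b <- if (b_total > 0) c_ / b_total else 0
    data.frame(term = tm, a_count = a, b_count = c_,
               a_total = a_total, b_total = b_total,
               odds_ratio = ft$odds_ratio,
               direction = if (prop_a >= prop_b) "over" else "under",
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = method)
  out$significant <- out$p_adjusted <= alpha
  out <- out[order(out$p_adjusted, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
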