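#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of a plain character vector of DNA strings (A,C,G,T,N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stop2 <- function(...) stop(..., call. = FALSE)

# Uniform integer draws from [lo, hi], safe against sample()'s scalar
# expansion when lo == hi.
draw_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

fmt_num <- function(x, digits = 4L) {
  ifelse(is.na(x), "NA",
         ifelse(abs(x - round(x)) < .Machine$double.eps * 4 & abs(x) < 1e15,
                format(round(x), scientific = FALSE, trim = TRUE),
                formatC(x, format = "f", digits = digits)))
}
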