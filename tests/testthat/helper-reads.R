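# Structure-aware stripping for simulated reads (lengths of the planted
# adapters are fixed: outer A 30 bp, barcode 6 bp, inner 5' 17 bp, inner 3'
# 20 bp, outer B 30 bp). Independent of the cleaning module under test.
strip_known_structure <- function(read, barcode) {
  stopifnot(substr(read, 31, 36) == barcode)
  substr(read, 30 + 6 + 17 + 1, nchar(read) - 20 - 30)
}

# TRUE when shortening exactly one homopolymer run of `insert` by 1-3 bp
# recovers an exact substring of `origin`.
shrinks_to_substring <- function(insert, origin) {
  r <- rle(strsplit(insert, "")[[1]])
  for (i in which(r$lengths >= 3L)) {
    for (k in 1:3) {
      if (r$lengths[i] - k < 2L) next
      r2 <- r
      r2$lengths[i] <- r2$lengths[i] - k
      if (grepl(paste(inverse.rle(r2), collapse = ""), origin, fixed = TRUE)) {
        return(TRUE)
      }
    }
  }
  FALSE
}
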