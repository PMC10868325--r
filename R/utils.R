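# Shared sequence helpers.

.BASES <- c("A", "C", "G", "T")

# Reverse-complement of a character vector of DNA strings (code-point
# reversal after complement; cross-checked against Biostrings in the tests).
revcomp <- function(x) {
  vapply(chartr("ACGTN", "TGCAN", x),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

# Complement of single bases (vectorized over characters).
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Random DNA string(s) drawn from the current RNG stream.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE), collapse = ""), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write lines with '\n' endings (binary mode keeps output byte-stable across
# platforms).
write_lines_lf <- function(lines, con) {
  if (is.character(con)) {
    con <- file(con, open = "wb")
    on.exit(close(con))
  }
  writeLines(lines, con, sep = "\n")
  invisible(sum(nchar(lines, type = "bytes")) + length(lines))
}
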