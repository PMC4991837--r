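# Shared internal helpers.

AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Residues safe for random flanks/spacers: cannot seed a heptamer (no W) or a
# zinc finger (no C, no H).
AA_SAFE <- setdiff(AA20, c("C", "H", "W"))

rand_aa <- function(n, alphabet = AA_SAFE) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
assert_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}
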