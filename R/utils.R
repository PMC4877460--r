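# Internal helpers shared across modules.

# Stop with a classed argument error (testable with class = "miRtrend_error").
abort_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("miRtrend_error", "error")))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# Reverse complement of DNA character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Number of mismatching positions between two equal-length strings.
str_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Run code under a temporary RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

tsv_write <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tsv_read <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
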