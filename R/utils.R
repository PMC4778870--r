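# Reverse complement over the mixed DNA/RNA alphabet used throughout:
# both T and U complement to A; U never appears in output (A pairs to T).
# Gap characters are preserved so gapped alignment rows can be flipped.
rev_comp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    comp <- chartr("ACGTUN", "TGCAAN", toupper(s))
    intToUtf8(rev(utf8ToInt(comp)))
  }, character(1), USE.NAMES = FALSE)
}

# Strip alignment gaps from a gapped row.
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# sample() without the scalar-x surprise: always samples from the elements
# of x, even when x has length 1.
sample_ids <- function(x, size) x[sample.int(length(x), size)]

assert_count_vector <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    abort(sprintf("`%s` must be a vector of non-negative integer counts.", name),
          class = "ptbseq_input_error")
  }
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name),
          class = "ptbseq_input_error")
  }
}
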