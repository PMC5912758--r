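# Shared fixtures and small utilities for the test suite.

toy_db <- function() {
  seq_db(c("abcbac", "acbcab", "bcbabc", "acbabc"),
         alphabet = custom_alphabet(c("a", "b", "c")))
}

adh_db <- function() example_db("adh_short")

# Random database over the first `alpha_size` lowercase letters.
random_db <- function(n_seq, max_len, alpha_size, seed) {
  set.seed(seed)
  syms <- letters[seq_len(alpha_size)]
  lens <- sample.int(max_len, n_seq, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(syms, L, replace = TRUE), collapse = "")
  }, character(1))
  seq_db(seqs, alphabet = custom_alphabet(syms))
}

# Named support-count vector from a mining result, in result order.
support_counts <- function(result) {
  out <- vapply(result, `[[`, integer(1), "support_count")
  names(out) <- vapply(result, `[[`, character(1), "pattern")
  out
}

# Naive occurrence scan used as an independent check of find_occurrences.
naive_occurrences <- function(pattern, sequence) {
  k <- nchar(pattern)
  n <- nchar(sequence)
  if (k > n) return(integer(0))
  which(vapply(seq_len(n - k + 1L), function(i) {
    substr(sequence, i, i + k - 1L) == pattern
  }, logical(1)))
}
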