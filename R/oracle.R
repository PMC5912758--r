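#' Brute-force enumeration of frequent contiguous substrings
#'
#' Independent reference implementation used to validate the miner on small
#' inputs. It enumerates every substring of every sequence directly (no
#' position tables, no candidate join, no pruning — nothing shared with the
#' miner's machinery), counts for each distinct substring the number of
#' DISTINCT sequences containing it (containment, not occurrence count), and
#' returns those meeting the threshold. Quadratic in sequence length: meant
#' for toy and small synthetic databases only.
#'
#' @param db A [seq_db()].
#' @param mincount Integer minimum support count (>= 1).
#' @param max_len Optional cap on substring length.
#' @return Named integer vector: pattern string -> support count, ordered by
#'   length then lexicographic (byte order).
#' @examples
#' db <- seq_db(c("abcbac", "acbcab", "bcbabc", "acbabc"),
#'              alphabet = custom_alphabet(c("a", "b", "c")))
#' enumerate_frequent_substrings(db, 4)
#' @export
enumerate_frequent_substrings <- function(db, mincount, max_len = Inf) {
  stopifnot(inherits(db, "seq_db"), mincount >= 1L)
  per_seq <- lapply(db$sequences, function(s) {
    n <- nchar(s)
    if (n == 0L) return(character(0))
    subs <- unlist(lapply(seq_len(n), function(i) {
      j_max <- if (is.finite(max_len)) min(n, i + max_len - 1L) else n
      if (j_max < i) return(character(0))
      substring(s, i, i:j_max)
    }), use.names = FALSE)
    unique(subs)
  })
  counts <- table(unlist(per_seq, use.names = FALSE))
  counts <- counts[counts >= mincount]
  out <- as.integer(counts)
  names(out) <- names(counts)
  ord <- order(nchar(names(out)), names(out), method = "radix")
  out[ord]
}
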