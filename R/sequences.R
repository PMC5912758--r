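#' Sequence databases
#'
#' A `seq_db` is an ordered, index-addressable collection of identified
#' residue strings sharing one alphabet — the in-memory representation of a
#' biological sequence database. Sequences are stored as plain character
#' strings; the n-th record is addressed by its 1-based integer index.
#'
#' @param sequences Character vector of residue strings.
#' @param ids Record identifiers; defaults to `"1"`, `"2"`, ... in input
#'   order.
#' @param alphabet A [bio_alphabet()], a kind name (`"dna"`, `"rna"`,
#'   `"protein"`), or `"auto"` to detect from the data.
#' @param mode Validation mode: `"strict"` rejects residues outside the
#'   alphabet; `"lenient"` keeps them with a warning and treats them as
#'   ordinary distinct symbols.
#' @return An object of class `seq_db`: a list with `ids`, `sequences`
#'   and `alphabet`.
#' @examples
#' db <- seq_db(c("ACGT", "GGTA"), alphabet = "dna")
#' length(db)
#' @export
seq_db <- function(sequences, ids = NULL, alphabet = "auto",
                   mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("empty database", call. = FALSE)
  if (anyNA(sequences)) stop("sequences must not be NA", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences)) {
    stop("`ids` and `sequences` lengths differ", call. = FALSE)
  }
  alphabet <- resolve_alphabet(alphabet, sequences)
  for (i in seq_along(sequences)) {
    validate_sequence(sequences[i], alphabet, mode = mode, id = ids[i])
  }
  structure(list(ids = ids, sequences = sequences, alphabet = alphabet),
            class = "seq_db")
}

#' @export
length.seq_db <- function(x) length(x$sequences)

#' @export
print.seq_db <- function(x, ...) {
  cat(sprintf("<seq_db: %d sequences, alphabet %s, lengths %d..%d>\n",
              length(x), x$alphabet$kind,
              min(nchar(x$sequences)), max(nchar(x$sequences))))
  invisible(x)
}

#' Validate a residue string against an alphabet
#'
#' In strict mode any residue outside the alphabet is an error naming the
#' sequence id, the offending symbol and its 1-based offset. In lenient mode
#' unknown residues are kept, a warning is emitted, and they participate in
#' mining as ordinary distinct symbols.
#'
#' @param residues A single residue string.
#' @param alphabet A [bio_alphabet()].
#' @param mode `"strict"` or `"lenient"`.
#' @param id Sequence identifier used in diagnostics.
#' @return The residue string, invisibly, if accepted.
#' @examples
#' validate_sequence("ACGT", bio_alphabet("dna"))
#' @export
validate_sequence <- function(residues, alphabet, mode = c("strict", "lenient"),
                              id = "<unnamed>") {
  mode <- match.arg(mode)
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!is_bio_alphabet(alphabet)) stop("`alphabet` must be a bio_alphabet",
                                       call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet$symbols)
  if (length(bad) > 0L) {
    if (mode == "strict") {
      stop(sprintf("sequence '%s': symbol '%s' at offset %d is not in the %s alphabet",
                   id, chars[bad[1]], bad[1], alphabet$kind), call. = FALSE)
    }
    warning(sprintf("sequence '%s': %d residue(s) outside the %s alphabet (e.g. '%s' at offset %d); kept as ordinary symbols",
                    id, length(bad), alphabet$kind, chars[bad[1]], bad[1]),
            call. = FALSE)
  }
  invisible(residues)
}

#' Test one contiguous occurrence
#'
#' Checks whether `pattern` occurs in `sequence` starting at the given
#' 1-based position, i.e. whether `sequence[start .. start+k-1]` exists and
#' equals the pattern residue-for-residue. A start position that runs off the
#' end of the sequence yields `FALSE`, not an error.
#'
#' @param pattern Pattern string (length >= 1).
#' @param sequence Residue string.
#' @param start 1-based start position.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_contiguous_occurrence("abc", "abcbac", 1)
#' @export
is_contiguous_occurrence <- function(pattern, sequence, start) {
  stopifnot(nchar(pattern) >= 1L, length(start) == 1L)
  start <- as.integer(start)
  if (start < 1L) return(FALSE)
  k <- nchar(pattern)
  if (start + k - 1L > nchar(sequence)) return(FALSE)
  substr(sequence, start, start + k - 1L) == pattern
}
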