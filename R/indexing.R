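#' Find all occurrence start positions of a pattern in one sequence
#'
#' Returns every 1-based start position at which `pattern` occurs in
#' `sequence`, including overlapping occurrences (e.g. `"aa"` in `"aaaa"`
#' starts at 1, 2 and 3). Absence is an empty integer vector, never an error.
#'
#' @param pattern Pattern string (length >= 1).
#' @param sequence Residue string.
#' @return Strictly increasing integer vector of start positions.
#' @examples
#' find_occurrences("b", "bcbabc")
#' find_occurrences("aa", "aaaa")
#' @export
find_occurrences <- function(pattern, sequence) {
  k <- nchar(pattern)
  stopifnot(k >= 1L)
  n <- nchar(sequence)
  if (k > n) return(integer(0))
  if (k == 1L) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    return(which(chars == pattern))
  }
  # anchor on the first residue, then verify the rest of the window
  first <- substr(pattern, 1L, 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  starts <- which(chars == first)
  starts <- starts[starts + k - 1L <= n]
  if (length(starts) == 0L) return(integer(0))
  hits <- substring(sequence, starts, starts + k - 1L) == pattern
  starts[hits]
}

#' Build the position table and database index for one pattern
#'
#' One pass over the database (or over an index-restricted view of it)
#' collects, per sequence, the sorted start positions of `pattern` (the
#' position table, ST) and the sorted indices of the sequences that contain
#' it at least once (the DB-Index). The position table always has one row per
#' sequence of the full database: rows for sequences outside the restriction,
#' and rows where the pattern is absent, are empty. The DB-Index cardinality
#' therefore always equals the number of non-empty rows.
#'
#' @param db A [seq_db()].
#' @param pattern Pattern string (length >= 1).
#' @param restrict Optional integer vector of 1-based sequence indices: only
#'   these sequences are scanned.
#' @return A list with `pattern`, `st` (list of integer vectors, one per
#'   database sequence), `dbindex` (sorted integer vector), `support_count`
#'   and `support`, of class `pattern_record`.
#' @examples
#' db <- seq_db(c("abcbac", "acbcab", "bcbabc", "acbabc"),
#'              alphabet = custom_alphabet(c("a", "b", "c")))
#' build_st_dbindex(db, "a")
#' @export
build_st_dbindex <- function(db, pattern, restrict = NULL) {
  stopifnot(inherits(db, "seq_db"))
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L) {
    stop("`pattern` must be a single non-empty string", call. = FALSE)
  }
  n <- length(db)
  scan <- if (is.null(restrict)) seq_len(n) else sort(unique(as.integer(restrict)))
  if (length(scan) > 0L && (min(scan) < 1L || max(scan) > n)) {
    stop("`restrict` indices out of range", call. = FALSE)
  }
  st <- rep(list(integer(0)), n)
  for (i in scan) {
    st[[i]] <- find_occurrences(pattern, db$sequences[i])
  }
  new_pattern_record(pattern, st, n)
}

# Assemble a pattern_record from an ST; the DB-Index is derived from the
# non-empty rows, so the Property-1 identity holds by construction.
new_pattern_record <- function(pattern, st, db_size) {
  dbindex <- which(lengths(st) > 0L)
  structure(
    list(pattern = pattern, st = st, dbindex = dbindex,
         support_count = length(dbindex),
         support = length(dbindex) / db_size),
    class = "pattern_record"
  )
}

#' @export
print.pattern_record <- function(x, ...) {
  cat(sprintf("<pattern_record '%s': support %d/%d (%.1f%%), sequences {%s}>\n",
              x$pattern, x$support_count, length(x$st), 100 * x$support,
              paste(x$dbindex, collapse = ",")))
  invisible(x)
}

#' Count support from a position table
#'
#' Support is counted from the index structures alone, never by rescanning
#' sequences: the support count is the number of non-empty position-table
#' rows (equivalently the DB-Index cardinality), and the support fraction is
#' that count divided by the database size.
#'
#' @param st Position table: a list with one integer vector per database
#'   sequence.
#' @param db_size Number of sequences in the database.
#' @return A list with `support_count` and `support`.
#' @examples
#' support_of(list(c(2L), integer(0), c(7L), integer(0)), 4)
#' @export
support_of <- function(st, db_size) {
  if (db_size == 0L) stop("database size must be positive", call. = FALSE)
  if (length(st) != db_size) {
    stop("position table must have one row per database sequence", call. = FALSE)
  }
  cnt <- sum(lengths(st) > 0L)
  list(support_count = cnt, support = cnt / db_size)
}

# Integer support threshold: smallest count c with c/n >= minsup, computed
# with a guard against floating-point round-up at exact boundaries.
mincount_for <- function(minsup, n) {
  if (!is.numeric(minsup) || length(minsup) != 1L || is.na(minsup) ||
      minsup <= 0 || minsup > 1) {
    stop("`minsup` must be a fraction in (0, 1]", call. = FALSE)
  }
  max(1L, as.integer(ceiling(minsup * n - 1e-9)))
}
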