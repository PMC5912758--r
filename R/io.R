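#' Read a sequence database from a file
#'
#' Two input formats: standard multi-record FASTA (record order preserved,
#' full description lines kept as ids), or plain text with one sequence per
#' line (ids are the 1-based line numbers). Residues are uppercased on read
#' by default, matching FASTA conventions. With `alphabet = "auto"` the
#' alphabet is detected from the data: protein if any symbol falls outside
#' `{A,C,G,T,U}`, RNA if `U` is present, otherwise DNA.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"lines"`.
#' @param alphabet A [bio_alphabet()], a kind name, or `"auto"`.
#' @param mode Validation mode, `"strict"` or `"lenient"` (see
#'   [validate_sequence()]).
#' @param uppercase Uppercase residues on read (default `TRUE`).
#' @return A [seq_db()].
#' @export
read_seq_db <- function(path, format = c("fasta", "lines"),
                        alphabet = "auto", mode = c("strict", "lenient"),
                        uppercase = TRUE) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    ids <- names(set)
  } else {
    seqs <- readLines(path, warn = FALSE)
    seqs <- seqs[nzchar(trimws(seqs))]
    seqs <- trimws(seqs)
    ids <- as.character(seq_along(seqs))
  }
  if (length(seqs) == 0L) stop("empty database", call. = FALSE)
  if (uppercase) seqs <- toupper(seqs)
  seq_db(seqs, ids = ids, alphabet = alphabet, mode = mode)
}

#' Write a sequence database as multi-record FASTA
#'
#' @param db A [seq_db()].
#' @param path Output file.
#' @param provenance_path Optional path for a tab-separated provenance
#'   sidecar (sequence id, motif, offset) when `db` carries a `provenance`
#'   attribute from [generate_database()].
#' @return `path`, invisibly.
#' @export
write_seq_db <- function(db, path, provenance_path = NULL) {
  stopifnot(inherits(db, "seq_db"))
  set <- Biostrings::BStringSet(db$sequences)
  names(set) <- db$ids
  Biostrings::writeXStringSet(set, filepath = path)
  prov <- attr(db, "provenance")
  if (!is.null(provenance_path) && !is.null(prov)) {
    utils::write.table(prov, provenance_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Render a mining result as a data frame
#'
#' One row per frequent pattern, in the miner's deterministic order:
#' pattern, length, support count, support fraction, the 1-based DB-Index as
#' a comma-separated string, and the occurrence positions per containing
#' sequence as `"seqindex:p1,p2,..."` entries joined by semicolons. All
#' coordinates and indices are 1-based.
#'
#' @param x A `bsp_result` from [mine_bsp()].
#' @param ... Unused.
#' @return A data frame with one row per pattern.
#' @export
as.data.frame.bsp_result <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(pattern = character(0), length = integer(0),
                      support_count = integer(0), support = numeric(0),
                      db_indices = character(0), positions = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(unclass(x), function(r) {
    pos <- vapply(r$dbindex, function(i) {
      sprintf("%d:%s", i, paste(r$st[[i]], collapse = ","))
    }, character(1))
    data.frame(pattern = r$pattern, length = nchar(r$pattern),
               support_count = r$support_count, support = r$support,
               db_indices = paste(r$dbindex, collapse = ","),
               positions = paste(pos, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a pattern report
#'
#' TSV: a header row plus one line per pattern. JSON: an array of objects
#' with the same fields. Identical inputs produce byte-identical files.
#'
#' @param result A `bsp_result` from [mine_bsp()].
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(result)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
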