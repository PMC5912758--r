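#' Residue alphabets
#'
#' Constructors for the residue alphabets over which sequence databases are
#' defined. The three named alphabets are the standard ones: DNA
#' \code{{A,C,G,T}}, RNA \code{{A,C,G,U}} and the 20 one-letter amino-acid
#' codes. `custom_alphabet()` builds an alphabet from an arbitrary set of
#' single-character symbols, which is convenient for toy examples and for
#' non-standard residue codes.
#'
#' @param kind One of `"dna"`, `"rna"`, `"protein"` (case-insensitive).
#' @param symbols Character vector of unique single-character symbols.
#' @return An object of class `bio_alphabet`: a list with elements `kind`
#'   and `symbols`.
#' @examples
#' bio_alphabet("dna")
#' custom_alphabet(c("a", "b", "c"))
#' @export
bio_alphabet <- function(kind = c("dna", "rna", "protein")) {
  kind <- match.arg(tolower(kind), c("dna", "rna", "protein"))
  symbols <- switch(kind,
    dna = c("A", "C", "G", "T"),
    rna = c("A", "C", "G", "U"),
    protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  )
  structure(list(kind = kind, symbols = symbols), class = "bio_alphabet")
}

#' @rdname bio_alphabet
#' @export
custom_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 1L || anyNA(symbols)) {
    stop("a custom alphabet needs at least one non-NA symbol", call. = FALSE)
  }
  if (any(nchar(symbols) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be unique", call. = FALSE)
  }
  structure(list(kind = "custom", symbols = sort(symbols)),
            class = "bio_alphabet")
}

#' @export
print.bio_alphabet <- function(x, ...) {
  cat(sprintf("<bio_alphabet: %s, %d symbols: %s>\n",
              x$kind, length(x$symbols), paste(x$symbols, collapse = "")))
  invisible(x)
}

is_bio_alphabet <- function(x) inherits(x, "bio_alphabet")

# Resolve an alphabet argument: an object, a kind name, or "auto" from data.
resolve_alphabet <- function(alphabet, residues = NULL) {
  if (is_bio_alphabet(alphabet)) return(alphabet)
  if (!is.character(alphabet) || length(alphabet) != 1L) {
    stop("`alphabet` must be a bio_alphabet or a single string", call. = FALSE)
  }
  if (tolower(alphabet) == "auto") {
    if (is.null(residues)) stop("cannot auto-detect alphabet without data",
                                call. = FALSE)
    return(detect_alphabet(residues))
  }
  bio_alphabet(alphabet)
}

# Auto-detection: protein if any symbol outside {A,C,G,T,U};
# otherwise RNA if U present, else DNA.
detect_alphabet <- function(sequences) {
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE))
  if (any(!chars %in% c("A", "C", "G", "T", "U"))) return(bio_alphabet("protein"))
  if ("U" %in% chars) return(bio_alphabet("rna"))
  bio_alphabet("dna")
}
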