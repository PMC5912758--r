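#' Bundled example databases
#'
#' Two small databases ship with the package: `"toy"`, four 6-residue
#' sequences over the symbols a/b/c used throughout the documentation, and
#' `"adh_short"`, four members of the short-chain dehydrogenase/reductase
#' family (Pfam PF00106) that share conserved motifs such as
#' `TGITVNAVCPG` and the NAD(P)-binding `TG.TSGIG` region.
#'
#' @param name `"toy"` or `"adh_short"`.
#' @param mode Validation mode passed to [read_seq_db()]; the toy database
#'   uses non-standard symbols and is read leniently.
#' @return A [seq_db()].
#' @examples
#' example_db("toy")
#' @export
example_db <- function(name = c("toy", "adh_short"),
                       mode = c("lenient", "strict")) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  if (name == "toy") {
    path <- system.file("extdata", "toy_database.txt", package = "fcpminer",
                        mustWork = TRUE)
    # kept lowercase with an explicit custom alphabet so reported patterns
    # match the documented examples (a, ab, cbabc, ...)
    seqs <- readLines(path, warn = FALSE)
    seq_db(seqs, alphabet = custom_alphabet(c("a", "b", "c")))
  } else {
    path <- system.file("extdata", "adh_short_family.fasta",
                        package = "fcpminer", mustWork = TRUE)
    read_seq_db(path, format = "fasta", alphabet = "protein", mode = mode)
  }
}
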