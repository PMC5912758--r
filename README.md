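# fcpminer

Index-based mining of frequent contiguous patterns in biological sequences.

## The problem

Families of homologous DNA, RNA or protein sequences share conserved
contiguous runs of residues — motifs such as the NAD(P)-binding
`TGxxSGIG` region or the `TGITVNAVCPG` stretch in short-chain
dehydrogenases/reductases. Finding every contiguous substring that occurs in
at least a given fraction of the sequences of a database is a frequent-pattern
mining problem, but the generic sequential-pattern miners (PrefixSpan, SPAM
and their descendants) allow gaps, so they both report patterns a biologist
does not want and pay for a vastly larger search space. `fcpminer` is for
people who want the exhaustive, exact set of *contiguous* frequent patterns —
with their occurrence positions — from a few dozen to a few thousand
sequences, plus the tooling to validate and benchmark that search: an
independent brute-force oracle and a reproducible planted-motif generator.

## The method

For a database `D = {s_1, ..., s_n}` and a pattern `p`, two index structures
are kept:

* the **position table** `ST(p)`: one row per database sequence, row *i*
  holding the sorted 1-based start positions of `p` in `s_i` (overlapping
  occurrences included, empty row when `p` is absent);
* the **DB-Index** `I(p) = { i : p occurs in s_i }`, the sorted indices of the
  containing sequences.

The support count of `p` is `|I(p)|`, which always equals the number of
non-empty rows of `ST(p)`, so support is read off the index without touching
the sequences. `p` is **frequent** when `|I(p)| / n >= minsup` (boundary
inclusive); `mincount = ceiling(minsup * n)` is the equivalent integer
threshold.

Mining is level-wise. One scan of the database builds `ST` and `I` for every
single residue. Then, repeatedly, every ordered pair `(p, q)` of frequent
k-patterns (self-pairs included, so homopolymer runs grow) is tested for
extension:

1. **prune:** `|I(p) ∩ I(q)| >= mincount` — by anti-monotonicity the
   support of any extension is bounded by this intersection cardinality, so
   failing pairs are discarded before any work;
2. **adjacency:** some shared sequence has an occurrence of `p` at a position
   `j` and of `q` at `j + 1`, which forces the (k−1)-residue suffix of `p` to
   equal the prefix of `q`.

An admissible pair is connected into the (k+1)-pattern `p ⊕ q` (`p` plus the
last residue of `q`), and its position table is computed purely by position
arithmetic on the parents' rows — `ST(p⊕q)[i] = { j ∈ ST(p)[i] : j+1 ∈
ST(q)[i] }` over the shared indices — never by rescanning sequences. The
recursion stops when a level yields no frequent pattern. The result is the
complete set of frequent contiguous patterns of every length, each with its
position table, DB-Index, support count and support fraction, in a
deterministic order (length, then lexicographic).

## Worked example

The package ships a four-sequence toy database over the symbols a/b/c:

```r
library(fcpminer)
db <- example_db("toy")           # abcbac, acbcab, bcbabc, acbabc
mine_bsp(db, minsup = 0.5)
#> <bsp_result: 17 frequent patterns, minsup 0.5 (mincount 2) over 4 sequences>
#>    pattern length support_count support
#> 1        a      1             4    1.00
#> 2        b      1             4    1.00
#> 3        c      1             4    1.00
#> 4       ab      2             4    1.00
#> 5       ac      2             3    0.75
#> ...
```

17 patterns are frequent in at least 2 of the 4 sequences, the longest being
`cbabc` (in sequences 3 and 4). Individual index structures are inspectable:

```r
build_st_dbindex(db, "ab")
#> <pattern_record 'ab': support 4/4 (100.0%), sequences {1,2,3,4}>
```

On the bundled four-member PF00106 protein family, mining at 50% support
returns 964 patterns (longest length 28), among them the conserved 11-mers:

```r
adh <- example_db("adh_short")
df  <- as.data.frame(mine_bsp(adh, minsup = 0.5))
df[df$pattern == "TGITVNAVCPG", c("support_count", "db_indices")]
#>   support_count db_indices
#>             3      2,3,4
```

Every mining run can be cross-checked against the independent brute-force
enumerator, `enumerate_frequent_substrings()`, which shares no code with the
miner; synthetic databases with motifs planted at a controlled support come
from `generate_database(synth_spec(...))`. A command-line front end with
`mine`, `synth` and `oracle` subcommands lives at
`system.file("cli", "fcpminer", package = "fcpminer")`:

```sh
Rscript inst/cli/fcpminer mine --input family.fasta --minsup 0.5 \
    --verify-oracle --output report.tsv
```

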