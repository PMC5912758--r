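---
title: "Mining frequent contiguous patterns with position tables and a database index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining frequent contiguous patterns with position tables and a database index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcpminer)
```

## Model and assumptions

`fcpminer` treats a biological sequence database as an ordered collection of
plain residue strings over one alphabet (DNA, RNA, the 20 one-letter
amino-acid codes, or a user-supplied custom alphabet). A *pattern* is a
contiguous run of residues; two patterns are equal exactly when their strings
are equal. There is no strand logic, no reverse complement, no IUPAC
ambiguity expansion, no gaps and no mismatch tolerance: a pattern either
occurs verbatim at a position or it does not. These are deliberate modelling
choices — the method's guarantees (exactness and completeness of the result
set) depend on occurrence being a crisp, checkable predicate.

Support is *sequence containment*: the support count of a pattern is the
number of distinct sequences containing it at least once, regardless of how
many times it occurs within a sequence. A pattern is frequent when its
support fraction reaches the threshold `minsup`, boundary inclusive.

## The index structures and the level-wise search

Two structures carry all state. The position table `ST(p)` has one row per
database sequence — always, even under a restricted scan, so that row index
and database index coincide everywhere — holding the sorted 1-based start
positions of `p`, overlapping occurrences included. The DB-Index `I(p)` is
the sorted list of containing sequences; it is derived from the non-empty
rows at construction, so the identity `|I(p)| = #non-empty rows` holds by
construction and is asserted in the tests rather than trusted.

Level k+1 is generated from level k by an adjacency join over all ordered
pairs of frequent k-patterns, self-pairs included (otherwise homopolymer
runs such as `AAA` could never be reached from `AA`). A pair `(p, q)` is
joined only if:

1. `|I(p) ∩ I(q)| >= mincount`. Any extension occurs only in sequences
   containing both parents, so this intersection bounds the extension's
   support — the prune discards hopeless pairs before any position work.
2. Some shared sequence has `j ∈ ST(p)` and `j + 1 ∈ ST(q)`. For contiguous
   equal-length patterns this adjacency forces the (k−1)-suffix of `p` to
   equal the (k−1)-prefix of `q`, so the implementation groups patterns by
   (k−1)-prefix and only examines overlap-compatible pairs; this is a pure
   speed-up and cannot change the result (the oracle-equivalence suite would
   catch it if it could).

The connected pattern is `p` plus the last residue of `q` — one residue per
level. Its position table is computed by position arithmetic on the parents'
rows (`j` is a start of `p ⊕ q` in sequence `i` iff `j ∈ ST(p)[i]` and
`j + 1 ∈ ST(q)[i]`), restricted to the shared indices. A literal rescan mode
(`method = "rescan"`) rebuilds each candidate's table by scanning the
restricted view of the database instead; it exists purely to cross-validate
the index arithmetic and the tests require the two modes to agree byte for
byte. Each (k+1)-string has exactly one generating pair (its k-prefix and
k-suffix), so no duplicate records can arise; this is asserted defensively.

The recursion stops when a level produces no frequent pattern. Stated loop
guards on the index structures alone do not terminate (an empty level still
has a defined, empty index), so "no frequent survivors" is the termination
criterion used.

## Parameters

* `minsup` — minimum support fraction in (0, 1], boundary inclusive.
  Thresholding is done in exact integer arithmetic: a pattern is frequent iff
  its support count reaches `mincount = ceiling(minsup * n)`, computed once
  with a `1e-9` guard so that floating-point noise at exact boundaries such
  as `0.5 * 4` can never flip a decision. An explicit `mincount` argument
  takes precedence over `minsup` when both are given.
* `min_len`, `max_len` — report-length filters. By default every frequent
  length is reported, single residues included; `max_len` also stops the
  recursion early, which is sound because no reportable pattern lies beyond
  it.
* `maximal_only` — opt-in post-filter keeping only patterns not contained in
  any other reported pattern. It is presentation sugar: the mining result is
  complete, and maximality is decided on the reported set by substring
  containment.
* Coordinates are 1-based and inclusive everywhere a user sees them: position
  tables, DB-Indexes, reports, provenance sidecars.
* Validation is strict by default for the three named alphabets — a residue
  outside the alphabet is an error naming the sequence, symbol and offset —
  because silently admitting `X`/`N` placeholder codes would perturb pattern
  counts. A lenient mode keeps unknown residues (with a warning) and treats
  them as ordinary distinct symbols, which is also how toy alphabets and
  non-standard codes are handled.

## The brute-force oracle

`enumerate_frequent_substrings()` is an intentionally naive second
implementation of the same definition: enumerate every substring of every
sequence, deduplicate per sequence, count containing sequences, keep those
meeting the threshold. It shares no mechanism with the miner — no position
tables, no join, no prune — which is what makes the equivalence tests
meaningful: on every tested input (the worked fixtures plus 200 randomly
generated databases of up to 20 sequences, length up to 60, alphabet sizes
2–6, four thresholds) the miner must reproduce the oracle's pattern set and
support counts exactly. The oracle is quadratic in sequence length and is
not meant for large inputs.

## The synthetic generator

`generate_database(synth_spec(...))` emulates the one property of a
homologous family that matters to this method: a conserved contiguous motif
present in a controlled fraction of member sequences. Background residues
are i.i.d. uniform over the alphabet; each motif is planted into exactly
`ceiling(f * n)` sequences, chosen without replacement, at a uniformly
random valid offset, overwriting the background; the carriers and offsets
are recorded in a provenance table. Identical specs (including the seed)
generate identical databases.

Two deliberate simplifications. First, planted copies may coincide with
chance background occurrences, so the support guarantee is one-sided (at
least the target fraction) — which is exactly what the recovery property
needs. Second, when several motifs are planted, a later motif may overwrite
part of an earlier copy if offsets collide; this is deterministic given the
seed and documented rather than prevented. Real protein families have
position-specific composition, substitutions, indels and phylogenetic
correlation; none of that is modelled, so passing recovery tests demonstrate
the miner's correctness and sensitivity under clean conditions, not
performance on real families.

The default recovery condition used in the tests — a 7-residue motif planted
at support 0.8 in 50 protein sequences of length 200, mined at `minsup`
0.5 across 20 seeds — matches the scale at which a single conserved motif in
a small family is a realistic target, and is small enough that the full
suite runs in well under a minute.

## Worked fixtures and a documented discrepancy

The toy database (`example_db("toy")`: `abcbac`, `acbcab`, `bcbabc`,
`acbabc`) is small enough to verify by hand: at `minsup` 0.5 exactly 17
patterns are frequent, at 1.0 exactly 6, and the position table of `a` is
`[{1,5}, {1,5}, {4}, {1,4}]`.

```{r toy}
db <- example_db("toy")
mine_bsp(db, minsup = 0.5)
```

The protein fixture (`example_db("adh_short")`) is four members of the
short-chain dehydrogenase/reductase family, Pfam PF00106. Mining at 50%
support gives 964 frequent patterns, cross-checked exactly against the
brute-force oracle; the conserved 11-mers `TGITVNAVCPG` and `PYSASKHGVVG`
appear in sequences 2–4. A count of 263 patterns has been reported for this
family at the same threshold; exhaustive enumeration on the sequences as
printed here does not reproduce that figure under any nearby reading
(support threshold 3 gives 334, threshold 4 gives 89, maximal-only gives
76), and the occurrence positions quoted alongside it are internally
offset-consistent but do not match direct counts on these sequences —
indicating the figure was obtained on slightly different sequence text. The
enumeration result on the bundled sequences is therefore treated as the
authoritative reference; the discrepancy is reported by the test suite, not
reconciled.

## Numerical and degenerate-input choices

* Output order is deterministic: length ascending, then lexicographic in
  byte order (`method = "radix"`), independent of locale and hash order.
* Empty databases and thresholds outside (0, 1] are errors; an absent
  pattern is an empty position row, never an error.
* A zero-length sequence participates harmlessly (all rows empty).
* Pattern-table rows are kept for all sequences even when a scan is
  restricted to a DB-Index, so database indices address rows directly at
  every level.
* The report writers emit byte-identical files for identical inputs; reports
  carry 1-based coordinates only.

## Limitations

Exact contiguous matching only — no mismatches, gaps, or ambiguity codes; a
motif conserved at 90% identity but never verbatim will not be found. Memory
holds every frequent pattern's position table at the current level, so very
low thresholds on large, highly similar families are expensive (the number
of frequent patterns, not the database, dominates). The oracle and the
planted-motif guarantees are desk-scale validation tools; scalability
claims beyond that are out of scope here. Execution is single-threaded.
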