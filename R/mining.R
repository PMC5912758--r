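#' Fast frequent-pattern test from a position table
#'
#' A pattern is frequent when the fraction of non-empty rows of its position
#' table — its support — reaches the minimum support threshold, boundary
#' inclusive. The test reads the table only; it never rescans the database.
#'
#' @param record A `pattern_record` (see [build_st_dbindex()]), or a bare
#'   position table (list of integer vectors).
#' @param minsup Minimum support fraction in (0, 1].
#' @return `TRUE` if the pattern is frequent.
#' @examples
#' db <- seq_db(c("abcbac", "acbcab", "bcbabc", "acbabc"),
#'              alphabet = custom_alphabet(c("a", "b", "c")))
#' distinguish(build_st_dbindex(db, "a"), 0.5)
#' @export
distinguish <- function(record, minsup) {
  st <- if (inherits(record, "pattern_record")) record$st else record
  n <- length(st)
  sup <- support_of(st, n)
  sup$support_count >= mincount_for(minsup, n)
}

#' Extension admissibility of two equal-length patterns
#'
#' Two length-k patterns can be connected into a (k+1)-pattern when
#' (1) the intersection of their DB-Indexes has cardinality at least
#' `mincount` — the anti-monotonicity prune, since the connected pattern's
#' support cannot exceed that cardinality — and (2) in at least one shared
#' sequence the first pattern has an occurrence at some position q with the
#' second at q + 1.
#'
#' @param p1,p2 `pattern_record`s of equal pattern length.
#' @param mincount Integer minimum support count.
#' @return A list with `ok` (logical) and `shared` (the DB-Index
#'   intersection, for reuse by the caller).
#' @export
can_connect <- function(p1, p2, mincount) {
  if (nchar(p1$pattern) != nchar(p2$pattern)) {
    stop("patterns must have equal length to be connected", call. = FALSE)
  }
  shared <- intersect(p1$dbindex, p2$dbindex)
  if (length(shared) < mincount) {
    return(list(ok = FALSE, shared = shared))
  }
  for (i in shared) {
    if (any((p1$st[[i]] + 1L) %in% p2$st[[i]])) {
      return(list(ok = TRUE, shared = shared))
    }
  }
  list(ok = FALSE, shared = shared)
}

#' Connect two admissible equal-length patterns
#'
#' The connected pattern has length k + 1: the first pattern followed by the
#' last residue of the second (equivalently, the overlap merge across their
#' shared (k-1)-residue suffix/prefix). Adjacent occurrences of equal-length
#' contiguous patterns force that overlap, so it is asserted defensively.
#'
#' @param p1,p2 Pattern strings of equal length k.
#' @return The (k+1)-length connected pattern string.
#' @examples
#' connect_patterns("ab", "bc")
#' @export
connect_patterns <- function(p1, p2) {
  k <- nchar(p1)
  if (nchar(p2) != k) stop("patterns must have equal length", call. = FALSE)
  if (k > 1L && substr(p1, 2L, k) != substr(p2, 1L, k - 1L)) {
    stop(sprintf("'%s' and '%s' do not overlap on a (k-1)-suffix/prefix", p1, p2),
         call. = FALSE)
  }
  paste0(p1, substr(p2, k, k))
}

#' Grow one level: all (k+1)-candidates from the frequent k-patterns
#'
#' Iterates over all ordered pairs of frequent k-patterns (self-pairs
#' included, so homopolymer runs extend). A pair is joined only if the
#' patterns overlap on a (k-1)-residue suffix/prefix, the DB-Index
#' intersection reaches `mincount`, and an adjacent occurrence pair exists.
#' Each surviving candidate's position table is built restricted to the
#' shared sequence indices: in the default `"positions"` method a candidate
#' start q in sequence i is recorded iff q is a start of the first pattern
#' and q + 1 a start of the second there — pure position-list intersection,
#' no sequence rescan. The `"rescan"` method instead rescans the restricted
#' view of the database for the candidate string; it exists to cross-validate
#' the index arithmetic and must give identical results.
#'
#' Support filtering of the returned candidates is the caller's job.
#'
#' @param records Named list of frequent k-`pattern_record`s.
#' @param mincount Integer minimum support count.
#' @param db The [seq_db()] (required for `method = "rescan"`).
#' @param method `"positions"` (default) or `"rescan"`.
#' @return A list with `candidates` (named list of (k+1)-`pattern_record`s)
#'   and `stats` (counts of pairs examined and pruned at each stage).
#' @export
st_update <- function(records, mincount, db = NULL,
                      method = c("positions", "rescan")) {
  method <- match.arg(method)
  if (method == "rescan" && is.null(db)) {
    stop("`db` is required for method = \"rescan\"", call. = FALSE)
  }
  candidates <- list()
  stats <- c(n_pairs = 0L, n_joinable = 0L, n_pruned_index = 0L,
             n_pruned_adjacency = 0L, n_candidates = 0L)
  if (length(records) == 0L) {
    return(list(candidates = candidates, stats = as.list(stats)))
  }
  k <- nchar(records[[1]]$pattern)
  pats <- vapply(records, `[[`, character(1), "pattern")
  # group by (k-1)-prefix so only overlap-compatible ordered pairs are tried;
  # overlap is a necessary condition for occurrence-level adjacency
  prefixes <- substr(pats, 1L, max(k - 1L, 0L))
  by_prefix <- split(seq_along(records), prefixes)
  for (i in seq_along(records)) {
    p1 <- records[[i]]
    suf <- substr(p1$pattern, 2L, k)
    partners <- if (k == 1L) seq_along(records) else by_prefix[[suf]]
    if (is.null(partners)) next
    for (j in partners) {
      p2 <- records[[j]]
      stats["n_pairs"] <- stats["n_pairs"] + 1L
      stats["n_joinable"] <- stats["n_joinable"] + 1L
      cc <- can_connect(p1, p2, mincount)
      if (!cc$ok) {
        if (length(cc$shared) < mincount) {
          stats["n_pruned_index"] <- stats["n_pruned_index"] + 1L
        } else {
          stats["n_pruned_adjacency"] <- stats["n_pruned_adjacency"] + 1L
        }
        next
      }
      cand_pat <- connect_patterns(p1$pattern, p2$pattern)
      if (!is.null(candidates[[cand_pat]])) {
        stop(sprintf("duplicate candidate '%s' generated", cand_pat),
             call. = FALSE)  # unreachable: the generating pair is unique
      }
      if (method == "rescan") {
        rec <- build_st_dbindex(db, cand_pat, restrict = cc$shared)
      } else {
        n <- length(p1$st)
        st <- rep(list(integer(0)), n)
        for (s in cc$shared) {
          r1 <- p1$st[[s]]
          st[[s]] <- r1[(r1 + 1L) %in% p2$st[[s]]]
        }
        rec <- new_pattern_record(cand_pat, st, n)
      }
      # Property-2 guard: support of the candidate is bounded by the
      # DB-Index intersection cardinality of its generating pair
      stopifnot(rec$support_count <= length(cc$shared))
      candidates[[cand_pat]] <- rec
      stats["n_candidates"] <- stats["n_candidates"] + 1L
    }
  }
  list(candidates = candidates, stats = as.list(stats))
}

#' Mine all frequent contiguous patterns from a sequence database
#'
#' Level-wise mining: one scan collects the distinct single residues and
#' their position tables and DB-Indexes; the frequent single residues seed
#' the recursion, and each level joins the frequent k-patterns into
#' (k+1)-candidates via [st_update()], keeping those whose support reaches
#' the threshold, until a level yields no frequent pattern. The result
#' contains every frequent pattern of every length (subject to the optional
#' length filters), each with its position table, DB-Index, support count and
#' support fraction, deterministically ordered by length then lexicographic
#' (byte order).
#'
#' @param db A [seq_db()].
#' @param minsup Minimum support fraction in (0, 1]. A pattern is frequent
#'   when (number of sequences containing it) / (database size) >= `minsup`,
#'   boundary inclusive.
#' @param mincount Optional integer support count; when given it takes
#'   precedence over `minsup`.
#' @param min_len,max_len Report only patterns with length in
#'   `[min_len, max_len]`. Mining stops at `max_len` since longer patterns
#'   could never be reported.
#' @param maximal_only If `TRUE`, post-filter to patterns not contained (as a
#'   contiguous substring) in any other reported pattern.
#' @param method Candidate position-table construction: `"positions"`
#'   (index arithmetic, default) or `"rescan"` (restricted database rescan;
#'   for cross-validation).
#' @param verbose Print per-level join/prune statistics.
#' @return An object of class `bsp_result`: a named list of
#'   `pattern_record`s with attributes `db_size`, `minsup`, `mincount` and
#'   `level_stats` (a data frame with one row per level: candidates
#'   generated, candidates pruned by the index-intersection condition, by
#'   the adjacency condition, and frequent survivors).
#' @examples
#' db <- seq_db(c("abcbac", "acbcab", "bcbabc", "acbabc"),
#'              alphabet = custom_alphabet(c("a", "b", "c")))
#' res <- mine_bsp(db, minsup = 0.5)
#' length(res)
#' @export
mine_bsp <- function(db, minsup = 0.5, mincount = NULL, min_len = 1L,
                     max_len = Inf, maximal_only = FALSE,
                     method = c("positions", "rescan"), verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(db, "seq_db"))
  n <- length(db)
  if (is.null(mincount)) {
    mincount <- mincount_for(minsup, n)
  } else {
    mincount <- as.integer(mincount)
    if (mincount < 1L || mincount > n) {
      stop("`mincount` must be between 1 and the database size", call. = FALSE)
    }
    minsup <- mincount / n
  }
  min_len <- max(1L, as.integer(min_len))

  # level 1: one scan, split each sequence into residues once
  chars <- strsplit(db$sequences, "", fixed = TRUE)
  items <- sort(unique(unlist(chars, use.names = FALSE)), method = "radix")
  level <- list()
  for (it in items) {
    st <- lapply(chars, function(v) which(v == it))
    level[[it]] <- new_pattern_record(it, st, n)
  }
  frequent <- Filter(function(r) r$support_count >= mincount, level)
  stats_rows <- list(data.frame(
    k = 1L, n_candidates = length(level), n_pruned_index = 0L,
    n_pruned_adjacency = 0L, n_frequent = length(frequent)))
  all_records <- frequent

  k <- 1L
  while (length(frequent) > 0L && k < max_len) {
    up <- st_update(frequent, mincount, db = db, method = method)
    frequent <- Filter(function(r) r$support_count >= mincount, up$candidates)
    k <- k + 1L
    stats_rows[[k]] <- data.frame(
      k = k, n_candidates = up$stats$n_candidates,
      n_pruned_index = up$stats$n_pruned_index,
      n_pruned_adjacency = up$stats$n_pruned_adjacency,
      n_frequent = length(frequent))
    if (verbose) {
      message(sprintf("level %d: %d candidates (%d pruned by index, %d by adjacency), %d frequent",
                      k, up$stats$n_candidates, up$stats$n_pruned_index,
                      up$stats$n_pruned_adjacency, length(frequent)))
    }
    all_records <- c(all_records, frequent)
  }

  pats <- vapply(all_records, `[[`, character(1), "pattern")
  keep <- nchar(pats) >= min_len & nchar(pats) <= max_len
  all_records <- all_records[keep]
  pats <- pats[keep]
  ord <- order(nchar(pats), pats, method = "radix")
  all_records <- all_records[ord]

  res <- structure(all_records, class = "bsp_result",
                   db_size = n, minsup = minsup, mincount = mincount,
                   level_stats = do.call(rbind, stats_rows))
  if (maximal_only) res <- maximal_patterns(res) else res
}

#' Keep only maximal patterns
#'
#' Filters a mining result to the patterns that are not a contiguous
#' substring of any other reported pattern.
#'
#' @param result A `bsp_result` (or plain named list of `pattern_record`s).
#' @return The filtered result, attributes preserved.
#' @export
maximal_patterns <- function(result) {
  pats <- vapply(result, `[[`, character(1), "pattern")
  if (length(pats) <= 1L) return(result)
  keep <- vapply(seq_along(pats), function(i) {
    !any(vapply(pats[-i], function(q) grepl(pats[i], q, fixed = TRUE),
                logical(1)))
  }, logical(1))
  out <- result[keep]
  attributes(out) <- c(attributes(out),
                       attributes(result)[c("db_size", "minsup", "mincount",
                                            "level_stats")])
  class(out) <- "bsp_result"
  out
}

#' @export
print.bsp_result <- function(x, n = 10L, ...) {
  cat(sprintf("<bsp_result: %d frequent patterns, minsup %.3g (mincount %d) over %d sequences>\n",
              length(x), attr(x, "minsup"), attr(x, "mincount"),
              attr(x, "db_size")))
  if (length(x) > 0L) {
    df <- as.data.frame(x)
    print(utils::head(df[, c("pattern", "length", "support_count", "support")], n))
    if (length(x) > n) cat(sprintf("... and %d more\n", length(x) - n))
  }
  invisible(x)
}
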