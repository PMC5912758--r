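# Frozen reference for the toy database at mincount 2 (minsup 0.5 of 4):
# computed by exhaustive substring enumeration over the four 6-mers.
toy_frequent_05 <- c(
  a = 4L, b = 4L, c = 4L,
  ab = 4L, ac = 3L, ba = 3L, bc = 4L, cb = 4L,
  abc = 3L, acb = 2L, bab = 2L, bcb = 2L, cba = 3L,
  babc = 2L, bcba = 2L, cbab = 2L,
  cbabc = 2L
)

test_that("the frequency test is boundary-inclusive and rescans nothing", {
  db <- toy_db()
  expect_true(distinguish(build_st_dbindex(db, "a"), 0.5))
  two_of_four <- list(1L, integer(0), 3L, integer(0))
  expect_true(distinguish(two_of_four, 0.5))
  one_of_four <- list(1L, integer(0), integer(0), integer(0))
  expect_false(distinguish(one_of_four, 0.5))
})

test_that("extension admissibility combines the index prune and adjacency", {
  db <- toy_db()
  a <- build_st_dbindex(db, "a")
  b <- build_st_dbindex(db, "b")
  cc <- can_connect(a, b, 2L)
  expect_true(cc$ok)
  expect_identical(cc$shared, 1:4)

  # 'c' never occurs at adjacent positions q, q+1 in any toy sequence
  c_rec <- build_st_dbindex(db, "c")
  expect_false(can_connect(c_rec, c_rec, 2L)$ok)

  # disjoint DB-Indexes fail the cardinality condition outright
  db2 <- seq_db(c("aa", "bb"), alphabet = custom_alphabet(c("a", "b")))
  d1 <- build_st_dbindex(db2, "a")
  d2 <- build_st_dbindex(db2, "b")
  expect_false(can_connect(d1, d2, 1L)$ok)

  expect_error(can_connect(a, build_st_dbindex(db, "ab"), 1L), "equal length")
})

test_that("connection is the (k+1) suffix/prefix overlap merge", {
  expect_identical(connect_patterns("a", "b"), "ab")
  expect_identical(connect_patterns("ab", "bc"), "abc")
  expect_identical(connect_patterns("YSASKHGVV", "SASKHGVVG"), "YSASKHGVVG")
  expect_error(connect_patterns("ab", "ca"), "overlap")
  expect_error(connect_patterns("ab", "a"), "equal length")
})

test_that("one level step generates exactly the adjacency-supported 2-mers", {
  db <- toy_db()
  ones <- sapply(c("a", "b", "c"), function(p) build_st_dbindex(db, p),
                 simplify = FALSE)
  up <- st_update(ones, mincount = 2L)
  counts <- vapply(up$candidates, `[[`, integer(1), "support_count")
  # 'ca' is generated (adjacent in sequence 2 only) but is infrequent
  expect_equal(counts[["ca"]], 1L)
  frequent <- counts[counts >= 2L]
  expect_mapequal(frequent, c(ab = 4L, bc = 4L, cb = 4L, ba = 3L, ac = 3L))
  # candidate positions are starts of the pattern in the full sequences
  expect_identical(up$candidates[["ab"]]$st[[1]], 1L)

  expect_length(st_update(list(), 2L)$candidates, 0L)
})

test_that("self-joins extend homopolymer runs", {
  db <- seq_db(c("aaaa", "baaa"), alphabet = custom_alphabet(c("a", "b")))
  res <- support_counts(mine_bsp(db, minsup = 1.0))
  expect_equal(res[["aa"]], 2L)
  expect_equal(res[["aaa"]], 2L)
  expect_false("aaaa" %in% names(res))
})

test_that("mining the toy database returns the exact frequent-pattern sets", {
  db <- toy_db()
  res <- mine_bsp(db, minsup = 0.5)
  got <- support_counts(res)
  expect_identical(names(got), names(toy_frequent_05))  # order: length, lex
  expect_identical(unname(got), unname(toy_frequent_05))

  res_full <- support_counts(mine_bsp(db, minsup = 1.0))
  expect_mapequal(res_full, c(a = 4L, b = 4L, c = 4L, ab = 4L, bc = 4L, cb = 4L))
})

test_that("the rescan construction gives results identical to index arithmetic", {
  for (db in list(toy_db(), random_db(8, 30, 3, seed = 21))) {
    fast <- mine_bsp(db, minsup = 0.25, method = "positions")
    slow <- mine_bsp(db, minsup = 0.25, method = "rescan")
    expect_identical(as.data.frame(fast), as.data.frame(slow))
  }
})

test_that("length filters and the maximal post-filter behave as documented", {
  db <- toy_db()
  res23 <- mine_bsp(db, minsup = 0.5, min_len = 2, max_len = 3)
  lens <- nchar(names(support_counts(res23)))
  expect_true(all(lens >= 2 & lens <= 3))
  expect_equal(length(res23), sum(nchar(names(toy_frequent_05)) %in% 2:3))

  mx <- names(support_counts(maximal_patterns(mine_bsp(db, minsup = 0.5))))
  expect_true("cbabc" %in% mx)
  expect_false("bab" %in% mx)
  expect_false(any(vapply(mx, function(p) {
    any(vapply(setdiff(mx, p), grepl, logical(1), pattern = p, fixed = TRUE))
  }, logical(1))))

  empty <- mine_bsp(db, minsup = 0.5, min_len = 10)
  expect_length(empty, 0L)
  expect_identical(maximal_patterns(empty), empty)
})

test_that("invalid thresholds are rejected", {
  db <- toy_db()
  expect_error(mine_bsp(db, minsup = 0), "\\(0, 1\\]")
  expect_error(mine_bsp(db, minsup = 1.5), "\\(0, 1\\]")
  expect_error(mine_bsp(db, mincount = 0), "between 1")
  expect_error(mine_bsp(db, mincount = 5), "between 1")
})

test_that("an explicit mincount takes precedence over minsup", {
  db <- toy_db()
  expect_identical(support_counts(mine_bsp(db, minsup = 1.0, mincount = 2L)),
                   support_counts(mine_bsp(db, minsup = 0.5)))
})

test_that("every contiguous subpattern of a reported pattern is reported with >= support", {
  for (db in list(toy_db(), random_db(10, 40, 3, seed = 31))) {
    got <- support_counts(mine_bsp(db, minsup = 0.3))
    for (p in names(got)) {
      k <- nchar(p)
      if (k == 1) next
      for (i in seq_len(k)) for (j in i:k) {
        sub <- substr(p, i, j)
        expect_true(sub %in% names(got))
        expect_gte(got[[sub]], got[[p]])
      }
    }
  }
})

test_that("raising minsup never adds a pattern (nested result sets)", {
  db <- random_db(12, 40, 4, seed = 41)
  grid <- c(0.25, 0.5, 0.75, 1.0)
  sets <- lapply(grid, function(ms) support_counts(mine_bsp(db, minsup = ms)))
  for (i in seq_along(grid)[-1]) {
    expect_true(all(names(sets[[i]]) %in% names(sets[[i - 1]])))
    expect_identical(sets[[i - 1]][names(sets[[i]])], sets[[i]])
  }
})

test_that("per-level statistics expose the candidate join and prune", {
  db <- toy_db()
  res <- mine_bsp(db, minsup = 0.5)
  st <- attr(res, "level_stats")
  expect_true(all(c("k", "n_candidates", "n_pruned_index", "n_frequent")
                  %in% names(st)))
  expect_identical(st$n_frequent[st$k == 1], 3L)
  expect_identical(st$n_frequent[st$k == 2], 5L)
  expect_identical(sum(st$n_frequent), length(res))
})
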