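test_that("size filtering keeps each caller inside its trusted range", {
  spec <- default_filter_spec()
  calls <- deletion_calls("c1",
                          c(0, 0, 0, 0),
                          c(80, 5000, 5000, 500),
                          c("HC", "HC", "Pindel", "BD"))
  kept <- filter_calls(calls, spec)
  # HC size 80 retained; HC size 5000 removed; Pindel 5000 retained;
  # BD 500 below its 1 kb minimum removed
  expect_equal(kept$caller, c("HC", "Pindel"))
  expect_equal(kept$size, c(80, 5000))
  # bounds are inclusive
  edge <- deletion_calls("c1", c(0, 0), c(100, 30000), c("HC", "Pindel"))
  expect_equal(nrow(filter_calls(edge, spec)), 2)
  expect_equal(nrow(filter_calls(calls[0, ], spec)), 0)
})

test_that("unknown callers are an error unless explicitly allowed", {
  calls <- deletion_calls("c1", 0, 50, "Delly")
  expect_error(filter_calls(calls, default_filter_spec()), "Delly")
  spec <- filter_spec("HC", 1, 100, allow_unlisted = TRUE)
  expect_equal(nrow(filter_calls(calls, spec)), 1)
})

test_that("reciprocal overlap demands strictly more than the fraction on both sides", {
  a <- deletion_calls("c1", 0, 300, "HC")
  expect_true(mutual_overlap_exceeds(a, deletion_calls("c1", 0, 300, "BD")))
  # overlap 200 == 2/3 * 300 exactly: not strictly more
  expect_false(mutual_overlap_exceeds(a, deletion_calls("c1", 100, 400, "BD")))
  expect_true(mutual_overlap_exceeds(a, deletion_calls("c1", 90, 390, "BD")))
  # one-sided containment fails reciprocity but passes "either" mode
  small <- deletion_calls("c1", 0, 90, "BD")
  expect_false(mutual_overlap_exceeds(a, small))
  expect_true(mutual_overlap_exceeds(a, small, mode = "either"))
  expect_false(mutual_overlap_exceeds(a, deletion_calls("c2", 0, 300, "BD")))
})

test_that("merging keeps the higher-precision member of a duplicated pair", {
  cfg <- merge_config()
  pind <- deletion_calls("c1", 10000, 15000, "Pindel")
  bd <- deletion_calls("c1", 10000, 15000, "BD")
  merged <- merge_callsets(list(pind, bd), cfg)
  expect_equal(merged$caller, "Pindel")  # prior 0.93 beats BD's 0.91
  expect_equal(merged$precision, 0.93)
  # non-duplicates are both retained
  far <- merge_callsets(list(pind, deletion_calls("c1", 40000, 45000, "BD")), cfg)
  expect_equal(nrow(far), 2)
  # a callset with no internal overlaps comes back unchanged up to sorting
  set.seed(9)
  calls <- deletion_calls("c1", seq(0, 900, 100), seq(10, 910, 100), "HC")
  solo <- merge_callsets(calls, cfg)
  expect_equal(solo$start, calls$start)
})

test_that("merged output never contains a duplicate pair and is idempotent", {
  set.seed(31)
  cfg <- merge_config()
  for (rep in 1:15) {
    calls <- random_callset(40, max_coord = 2000)
    merged <- merge_callsets(calls, cfg)
    if (nrow(merged) > 1) {
      for (i in seq_len(nrow(merged) - 1)) {
        for (j in seq(i + 1, nrow(merged))) {
          expect_false(mutual_overlap_exceeds(merged[i, ], merged[j, ],
                                              cfg$overlap_fraction))
        }
      }
    }
    again <- merge_callsets(merged[, names(calls)], cfg)
    expect_equal(again$start, merged$start)
    expect_equal(again$caller, merged$caller)
    # merging the merged output with a duplicate of itself is also a no-op
    doubled <- merge_callsets(list(merged[, names(calls)], merged[, names(calls)]), cfg)
    expect_equal(doubled$start, merged$start)
    expect_equal(doubled$caller, merged$caller)
  }
})

test_that("merging is invariant to callset order and matches the fixed-point oracle", {
  set.seed(57)
  cfg <- merge_config()
  for (rep in 1:12) {
    sets <- list(random_callset(12, max_coord = 1500),
                 random_callset(12, max_coord = 1500),
                 random_callset(12, max_coord = 1500))
    m1 <- merge_callsets(sets, cfg)
    m2 <- merge_callsets(rev(sets), cfg)
    perm <- lapply(sets, function(s) s[sample(nrow(s)), , drop = FALSE])
    m3 <- merge_callsets(perm, cfg)
    expect_equal(m1, m2)
    expect_equal(m1, m3)
    pooled <- do.call(rbind, sets)
    want <- oracle_merge(pooled, cfg)
    expect_equal(m1$contig, want$contig)
    expect_equal(m1$start, want$start)
    expect_equal(m1$end, want$end)
    expect_equal(m1$caller, want$caller)
  }
})

test_that("tie-breaks between equal-precision duplicates are deterministic", {
  prof <- precision_profile(data.frame(caller = c("A", "B"), low = c(1, 1),
                                       high = c(1e6, 1e6),
                                       precision = c(0.9, 0.9)))
  cfg <- merge_config(precision_profile = prof, caller_priority = c("A", "B"))
  # equal precision: caller priority decides
  m <- merge_callsets(list(deletion_calls("c1", 100, 200, "B"),
                           deletion_calls("c1", 100, 200, "A")), cfg)
  expect_equal(m$caller, "A")
  # same caller, same precision: smaller start survives
  m2 <- merge_callsets(list(deletion_calls("c1", 100, 220, "A"),
                            deletion_calls("c1", 110, 220, "A")), cfg)
  expect_equal(m2$start, 100)
  # same start: larger size survives
  m3 <- merge_callsets(list(deletion_calls("c1", 100, 200, "A"),
                            deletion_calls("c1", 100, 210, "A")), cfg)
  expect_equal(m3$end, 210)
})
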