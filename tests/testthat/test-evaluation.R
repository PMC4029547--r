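test_that("effective regions extend symmetrically and clamp at boundaries", {
  # a 1-bp deletion with 50 bp margin has a 101-bp effective region
  er <- effective_region(gintervals("c1", 100, 101), margin = 50)
  expect_equal(c(er$start, er$end), c(50, 151))
  expect_equal(interval_length(er), 101)
  # zero margin is the identity
  er0 <- effective_region(gintervals("c1", 100, 200), margin = 0)
  expect_equal(c(er0$start, er0$end), c(100, 200))
  # clamping at both chromosome ends
  erc <- effective_region(gintervals("c1", 10, 20), margin = 50,
                          contig_length = c(c1 = 40))
  expect_equal(c(erc$start, erc$end), c(0, 40))
})

test_that("match quality reproduces the 1-bp/10-bp-offset worked example", {
  call <- deletion_calls("c1", 110, 111, "HC")
  truth <- truth_records("c1", 100, 101, "DEL")
  q <- call_quality(call, truth, margin = 50)
  expect_equal(q, 91 / 111)
  expect_equal(round(q, 1), 0.8)
  # identical regions score 1 regardless of margin
  same <- truth_records("c1", 110, 111, "DEL")
  expect_equal(call_quality(call, same, margin = 0), 1)
  expect_equal(call_quality(call, same, margin = 50), 1)
  # separation beyond twice the margin: disjoint effective regions, q = 0
  far <- truth_records("c1", 300, 301, "DEL")
  expect_equal(call_quality(call, far, margin = 50), 0)
  # insertions are rejected
  ins <- truth_records("c1", 100, 101, "INS", inserted_sequence = "ACGT")
  expect_error(call_quality(call, ins), "deletion")
})

test_that("quality is symmetric, translation-invariant, and bounded", {
  set.seed(7)
  for (rep in 1:40) {
    a <- random_intervals(1, contigs = "c1")
    b <- random_intervals(1, contigs = "c1")
    ca <- deletion_calls(a$contig, a$start, a$end, "x")
    cb <- deletion_calls(b$contig, b$start, b$end, "y")
    q1 <- call_quality(ca, truth_records(b$contig, b$start, b$end, "DEL"), 50)
    q2 <- call_quality(cb, truth_records(a$contig, a$start, a$end, "DEL"), 50)
    expect_equal(q1, q2)
    expect_gte(q1, 0); expect_lte(q1, 1)
    off <- 1000
    q3 <- call_quality(deletion_calls(a$contig, a$start + off, a$end + off, "x"),
                       truth_records(b$contig, b$start + off, b$end + off, "DEL"), 50)
    expect_equal(q1, q3)
  }
})

test_that("the margin's influence on quality vanishes as deletion size grows", {
  offset <- 10
  sizes <- c(100, 1000, 1e4, 1e5)
  diffs <- vapply(sizes, function(L) {
    call <- deletion_calls("c1", 1e6 + offset, 1e6 + offset + L, "x")
    truth <- truth_records("c1", 1e6, 1e6 + L, "DEL")
    abs(call_quality(call, truth, 50) - call_quality(call, truth, 0))
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))  # monotone decay
  expect_lt(diffs[length(diffs)], 0.01)
  # and for a fixed offset, quality itself grows towards 1 with size
  qs <- vapply(sizes, function(L) {
    call_quality(deletion_calls("c1", offset, offset + L, "x"),
                 truth_records("c1", 0, L, "DEL"), 50)
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
  expect_gt(qs[length(qs)], 0.999)
})

test_that("per-bin precision and recall follow the best-match-mean formulas", {
  cfg <- evaluation_config(margin = 50, bins = size_bins(c(1, 10, 100, 1000)))
  # three calls in one bin with individual max-qualities {1, 91/111, 0}
  truths <- truth_records("c1", c(1000, 3000), c(1001, 3001), "DEL")
  calls <- deletion_calls("c1", c(1000, 3010, 9000), c(1001, 3011, 9001), "HC")
  rep <- evaluate_deletions(calls, truths, cfg)
  expect_equal(rep$precision[1], mean(c(1, 91 / 111, 0)))
  expect_equal(rep$n_called, c(3, 0, 0))
  expect_equal(rep$recall[1], mean(c(1, 91 / 111)))
  expect_equal(rep$n_prepared, c(2, 0, 0))
  # one truth alone in its bin matched at 91/111
  r1 <- evaluate_deletions(deletion_calls("c1", 3010, 3011, "HC"),
                           truth_records("c1", 3000, 3001, "DEL"), cfg)
  expect_equal(r1$recall[1], 91 / 111)
})

test_that("identical call and truth sets give precision == recall == 1", {
  set.seed(11)
  truths <- random_truthset(30, ins_fraction = 0)
  calls <- deletion_calls(truths$contig, truths$start, truths$end, "HC")
  rep <- evaluate_deletions(calls, truths, evaluation_config())
  occupied <- rep$n_called > 0
  expect_true(any(occupied))
  expect_equal(rep$precision[occupied], rep(1, sum(occupied)))
  expect_equal(rep$recall[rep$n_prepared > 0], rep(1, sum(rep$n_prepared > 0)))
  expect_equal(rep$f_measure[occupied], rep(1, sum(occupied)))
})

test_that("empty bins are undefined, not zero; no calls means zero recall", {
  cfg <- evaluation_config(bins = size_bins(c(1, 10, 100)))
  truths <- truth_records("c1", 100, 150, "DEL")
  no_calls <- deletion_calls(character(), numeric(), numeric(), character())
  rep <- evaluate_deletions(no_calls, truths, cfg)
  expect_true(all(is.na(rep$precision)))
  expect_equal(rep$recall[2], 0)
  expect_true(is.na(rep$recall[1]))
  # a single call overlapping nothing scores precision 0 in its bin
  lone <- deletion_calls("c1", 5000, 5005, "HC")
  rep2 <- evaluate_deletions(lone, truths, cfg)
  expect_equal(rep2$precision[1], 0)
})

test_that("evaluation matches the all-pairs oracle on random instances", {
  set.seed(123)
  bins <- size_bins(c(1, 10, 100, 1000))
  for (rep in 1:25) {
    calls <- random_callset(sample(0:30, 1))
    truths <- random_truthset(sample(1:30, 1))
    got <- evaluate_deletions(calls, truths, evaluation_config(50, bins))
    want <- oracle_evaluate(calls, truths, 50, bins)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("F-measure is the harmonic mean with a 0/0 convention", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0.9, 0.9), 0.9)
  expect_equal(f_measure(1, 0.5), 2 / 3)
  expect_equal(f_measure(0, 0), 0)
  expect_true(is.na(f_measure(NA, 1)))
})

test_that("evaluation reports round-trip through TSV", {
  set.seed(5)
  truths <- random_truthset(10, ins_fraction = 0)
  calls <- random_callset(10)
  rep <- evaluate_deletions(calls, truths, evaluation_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(as.data.frame(back), as.data.frame(rep))
})
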