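test_that("SV injection conserves sequence length and reports reference coordinates", {
  ref <- random_genome(c(chr1 = 10000), seed = 2)
  # exactly one 100-bp deletion
  cfg <- simulation_config(n_sv = 1, del_fraction = 1,
                           size_sampler = function(n) rep(100L, n), seed = 3)
  sim <- inject_svs(ref, cfg)
  expect_equal(nchar(sim$genome), c(chr1 = 9900))
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$sv_type, "DEL")
  expect_equal(sim$truth$size, 100)
  # the deleted span is excised at the truth's reference coordinates
  s <- sim$truth$start; e <- sim$truth$end
  expect_equal(substr(sim$genome[[1]], 1, s),
               substr(ref[[1]], 1, s))
  expect_equal(substr(sim$genome[[1]], s + 1, s + 50),
               substr(ref[[1]], e + 1, e + 50))
})

test_that("insertions splice in after the anchor base", {
  ref <- random_genome(c(chr1 = 5000), seed = 4)
  cfg <- simulation_config(n_sv = 1, del_fraction = 0,
                           size_sampler = function(n) rep(7L, n), seed = 5)
  sim <- inject_svs(ref, cfg)
  tr <- sim$truth
  expect_equal(tr$sv_type, "INS")
  expect_equal(nchar(tr$inserted_sequence), 7)
  expect_equal(nchar(sim$genome), c(chr1 = 5007))
  anchor_end <- tr$end  # anchor base kept, insertion follows
  expect_equal(substr(sim$genome[[1]], anchor_end + 1, anchor_end + 7),
               tr$inserted_sequence)
})

test_that("injection is reproducible, respects n_sv = 0, and fails loudly when full", {
  ref <- random_genome(c(chr1 = 8000, chr2 = 4000), seed = 6)
  cfg <- simulation_config(n_sv = 20, size_sampler = default_size_sampler(1, 200),
                           seed = 77)
  s1 <- inject_svs(ref, cfg)
  s2 <- inject_svs(ref, cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s0 <- inject_svs(ref, simulation_config(n_sv = 0))
  expect_identical(s0$genome, ref)
  expect_equal(nrow(s0$truth), 0)
  # SVs that cannot be placed raise an informative error
  tiny <- random_genome(c(chr1 = 500), seed = 1)
  expect_error(inject_svs(tiny, simulation_config(
    n_sv = 5, del_fraction = 1, size_sampler = function(n) rep(400L, n),
    seed = 1), max_tries_per_sv = 50), "fewer or smaller")
})

test_that("read pairs obey the depth formula and are error-free substrings at rate 0", {
  genome <- random_genome(c(chr1 = 60000), seed = 8)
  cfg <- simulation_config(depth = 2, error_rate = 0, seed = 9)
  r <- simulate_reads(genome, cfg)
  expect_equal(length(r$read1), round(2 * 60000 / 200))
  expect_equal(length(r$read2), length(r$read1))
  # with no errors every mate is an exact (reverse-complemented) substring
  fr <- r$fragments
  r1_true <- substring(genome[fr$contig], fr$start + 1, fr$start + 100)
  r2_true <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(genome[fr$contig], fr$end - 99, fr$end))))
  expect_identical(r$read1, unname(r1_true))
  expect_identical(r$read2, unname(r2_true))
  # FR orientation: all fragments fit inside the contig
  expect_true(all(fr$start >= 0 & fr$end <= 60000))
  expect_true(all(fr$end - fr$start >= 200))
})

test_that("insert sizes and substitution errors follow the configured model", {
  genome <- random_genome(c(chr1 = 3e5), seed = 10)
  cfg <- simulation_config(depth = 10, error_rate = 0.01, seed = 11)
  r <- simulate_reads(genome, cfg)  # 15,000 pairs
  ins <- r$fragments$end - r$fragments$start
  n <- length(ins)
  expect_lt(abs(mean(ins) - 350), 4 * 50 / sqrt(n))
  expect_lt(abs(sd(ins) - 50), 4 * 50 / sqrt(2 * n))
  expect_true(all(ins >= 200))
  # observed mismatch rate against the source genome ~ error_rate
  fr <- r$fragments
  r1_true <- substring(genome[fr$contig], fr$start + 1, fr$start + 100)
  mism <- sum(utf8ToInt(paste(r$read1, collapse = "")) !=
              utf8ToInt(paste(r1_true, collapse = "")))
  rate <- mism / (n * 100)
  se <- sqrt(0.01 * 0.99 / (n * 100))
  expect_lt(abs(rate - 0.01), 4 * se)
})

test_that("read simulation is a pure function of the seed and warns on short contigs", {
  genome <- random_genome(c(chr1 = 20000), seed = 12)
  cfg <- simulation_config(depth = 1, seed = 13)
  a <- simulate_reads(genome, cfg)
  b <- simulate_reads(genome, cfg)
  expect_identical(a$read1, b$read1)
  expect_identical(a$read2, b$read2)
  mixed <- c(genome, c(stub = strrep("A", 50)))
  expect_warning(simulate_reads(mixed, cfg), "shorter")
})

test_that("truth sets round-trip through BED", {
  set.seed(14)
  truth <- random_truthset(50)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(truth, path)
  back <- read_truth_bed(path)
  rownames(truth) <- rownames(back) <- NULL
  expect_equal(back, truth)
})
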