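adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming recovers insert lengths and applies the 17 nt floor", {
  ins21 <- substr(strrep("ACGTA", 5), 1, 21)
  ins10 <- "ACGTACGTAC"
  reads <- reads_from_inserts(c(ins21, ins10), adapter)
  out <- trim_and_filter(reads, adapter)
  expect_equal(out$reads$seq, ins21)       # 21 nt insert retained
  expect_equal(out$stats$n_too_short, 1L)  # 10 nt insert discarded
  expect_equal(out$stats$n_adapter_trimmed, 2L)
  expect_equal(out$stats$n_out, 1L)
})

test_that("reads without an adapter occurrence pass through untrimmed", {
  seqs <- c(strrep("ACTG", 5), strrep("ACTG", 10))  # 20 nt and 40 nt
  reads <- data.frame(id = c("a", "b"), seq = seqs,
                      qual = strrep("I", nchar(seqs)))
  out <- trim_and_filter(reads, adapter)
  expect_equal(out$reads$seq, seqs[1])    # within [17, 30]: kept as is
  expect_equal(out$stats$n_too_long, 1L)  # 40 nt: discarded
  expect_equal(out$stats$n_adapter_trimmed, 0L)
})

test_that("suffix-anchored partial adapter matches are trimmed", {
  ins <- strrep("GATC", 5)  # 20 nt
  # read ends with only the first 6 adapter bases (overlap >= 3, 0 mm)
  read <- paste0(ins, substr(adapter, 1, 6))
  reads <- data.frame(id = "p", seq = read, qual = strrep("I", nchar(read)))
  out <- trim_and_filter(reads, adapter)
  expect_equal(out$reads$seq, ins)
  # a 2 nt overlap is below the minimum and must not trim
  read2 <- paste0(ins, substr(adapter, 1, 2))
  reads2 <- data.frame(id = "q", seq = read2,
                       qual = strrep("I", nchar(read2)))
  out2 <- trim_and_filter(reads2, adapter)
  expect_equal(out2$reads$seq, read2)
})

test_that("full-adapter matches tolerate up to 10% mismatches", {
  ins <- strrep("GATC", 5)
  mism_adapter <- adapter
  substr(mism_adapter, 3, 3) <- "C"  # 1 mismatch in 21 nt (<= 2 allowed)
  read <- substr(paste0(ins, mism_adapter, strrep("A", 75)), 1, 75)
  reads <- data.frame(id = "m", seq = read, qual = strrep("I", 75))
  out <- trim_and_filter(reads, adapter)
  expect_equal(out$reads$seq, ins)
})

test_that("low-quality 3' tails are trimmed before adapter search", {
  ins <- strrep("GATC", 5)
  read <- paste0(ins, strrep("G", 10))
  qual <- paste0(strrep("I", 20), strrep("#", 10))  # tail at Q2
  reads <- data.frame(id = "q", seq = read, qual = qual)
  out <- trim_and_filter(reads, adapter, min_q = 20)
  expect_equal(out$reads$seq, ins)
  expect_equal(out$stats$n_quality_trimmed, 1L)
})

test_that("malformed records are reported by id", {
  reads <- data.frame(id = c("ok", "bad1"),
                      seq = c(strrep("A", 20), strrep("A", 20)),
                      qual = c(strrep("I", 20), strrep("I", 19)))
  expect_error(trim_and_filter(reads, adapter), "bad1")
})

test_that("read classification: spike precedence, isomiR tolerance, thresholds", {
  refs <- c("mirA" = "ACGUAGGCAUGGCAUUACGG",    # 20 nt
            "mirB" = "GGGCCCAAAUUUGGGCCCAA")
  refs_dna <- chartr("U", "T", refs)
  core_I <- chartr("U", "T", default_panel$core[1])

  # flanked core -> spike label, even though flanks are arbitrary
  expect_identical(classify_read(paste0("GGGG", core_I, "TTTT"),
                                 default_panel, refs), "I")
  # exact mature sequence -> that miRNA
  expect_identical(classify_read(refs_dna[["mirA"]], default_panel, refs),
                   "mirA")
  # two substitutions exceed max_mismatch = 1
  r2 <- refs_dna[["mirA"]]
  substr(r2, 2, 3) <- "TT"
  expect_identical(classify_read(r2, default_panel, refs,
                                 max_mismatch = 1), "unmapped")
  # 3' end may differ by up to 2 nt either way
  expect_identical(classify_read(substr(refs_dna[["mirA"]], 1, 18),
                                 default_panel, refs), "mirA")
  expect_identical(classify_read(paste0(refs_dna[["mirA"]], "GT"),
                                 default_panel, refs), "mirA")
  expect_identical(classify_read(substr(refs_dna[["mirA"]], 1, 17),
                                 default_panel, refs), "unmapped")
  # one mismatch plus a 3' trim still matches
  r3 <- substr(refs_dna[["mirA"]], 1, 19)
  substr(r3, 5, 5) <- "C"
  expect_identical(classify_read(r3, default_panel, refs), "mirA")
  # spike core embedded in a read that also resembles a miRNA -> spike wins
  r4 <- paste0(core_I, substr(refs_dna[["mirA"]], 1, 7))
  expect_identical(classify_read(r4, default_panel, refs), "I")
})

test_that("ambiguous equal-best hits resolve to the smallest name and are flagged", {
  refs <- c(zmir = "ACGTACGTACGTACGTACGT", amir = "ACGTACGTACGTACGTACGT")
  cl <- classify_reads("ACGTACGTACGTACGTACGT", default_panel, refs)
  expect_identical(cl$feature, "amir")
  expect_true(cl$ambiguous)
})

test_that("classification is a pure function", {
  reads <- c(chartr("U", "T", tiny_refs[1:5]), strrep("A", 20))
  a <- classify_reads(reads, default_panel, tiny_refs)
  b <- classify_reads(reads, default_panel, tiny_refs)
  expect_identical(a, b)
})

test_that("counting conserves reads and reproduces simulated truth", {
  cfg <- sim_config(n_mirnas = 30, depth = 20000, seed = 31)
  sim <- simulate_library(cfg, default_panel, tiny_refs,
                          return_reads = TRUE)
  cm <- count_samples(list(s1 = sim$reads), default_panel,
                      tiny_refs[1:30], adapter = cfg$adapter)
  # conservation: spike + miRNA + unmapped = surviving
  expect_identical(sum(cm$counts[, 1]), cm$stats$surviving)
  expect_identical(
    cm$stats$spike + cm$stats$mirna + cm$stats$unmapped,
    cm$stats$surviving)
  # lossless round trip on a noiseless-channel simulation
  truth <- stats::setNames(sim$truth$count, sim$truth$feature)
  expect_identical(cm$counts[names(truth), 1], truth)
  expect_identical(unname(cm$counts["unmapped", 1]), 0L)
})

test_that("counting handles empty samples and rejects duplicates", {
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0))
  cm <- count_samples(list(s1 = empty), default_panel, tiny_refs[1:5],
                      adapter = adapter)
  expect_true(all(cm$counts[, 1] == 0L))
  expect_error(
    count_samples(stats::setNames(list(empty, empty), c("a", "a")),
                  default_panel, tiny_refs[1:5], adapter = adapter),
    "duplicate sample ids")
})

test_that("FASTQ files round-trip through read_fastq", {
  cfg <- sim_config(n_mirnas = 5, depth = 500, seed = 77)
  f <- withr::local_tempfile(fileext = ".fastq")
  sim <- simulate_library(cfg, default_panel, tiny_refs, fastq = f,
                          return_reads = TRUE)
  back <- read_fastq(f)
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$qual, sim$reads$qual)
})
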