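# Read pre-processing: truncation, quality, adapters, complexity, length.

ADAPTER <- TRUSEQ_ADAPTER
MIRNA <- "TGAGGTAGTAGGTTGTATAGTT"  # canonical 22-nt let-7 sequence

test_that("reads are truncated to 50 nt, shorter reads unchanged", {
  long <- strrep("A", 75)
  expect_equal(nchar(truncate_read(long)), 50)
  expect_equal(truncate_read(strrep("A", 22)), strrep("A", 22))
  expect_equal(nchar(truncate_read(strrep("A", 50))), 50)
  tq <- truncate_read(long, strrep("I", 75))
  expect_equal(nchar(tq$qual), 50)
})

test_that("quality filter discards only when low-quality bases exceed half", {
  expect_true(passes_quality(strrep("?", 30)))        # all Q30
  expect_false(passes_quality(qual_mix(10, 6)))       # 0.6 > 0.5
  expect_true(passes_quality(qual_mix(10, 5)))        # exactly half passes
  expect_false(passes_quality(""))                    # zero-length fails
  # offset 64: 'Y' = 89 -> Q25 passes, 'I' = 73 -> Q9 fails
  expect_true(passes_quality(strrep("Y", 10), phred_offset = 64))
  expect_false(passes_quality(strrep("I", 10), phred_offset = 64))
})

test_that("TruSeq trimming cuts at the last adapter 8-mer occurrence", {
  k8 <- substr(ADAPTER, 1, 8)
  r <- trim_adapter_truseq(paste0(MIRNA, ADAPTER), ADAPTER)
  expect_equal(r$insert, MIRNA)
  expect_true(r$adapter_found)

  # 8-mer at two positions: cut at the later one
  seq2 <- paste0("ACGTC", k8, "TTTTTTTTTTTTTTTTT", k8, "GGG")
  r2 <- trim_adapter_truseq(seq2, ADAPTER)
  expect_equal(r2$insert, paste0("ACGTC", k8, "TTTTTTTTTTTTTTTTT"))
  expect_true(r2$adapter_found)

  expect_error(trim_adapter_truseq("ACGT", "TGGAATT"), "at least 8")
})

test_that("partial-adapter suffix fallback matches a brute-force oracle", {
  base <- "CGCGCGTATATAGCGCGCTTCTC"  # contains no adapter prefix piece
  cases <- withr::with_seed(13, lapply(1:30, function(i) {
    k <- sample(0:7, 1)
    list(seq = paste0(base, substr(ADAPTER, 1, k)), k = k)
  }))
  for (cs in cases) {
    r <- trim_adapter_truseq(cs$seq, ADAPTER)
    # oracle: longest suffix of seq equal to an adapter prefix, k = 7..1
    want_cut <- 0
    for (k in 7:1) {
      if (nchar(cs$seq) >= k &&
          substr(cs$seq, nchar(cs$seq) - k + 1, nchar(cs$seq)) ==
          substr(ADAPTER, 1, k)) { want_cut <- k; break }
    }
    expect_equal(r$insert, substr(cs$seq, 1, nchar(cs$seq) - want_cut))
    expect_false(r$adapter_found)
  }
})

test_that("NEXTflex trimming strips the 4+4 randomized bases", {
  decorated <- paste0("TCAG", MIRNA, "GATC", ADAPTER, "AAAA")
  r <- trim_adapter_nextflex(decorated, ADAPTER)
  expect_equal(r$insert, MIRNA)
  expect_true(r$adapter_found)

  # no adapter: only the 4 leading bases removed
  r2 <- trim_adapter_nextflex("TCAGACGTACGTACGTACGTAC", ADAPTER)
  expect_equal(r2$insert, "ACGTACGTACGTACGTAC")
  expect_false(r2$adapter_found)

  # adapter found with exactly 8 nt between the randomized flanks -> empty
  r3 <- trim_adapter_nextflex(paste0("TCAG", "GATC", ADAPTER), ADAPTER)
  expect_equal(r3$insert, "")
  expect_true(r3$adapter_found)
})

test_that("CATS trimming cuts at the left-most poly-A 8-mer, else the tail", {
  r <- trim_adapter_cats(paste0("GTC", MIRNA, strrep("A", 20)))
  expect_equal(r$insert, MIRNA)
  expect_true(r$adapter_found)

  # trailing run shorter than 8: suffix cascade trims it
  r2 <- trim_adapter_cats("GTCACGTACGTACGTACGTCAAA")
  expect_equal(r2$insert, "ACGTACGTACGTACGTC")
  expect_false(r2$adapter_found)

  # no A at all after the leading trim
  r3 <- trim_adapter_cats("GTCCGTCGTCGGTCGTCGTC")
  expect_equal(r3$insert, "CGTCGTCGGTCGTCGTC")
  expect_false(r3$adapter_found)
})

test_that("low-complexity detection matches exhaustive motif checking", {
  expect_true(is_low_complexity(strrep("A", 18)))
  expect_true(is_low_complexity(strrep("AC", 10)))
  expect_true(is_low_complexity(paste0(strrep("ACG", 6), "A")))  # truncated unit
  expect_false(is_low_complexity(MIRNA))

  oracle <- function(s) {
    n <- nchar(s)
    for (m in 1:3) {
      if (n < 2 * m) next
      motif <- substr(s, 1, m)
      if (substr(strrep(motif, ceiling(n / m)), 1, n) == s) return(TRUE)
    }
    FALSE
  }
  cases <- withr::with_seed(17, c(
    stringi::stri_rand_strings(40, 20, "[ACGT]"),
    strrep(stringi::stri_rand_strings(10, 2, "[ACGT]"), 10),
    strrep(stringi::stri_rand_strings(10, 3, "[ACGT]"), 7)
  ))
  expect_equal(is_low_complexity(cases),
               vapply(cases, oracle, logical(1), USE.NAMES = FALSE))
})

test_that("full pre-processing assigns statuses and reasons as specified", {
  cfg <- sample_config("s", adapter = ADAPTER)
  reads <- make_reads(c(
    paste0(MIRNA, ADAPTER, strrep("G", 20)),      # perfect
    paste0(ADAPTER, strrep("G", 40)),             # adapter dimer
    strrep("CGTA", 15),                           # 60 nt, no adapter anywhere
    paste0("ACGTNCGTACGTACGTACGTAC", ADAPTER),    # N in insert
    paste0(strrep("AC", 11), ADAPTER),            # low-complexity insert
    paste0("ACGTACGTACGTACG", ADAPTER)            # 15 nt insert: too short
  ), qual = strrep("I", c(75, 73, 60, 55, 55, 48)))
  reads$qual[1] <- strrep("I", nchar(reads$seq[1]))
  for (i in seq_len(nrow(reads))) reads$qual[i] <- strrep("I", nchar(reads$seq[i]))
  pre <- preprocess_reads(reads, cfg)

  expect_equal(pre$status[1], "qc_passed_adapter_found")
  expect_equal(pre$insert[1], MIRNA)
  expect_equal(pre$insert_len[2], 0L)
  expect_equal(pre$discard_reason[2], "too_short")
  expect_equal(pre$status[3], "qc_passed_adapter_unrecognized")
  expect_equal(pre$insert_len[3], 50L)  # truncated cap, adapter never seen
  expect_equal(pre$discard_reason[4:6],
               c("ambiguous_nt", "low_complexity", "too_short"))
  expect_true(all(pre$pre_trim_len <= 50))
})

test_that("low-quality reads are discarded before adapter processing", {
  cfg <- sample_config("s", adapter = ADAPTER)
  reads <- make_reads(paste0(MIRNA, ADAPTER),
                      qual = qual_mix(nchar(MIRNA) + nchar(ADAPTER),
                                      nchar(MIRNA) + nchar(ADAPTER) - 10))
  pre <- preprocess_reads(reads, cfg)
  expect_equal(pre$discard_reason, "low_quality")
  expect_true(is.na(pre$insert))
})

test_that("UMI prefixes are trimmed before everything else", {
  cfg <- sample_config("s", adapter = ADAPTER, umi_prefix_len = 10)
  umi_read <- paste0(strrep("T", 10), MIRNA, ADAPTER)
  reads <- make_reads(umi_read)
  pre <- preprocess_reads(reads, cfg)
  expect_equal(pre$insert, MIRNA)
})

test_that("pipeline conservation: statuses partition the input exactly", {
  b <- tiny_bundle()
  smp <- generate_sample(synth_spec(2000, seed = 19, per_base_error_rate = 0.02,
                                    quality_mean = 22, quality_sd = 6),
                         b, b$clades[1])
  cfg <- sample_config("s", adapter = TRUSEQ_ADAPTER)
  pre <- preprocess_reads(smp$reads, cfg)
  counts <- table(ifelse(pre$status == "discarded", pre$discard_reason,
                         pre$status))
  expect_equal(sum(counts), nrow(smp$reads))
  expect_true(all(pre$discard_reason[pre$status == "discarded"] != "none"))
  expect_true(all(pre$discard_reason[pre$status != "discarded"] == "none"))
  expect_true(all(pre$insert_len[startsWith(pre$status, "qc_passed")] >= 18))
})

test_that("adapter trimming is idempotent on adapter-free inserts", {
  inserts <- withr::with_seed(23, stringi::stri_rand_strings(200, 22, "[CGT]"))
  # [CGT] alphabet cannot contain the adapter 8-mer (starts TGGAATTC) nor an
  # A-initial prefix piece; filter any accidental suffix overlap
  r1 <- trim_adapter_truseq(inserts, ADAPTER)
  keep <- !r1$adapter_found & r1$insert == inserts
  r2 <- trim_adapter_truseq(r1$insert[keep], ADAPTER)
  expect_equal(r2$insert, r1$insert[keep])
})
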