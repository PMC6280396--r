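# Index demultiplexing and post-sequencing contamination cleaning.

ADAPTER <- TRUSEQ_ADAPTER

test_that("inline index extraction follows the adapter-end arithmetic", {
  insert <- strrep("GTCA", 5)  # 20 nt, adapter-free
  idx <- "ACGTAC"
  # 75-nt read: 22-nt insert + 33-nt adapter + 6-nt index + filler
  insert22 <- paste0(insert, "GG")
  read <- paste0(insert22, ADAPTER, idx, strrep("T", 75 - 22 - 33 - 6))
  expect_equal(nchar(read), 75)
  expect_equal(extract_inline_index(read, ADAPTER, 6), idx)

  # adapter 8-mer absent -> unreadable
  expect_equal(extract_inline_index(strrep("GTCA", 18), ADAPTER, 6),
               NA_character_)

  # index truncated by the read end -> unreadable
  short <- paste0(strrep("GTCA", 6), "C", ADAPTER, substr(idx, 1, 2))
  expect_equal(extract_inline_index(short, ADAPTER, 6), NA_character_)

  # 8-mer present but the full adapter does not follow -> unreadable
  partial <- paste0(insert22, substr(ADAPTER, 1, 12), strrep("T", 30))
  expect_equal(extract_inline_index(partial, ADAPTER, 6), NA_character_)

  expect_error(extract_inline_index(read, ADAPTER, 0), ">= 1")
})

make_mux_read <- function(insert, inline_idx, seq_idx,
                          read_length = 75, id = "r1") {
  seq <- paste0(insert, ADAPTER, inline_idx,
                strrep("G", max(read_length - nchar(insert) - 33 -
                                  nchar(inline_idx), 0)))
  make_reads(substr(seq, 1, read_length), read_id = id, seq_index = seq_idx)
}

SHEET <- tibble::tibble(sample_id = c("a", "b"),
                        index = c("AAACCC", "GGGTTT"),
                        adapter = ADAPTER)

test_that("demultiplex verdicts across the three regimes", {
  ins <- strrep("GTCA", 6)  # 24-nt adapter-free insert

  # perfect index, consistent inline
  r <- make_mux_read(ins, "AAACCC", "AAACCC")
  expect_equal(demultiplex(r, SHEET, "strict_consistent")$verdict,
               "assigned_consistent")
  expect_equal(demultiplex(r, SHEET, "strict")$verdict,
               "assigned_unverifiable")

  # one index misread: mismatch1 assigns, strict rejects
  r1 <- make_mux_read(ins, "AAACCC", "AAACCG")
  expect_equal(demultiplex(r1, SHEET, "mismatch1")$assigned_sample, "a")
  d1s <- demultiplex(r1, SHEET, "strict")
  expect_equal(d1s$verdict, "rejected_index_mismatch")
  expect_true(is.na(d1s$assigned_sample))

  # mis-pairing: sequencer index = sample a, inline index = sample b
  r2 <- make_mux_read(ins, "GGGTTT", "AAACCC")
  d2 <- demultiplex(r2, SHEET, "strict_consistent")
  expect_equal(d2$verdict, "rejected_inconsistent")
  expect_true(is.na(d2$assigned_sample))
  expect_equal(d2$candidate_sample, "a")
  expect_equal(d2$inline_index, "GGGTTT")

  # unreadable inline index -> assigned but unverifiable
  long_ins <- strrep("GTCA", 15)  # 60 nt: adapter runs off the read end
  r3 <- make_mux_read(long_ins, "", "AAACCC")
  expect_equal(demultiplex(r3, SHEET, "strict_consistent")$verdict,
               "assigned_unverifiable")

  # missing sequencer index -> rejected outright
  r4 <- make_mux_read(ins, "AAACCC", NA_character_)
  expect_equal(demultiplex(r4, SHEET, "strict_consistent")$verdict,
               "rejected_index_mismatch")
})

test_that("close sample indices trigger the distance warning in mismatch1", {
  close_sheet <- tibble::tibble(sample_id = c("a", "b"),
                                index = c("AAACCC", "AAACCG"),
                                adapter = ADAPTER)
  r <- make_mux_read(strrep("GTCA", 6), "AAACCC", "AAACCC")
  expect_warning(demultiplex(r, close_sheet, "mismatch1"), "Hamming")
  # ambiguous read (distance 1 to both) is rejected, not guessed
  amb <- make_mux_read(strrep("GTCA", 6), "AAACCT", "AAACCT")
  expect_equal(suppressWarnings(
    demultiplex(amb, close_sheet, "mismatch1")$verdict),
    "rejected_index_mismatch")
})

test_that("stringency is monotone and ground-truth events are fully scored", {
  b <- tiny_bundle()
  specs <- list(
    a = synth_spec(800, seed = 51, index = "AAACCC"),
    b = synth_spec(800, seed = 52, index = "GGGTTT")
  )
  run <- generate_multiplexed_run(specs, b, clades = b$clades[1:2],
                                  index_misread_rate = 0.02,
                                  mispair_rate = 0.05, seed = 53)
  d1 <- demultiplex(run$reads, run$samples, "mismatch1")
  d2 <- demultiplex(run$reads, run$samples, "strict")
  d3 <- demultiplex(run$reads, run$samples, "strict_consistent")
  kept <- function(d) d$read_id[startsWith(d$verdict, "assigned")]
  expect_true(all(kept(d3) %in% kept(d2)))
  expect_true(all(kept(d2) %in% kept(d1)))

  tr <- merge(run$truth, d3, by = "read_id")
  # every readable mis-paired read is rejected as inconsistent
  mp <- tr[tr$event == "mispair" & !is.na(tr$inline_index), ]
  expect_gt(nrow(mp), 0)
  expect_true(all(mp$verdict == "rejected_inconsistent"))
  # no false rejections among clean reads
  clean <- tr[tr$event == "none", ]
  expect_true(all(startsWith(clean$verdict, "assigned")))
  # strict removes every misread index (sample indices are >= 3 apart, so
  # a misread cannot land on another valid index) ...
  tr2 <- merge(run$truth, d2, by = "read_id")
  misread <- tr2[tr2$event == "misread", ]
  expect_gt(nrow(misread), 0)
  expect_true(all(misread$verdict == "rejected_index_mismatch"))
  # ... but cannot catch mis-pairings: those carry a valid index and are
  # assigned to the wrong sample; only the inline-index filter removes them
  mp2 <- tr2[tr2$event == "mispair", ]
  expect_true(all(startsWith(mp2$verdict, "assigned")))
  expect_true(all(mp2$assigned_sample != mp2$sample_id))
})

test_that("mis-pairing alone: strict keeps everything, consistent cleans", {
  b <- tiny_bundle()
  specs <- list(
    a = synth_spec(500, seed = 61, index = "AAACCC"),
    b = synth_spec(500, seed = 62, index = "GGGTTT")
  )
  run <- generate_multiplexed_run(specs, b, clades = b$clades[1:2],
                                  index_misread_rate = 0,
                                  mispair_rate = 0.08, seed = 63)
  d2 <- demultiplex(run$reads, run$samples, "strict")
  expect_true(all(startsWith(d2$verdict, "assigned")))  # indices all valid
  d3 <- demultiplex(run$reads, run$samples, "strict_consistent")
  tr <- merge(run$truth, d3, by = "read_id")
  readable_mp <- tr[tr$event == "mispair" & !is.na(tr$inline_index), ]
  expect_true(all(readable_mp$verdict == "rejected_inconsistent"))
})

test_that("clean_run writes per-sample FASTQ with sequences untouched", {
  b <- tiny_bundle()
  specs <- list(
    a = synth_spec(300, seed = 71, index = "AAACCC"),
    b = synth_spec(300, seed = 72, index = "GGGTTT")
  )
  run <- generate_multiplexed_run(specs, b, clades = b$clades[1:2],
                                  index_misread_rate = 0.01,
                                  mispair_rate = 0.05, seed = 73)
  out_dir <- tempfile()
  res <- clean_run(run$reads, run$samples, out_dir = out_dir)
  expect_setequal(names(res$files), c("a", "b"))
  expect_true(all(file.exists(res$files)))

  back <- read_fastq(res$files[["a"]])
  # the writer embeds the index as a CASAVA description; match on the token
  back_ids <- sub(" .*$", "", back$read_id)
  orig <- run$reads[match(back_ids, run$reads$read_id), ]
  expect_equal(back$seq, orig$seq)
  expect_equal(back$qual, orig$qual)
  expect_equal(back$seq_index, orig$seq_index)

  # report counts partition the run
  verd_cols <- c("assigned_consistent", "assigned_unverifiable",
                 "rejected_index_mismatch", "rejected_inconsistent")
  expect_equal(sum(as.matrix(res$report[, verd_cols])), nrow(run$reads))

  # with zero corruption, strict_consistent output equals mismatch1 output
  clean0 <- generate_multiplexed_run(specs, b, clades = b$clades[1:2],
                                     seed = 74)
  r_strict <- clean_run(clean0$reads, clean0$samples, out_dir = tempfile())
  r_mm1 <- clean_run(clean0$reads, clean0$samples, mode = "mismatch1",
                     out_dir = tempfile())
  expect_equal(sort(read_fastq(r_strict$files[["a"]])$read_id),
               sort(read_fastq(r_mm1$files[["a"]])$read_id))

  # drop_unverifiable retains only consistent reads
  res_drop <- clean_run(run$reads, run$samples, out_dir = tempfile(),
                        drop_unverifiable = TRUE)
  kept_ids <- sub(" .*$", "",
                  unlist(lapply(res_drop$files,
                                function(f) read_fastq(f)$read_id)))
  dec <- res$decisions
  expect_setequal(kept_ids, dec$read_id[dec$verdict == "assigned_consistent"])
})
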