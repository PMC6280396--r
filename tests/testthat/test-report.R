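# Whole-sample QC and trace orchestration, report serialization.

make_entry <- function(reads, id, expected_clade = NA, species = "s01a") {
  list(config = sample_config(id, adapter = TRUSEQ_ADAPTER,
                              species = species,
                              expected_clade = expected_clade),
       reads = reads)
}

test_that("run_qc summaries satisfy the conservation identities", {
  b <- tiny_bundle()
  cc <- bundle_catalog(b)
  db <- bundle_db(b)
  smp <- generate_sample(synth_spec(2000, seed = 201,
                                    per_base_error_rate = 0.01,
                                    quality_mean = 28, quality_sd = 6),
                         b, b$clades[1])
  s <- run_qc(list(make_entry(smp$reads, "x1", b$clades[1])), db, cc,
              checkpoint_step = 250)[["x1"]]

  expect_equal(s$n_input, 2000L)
  # QC categories partition the input
  expect_equal(sum(s$qc_category_counts$reads), s$n_input)
  # PHRED histogram covers every input read
  expect_equal(sum(s$phred_histogram$reads), s$n_input)
  # length histogram covers all adapter-trimmed reads (input - low_quality)
  low_q <- s$qc_category_counts$reads[
    s$qc_category_counts$category == "discarded_low_quality"]
  expect_equal(sum(s$length_histogram$reads), s$n_input - low_q)
  # RNA types partition QC-passed reads
  expect_equal(sum(s$rna_type_counts$reads), s$n_qc_passed)
  # complexity endpoint equals the distinct precursor count
  expect_equal(s$complexity_curve$distinct_precursors[
    nrow(s$complexity_curve)], s$distinct_precursors)
})

test_that("mixed samples surface the contaminating clade in the report", {
  b <- tiny_bundle()
  cc <- bundle_catalog(b)
  db <- bundle_db(b)
  host <- generate_sample(synth_spec(2000, seed = 203), b, b$clades[1])
  cont <- generate_sample(synth_spec(400, seed = 204), b, b$clades[2])
  mix <- spike_mix(host, cont, fraction = 0.1, total_n = 2000, seed = 205)

  s <- run_qc(list(make_entry(mix$reads, "mix", b$clades[1])), db, cc,
              checkpoint_step = 500)[["mix"]]
  prof <- s$clade_profile
  expect_equal(unname(prof$read_counts[b$clades[2]]), 200L)
  expect_equal(unname(prof$composition[b$clades[2]]), 0.1)
  expect_equal(s$contamination$clade, b$clades[2])
})

test_that("a wrong configured adapter turns the library into artifacts", {
  b <- tiny_bundle()
  cc <- bundle_catalog(b)
  db <- bundle_db(b)
  smp <- generate_sample(synth_spec(800, seed = 207), b, b$clades[1])
  wrong <- list(config = sample_config("bad", adapter = "CTGTAGGCACCATCAAT",
                                       species = "s01a"),
                reads = smp$reads)
  s <- run_qc(list(wrong), db, cc, checkpoint_step = 500)[["bad"]]
  # the adapter is never recognized, and the unclipped adapter sequence
  # aligns to the artifact database
  unrec <- s$qc_category_counts$reads[
    s$qc_category_counts$category == "qc_passed_adapter_unrecognized"]
  expect_gt(unrec / s$n_input, 0.85)
  art <- s$rna_type_counts$reads[s$rna_type_counts$rna_type == "artifact"]
  expect_gt(art / s$n_qc_passed, 0.85)
  expect_true("mirna_content_flag" %in% s$flags)
})

test_that("report files are written, self-consistent, and reproducible", {
  b <- tiny_bundle()
  cc <- bundle_catalog(b)
  db <- bundle_db(b)
  smp <- generate_sample(synth_spec(1000, seed = 209), b, b$clades[1])
  entries <- list(make_entry(smp$reads, "s1", b$clades[1]))

  od <- tempfile()
  run_qc(entries, db, cc, output_dir = od, checkpoint_step = 250)
  expect_true(all(file.exists(file.path(od, c(
    "summary.json", "report.html", "phred.tsv", "length_distribution.tsv",
    "qc_stats.tsv", "rna_types.tsv", "complexity.tsv",
    "clade_read_counts.tsv", "clade_unique_sequence_counts.tsv")))))

  js <- jsonlite::read_json(file.path(od, "summary.json"))
  expect_equal(js[[1]]$n_input, 1000L)
  tab <- read.delim(file.path(od, "clade_read_counts.tsv"))
  expect_equal(sum(tab$reads), js[[1]]$total_clade_specific_reads)

  # rerun on identical input: identical JSON bytes
  od2 <- tempfile()
  run_qc(entries, db, cc, output_dir = od2, checkpoint_step = 250)
  expect_identical(readLines(file.path(od, "summary.json")),
                   readLines(file.path(od2, "summary.json")))
})

test_that("run_trace profiles single-clade samples as single-coloured bars", {
  b <- tiny_bundle()
  cc <- bundle_catalog(b)
  entries <- lapply(seq_along(b$clades), function(i) {
    smp <- generate_sample(synth_spec(400, seed = 210 + i), b, b$clades[i])
    make_entry(smp$reads, paste0("cl_", b$clades[i]))
  })
  od <- tempfile()
  profiles <- run_trace(entries, cc, output_dir = od)
  for (i in seq_along(b$clades)) {
    p <- profiles[[paste0("cl_", b$clades[i])]]
    expect_equal(unname(p$composition[b$clades[i]]), 1.0)
  }
  expect_true(file.exists(file.path(od, "clade_read_counts.tsv")))
  expect_true(file.exists(file.path(od, "clade_composition.png")))

  # empty sample: profile renders with zero clade-specific reads
  empty_entry <- make_entry(make_reads(strrep("CGT", 20)), "empty")
  p0 <- run_trace(list(empty_entry), cc)[["empty"]]
  expect_equal(p0$total_clade_specific_reads, 0L)
})

test_that("species-mode tracing resolves each sample to its species", {
  mature <- tibble::tibble(
    id = sprintf("sp%02d-novel-1", 1:12),
    seq = withr::with_seed(213, stringi::stri_rand_strings(12, 22, "[ACGT]"))
  )
  cs <- build_species_catalog(mature)
  for (i in c(1, 6, 12)) {
    reads <- make_reads(rep(mature$seq[i], 30))
    got <- assign_species(reads$seq, cs)
    expect_true(all(got == sprintf("sp%02d", i)))
  }
})
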